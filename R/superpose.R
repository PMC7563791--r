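# Rigid-body superposition and the fluctuation/displacement observables
# built on it. All RMSD here is plain (unweighted) coordinate RMSD; a
# weights argument is accepted where mass weighting could matter.

.centroid <- function(xyz, w = NULL) {
  if (is.null(w)) colMeans(xyz) else colSums(xyz * w) / sum(w)
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' \code{mobile} onto \code{reference}. Reflections are corrected so the
#' rotation determinant is +1. The fitted mobile coordinates are
#' \code{mobile \%*\% rotation + translation} (rows are points).
#'
#' @param mobile n x 3 coordinates to move.
#' @param reference n x 3 target coordinates.
#' @param weights optional per-point weights (e.g. masses).
#' @return list of class \code{superposition} with \code{rotation} (3 x 3),
#'   \code{translation} (length 3) and \code{rmsd} (Angstrom, the minimised
#'   value over the fitted points).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3) stop("need at least 3 points for superposition")
  pm <- .centroid(mobile, weights)
  qm <- .centroid(reference, weights)
  P <- sweep(mobile, 2, pm)
  Q <- sweep(reference, 2, qm)
  if (!is.null(weights)) {
    sw <- sqrt(weights / sum(weights))
    C <- crossprod(P * sw, Q * sw)
  } else {
    C <- crossprod(P, Q)
  }
  # rank check: all points collinear makes the rotation about the line free
  sv <- svd(C)
  if (sv$d[1] > 0 && sv$d[2] / sv$d[1] < 1e-10) {
    # covariance may be rank-deficient because the point set itself is
    pc <- svd(P)$d
    if (pc[2] / max(pc[1], .Machine$double.eps) < 1e-8)
      stop("degenerate (collinear) point set: superposition not unique")
  }
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  if (is.null(weights)) {
    rmsd <- sqrt(sum((fitted - Q)^2) / n)
  } else {
    rmsd <- sqrt(sum(weights * rowSums((fitted - Q)^2)) / sum(weights))
  }
  structure(list(rotation = R, translation = as.numeric(qm - pm %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param xyz n x 3 coordinates.
#' @param fit a \code{superposition}.
#' @return transformed n x 3 coordinates.
#' @export
apply_superposition <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, "+")
}

# Fit frame coordinates onto reference over fit_idx, return transformed full
# coordinate matrix.
.fit_frame <- function(xyz, ref_xyz, fit_idx) {
  fit <- kabsch(xyz[fit_idx, , drop = FALSE], ref_xyz[fit_idx, , drop = FALSE])
  apply_superposition(xyz, fit)
}

#' RMSD time series of a trajectory against a reference structure
#'
#' Each frame is least-squares fitted to the reference on \code{fit_sel},
#' and the RMSD is then evaluated on \code{measure_sel}. Fitting and
#' measuring on different selections reproduces per-domain analyses (fit on
#' one domain, measure another); by default the two coincide.
#'
#' @param trajectory an \code{md_trajectory}.
#' @param fit_sel selection used for fitting.
#' @param measure_sel selection used for the RMSD; defaults to
#'   \code{fit_sel}.
#' @param reference an \code{md_structure}; defaults to the iterative
#'   average structure of the trajectory.
#' @return data.frame with columns \code{time_ns} and \code{rmsd}.
#' @export
rmsd_series <- function(trajectory, fit_sel, measure_sel = fit_sel,
                        reference = NULL) {
  topo <- trajectory$topology
  if (is.null(reference)) reference <- average_structure(trajectory, fit_sel)
  fi <- resolve_selection(topo, fit_sel)
  mi <- resolve_selection(topo, measure_sel)
  fr <- resolve_selection(reference, fit_sel)
  mr <- resolve_selection(reference, measure_sel)
  if (length(fi) != length(fr) || length(mi) != length(mr))
    stop("selection resolves to different atom counts on trajectory and reference")
  ref_xyz <- coords(reference)
  vals <- vapply(trajectory$frames, function(f) {
    fit <- kabsch(f[fi, , drop = FALSE], ref_xyz[fr, , drop = FALSE])
    moved <- apply_superposition(f[mi, , drop = FALSE], fit)
    coord_rmsd(moved, ref_xyz[mr, , drop = FALSE])
  }, numeric(1))
  data.frame(time_ns = frame_times(trajectory), rmsd = vals)
}

#' Iterative average structure of a trajectory
#'
#' Repeatedly fits every frame to the running mean on \code{fit_sel} and
#' recomputes the mean, until the mean moves by less than \code{tol}
#' (RMSD between successive means) or \code{max_iter} iterations.
#'
#' @param trajectory an \code{md_trajectory}.
#' @param fit_sel selection used for fitting.
#' @param tol convergence tolerance in Angstrom (default 1e-4, below PDB
#'   coordinate precision).
#' @param max_iter iteration cap; on hitting it a warning is issued and the
#'   last mean returned.
#' @return an \code{md_structure} with the averaged coordinates.
#' @export
average_structure <- function(trajectory, fit_sel = atom_selection(),
                              tol = 1e-4, max_iter = 50) {
  topo <- trajectory$topology
  fi <- resolve_selection(topo, fit_sel)
  mean_xyz <- trajectory$frames[[1]]
  nf <- n_frames(trajectory)
  if (nf == 1) return(set_coords(topo, mean_xyz))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    acc <- matrix(0, nrow(mean_xyz), 3)
    for (f in trajectory$frames)
      acc <- acc + .fit_frame(f, mean_xyz, fi)
    new_mean <- acc / nf
    shift <- coord_rmsd(new_mean, mean_xyz)
    mean_xyz <- new_mean
    if (shift < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("average structure not converged after %d iterations",
                    max_iter))
  set_coords(topo, mean_xyz)
}

.residue_keys <- function(atoms) paste(atoms$chain, atoms$resno, sep = "|")

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of atomic positions about the iterative
#' average structure, after fitting every frame on \code{fit_sel}. The
#' per-atom RMSF is averaged over backbone atoms within each residue; the
#' per-atom values are attached as an attribute.
#'
#' @param trajectory an \code{md_trajectory} with at least 2 frames.
#' @param fit_sel selection used for fitting.
#' @param group_atoms atom class averaged per residue (default backbone).
#' @return data.frame (class \code{residue_profile}) with columns
#'   \code{chain}, \code{resno}, \code{value} (Angstrom); per-atom RMSF in
#'   \code{attr(, "atom_rmsf")}.
#' @export
rmsf_profile <- function(trajectory, fit_sel = atom_selection(),
                         group_atoms = "backbone") {
  if (n_frames(trajectory) < 2)
    stop("RMSF requires at least 2 frames")
  topo <- trajectory$topology
  fi <- resolve_selection(topo, fit_sel)
  avg <- average_structure(trajectory, fit_sel)
  avg_xyz <- coords(avg)
  msf <- matrix(0, n_atoms(topo), 1)
  for (f in trajectory$frames) {
    d <- .fit_frame(f, avg_xyz, fi) - avg_xyz
    msf <- msf + rowSums(d^2)
  }
  atom_rmsf <- sqrt(msf[, 1] / n_frames(trajectory))
  gi <- resolve_selection(topo, atom_selection(atoms = group_atoms))
  a <- topo$atoms[gi, , drop = FALSE]
  key <- .residue_keys(a)
  per_res <- tapply(atom_rmsf[gi], key, mean)
  ord <- match(unique(key), names(per_res))
  out <- data.frame(
    chain = a$chain[!duplicated(key)],
    resno = a$resno[!duplicated(key)],
    value = as.numeric(per_res[ord])
  )
  attr(out, "atom_rmsf") <- atom_rmsf
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Difference of two per-residue profiles
#'
#' Elementwise \code{a - b}; results may be negative (e.g. flexibility lost
#' on complexation). Residue keys must coincide.
#'
#' @param a,b \code{residue_profile} data.frames with identical residue keys.
#' @return a \code{residue_profile} of differences.
#' @export
profile_difference <- function(a, b) {
  ka <- paste(a$chain, a$resno, sep = "|")
  kb <- paste(b$chain, b$resno, sep = "|")
  if (!identical(sort(ka), sort(kb))) {
    sd <- union(setdiff(ka, kb), setdiff(kb, ka))
    stop("residue keys differ between profiles: ",
         paste(sd, collapse = ", "))
  }
  out <- a
  out$value <- a$value - b$value[match(ka, kb)]
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Per-residue displacement map between two structures
#'
#' Fits \code{b} onto \code{a} over \code{fit_sel}, then reports the mean
#' backbone-atom displacement per residue (over residues present in both).
#' Fitting on a rigid core and excluding a moving element exposes that
#' element's displacement.
#'
#' @param a reference \code{md_structure}.
#' @param b \code{md_structure} to compare.
#' @param fit_sel selection used for the rigid fit.
#' @param group_atoms atom class averaged per residue (default backbone).
#' @return a \code{residue_profile} of displacements (Angstrom, >= 0).
#' @export
displacement_map <- function(a, b, fit_sel = atom_selection(),
                             group_atoms = "backbone") {
  ka <- paste(a$atoms$chain, a$atoms$resno, a$atoms$name, sep = "|")
  kb <- paste(b$atoms$chain, b$atoms$resno, b$atoms$name, sep = "|")
  common <- intersect(ka, kb)
  if (length(common) == 0) stop("structures share no common atoms")
  ia <- match(common, ka); ib <- match(common, kb)
  sa <- subset_structure(a, ia)
  sb <- subset_structure(b, ib)
  fi <- resolve_selection(sa, fit_sel)
  fit <- kabsch(coords(sb)[fi, , drop = FALSE], coords(sa)[fi, , drop = FALSE])
  moved <- apply_superposition(coords(sb), fit)
  disp <- sqrt(rowSums((moved - coords(sa))^2))
  gi <- resolve_selection(sa, atom_selection(atoms = group_atoms))
  at <- sa$atoms[gi, , drop = FALSE]
  key <- .residue_keys(at)
  per_res <- tapply(disp[gi], key, mean)
  ord <- match(unique(key), names(per_res))
  out <- data.frame(
    chain = at$chain[!duplicated(key)],
    resno = at$resno[!duplicated(key)],
    value = as.numeric(per_res[ord])
  )
  class(out) <- c("residue_profile", "data.frame")
  out
}
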