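# GROMOS conformational clustering on a pairwise-RMSD matrix, with
# dwell-time filtering and medoid representatives.

#' Pairwise RMSD matrix of a trajectory
#'
#' Entry (i, j) is the Kabsch-fitted RMSD between frames i and j on the
#' given selection.
#'
#' @param trajectory an \code{md_trajectory} with at least 2 frames.
#' @param sel selection the RMSD is computed on (e.g. backbone).
#' @return symmetric n x n matrix of class \code{rmsd_matrix} (Angstrom),
#'   zero diagonal.
#' @export
pairwise_rmsd <- function(trajectory, sel = atom_selection(atoms = "backbone")) {
  nf <- n_frames(trajectory)
  if (nf < 2) stop("pairwise RMSD needs at least 2 frames")
  if (nf > 20000)
    stop("pairwise RMSD matrix held in memory: limited to 20000 frames, got ",
         nf, "; stride the trajectory first")
  idx <- resolve_selection(trajectory$topology, sel)
  n <- length(idx)
  # pre-centre each frame's selected coordinates; the fitted msd then
  # follows from the singular values of the cross-covariance
  cent <- lapply(trajectory$frames, function(f) {
    x <- f[idx, , drop = FALSE]
    sweep(x, 2, colMeans(x))
  })
  ss <- vapply(cent, function(x) sum(x^2), numeric(1))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    Pi <- cent[[i]]
    for (j in (i + 1):nf) {
      C <- crossprod(Pi, cent[[j]])
      sv <- svd(C, nu = 0, nv = 0)$d
      d <- sign(det(C))
      if (d < 0) sv[3] <- -sv[3]
      msd <- (ss[i] + ss[j] - 2 * sum(sv)) / n
      m[i, j] <- m[j, i] <- sqrt(max(msd, 0))
    }
  }
  class(m) <- c("rmsd_matrix", class(m))
  m
}

#' GROMOS clustering of a pairwise-RMSD matrix
#'
#' Greedy neighbour clustering: the frame with the most neighbours within
#' \code{cutoff} becomes a cluster centre, it and its neighbours are removed,
#' and the scan repeats until no frames remain. Ties on neighbour count are
#' broken toward the lowest frame index. Every frame is assigned to exactly
#' one cluster; clusters whose dwell time (member count x \code{dt_ns})
#' falls strictly below \code{min_dwell_ns} are then marked discarded (a
#' dwell time exactly equal to the threshold is retained). Each cluster's
#' representative is its medoid: the member minimising the summed RMSD to
#' its co-members; the greedy centre is also recorded.
#'
#' @param m an \code{rmsd_matrix} (or plain symmetric matrix, Angstrom).
#' @param cutoff neighbour cutoff in Angstrom (default 1.5 on backbone
#'   atoms, the standard choice for domain-scale substates).
#' @param dt_ns frame interval in ns used to convert counts to dwell times.
#' @param min_dwell_ns dwell-time threshold in ns (default 100).
#' @return object of class \code{cluster_set}: list with \code{assignments}
#'   (frame -> cluster id), \code{clusters} (data.frame: id, size, dwell_ns,
#'   percent, representative, center, retained, ordered by size descending)
#'   \code{members} (list of member index vectors), plus the parameters.
#' @export
gromos_cluster <- function(m, cutoff = 1.5, dt_ns = 1, min_dwell_ns = 100) {
  m <- unclass(m)
  n <- nrow(m)
  if (is.null(n) || n < 1) stop("empty RMSD matrix")
  if (cutoff <= 0) stop("cutoff must be positive")
  adj <- m <= cutoff
  remaining <- rep(TRUE, n)
  assignments <- integer(n)
  members <- list()
  centers <- integer(0)
  k <- 0
  while (any(remaining)) {
    live <- which(remaining)
    # neighbour count among remaining frames, including the frame itself
    counts <- colSums(adj[live, live, drop = FALSE])
    center <- live[which.max(counts)]  # which.max takes the first maximum
    mem <- live[adj[live, center]]
    k <- k + 1
    assignments[mem] <- k
    members[[k]] <- mem
    centers[k] <- center
    remaining[mem] <- FALSE
  }
  sizes <- lengths(members)
  ord <- order(-sizes, seq_along(sizes))
  members <- members[ord]
  centers <- centers[ord]
  sizes <- sizes[ord]
  relabel <- match(seq_along(ord), ord)
  assignments <- relabel[assignments]
  medoid <- vapply(members, function(mem) {
    if (length(mem) == 1) return(mem)
    s <- rowSums(m[mem, mem, drop = FALSE])
    mem[which.min(s)]
  }, integer(1))
  dwell <- sizes * dt_ns
  clusters <- data.frame(
    id = seq_along(members),
    size = sizes,
    dwell_ns = dwell,
    percent = 100 * sizes / n,
    representative = medoid,
    center = centers,
    retained = dwell >= min_dwell_ns
  )
  structure(list(assignments = assignments, clusters = clusters,
                 members = members, cutoff = cutoff, dt_ns = dt_ns,
                 min_dwell_ns = min_dwell_ns),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (%d retained), cutoff %.2f A, min dwell %g ns\n",
              nrow(x$clusters), sum(x$clusters$retained), x$cutoff,
              x$min_dwell_ns))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Cluster summary table
#' @param object a \code{cluster_set}.
#' @param ... ignored.
#' @return the \code{clusters} data.frame (id, size, percent, dwell_ns, ...).
#' @export
summary.cluster_set <- function(object, ...) object$clusters

#' Per-frame cluster assignment table
#' @param x a \code{cluster_set}.
#' @param t0_ns,dt_ns optional timing to add a time_ns column.
#' @param ... ignored.
#' @return data.frame (frame, time_ns, cluster_id, retained, is_representative).
#' @export
as.data.frame.cluster_set <- function(x, t0_ns = 0, dt_ns = x$dt_ns, ...) {
  n <- length(x$assignments)
  cl <- x$assignments
  data.frame(
    frame = seq_len(n),
    time_ns = t0_ns + (seq_len(n) - 1) * dt_ns,
    cluster_id = cl,
    retained = x$clusters$retained[cl],
    is_representative = seq_len(n) %in% x$clusters$representative
  )
}

#' Representative structure of a cluster
#'
#' Returns the medoid frame of a retained cluster as a structure — the
#' member closest (in summed RMSD) to all its co-members, standing in for
#' "the structure closest to the centre" of the cluster.
#'
#' @param trajectory the \code{md_trajectory} the clustering was run on.
#' @param clusters a \code{cluster_set}.
#' @param cluster_id id of a retained cluster.
#' @param which \code{"medoid"} (default) or \code{"center"} (the greedy
#'   most-neighbours frame).
#' @return an \code{md_structure}.
#' @export
representative_structure <- function(trajectory, clusters, cluster_id,
                                     which = c("medoid", "center")) {
  which <- match.arg(which)
  cl <- clusters$clusters
  row <- cl[cl$id == cluster_id, ]
  if (nrow(row) == 0) stop("unknown cluster id: ", cluster_id)
  if (!row$retained)
    stop("cluster ", cluster_id, " was discarded by the dwell-time filter")
  idx <- if (which == "medoid") row$representative else row$center
  frame_structure(trajectory, idx)
}
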