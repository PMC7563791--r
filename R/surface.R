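# Solvent-accessible surface area and interface shape complementarity.
#
# Two independent SASA backends are provided: a slice-based Lee-Richards
# integration (the default used throughout the package) and a Shrake-Rupley
# point quadrature (used as a numerical cross-check). Gap volume follows the
# SURFNET construction: gap spheres grown between the two chains' surfaces,
# shrunk away from intruding atoms, and integrated as a union of spheres.
# Hydrogens are excluded from all surface computation (united-atom radii).

# total measure covered on a circle (circumference 2*pi) by angular
# intervals [centre - half, centre + half]; full == TRUE marks full cover
.covered_arc <- function(centre, half) {
  if (length(centre) == 0) return(0)
  a <- (centre - half) %% (2 * pi)
  b <- a + 2 * half
  wrap <- b > 2 * pi
  starts <- c(a, rep(0, sum(wrap)))
  ends <- c(pmin(b, 2 * pi), b[wrap] - 2 * pi)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0
  cur_s <- starts[1]; cur_e <- ends[1]
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= cur_e) {
      cur_e <- max(cur_e, ends[k])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- starts[k]; cur_e <- ends[k]
    }
  }
  tot + (cur_e - cur_s)
}

.surface_atoms <- function(structure, include_hydrogens) {
  a <- structure$atoms
  idx <- if (include_hydrogens) seq_len(nrow(a)) else which(a$elem != "H")
  if (length(idx) == 0) stop("no atoms left for surface computation")
  key <- paste(round(a$x[idx], 6), round(a$y[idx], 6), round(a$z[idx], 6))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate atom position(s) treated as one")
  }
  list(idx = idx, dup = dup)
}

#' Lee-Richards solvent-accessible surface area
#'
#' Slice-based integration of the solvent-accessible surface: each atom's
#' sphere is expanded by the probe radius and cut into z-slices; on every
#' slice the arc of the atom's circle not covered by neighbouring circles
#' contributes its accessible fraction of the slab area. Hydrogens are
#' excluded by default; atoms duplicated at identical coordinates are
#' counted once (with a warning).
#'
#' @param structure an \code{md_structure} (radii from its \code{vdw} column).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param slice_dz slice thickness in Angstrom (default 0.1; accuracy is
#'   roughly proportional to \code{slice_dz}).
#' @param include_hydrogens include H atoms (default FALSE).
#' @return list of class \code{sasa_result}: \code{atom_area} (per input
#'   atom, 0 for excluded atoms), \code{total}, \code{probe}.
#' @export
lee_richards_sasa <- function(structure, probe = 1.4, slice_dz = 0.1,
                              include_hydrogens = FALSE) {
  if (probe < 0) stop("probe radius must be >= 0")
  if (slice_dz <= 0) stop("slice_dz must be positive")
  sa <- .surface_atoms(structure, include_hydrogens)
  use <- sa$idx[!sa$dup]
  at <- structure$atoms[use, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$vdw + probe
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can intersect atom i's
    dvec <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(dvec^2)
    nb <- which(d2 < (R[i] + R)^2 & d2 > 1e-12)
    dx <- dvec[nb, 1]; dy <- dvec[nb, 2]; dz_nb <- dvec[nb, 3]
    dxy2 <- dx^2 + dy^2
    dxy <- sqrt(dxy2)
    theta <- atan2(dy, dx)
    Rj <- R[nb]
    # slabs span [-R, R] exactly: an isolated sphere integrates to 4*pi*R^2
    nsl <- max(1L, ceiling(2 * R[i] / slice_dz))
    dz_i <- 2 * R[i] / nsl
    zs <- -R[i] + (seq_len(nsl) - 0.5) * dz_i
    area_i <- 0
    for (z in zs) {
      ri2 <- R[i]^2 - z^2
      if (ri2 <= 0) next
      ri <- sqrt(ri2)
      if (length(nb) == 0) { area_i <- area_i + 1; next }  # full circle
      dzj <- z - dz_nb
      act <- which(abs(dzj) < Rj)
      if (length(act) == 0) { area_i <- area_i + 1; next }
      rj2 <- Rj[act]^2 - dzj[act]^2
      rj <- sqrt(rj2)
      dj <- dxy[act]
      # circle i fully engulfed by a neighbour circle on this slice
      if (any(dj + ri <= rj)) next
      # neighbours that actually cut the perimeter of circle i
      cut <- dj < ri + rj & dj + rj > ri & dj > 0
      if (!any(cut)) { area_i <- area_i + 1; next }
      cosa <- (dj[cut]^2 + ri2 - rj2[cut]) / (2 * dj[cut] * ri)
      cosa <- pmin(1, pmax(-1, cosa))
      covered <- .covered_arc(theta[act][cut], acos(cosa))
      area_i <- area_i + max(0, 1 - covered / (2 * pi))
    }
    # each fully accessible slab of a sphere contributes 2*pi*R*dz
    areas[i] <- area_i * 2 * pi * R[i] * dz_i
  }
  atom_area <- numeric(n_atoms(structure))
  atom_area[use] <- areas
  structure(list(atom_area = atom_area, total = sum(areas), probe = probe),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.2f A^2 (probe %.2f A, %d contributing atoms)\n",
              x$total, x$probe, sum(x$atom_area > 0)))
  invisible(x)
}

# near-uniform points on the unit sphere (golden-spiral lattice)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-quadrature SASA: a near-uniform lattice of test points is placed on
#' each atom's probe-expanded sphere and points buried inside any
#' neighbouring expanded sphere are removed. Algorithmically independent of
#' \code{\link{lee_richards_sasa}}; the two agree to within the quadrature
#' resolution and serve as mutual numerical checks.
#'
#' @param structure an \code{md_structure}.
#' @param probe probe radius in Angstrom.
#' @param n_points test points per atom (default 10000).
#' @param include_hydrogens include H atoms (default FALSE).
#' @return a \code{sasa_result}.
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 10000,
                               include_hydrogens = FALSE) {
  if (probe < 0) stop("probe radius must be >= 0")
  sa <- .surface_atoms(structure, include_hydrogens)
  use <- sa$idx[!sa$dup]
  at <- structure$atoms[use, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  R <- at$vdw + probe
  n <- nrow(xyz)
  unit <- .sphere_points(n_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    dvec <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(dvec^2)
    nb <- which(d2 < (R[i] + R)^2 & d2 > 1e-12)
    pts <- unit * R[i]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- dvec[j, ]
      inside <- (pts[, 1] - dd[1])^2 + (pts[, 2] - dd[2])^2 +
        (pts[, 3] - dd[3])^2 < R[j]^2
      free <- free & !inside
      if (!any(free)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(free)
  }
  atom_area <- numeric(n_atoms(structure))
  atom_area[use] <- areas
  structure(list(atom_area = atom_area, total = sum(areas), probe = probe),
            class = "sasa_result")
}

# ---------------------------------------------------------------------------
# Gap volume (union of inter-chain gap spheres)

#' Volume of a union of spheres
#'
#' Integrates the union of spheres either on a cubic grid (counting grid
#' cells whose centre lies in any sphere) or by Monte-Carlo sampling of the
#' bounding box. The two routes are algorithmically independent.
#'
#' @param spheres data.frame with columns \code{x}, \code{y}, \code{z},
#'   \code{r} (Angstrom). Zero rows give volume 0.
#' @param grid grid spacing in Angstrom (grid method).
#' @param method \code{"grid"} or \code{"mc"}.
#' @param n_points Monte-Carlo sample size (mc method). Uses the current
#'   RNG state; seed outside for reproducibility.
#' @return volume in cubic Angstrom.
#' @export
sphere_union_volume <- function(spheres, grid = 0.5,
                                method = c("grid", "mc"), n_points = 1e6) {
  method <- match.arg(method)
  if (is.null(spheres) || nrow(spheres) == 0) return(0)
  lo <- c(min(spheres$x - spheres$r), min(spheres$y - spheres$r),
          min(spheres$z - spheres$r))
  hi <- c(max(spheres$x + spheres$r), max(spheres$y + spheres$r),
          max(spheres$z + spheres$r))
  if (method == "mc") {
    pts <- cbind(stats::runif(n_points, lo[1], hi[1]),
                 stats::runif(n_points, lo[2], hi[2]),
                 stats::runif(n_points, lo[3], hi[3]))
    inside <- rep(FALSE, n_points)
    for (s in seq_len(nrow(spheres))) {
      inside <- inside |
        ((pts[, 1] - spheres$x[s])^2 + (pts[, 2] - spheres$y[s])^2 +
           (pts[, 3] - spheres$z[s])^2 < spheres$r[s]^2)
    }
    return(prod(hi - lo) * mean(inside))
  }
  gx <- seq(lo[1] + grid / 2, hi[1], by = grid)
  gy <- seq(lo[2] + grid / 2, hi[2], by = grid)
  gz <- seq(lo[3] + grid / 2, hi[3], by = grid)
  occ <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
  for (s in seq_len(nrow(spheres))) {
    ix <- which(abs(gx - spheres$x[s]) <= spheres$r[s])
    iy <- which(abs(gy - spheres$y[s]) <= spheres$r[s])
    iz <- which(abs(gz - spheres$z[s]) <= spheres$r[s])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - spheres$x[s])^2
    dy2 <- (gy[iy] - spheres$y[s])^2
    dz2 <- (gz[iz] - spheres$z[s])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    occ[ix, iy, iz] <- occ[ix, iy, iz] | (d2 < spheres$r[s]^2)
  }
  sum(occ) * grid^3
}

#' Gap spheres between two chain sets
#'
#' Constructs the set of gap spheres between the van der Waals surfaces of
#' two chain sets: for every inter-chain heavy-atom pair, an initial sphere
#' is centred midway between the two atomic surfaces with radius
#' (d - r_a - r_b)/2; pairs whose initial radius exceeds \code{r_max} are
#' skipped; the sphere is then shrunk in 0.1 Angstrom steps, recentring away
#' from the most-penetrating third atom, until no atom penetrates (at most
#' 50 iterations); spheres ending below \code{r_min} are discarded.
#'
#' @param complex an \code{md_structure} containing both chain sets.
#' @param chains_A,chains_B disjoint chain-id sets.
#' @param r_min minimum retained sphere radius (Angstrom, default 1.0).
#' @param r_max maximum initial sphere radius (Angstrom, default 5.0).
#' @return data.frame of retained spheres (x, y, z, r).
#' @export
gap_spheres <- function(complex, chains_A, chains_B,
                        r_min = 1.0, r_max = 5.0) {
  if (r_min >= r_max) stop("r_min must be < r_max")
  a <- complex$atoms
  heavy <- a$elem != "H"
  ia <- which(heavy & a$chain %in% chains_A)
  ib <- which(heavy & a$chain %in% chains_B)
  if (!length(ia) || !length(ib)) stop("empty chain set")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- a$vdw
  all_idx <- which(heavy)
  res <- list()
  for (i in ia) {
    dvec <- sweep(xyz[ib, , drop = FALSE], 2, xyz[i, ], "-")
    d <- sqrt(rowSums(dvec^2))
    rg0 <- (d - rad[i] - rad[ib]) / 2
    cand <- which(rg0 > 0 & rg0 <= r_max)
    for (kk in cand) {
      j <- ib[kk]
      u <- dvec[kk, ] / d[kk]
      rg <- rg0[kk]
      centre <- xyz[i, ] + u * (rad[i] + rg)
      ok <- FALSE
      for (iter in seq_len(50)) {
        dd <- sweep(xyz[all_idx, , drop = FALSE], 2, centre, "-")
        pen <- rad[all_idx] + rg - sqrt(rowSums(dd^2))
        pen[all_idx %in% c(i, j)] <-
          pmin(pen[all_idx %in% c(i, j)], 0)  # tangency to the seed pair
        worst <- which.max(pen)
        if (pen[worst] <= 1e-6) { ok <- TRUE; break }
        rg <- rg - 0.1
        if (rg < r_min) break
        away <- -dd[worst, ]
        nrm <- sqrt(sum(away^2))
        if (nrm > 1e-9) centre <- centre + away / nrm * 0.1
      }
      if (ok && rg >= r_min)
        res[[length(res) + 1]] <- c(centre, rg)
    }
  }
  if (length(res) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      r = numeric(0)))
  m <- do.call(rbind, res)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], r = m[, 4])
}

#' Gap volume between two chain sets
#'
#' Volume of the union of the retained gap spheres (see
#' \code{\link{gap_spheres}}), integrated on a cubic grid.
#'
#' @inheritParams gap_spheres
#' @param grid integration grid spacing in Angstrom (default 0.5).
#' @return gap volume in cubic Angstrom; the retained spheres are attached
#'   as attribute \code{"spheres"}.
#' @export
gap_volume <- function(complex, chains_A, chains_B,
                       r_min = 1.0, r_max = 5.0, grid = 0.5) {
  if (grid <= 0) stop("grid spacing must be positive")
  sp <- gap_spheres(complex, chains_A, chains_B, r_min, r_max)
  v <- sphere_union_volume(sp, grid = grid, method = "grid")
  attr(v, "spheres") <- sp
  v
}

#' Interface complementarity report for a two-chain-set complex
#'
#' Computes the accessible surface areas of the isolated chain sets and of
#' the complex, the change of accessible surface area on binding
#' (Delta-ASA = asa_A + asa_B - asa_AB), the single-sided interface area
#' (Delta-ASA / 2), the inter-chain gap volume, and the gap index
#' (gap volume / interface area, Angstrom) — low gap index means tight
#' shape complementarity. When the chains make no contact the gap index is
#' undefined and reported as NA with \code{gap_index_defined = FALSE}.
#'
#' @param complex an \code{md_structure} containing both chain sets.
#' @param chains_A,chains_B disjoint, non-empty chain-id sets.
#' @param probe probe radius (Angstrom, default 1.4).
#' @param slice_dz Lee-Richards slice thickness (default 0.1).
#' @param r_min,r_max,grid gap-sphere parameters (see
#'   \code{\link{gap_spheres}}).
#' @return list of class \code{interface_report} with fields \code{asa_A},
#'   \code{asa_B}, \code{asa_AB}, \code{delta_asa}, \code{interface_area}
#'   (A^2), \code{gap_volume} (A^3), \code{gap_index} (A),
#'   \code{gap_index_defined}.
#' @export
interface_report <- function(complex, chains_A, chains_B, probe = 1.4,
                             slice_dz = 0.1, r_min = 1.0, r_max = 5.0,
                             grid = 0.5) {
  if (length(intersect(chains_A, chains_B)) > 0)
    stop("chain sets must be disjoint")
  a <- complex$atoms
  ia <- which(a$chain %in% chains_A)
  ib <- which(a$chain %in% chains_B)
  if (!length(ia) || !length(ib)) stop("empty chain set")
  sA <- subset_structure(complex, ia)
  sB <- subset_structure(complex, ib)
  sAB <- subset_structure(complex, sort(c(ia, ib)))
  asa_A <- lee_richards_sasa(sA, probe, slice_dz)$total
  asa_B <- lee_richards_sasa(sB, probe, slice_dz)$total
  asa_AB <- lee_richards_sasa(sAB, probe, slice_dz)$total
  delta <- asa_A + asa_B - asa_AB
  iface <- delta / 2
  gv <- as.numeric(gap_volume(complex, chains_A, chains_B, r_min, r_max, grid))
  defined <- iface > 1e-6
  structure(list(
    asa_A = asa_A, asa_B = asa_B, asa_AB = asa_AB,
    delta_asa = delta, interface_area = iface,
    gap_volume = gv,
    gap_index = if (defined) gv / iface else NA_real_,
    gap_index_defined = defined
  ), class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0(
    "interface_report:\n",
    "  ASA(A) %.1f  ASA(B) %.1f  ASA(AB) %.1f A^2\n",
    "  Delta-ASA %.1f A^2, interface area %.1f A^2\n",
    "  gap volume %.1f A^3, gap index %s\n"),
    x$asa_A, x$asa_B, x$asa_AB, x$delta_asa, x$interface_area,
    x$gap_volume,
    if (x$gap_index_defined) sprintf("%.2f A", x$gap_index) else
      "undefined (no contact)"))
  invisible(x)
}

#' @export
as.data.frame.interface_report <- function(x, ...) {
  data.frame(asa_A = x$asa_A, asa_B = x$asa_B, asa_AB = x$asa_AB,
             delta_asa = x$delta_asa, interface_area = x$interface_area,
             gap_volume = x$gap_volume, gap_index = x$gap_index)
}
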