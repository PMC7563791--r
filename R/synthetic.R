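# Generators for structures and trajectories with planted, recoverable
# properties: ideal helices, helix pairs at a chosen crossing angle,
# two-chain complexes with a controlled inter-surface gap, multistate
# trajectories with contiguous substate blocks, and random atom packings.
# Every generator is deterministic under its seed argument; the global RNG
# state is restored on exit.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# rotation taking +z onto unit vector u
.rotation_z_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * u[3] - z[3] * u[2],
         z[3] * u[1] - z[1] * u[3],
         z[1] * u[2] - z[2] * u[1])
  c_ <- sum(z * u)
  if (sum(v^2) < 1e-16) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 deg about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + c_))
}

.atom_row <- function(serial, name, elem, resname, resno, chain, xyz, vdw) {
  data.frame(serial = serial, name = name, elem = elem, resname = resname,
             resno = resno, chain = chain,
             x = xyz[1], y = xyz[2], z = xyz[3], vdw = vdw,
             stringsAsFactors = FALSE)
}

#' Ideal alpha-helix structure
#'
#' Places C-alpha atoms (plus stub backbone N, C, O at canonical helical
#' offsets) on an ideal helical lattice: rise 1.5 Angstrom per residue,
#' twist 100 degrees, C-alpha radius 2.3 Angstrom, built along
#' \code{direction} starting at \code{origin}.
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param radius C-alpha distance from the axis (Angstrom).
#' @param origin 3-vector, position of the residue-1 axis point.
#' @param direction axis direction (need not be unit length).
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @param radii_table element radii map.
#' @return an \code{md_structure} of 4 atoms per residue (N, CA, C, O).
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             origin = c(0, 0, 0), direction = c(0, 0, 1),
                             chain = "A", resno_start = 1,
                             radii_table = default_radii()) {
  if (n_res < 4) stop("need at least 4 residues for a helix")
  R <- .rotation_z_to(direction)
  tw <- twist * pi / 180
  # local (phase offset deg, radius, z offset) for the backbone stubs
  stubs <- list(N = c(-26, 1.60, -0.90), CA = c(0, radius, 0),
                C = c(26, 1.70, 0.90), O = c(40, 2.00, 1.25))
  rows <- vector("list", n_res * 4)
  serial <- 0
  for (k in seq_len(n_res) - 1) {
    base_ang <- k * tw
    for (nm in names(stubs)) {
      s <- stubs[[nm]]
      ang <- base_ang + s[1] * pi / 180
      local <- c(s[2] * cos(ang), s[2] * sin(ang), k * rise + s[3])
      pos <- as.numeric(R %*% local) + origin
      serial <- serial + 1
      elem <- substr(nm, 1, 1)
      rows[[serial]] <- .atom_row(serial, nm, elem, "ALA",
                                  resno_start + k, chain, pos,
                                  radius_for_element(elem, radii_table))
    }
  }
  md_structure(do.call(rbind, rows),
               metadata = list(generator = "ideal_helix",
                               rise = rise, twist = twist, radius = radius,
                               direction = direction / sqrt(sum(direction^2))))
}

#' Two ideal helices at a planted crossing angle and centre separation
#'
#' Helix A (chain A) is built along +z with its C-alpha centroid at the
#' origin; helix B (chain B) along the direction obtained by rotating +z by
#' \code{angle} degrees in the xz-plane, with its centroid at
#' (\code{center_separation}, 0, 0). The constructed N->C axis directions
#' subtend exactly the requested angle and the centroids sit exactly at the
#' requested separation.
#'
#' @param angle planted inter-axis angle in degrees, in [0, 180].
#' @param center_separation planted centroid separation (Angstrom).
#' @param n_res residues per helix (default 18, five full turns).
#' @param ... further arguments passed to \code{\link{make_ideal_helix}}.
#' @return an \code{md_structure} with chains A and B; planted parameters in
#'   \code{metadata}.
#' @export
make_helix_pair <- function(angle, center_separation, n_res = 18, ...) {
  if (angle < 0 || angle > 180) stop("angle must be in [0, 180] degrees")
  if (center_separation < 4)
    warning("centre separation under 4 Angstrom: helices will clash")
  ha <- make_ideal_helix(n_res, chain = "A", ...)
  ca_a <- resolve_selection(ha, atom_selection(atoms = "calpha"))
  cen_a <- colMeans(coords(ha)[ca_a, , drop = FALSE])
  ha <- set_coords(ha, sweep(coords(ha), 2, cen_a))
  th <- angle * pi / 180
  dir_b <- c(sin(th), 0, cos(th))
  hb <- make_ideal_helix(n_res, chain = "B", direction = dir_b, ...)
  ca_b <- resolve_selection(hb, atom_selection(atoms = "calpha"))
  cen_b <- colMeans(coords(hb)[ca_b, , drop = FALSE])
  target <- c(center_separation, 0, 0)
  hb <- set_coords(hb, sweep(coords(hb), 2, cen_b - target))
  atoms <- rbind(ha$atoms, hb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms, metadata = list(generator = "helix_pair",
                                      angle = angle,
                                      center_separation = center_separation))
}

#' Two-chain complex with a controlled inter-surface gap
#'
#' Two interdigitated corrugated slabs of carbon-like atoms (one residue
#' per atom): chain A carries bumps pointing up on alternating lattice
#' sites and chain B bumps pointing down on the complementary sites, so
#' that — as at a rough protein interface — buried surface persists over a
#' range of separations. Chain B is first seated at van der Waals tangency
#' (smallest inter-chain surface separation exactly 0) and then rigidly
#' pulled apart along z by \code{surface_gap}. Contacts and Delta-ASA
#' decrease, and the gap index increases, monotonically with the gap.
#'
#' @param n_atoms_per_chain atoms per slab.
#' @param surface_gap planted rigid pull-apart distance from van der
#'   Waals contact (Angstrom, >= 0).
#' @param seed RNG seed for the lateral jitter (shared between chains).
#' @param spacing lateral lattice spacing (Angstrom, default 3.6).
#' @param jitter lateral jitter amplitude (Angstrom, default 0.25).
#' @param corrugation bump height of the interdigitation (Angstrom,
#'   default 1.2).
#' @param radii_table element radii map.
#' @return an \code{md_structure} with chains A and B.
#' @export
make_two_chain_complex <- function(n_atoms_per_chain = 49, surface_gap = 1.0,
                                   seed = 1, spacing = 3.6, jitter = 0.25,
                                   corrugation = 1.2,
                                   radii_table = default_radii()) {
  if (surface_gap < 0) stop("surface_gap must be >= 0")
  m <- ceiling(sqrt(n_atoms_per_chain))
  site <- expand.grid(ix = seq_len(m), iy = seq_len(m))[
    seq_len(n_atoms_per_chain), ]
  vdw <- radius_for_element("C", radii_table)
  xy <- .with_seed(seed, {
    cbind(site$ix * spacing + stats::runif(nrow(site), -jitter, jitter),
          site$iy * spacing + stats::runif(nrow(site), -jitter, jitter))
  })
  parity <- (site$ix + site$iy) %% 2
  za <- corrugation * parity                    # A bumps up on odd sites
  n <- n_atoms_per_chain
  zb_rel <- -corrugation * (1 - parity)         # B bumps down on even sites
  # seat B at van der Waals tangency (minimum inter-chain surface
  # separation 0), then pull it apart rigidly along z by surface_gap
  surf_sep <- function(zoff) {
    d <- sqrt(outer(xy[, 1], xy[, 1], "-")^2 +
                outer(xy[, 2], xy[, 2], "-")^2 +
                outer(za, zb_rel + zoff, "-")^2)
    min(d) - 2 * vdw
  }
  zoff <- 2 * vdw + corrugation
  for (it in 1:30) {
    err <- surf_sep(zoff)
    if (abs(err) < 1e-9) break
    zoff <- zoff - err
  }
  zoff <- zoff + surface_gap
  atoms <- data.frame(
    serial = seq_len(2 * n),
    name = "CA",
    elem = "C",
    resname = "GLY",
    resno = c(seq_len(n), seq_len(n)),
    chain = rep(c("A", "B"), each = n),
    x = c(xy[, 1], xy[, 1]),
    y = c(xy[, 2], xy[, 2]),
    z = c(za, zb_rel + zoff),
    vdw = vdw,
    stringsAsFactors = FALSE
  )
  md_structure(atoms, metadata = list(generator = "two_chain_complex",
                                      surface_gap = surface_gap, seed = seed))
}

#' Multistate trajectory with planted substate structure
#'
#' Frames visit the given states in contiguous blocks whose total lengths
#' match the requested occupancies, with i.i.d. isotropic Gaussian noise of
#' standard deviation \code{noise_sigma} added per coordinate. The planted
#' per-frame state labels are returned for recovery scoring.
#'
#' @param states list of \code{md_structure} sharing one topology.
#' @param occupancies state occupancies, summing to 1.
#' @param n_frames total number of frames.
#' @param block_length if given, states alternate in blocks of this many
#'   frames (the final blocks truncated to honour the occupancies); by
#'   default each state occupies one contiguous block.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom).
#' @param dt_ns frame interval (ns).
#' @param t0_ns time of first frame (ns).
#' @param seed RNG seed.
#' @return list with \code{trajectory} (an \code{md_trajectory}) and
#'   \code{labels} (integer state index per frame).
#' @export
make_multistate_trajectory <- function(states, occupancies, n_frames,
                                       block_length = NULL, noise_sigma = 0,
                                       dt_ns = 1, t0_ns = 0, seed = 1) {
  if (abs(sum(occupancies) - 1) > 1e-9)
    stop("occupancies must sum to 1")
  if (length(states) != length(occupancies))
    stop("one occupancy per state required")
  na <- n_atoms(states[[1]])
  for (s in states[-1]) {
    if (n_atoms(s) != na ||
        !identical(s$atoms[, c("name", "resno", "chain")],
                   states[[1]]$atoms[, c("name", "resno", "chain")]))
      stop("states do not share a common topology")
  }
  counts <- floor(occupancies * n_frames)
  rem <- n_frames - sum(counts)
  if (rem > 0) {
    frac <- occupancies * n_frames - counts
    add <- order(-frac)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  if (is.null(block_length)) {
    labels <- rep(seq_along(states), counts)
  } else {
    labels <- integer(0)
    left <- counts
    s <- 1
    while (sum(left) > 0) {
      if (left[s] > 0) {
        take <- min(block_length, left[s])
        labels <- c(labels, rep(s, take))
        left[s] <- left[s] - take
      }
      s <- s %% length(states) + 1
    }
  }
  frames <- .with_seed(seed, {
    lapply(labels, function(l) {
      xyz <- coords(states[[l]])
      if (noise_sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                            ncol = 3)
      xyz
    })
  })
  list(trajectory = md_trajectory(states[[1]], frames, dt_ns, t0_ns),
       labels = labels)
}

#' Random atom packing in a cubic box
#'
#' Uniformly placed carbon-like atoms with rejection sampling enforcing a
#' minimum pairwise separation. Useful as oracle fodder for surface and
#' contact computations.
#'
#' @param n_atoms number of atoms.
#' @param box box edge length (Angstrom).
#' @param min_separation minimum pairwise distance (Angstrom).
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @param radii_table element radii map.
#' @return an \code{md_structure} (one residue per atom).
#' @export
make_random_structure <- function(n_atoms, box = 20, min_separation = 2.0,
                                  seed = 1, chain = "A",
                                  radii_table = default_radii()) {
  xyz <- .with_seed(seed, {
    out <- matrix(NA_real_, n_atoms, 3)
    placed <- 0
    tries <- 0
    max_tries <- 10000 * n_atoms
    while (placed < n_atoms) {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not pack ", n_atoms, " atoms at separation ",
             min_separation, " in a ", box, " A box")
      p <- stats::runif(3, 0, box)
      if (placed == 0 ||
          min(rowSums(sweep(out[seq_len(placed), , drop = FALSE], 2, p)^2)) >=
            min_separation^2) {
        placed <- placed + 1
        out[placed, ] <- p
      }
    }
    out
  })
  vdw <- radius_for_element("C", radii_table)
  md_structure(data.frame(
    serial = seq_len(n_atoms), name = "CA", elem = "C", resname = "GLY",
    resno = seq_len(n_atoms), chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = vdw,
    stringsAsFactors = FALSE
  ), metadata = list(generator = "random_structure", seed = seed))
}
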