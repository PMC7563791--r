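# Independent oracles used to verify the package's implementations.
# These deliberately avoid the code paths they check.

# --- rotation-grid RMSD oracle -------------------------------------------
# Minimum RMSD over rigid motions found by scanning rotations on an
# axis-angle grid (Fibonacci axes x angle steps), refined locally down to
# sub-0.1-degree resolution. Translation is removed by centring.

rotation_from_axis_angle <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

fib_axes <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

grid_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  n <- nrow(P)
  eval_rot <- function(axis, angle) {
    R <- rotation_from_axis_angle(axis, angle)
    sqrt(sum((P %*% t(R) - Q)^2) / n)
  }
  axes <- fib_axes(300)
  angles <- seq(0, 2 * pi, length.out = 61)[-61]
  best <- list(val = Inf)
  for (i in seq_len(nrow(axes))) for (ang in angles) {
    v <- eval_rot(axes[i, ], ang)
    if (v < best$val) best <- list(val = v, axis = axes[i, ], ang = ang)
  }
  # local refinement: shrink an axis/angle neighbourhood around the best
  span_ax <- 0.35; span_an <- 0.15
  for (lev in 1:8) {
    ax0 <- best$axis; an0 <- best$ang
    for (dx in seq(-span_ax, span_ax, length.out = 5))
      for (dy in seq(-span_ax, span_ax, length.out = 5))
        for (dz in seq(-span_ax, span_ax, length.out = 5))
          for (da in seq(-span_an, span_an, length.out = 5)) {
            ax <- ax0 + c(dx, dy, dz)
            if (sum(ax^2) < 1e-12) next
            v <- eval_rot(ax, an0 + da)
            if (v < best$val) best <- list(val = v, axis = ax, ang = an0 + da)
          }
    span_ax <- span_ax / 3; span_an <- span_an / 3
  }
  best$val
}

# --- brute-force GROMOS oracle -------------------------------------------
# Naive restatement of the greedy algorithm with explicit loops and a full
# neighbour re-scan per iteration.

gromos_brute <- function(m, cutoff) {
  n <- nrow(m)
  left <- seq_len(n)
  clusters <- list()
  while (length(left) > 0) {
    best_count <- -1; best_frame <- NA
    for (f in left) {
      cnt <- 0
      for (g in left) if (m[f, g] <= cutoff) cnt <- cnt + 1
      if (cnt > best_count) { best_count <- cnt; best_frame <- f }
      # ties: keep first (lowest index) since left is ascending
    }
    mem <- left[vapply(left, function(g) m[best_frame, g] <= cutoff,
                       logical(1))]
    clusters[[length(clusters) + 1]] <- sort(mem)
    left <- setdiff(left, mem)
  }
  clusters
}

# canonical form of a partition for comparison: list of sorted member sets,
# sorted by first member
canonical_partition <- function(members) {
  members <- lapply(members, sort)
  members[order(vapply(members, `[`, 0, 1))]
}

# --- fixtures -------------------------------------------------------------

# minimal hand-written PDB text (5 atoms, 2 residues, explicit elements)
fixture_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.722   6.803  -4.199  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.581   6.358  -4.045  1.00  0.00           O",
    "ATOM      5  N   GLY A   2      11.194   7.875  -3.571  1.00  0.00           N",
    "END")
}

# two single-residue, single-atom chains at an exact centre distance
fixture_two_atom_complex <- function(distance, vdw = 1.87) {
  md_structure(data.frame(
    serial = 1:2, name = "CA", elem = "C", resname = "GLY", resno = 1,
    chain = c("A", "B"), x = c(0, distance), y = 0, z = 0, vdw = vdw,
    stringsAsFactors = FALSE))
}

# a second conformational state at a prescribed Kabsch backbone RMSD from
# a base structure, built by scaling a smooth bending displacement
fixture_state_at_rmsd <- function(base, target_rmsd, sel = atom_selection(atoms = "backbone")) {
  x <- coords(base)
  bend <- outer(sin(seq_len(nrow(x)) / 4), c(1.0, -0.9, 0.8))
  idx <- resolve_selection(base, sel)
  scale <- 1
  for (i in 1:12) {
    x2 <- x + scale * bend
    r <- kabsch(x2[idx, ], x[idx, ])$rmsd
    if (abs(r - target_rmsd) < 1e-9) break
    scale <- scale * target_rmsd / r
  }
  set_coords(base, x + scale * bend)
}

# random two-chain structure for contact-map checks: two atom clouds with
# one residue per atom, overlapping enough to create contacts
fixture_random_two_chain <- function(n_per_chain = 40, seed = 1, box = 18) {
  a <- make_random_structure(n_per_chain, box = box, min_separation = 2,
                             seed = seed, chain = "A")
  b <- make_random_structure(n_per_chain, box = box, min_separation = 2,
                             seed = seed + 1000, chain = "B")
  xb <- coords(b)
  xb[, 1] <- xb[, 1] + box / 2  # partial overlap
  b <- set_coords(b, xb)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms)
}
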