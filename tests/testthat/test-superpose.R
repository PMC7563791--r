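rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("kabsch recovers rigid motions exactly", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  fit <- kabsch(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  y <- x %*% t(rot_z(90)) + matrix(rep(c(5, 5, 5), each = 10), 10, 3)
  fit <- kabsch(x, y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_equal(apply_superposition(x, fit), y, tolerance = 1e-8)
})

test_that("kabsch equals the rotation-grid oracle on the bent-triangle case", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  mob <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0))
  r_kabsch <- kabsch(mob, ref)$rmsd
  r_grid <- grid_min_rmsd(mob, ref)
  expect_lt(abs(r_kabsch - r_grid), 1e-3)
  expect_lte(r_kabsch, r_grid + 1e-9)  # never beaten by the grid search
})

test_that("rmsd is a metric on fitted conformations and never exceeds the unfitted value", {
  set.seed(12)
  for (i in 1:20) {
    a <- matrix(rnorm(30), 10, 3)
    b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
    fab <- kabsch(a, b)$rmsd
    fba <- kabsch(b, a)$rmsd
    expect_lt(abs(fab - fba), 1e-9)
    expect_lte(fab, coord_rmsd(a, b) + 1e-12)
    expect_equal(kabsch(a, a)$rmsd, 0, tolerance = 1e-10)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(seq_len(5), 0, 0)
  expect_error(kabsch(line, line + 1), "degenerate|collinear")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("rmsd_series fits per frame and matches a per-frame oracle", {
  h <- make_ideal_helix(10)
  tr <- md_trajectory(h, list(coords(h), coords(h), coords(h)), dt_ns = 1)
  sel <- atom_selection(atoms = "backbone")
  s <- rmsd_series(tr, sel, reference = h)
  expect_equal(s$rmsd, c(0, 0, 0), tolerance = 1e-10)

  # two-state trajectory: series must equal an independent frame-by-frame fit
  st2 <- fixture_state_at_rmsd(h, 2.0)
  tw <- make_multistate_trajectory(list(h, st2), c(0.5, 0.5), 8,
                                   noise_sigma = 0.05, seed = 4)
  s <- rmsd_series(tw$trajectory, sel, reference = h)
  idx <- resolve_selection(h, sel)
  oracle <- vapply(tw$trajectory$frames, function(f)
    kabsch(f[idx, ], coords(h)[idx, ])$rmsd, numeric(1))
  expect_equal(s$rmsd, oracle, tolerance = 1e-9)
  expect_equal(s$rmsd[1],
               kabsch(tw$trajectory$frames[[1]][idx, ],
                      coords(h)[idx, ])$rmsd)
})

test_that("average structure is a fixed point on static input and rigid-motion invariant", {
  h <- make_ideal_helix(8)
  tr <- md_trajectory(h, list(coords(h), coords(h)), 1)
  avg <- average_structure(tr)
  expect_equal(coords(avg), coords(h), tolerance = 1e-9)

  rot <- coords(h) %*% t(rot_z(40)) + 3
  tr2 <- md_trajectory(h, list(coords(h), rot), 1)
  avg2 <- average_structure(tr2)
  expect_equal(kabsch(coords(avg2), coords(h))$rmsd, 0, tolerance = 1e-6)
})

test_that("average of noisy frames converges to the template", {
  h <- make_ideal_helix(8)
  tr <- make_multistate_trajectory(list(h), 1, 500, noise_sigma = 0.1,
                                   seed = 9)
  avg <- average_structure(tr$trajectory)
  expect_lt(kabsch(coords(avg), coords(h))$rmsd, 0.02)
})

test_that("rmsf is zero for a static trajectory and peaks at a planted mobile residue", {
  h <- make_ideal_helix(10)
  static <- md_trajectory(h, list(coords(h), coords(h), coords(h)), 1)
  pr <- rmsf_profile(static)
  expect_true(all(pr$value < 1e-12))
  expect_error(rmsf_profile(md_trajectory(h, list(coords(h)), 1)),
               "at least 2")

  # one mobile residue among frozen ones
  idx5 <- which(h$atoms$resno == 5)
  set.seed(21)
  frames <- lapply(1:200, function(i) {
    x <- coords(h)
    x[idx5, ] <- x[idx5, ] + matrix(rnorm(length(idx5) * 3, sd = 0.5),
                                    ncol = 3)
    x
  })
  pr <- rmsf_profile(md_trajectory(h, frames, 1))
  expect_equal(pr$resno[which.max(pr$value)], 5)
  expect_gt(max(pr$value), 10 * sort(pr$value, decreasing = TRUE)[2])
})

test_that("profile differences subtract elementwise and demand matching keys", {
  a <- structure(data.frame(chain = "A", resno = 1:5,
                            value = c(1, 2, 3, 4, 5)),
                 class = c("residue_profile", "data.frame"))
  b <- structure(data.frame(chain = "A", resno = 1:5,
                            value = c(0.5, 2, 2, 5, 1)),
                 class = c("residue_profile", "data.frame"))
  expect_equal(profile_difference(a, a)$value, rep(0, 5))
  d_ab <- profile_difference(a, b)$value
  d_ba <- profile_difference(b, a)$value
  expect_equal(d_ab + d_ba, rep(0, 5))
  expect_equal(d_ab, c(0.5, 0, 1, -1, 4))
  b2 <- b; b2$resno <- 2:6
  expect_error(profile_difference(a, b2), "A\\|1|A\\|6")
})

test_that("displacement maps vanish under rigid motion and localise a moved loop", {
  h <- make_ideal_helix(12)
  expect_true(all(displacement_map(h, h)$value < 1e-12))
  rot <- set_coords(h, coords(h) %*% t(rot_z(25)) + 2)
  expect_true(all(displacement_map(h, rot)$value < 1e-8))

  # translate residues 9-12 by 3 A; fit on the untouched 1-8 core
  x <- coords(h)
  loop <- which(h$atoms$resno >= 9)
  x[loop, 1] <- x[loop, 1] + 3
  moved <- set_coords(h, x)
  dm <- displacement_map(h, moved, fit_sel = atom_selection(resid = c(1, 8)))
  expect_true(all(abs(dm$value[dm$resno <= 8]) < 1e-9))
  expect_true(all(abs(dm$value[dm$resno >= 9] - 3) < 1e-9))
})
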