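test_that("an isolated sphere reproduces the closed-form accessible area", {
  s <- fixture_two_atom_complex(100)       # far apart: both isolated
  res <- lee_richards_sasa(s, probe = 1.4)
  exact <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(res$atom_area[1], exact, tolerance = 0.005)
  expect_equal(res$atom_area[2], exact, tolerance = 0.005)
  expect_equal(res$total, sum(res$atom_area), tolerance = 1e-6)
  # non-interacting atoms: total equals the sum of isolated spheres
  expect_equal(res$total, 2 * exact, tolerance = 0.005)
})

test_that("Lee-Richards agrees with the Shrake-Rupley quadrature on random structures", {
  for (seed in 1:3) {
    s <- make_random_structure(50, box = 14, min_separation = 2.5,
                               seed = seed)
    lr <- lee_richards_sasa(s)$total
    sr <- shrake_rupley_sasa(s, n_points = 10000)$total
    expect_lt(abs(lr - sr) / sr, 0.01)
  }
})

test_that("duplicate atoms at identical coordinates are collapsed with a warning", {
  a <- fixture_two_atom_complex(100)$atoms
  dup <- a[1, ]; dup$serial <- 3; dup$resno <- 2   # same position, new id
  s <- md_structure(rbind(a, dup))
  expect_warning(res <- lee_richards_sasa(s), "duplicate")
  expect_equal(res$total, lee_richards_sasa(fixture_two_atom_complex(100))$total,
               tolerance = 1e-9)
})

test_that("adding an atom never increases the accessible area of existing atoms", {
  set.seed(51)
  for (rep in 1:10) {
    s <- make_random_structure(20, box = 10, min_separation = 2, seed = rep)
    base <- lee_richards_sasa(s)$atom_area
    extra <- s$atoms[1, ]
    extra$serial <- n_atoms(s) + 1
    extra$resno <- n_atoms(s) + 1
    extra[, c("x", "y", "z")] <- runif(3, 0, 10)
    s2 <- md_structure(rbind(s$atoms, extra))
    grown <- lee_richards_sasa(s2)$atom_area
    expect_true(all(grown[seq_len(n_atoms(s))] <= base + 1e-9))
  }
})

test_that("two-atom gap sphere matches the closed-form volume", {
  cx <- fixture_two_atom_complex(8)
  v <- gap_volume(cx, "A", "B", r_min = 1, r_max = 5, grid = 0.5)
  sp <- attr(v, "spheres")
  expect_equal(nrow(sp), 1)
  expect_equal(sp$r, (8 - 2 * 1.87) / 2, tolerance = 1e-9)
  exact <- 4 / 3 * pi * sp$r^3
  expect_lt(abs(as.numeric(v) - exact) / exact, 0.05)
})

test_that("gap spheres outside [r_min, r_max] yield zero volume", {
  # surface separation > 2*r_max: pair skipped
  expect_equal(as.numeric(gap_volume(fixture_two_atom_complex(15), "A", "B")), 0)
  # vdW contact: initial radius below r_min
  expect_equal(as.numeric(gap_volume(fixture_two_atom_complex(5), "A", "B")), 0)
})

test_that("union volume is subadditive with equality for disjoint spheres", {
  disjoint <- data.frame(x = c(0, 10, 20), y = 0, z = 0, r = c(1.5, 2, 1))
  v <- sphere_union_volume(disjoint, grid = 0.2)
  exact <- sum(4 / 3 * pi * disjoint$r^3)
  expect_lt(abs(v - exact) / exact, 0.03)
  overlapping <- data.frame(x = c(0, 1), y = 0, z = 0, r = c(1.5, 1.5))
  v2 <- sphere_union_volume(overlapping, grid = 0.1)
  expect_lt(v2, 2 * 4 / 3 * pi * 1.5^3)
})

test_that("grid integration converges and agrees with Monte-Carlo", {
  set.seed(52)
  for (rep in 1:5) {
    sp <- data.frame(x = runif(5, 0, 6), y = runif(5, 0, 6),
                     z = runif(5, 0, 6), r = runif(5, 1, 2.5))
    v50 <- sphere_union_volume(sp, grid = 0.5)
    v25 <- sphere_union_volume(sp, grid = 0.25)
    expect_lt(abs(v25 - v50) / v25, 0.03)
    vmc <- sphere_union_volume(sp, method = "mc", n_points = 2e5)
    expect_lt(abs(v50 - vmc) / vmc, 0.05)
  }
})

test_that("interface report composes SASA and gap volume correctly", {
  # far-separated chains: no buried area, undefined gap index
  far <- make_two_chain_complex(25, surface_gap = 100, seed = 3)
  r <- interface_report(far, "A", "B")
  expect_lt(abs(r$delta_asa), 1e-6)
  expect_false(r$gap_index_defined)
  expect_true(is.na(r$gap_index))

  # mirror-symmetric dimer: equal per-chain areas
  sym <- make_two_chain_complex(25, surface_gap = 1, seed = 3,
                                corrugation = 0)
  rs <- interface_report(sym, "A", "B")
  expect_equal(rs$asa_A, rs$asa_B, tolerance = 1e-6)
  expect_equal(rs$interface_area, rs$delta_asa / 2)
  expect_equal(rs$gap_index, rs$gap_volume / rs$interface_area)
  expect_gte(rs$delta_asa, 0)
})

test_that("interface report matches independently composed oracles", {
  cx <- make_two_chain_complex(25, surface_gap = 1.5, seed = 7)
  r <- interface_report(cx, "A", "B")
  # recompute Delta-ASA through the independent quadrature backend
  a <- cx$atoms
  sr <- function(idx) shrake_rupley_sasa(
    subset_structure(cx, idx), n_points = 5000)$total
  delta_sr <- sr(which(a$chain == "A")) + sr(which(a$chain == "B")) -
    sr(seq_len(nrow(a)))
  expect_lt(abs(r$delta_asa - delta_sr) / max(delta_sr, 1), 0.02)
  # recompute the sphere-union volume by Monte-Carlo integration
  sp <- gap_spheres(cx, "A", "B")
  set.seed(99)
  vmc <- sphere_union_volume(sp, method = "mc", n_points = 5e5)
  expect_lt(abs(r$gap_volume - vmc) / max(vmc, 1), 0.05)
})

test_that("pulling an interface apart loosens its complementarity", {
  g1 <- interface_report(make_two_chain_complex(36, 1, seed = 5), "A", "B")
  g2 <- interface_report(make_two_chain_complex(36, 2, seed = 5), "A", "B")
  g3 <- interface_report(make_two_chain_complex(36, 3, seed = 5), "A", "B")
  expect_true(g1$gap_index_defined && g3$gap_index_defined)
  expect_lt(g1$gap_index, g2$gap_index)
  expect_lt(g2$gap_index, g3$gap_index)
})
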