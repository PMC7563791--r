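test_that("the 5 A heavy-atom criterion is sharp at the boundary", {
  expect_equal(nrow(contact_map(fixture_two_atom_complex(4.9), "A", "B", 5)), 1)
  expect_equal(nrow(contact_map(fixture_two_atom_complex(5.1), "A", "B", 5)), 0)
})

test_that("grid-accelerated maps equal brute-force enumeration exactly", {
  for (seed in 1:20) {
    cx <- fixture_random_two_chain(40, seed = seed)
    g <- contact_map(cx, "A", "B", 5, method = "grid")
    b <- contact_map(cx, "A", "B", 5, method = "brute")
    expect_identical(as.data.frame(g), as.data.frame(b))
  }
})

test_that("contact maps are symmetric under chain-set exchange and monotone in cutoff", {
  cx <- fixture_random_two_chain(30, seed = 4)
  ab <- contact_map(cx, "A", "B", 5)
  ba <- contact_map(cx, "B", "A", 5)
  expect_identical(
    sort(paste(ab$chain_a, ab$res_a, ab$chain_b, ab$res_b)),
    sort(paste(ba$chain_b, ba$res_b, ba$chain_a, ba$res_a)))
  k4 <- trajmd:::.pair_keys(contact_map(cx, "A", "B", 4))
  k5 <- trajmd:::.pair_keys(contact_map(cx, "A", "B", 5))
  k6 <- trajmd:::.pair_keys(contact_map(cx, "A", "B", 6))
  expect_true(all(k4 %in% k5))
  expect_true(all(k5 %in% k6))
})

test_that("pseudo-chain selections allow intra-molecular domain interfaces", {
  cx <- fixture_random_two_chain(20, seed = 9)
  # treat each residue-number half as a pseudo-chain on the merged chains
  selA <- atom_selection(chains = "A")
  selB <- atom_selection(chains = "B")
  m1 <- contact_map(cx, selA, selB, 5)
  m2 <- contact_map(cx, "A", "B", 5)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  expect_error(contact_map(cx, selA, selA, 5), "overlap")
})

test_that("conserved-contact fractions are exact on constructed schedules", {
  cx <- make_two_chain_complex(25, 0.5, seed = 6)
  base <- coords(cx)
  apart <- base
  bidx <- which(cx$atoms$chain == "B")
  apart[bidx, 3] <- apart[bidx, 3] + 50
  tr <- md_trajectory(cx, list(base, base, apart), 1)
  s <- conserved_contact_series(tr, "A", "B", 5)
  expect_equal(s$conserved_fraction, c(1, 1, 0))
  expect_equal(s$total_contacts[3], 0)
  expect_error(conserved_contact_series(
    md_trajectory(cx, list(apart), 1), "A", "B", 5), "no interface")

  # break exactly half of the reference contacts at frame 3
  ref <- contact_map(cx, "A", "B", 5)
  resA <- sort(unique(ref$res_a))
  drop_res <- resA[seq_len(floor(length(resA) / 2))]
  kept <- ref[!ref$res_a %in% drop_res, ]
  frac_expect <- nrow(kept) / nrow(ref)
  broken <- base
  aidx <- which(cx$atoms$chain == "A" & cx$atoms$resno %in% drop_res)
  broken[aidx, 3] <- broken[aidx, 3] - 50
  tr2 <- md_trajectory(cx, list(base, broken), 1)
  s2 <- conserved_contact_series(tr2, "A", "B", 5)
  expect_equal(s2$conserved_fraction[1], 1)
  expect_equal(s2$conserved_fraction[2], frac_expect)
  expect_true(all(s2$conserved_fraction >= 0 & s2$conserved_fraction <= 1))
})

test_that("persistence fractions equal planted schedule densities and the threshold is strict", {
  cx <- fixture_two_atom_complex(4.5)
  near <- coords(cx)
  far <- near; far[2, 1] <- far[2, 1] + 50
  # contact present in 8 of 10 frames: fraction exactly 0.8
  frames <- c(rep(list(near), 8), rep(list(far), 2))
  tr <- md_trajectory(cx, frames, 1)
  pt <- persistence_table(tr, "A", "B", 5, threshold = 0.8)
  expect_equal(pt$pairs$fraction, 0.8)
  expect_equal(pt$residues$fraction, c(0.8, 0.8))
  # strictly-greater-than threshold: 0.8 at the 0.8 boundary is excluded
  expect_equal(nrow(pt$persistent), 0)
  pt2 <- persistence_table(tr, "A", "B", 5, threshold = 0.79)
  expect_equal(nrow(pt2$persistent), 2)

  # static contacting complex: every observed pair at exactly 1.0
  cxs <- make_two_chain_complex(16, 0.5, seed = 2)
  trs <- md_trajectory(cxs, list(coords(cxs), coords(cxs)), 1)
  pts <- persistence_table(trs, "A", "B", 5)
  expect_true(all(pts$pairs$fraction == 1))
  expect_equal(nrow(pts$persistent), nrow(pts$residues))
})

test_that("distance monitors evaluate exact Euclidean distances", {
  at <- data.frame(serial = 1:2, name = c("NZ", "O2G"), elem = c("N", "O"),
                   resname = c("LYS", "ATP"), resno = c(1065, 1),
                   chain = c("A", "B"),
                   x = c(0, 3), y = c(0, 4), z = c(0, 0),
                   vdw = c(1.65, 1.4), stringsAsFactors = FALSE)
  s <- md_structure(at)
  tr <- md_trajectory(s, list(coords(s), coords(s)), 1)
  mon <- parse_monitor("lys_atp: A:LYS:1065:NZ -- B:ATP:1:O2G")
  d <- distance_series(tr, list(mon))
  expect_equal(d$lys_atp, c(5, 5))   # 3-4-5 triangle, constant series

  # scripted separation ramp is reproduced exactly
  frames <- lapply(seq(3, 9, length.out = 7), function(r) {
    x <- coords(s); x[2, ] <- c(r, 0, 0); x
  })
  d2 <- distance_series(md_trajectory(s, frames, 1), list(mon))
  expect_equal(d2$lys_atp, seq(3, 9, length.out = 7), tolerance = 1e-6)

  expect_error(distance_series(tr, list(
    distance_monitor("bad", "A:LYS:1:NZ", "B:ATP:1:O2G"))), "bad")
})
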