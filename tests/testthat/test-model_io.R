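test_that("PDB reading preserves record count, serials and identities", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fixture_pdb_lines(), f)
  s <- read_pdb(f)
  expect_s3_class(s, "md_structure")
  expect_equal(n_atoms(s), 5)
  expect_equal(s$atoms$serial, 1:5)
  expect_equal(s$atoms$name, c("N", "CA", "C", "O", "N"))
  expect_equal(s$atoms$elem, c("N", "C", "C", "O", "N"))
  expect_equal(s$atoms$resno, c(1, 1, 1, 1, 2))
  # radii assigned from the default table
  expect_equal(s$atoms$vdw, c(1.65, 1.87, 1.87, 1.40, 1.65))
})

test_that("write/read round-trip preserves identity and coordinates", {
  s <- make_helix_pair(35, 13)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$resno, s$atoms$resno)
  expect_equal(s2$atoms$elem, s$atoms$elem)
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
  expect_true(max(abs(coords(s2) - round(coords(s), 3))) < 1e-9)
})

test_that("altloc records other than blank or A are dropped", {
  lines <- c(
    "ATOM      1  CB ASER A   1       0.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CB BSER A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  OG ASER A   1       0.000   1.000   0.000  0.50  0.00           O",
    "ATOM      4  OG BSER A   1       1.000   1.000   0.000  0.50  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_pdb(f)
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$name, c("CB", "OG"))
})

test_that("reader errors are specific", {
  expect_error(read_pdb(tempfile()), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), "no ATOM/HETATM")
  bad <- fixture_pdb_lines()
  bad[3] <- sub("10.722", "10.7xx2", bad[3])
  writeLines(bad, f)
  expect_error(read_pdb(f), "line 3")
})

test_that("written PDB has TER between chains and END terminator", {
  s1 <- subset_structure(make_ideal_helix(4), 1:4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(subset_structure(s1, 1), f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^ATOM", lines)), 1)
  expect_equal(sum(lines == "TER"), 1)
  expect_equal(lines[length(lines)], "END")

  pair <- make_helix_pair(90, 12)
  write_pdb(pair, f)
  lines <- readLines(f)
  ter_pos <- which(lines == "TER")
  expect_length(ter_pos, 2)
  # first TER sits between the last chain-A atom and the first chain-B atom
  atom_chains <- substr(lines[grepl("^ATOM", lines)], 22, 22)
  expect_equal(ter_pos[1], max(which(atom_chains == "A")) + 1)
})

test_that("coordinates that overflow the fixed columns are refused", {
  s <- fixture_two_atom_complex(8)
  x <- coords(s); x[2, 1] <- 12345
  expect_error(write_pdb(set_coords(s, x), tempfile()), "10000")
})

test_that("multi-model trajectories read and round-trip", {
  h <- make_ideal_helix(6)
  frames <- lapply(1:3, function(i) coords(h) + i * 0.5)
  tr <- md_trajectory(h, frames, dt_ns = 2, t0_ns = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, dt_ns = 2, t0_ns = 10)
  expect_equal(n_frames(tr2), 3)
  for (i in 1:3)
    expect_equal(tr2$frames[[i]], frames[[i]], tolerance = 1e-3,
                 ignore_attr = TRUE)
  expect_equal(frame_times(tr2), c(10, 12, 14))

  # single-model file reads as a 1-frame trajectory matching read_pdb
  write_pdb(h, f)
  tr1 <- read_trajectory(f, dt_ns = 1)
  expect_equal(n_frames(tr1), 1)
  expect_equal(tr1$topology$atoms$name, h$atoms$name)
})

test_that("inconsistent atom counts across models are rejected", {
  h <- make_ideal_helix(5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(md_trajectory(h, list(coords(h), coords(h)), 1), f)
  lines <- readLines(f)
  # drop one atom from model 2
  atom_idx <- which(grepl("^ATOM", lines))
  lines <- lines[-atom_idx[length(atom_idx)]]
  writeLines(lines, f)
  expect_error(read_trajectory(f, 1), "model 2")
})

test_that("selections resolve deterministically with correct semantics", {
  h <- make_ideal_helix(13, resno_start = 408)
  sel <- atom_selection(chains = "A", resid = c(408, 420), atoms = "backbone")
  idx <- resolve_selection(h, sel)
  expect_length(idx, 13 * 4)
  expect_identical(idx, resolve_selection(h, sel))  # idempotent
  # all-atom selection is the identity
  expect_equal(resolve_selection(h, atom_selection()), seq_len(n_atoms(h)))
  # selection strings parse to the same result
  expect_equal(resolve_selection(h, "chain=A; resid=408-420; atoms=backbone"),
               idx)
  expect_error(resolve_selection(h, atom_selection(chains = "Z")),
               "zero atoms")
})

test_that("heavy-atom selection excludes explicit hydrogens", {
  h <- make_ideal_helix(4)
  atoms <- h$atoms
  hrow <- atoms[atoms$name == "N", ]
  hrow$name <- paste0("H", seq_len(nrow(hrow)))
  hrow$elem <- "H"
  hrow$vdw <- 1.0
  hrow$x <- hrow$x + 0.5
  atoms <- rbind(atoms, hrow)
  atoms$serial <- seq_len(nrow(atoms))
  s <- md_structure(atoms)
  heavy <- resolve_selection(s, atom_selection(atoms = "heavy"))
  # brute scan of the atom table
  expect_equal(heavy, which(s$atoms$elem != "H"))
  expect_length(heavy, 16)
  # backbone subset of heavy subset of all
  bb <- resolve_selection(s, atom_selection(atoms = "backbone"))
  expect_true(all(bb %in% heavy))
  expect_true(all(heavy %in% seq_len(n_atoms(s))))
})

test_that("structure invariants are enforced", {
  a <- make_ideal_helix(4)$atoms
  a$resno <- 1  # collapse residues -> duplicate (chain, resno, name)
  expect_error(md_structure(a), "duplicate")
  expect_error(md_trajectory(make_ideal_helix(4), list(matrix(0, 2, 3)), 1),
               "atom count|does not match")
  expect_error(md_trajectory(make_ideal_helix(4), list(), 1), "at least one")
})
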