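test_that("read_pdb parses minimal and multi-model files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_length(s, 1)
  expect_equal(n_atoms(s[[1]]), 1)
  expect_equal(unname(coords(s[[1]])[1, ]), c(1, 2, 3))
  expect_equal(s[[1]]$atoms$name, "CA")
  expect_equal(s[[1]]$atoms$chain, "A")

  atom_line <- "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(rbind(sprintf("MODEL     %4d", 1:3),
                     atom_line, "ENDMDL"), "END"), f2)
  s3 <- read_pdb(f2)
  expect_length(s3, 3)
  expect_true(all(vapply(s3, function(x) x$atoms$name, "") == "CA"))
})

test_that("write_pdb then read_pdb round-trips a synthetic structure to 1e-3 A", {
  s <- random_structure(n = 50, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  back <- read_pdb(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$atoms$name, s$atoms$name)
  expect_equal(back[[1]]$atoms$chain, s$atoms$chain)
  expect_equal(back[[1]]$atoms$resid, s$atoms$resid)
  expect_lt(max(abs(coords(back[[1]]) - coords(s))), 1e-3 + 1e-12)

  # two structures -> MODEL blocks; single -> none
  s2 <- md_structure(s$atoms, s$xyz + 1, s$title)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(list(s, s2), f2)
  txt <- readLines(f2)
  expect_length(grep("^MODEL", txt), 2)
  expect_length(grep("^MODEL", readLines(f)), 0)
  back2 <- read_pdb(f2)
  expect_length(back2, 2)
  expect_lt(max(abs(coords(back2[[2]]) - coords(s2))), 1e-3 + 1e-12)
})

test_that("long (segment-style) chain labels survive the PDB round trip", {
  s <- gen_pseudo_nucleosome(pseudo_nucleosome_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  back <- read_pdb(f)[[1]]
  expect_equal(back$atoms$chain, s$atoms$chain)   # includes "H2A'"
  expect_lt(max(abs(coords(back) - coords(s))), 1e-3 + 1e-12)
})

test_that("read_pdb error handling: malformed records, empty files, icodes, overflow", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.000   bad     3.000  1.00  0.00           C"), f)
  expect_error(read_pdb(f), "line 2")

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f2)
  expect_error(read_pdb(f2), "empty")

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(
    "ATOM      1  CA  ALA A   1A      1.000   2.000   3.000  1.00  0.00           C",
    f3)
  expect_error(read_pdb(f3), "insertion")

  s <- random_structure(10)
  s$xyz[1, 1] <- 2e5
  expect_error(write_pdb(s, withr::local_tempfile(fileext = ".pdb")),
               "overflow")
})

test_that("alternate locations keep the highest-occupancy atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB  ALA A   1       3.000   0.000   0.000  1.00  0.00           C"), f)
  s <- read_pdb(f)[[1]]
  expect_equal(n_atoms(s), 2)
  expect_equal(unname(coords(s)[s$atoms$name == "CA", 1]), 2)
})

test_that("select_atoms filters by conjunction, preserves order, is idempotent", {
  s <- gen_pseudo_nucleosome(pseudo_nucleosome_spec(seed = 1))
  tail_sel <- select_atoms(s, chain = "H4", resid = 18:23)
  expect_length(tail_sel, 6)
  expect_equal(s$atoms$resname[tail_sel],
               c("HIS", "ARG", "LYS", "GLY", "LEU", "ARG"))

  expect_length(select_atoms(s, name = "OW"), 0)      # empty is not an error
  all_sel <- select_atoms(s)
  expect_equal(as.integer(all_sel), seq_len(n_atoms(s)))

  sub <- subset_structure(s, tail_sel)
  again <- select_atoms(sub, chain = "H4", resid = 18:23)
  expect_equal(as.integer(again), seq_len(6))          # idempotent on the subset

  expect_error(select_atoms(s, resnum = 1), "unknown selection field")
})

test_that("extract_ensemble snaps evenly spaced targets to nearest frames", {
  s <- random_structure(n = 10, seed = 2)
  # 20 ns trajectory at 0.05 ns/frame
  nf <- 400
  traj <- md_ensemble(s, replicate(nf, coords(s), simplify = FALSE),
                      times = 0.05 * seq_len(nf))
  e <- extract_ensemble(traj, 14, 20, 120)
  expect_equal(n_frames(e), 120)
  expect_true(all(diff(e$times) > 0))
  expect_true(all(e$times >= 14 & e$times <= 20))

  # synthetic 100-frame trajectory, full window, n = 10 -> indices 1,11,...,91
  traj2 <- md_ensemble(s, lapply(1:100, function(i) coords(s) + i),
                       times = 0.1 * (0:99))
  e2 <- extract_ensemble(traj2, 0, 10, 10)
  got <- vapply(e2$frames, function(f) f[1, 1] - coords(s)[1, 1], numeric(1))
  expect_equal(got, seq(1, 91, by = 10))

  # window equal to one frame's time, n = 1
  e3 <- extract_ensemble(traj2, 0.95, 1.05, 1)
  expect_equal(e3$times, 1.0)

  expect_error(extract_ensemble(traj2, 0, 1, 500), "insufficient frames")
})
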