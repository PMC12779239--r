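test_that("PDB reading assembles topology, residues and nm coordinates", {
  rs <- read_structure(dipeptide_path())
  top <- rs$topology
  expect_equal(n_atoms(top), 10)
  expect_equal(nrow(top$residues), 2)
  expect_equal(top$residues$residue_name, c("ALA", "GLY"))
  # file order and names preserved
  expect_equal(top$atoms$name[1:5], c("N", "CA", "C", "O", "CB"))
  # Angstrom -> nm at the boundary
  expect_equal(rs$frame$coordinates[1, 1], 0.1204, tolerance = 1e-8)
  # CA in a standard amino acid is carbon, not calcium
  expect_equal(top$atoms$element[2], "C")
  expect_true(all(top$atoms$is_heavy))
})

test_that("minimal one-atom PDB and malformed records behave as documented", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  rs <- read_structure(f)
  expect_equal(n_atoms(rs$topology), 1)
  expect_equal(nrow(rs$topology$residues), 1)

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       oops.   2.000   3.000  1.00  0.00           C"),
    bad)
  expect_error(read_structure(bad), "line 2", class = "mdbind_format_error")

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_structure(empty), class = "mdbind_empty_input_error")
})

test_that("structure round-trip preserves order, names and coordinates", {
  rs <- read_structure(dipeptide_path())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(f, rs$topology, rs$frame)
  rs2 <- read_structure(f)
  expect_equal(rs2$topology$atoms$name, rs$topology$atoms$name)
  expect_equal(rs2$topology$atoms$residue_index, rs$topology$atoms$residue_index)
  expect_equal(rs2$topology$atoms$author_resid, rs$topology$atoms$author_resid)
  # 1e-3 Angstrom = 1e-4 nm
  expect_lt(max(abs(rs2$frame$coordinates - rs$frame$coordinates)), 1e-4)
})

test_that("parameter tables attach, report charges, and reject bad input", {
  rs <- read_structure(dipeptide_path())
  top <- set_group(rs$topology, "all", seq_len(10))
  expect_message(top2 <- read_atom_parameters(dipeptide_params_path(), top),
                 "net charge")
  expect_equal(sum(top2$atoms$charge), attr(top2, "group_charges")[["all"]])
  expect_equal(top2$atoms$lj_sigma[1], 0.325)

  # table missing an atom names it
  tab <- read.table(dipeptide_params_path(), header = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab[-5, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_atom_parameters(f, top), "CB",
               class = "mdbind_missing_parameter_error")

  # duplicate rows are ambiguous
  write.table(rbind(tab, tab[1, ]), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_atom_parameters(f, top), class = "mdbind_ambiguity_error")
})

test_that("Lorentz-Berthelot combination gives the arithmetic-mean sigma", {
  # two beads sigma 0.30/0.34 -> sigma_ij = 0.32; LJ crosses zero at r = 0.32
  top <- bead_topology(2, charge = 0, sigma = c(0.30, 0.34), epsilon = 1)
  top <- set_group(top, "receptor", 1)
  top <- set_group(top, "ligand", 2)
  arr <- array(0, c(2, 2, 3)); arr[, 2, 1] <- 0.32
  tr <- as_trajectory(arr, top, times = 1:2, discard_ns = 0)
  e <- group_interaction_energy(tr, "receptor", "ligand")
  expect_equal(e$total[1], 0, tolerance = 1e-10)
})

test_that("selection grammar is deterministic, composable and validated", {
  rs <- read_structure(dipeptide_path())
  top <- rs$topology
  expect_equal(length(select_atoms(top, "name CA")), 2)
  expect_equal(select_atoms(top, "chain A and resid 1"), 1:5)
  expect_equal(select_atoms(top, "resid 1-2"), 1:10)
  expect_error(select_atoms(top, "chain Q and resid 5-3"), "reversed",
               class = "mdbind_parse_error")
  expect_error(select_atoms(top, "resid"), class = "mdbind_parse_error")
  expect_warning(select_atoms(top, "chain Z"), "no atoms")

  # idempotent / order-stable; union of disjoint groups has no duplicates
  s1 <- select_atoms(top, "name CA or name N")
  expect_identical(s1, sort(unique(s1)))
  u <- union(select_atoms(top, "resid 1"), select_atoms(top, "resid 2"))
  expect_equal(anyDuplicated(u), 0L)

  # heavy excludes hydrogens
  ht <- topology(data.frame(
    name = c("N", "H"), element = c("N", "H"), residue_index = c(1, 1),
    residue_name = "GLY", chain_id = "A"))
  expect_equal(select_atoms(ht, "heavy"), 1L)
})

test_that("trajectory loading enforces the discard and topology contracts", {
  rs <- read_structure(dipeptide_path())
  spec <- toy_complex_spec(n_frames = 3)
  tc <- gen_toy_complex(spec)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(f, tc$parent$topology, tc$parent$trajectory)
  tr <- load_trajectory(f, tc$parent$topology, dt_ps = 1, discard_ns = 0)
  expect_equal(dim(tr$replicas[[1]]$coords)[1], 3)

  # 1000 frames at 1 ns spacing, discard 200 ns -> 800 analysis frames
  top <- bead_topology(2)
  arr <- array(rnorm(1000 * 2 * 3, sd = 0.01), c(1000, 2, 3))
  tr2 <- as_trajectory(arr, top, times = (1:1000) * 1000, discard_ns = 200)
  expect_equal(length(analysis_frames(tr2)), 800)

  # atom-count mismatch and non-monotone times are errors
  expect_error(load_trajectory(f, rs$topology),
               class = "mdbind_mismatch_error")
  expect_error(as_trajectory(arr, top, times = rep(1, 1000)),
               class = "mdbind_format_error")
})
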