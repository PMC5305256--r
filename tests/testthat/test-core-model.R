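test_that("PDB structures parse with correct residues, atoms and hetero ions", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  s <- read_structure(f)
  expect_equal(nrow(s$residues), 3)
  expect_equal(n_atoms(s), 14)
  expect_equal(s$residues$residue_name, c("ALA", "GLY", "ALA"))
  expect_true(all(s$atoms$is_backbone[s$atoms$name %in% c("N", "CA", "C", "O")]))

  # hetero ion retained as a single-atom residue
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_lines()[1:14],
               pdb_line(15, "MG", "MG", "A", 4, 20, 20, 20,
                        record = "HETATM", element = "MG"),
               "END"), f2)
  s2 <- read_structure(f2)
  expect_true("MG" %in% s2$residues$residue_name)
  expect_equal(nrow(s2$residues), 4)
})

test_that("unparseable or malformed PDB input is rejected with clear errors", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "empty structure")
  bad <- toy_pdb_lines()
  substr(bad[3], 31, 38) <- "  xx.yyy"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_structure(f2), "malformed coordinates")
})

test_that("multi-model files become ensembles with per-model validation", {
  block <- function(k, lines) c(sprintf("MODEL %8d", k), lines, "ENDMDL")
  atoms <- toy_pdb_lines()[1:14]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(unlist(lapply(1:7, block, lines = atoms)), "END"), f)
  ens <- read_ensemble(f, frame_interval = 0.02)
  expect_equal(n_frames(ens), 7)
  expect_equal(n_atoms(ens), 14)

  # a single un-modeled PDB counts as one frame
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(atoms, "END"), f1)
  expect_equal(n_frames(read_ensemble(f1)), 1)

  # model 3 missing an atom is named in the error
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(unlist(lapply(1:2, block, lines = atoms)),
               block(3, atoms[-5]), block(4, atoms), "END"), f3)
  expect_error(read_ensemble(f3), "model 3")

  # unbalanced MODEL/ENDMDL is a parse error
  f4 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1", atoms, "MODEL        2", atoms, "ENDMDL"), f4)
  expect_error(read_ensemble(f4), "MODEL")
})

test_that("multi-model round trip preserves topology and coordinates", {
  ref <- make_ca_structure(8)
  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.05,
                                             n_frames = 5, seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, f)
  back <- read_ensemble(f)
  expect_equal(n_frames(back), 5)
  expect_equal(n_atoms(back), 8)
  expect_equal(back$topology$residues$residue_name,
               ens$topology$residues$residue_name)
  expect_equal(residue_labels(back$topology), residue_labels(ens$topology))
  # PDB stores 0.001 Angstrom = 1e-4 nm precision
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-4)
})

test_that("superposition removes rigid-body motion and matches the quaternion oracle", {
  ref <- make_ca_structure(6)
  refxyz <- as.numeric(t(ref$coords))

  # pure translation
  shifted <- matrix(refxyz + rep(c(1, 2, 3), 6), nrow = 1)
  ens <- ensemble(ref, shifted)
  fit <- superpose_frames(ens, ref$coords, selection = "calpha")
  expect_lt(max(abs(fit$xyz[1, ] - refxyz)), 1e-9)

  # 90-degree rotation about z
  P <- ref$coords %*% t(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  ens2 <- ensemble(ref, matrix(as.numeric(t(P)), nrow = 1))
  fit2 <- superpose_frames(ens2, ref$coords)
  expect_lt(max(abs(fit2$xyz[1, ] - refxyz)), 1e-9)

  # 4-atom toy with one displaced atom: RMSD equals the independent oracle
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B <- A
  B[4, ] <- B[4, ] + c(0.4, 0, 0)
  toy <- make_ca_structure(4)
  toy$coords <- A
  ensB <- ensemble(toy, matrix(as.numeric(t(B)), nrow = 1))
  s <- rmsd_series(ensB, A, selection = "calpha")
  expect_equal(s$value[1], horn_rmsd(A, B), tolerance = 1e-8)
})

test_that("superposition is idempotent and preserves intra-frame distances", {
  ref <- make_ca_structure(10)
  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.08,
                                             n_frames = 6, seed = 11))
  fit1 <- superpose_frames(ens, ref$coords)
  fit2 <- superpose_frames(fit1, ref$coords)
  expect_lt(max(abs(fit1$xyz - fit2$xyz)), 1e-6)
  for (k in c(1, 4, 6)) {
    d_before <- dist(frame_coords(ens, k))
    d_after <- dist(frame_coords(fit1, k))
    expect_lt(max(abs(d_before - d_after)), 1e-9)
  }
})

test_that("degenerate superposition selections are rejected", {
  # explicitly collinear 4-atom reference
  line <- structure_model(
    data.frame(name = "CA", element = "C", residue_ordinal = 1:4,
               residue_name = "ALA", chain_id = "A"),
    cbind(x = 0.38 * (0:3), y = 0, z = 0))
  ens <- gen_harmonic_ensemble(harmonic_spec(line, isotropic_sigma = 0.02,
                                             n_frames = 2, seed = 1))
  expect_error(superpose_frames(ens, line$coords), "collinear")
  ref2 <- make_ca_structure(2)
  ens2 <- gen_harmonic_ensemble(harmonic_spec(ref2, isotropic_sigma = 0.02,
                                              n_frames = 2, seed = 1))
  expect_error(superpose_frames(ens2, ref2$coords), "degenerate")
})
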