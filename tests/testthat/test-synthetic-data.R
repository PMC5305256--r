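test_that("harmonic generator honours degenerate and deterministic contracts", {
  ref <- make_ca_structure(5)
  still <- gen_harmonic_ensemble(harmonic_spec(ref, n_frames = 4, seed = 1))
  expect_true(all(apply(still$xyz, 2, function(x) all(x == x[1]))))
  expect_equal(still$xyz[1, ], as.numeric(t(ref$coords)))

  a <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.02,
                                           n_frames = 50, seed = 42))
  b <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.02,
                                           n_frames = 50, seed = 42))
  expect_identical(a$xyz, b$xyz)
  c <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.02,
                                           n_frames = 50, seed = 43))
  expect_false(identical(a$xyz, c$xyz))

  # non-orthonormal modes rejected
  v <- rep(1, 15)
  expect_error(harmonic_spec(ref, mode_vectors = list(v), mode_amplitudes = 0.1),
               "orthonormal")
})

test_that("harmonic fluctuations match the closed-form RMSF and covariance trace", {
  ref <- make_ca_structure(50)
  sigma <- 0.02
  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = sigma,
                                             n_frames = 5000, seed = 7))
  # raw per-atom RMSF about the per-atom mean (no fitting): E[RMSF] = sigma*sqrt(3)
  mu <- colMeans(ens$xyz)
  msf_coord <- colMeans(sweep(ens$xyz, 2, mu)^2)
  rmsf <- sqrt(msf_coord[c(TRUE, FALSE, FALSE)] + msf_coord[c(FALSE, TRUE, FALSE)] +
                 msf_coord[c(FALSE, FALSE, TRUE)])
  expect_equal(mean(rmsf), sigma * sqrt(3), tolerance = 0.03)

  # covariance trace -> 3N sigma^2 (within 5% at 5000 frames)
  expect_equal(covariance_trace(ens), 3 * 50 * sigma^2, tolerance = 0.05)

  # with planted modes the trace converges to sum(a^2) + 3N sigma^2
  nc <- 3 * 50
  v1 <- rep(0, nc); v1[1] <- 1
  v2 <- rep(0, nc); v2[5] <- 1
  ens2 <- gen_harmonic_ensemble(harmonic_spec(
    ref, mode_vectors = list(v1, v2), mode_amplitudes = c(0.1, 0.05),
    isotropic_sigma = sigma, n_frames = 5000, seed = 8))
  expect_equal(covariance_trace(ens2), 0.1^2 + 0.05^2 + nc * sigma^2,
               tolerance = 0.05)
})

test_that("basin mixtures realise the planted weights and separation", {
  base <- make_ca_structure(10)
  refs <- make_basin_references(base, 2, separation = 2, seed = 5)
  spec <- basin_spec(refs, list(c(1, 0), c(0.5, 0.5)),
                     intra_basin_sigma = 0.05, min_separation = 2,
                     n_frames = 2000, seed = 1)

  # degenerate mixture: every frame within jitter of basin 1
  e1 <- gen_basin_mixture(spec, 1)
  ref1 <- as.numeric(t(refs[[1]]$coords))
  dev <- sqrt(rowMeans(sweep(e1$xyz, 2, ref1)^2))  # per-coordinate RMS
  expect_lt(max(dev), 0.05 * 2)  # all frames are basin-1 jitter

  # 0.5/0.5 at 2000 frames: empirical fraction within the binomial bound,
  # recovered by independent nearest-reference assignment
  e2 <- gen_basin_mixture(spec, 2)
  d1 <- sqrt(rowSums(sweep(e2$xyz, 2, ref1)^2))
  d2 <- sqrt(rowSums(sweep(e2$xyz, 2, as.numeric(t(refs[[2]]$coords)))^2))
  frac1 <- mean(d1 < d2)
  expect_equal(frac1, 0.5, tolerance = 0.06)  # 0.5 +/- 0.03 absolute
  expect_equal(frac1, mean(attr(e2, "basin_assignment") == 1), tolerance = 1e-12)

  # references violating min_separation are rejected
  expect_error(basin_spec(refs, list(c(1, 0)), min_separation = 100),
               "min_separation")
})

test_that("well-separated basins satisfy the CES separability guarantee", {
  base <- make_ca_structure(8)
  sigma <- 0.02
  refs <- make_basin_references(base, 2, separation = 20 * sigma * 10, seed = 2)
  spec <- basin_spec(refs, list(c(1, 0), c(0, 1)), intra_basin_sigma = sigma,
                     min_separation = 20 * sigma, n_frames = 60, seed = 3)
  ea <- gen_basin_mixture(spec, 1)
  eb <- gen_basin_mixture(spec, 2)
  pw <- pairwise_rmsd(list(ea, eb))
  cross <- pw$rmsd[pw$origin == 1, pw$origin == 2]
  within <- pw$rmsd[pw$origin == 1, pw$origin == 1]
  expect_gt(min(cross), 10 * max(within))
})

test_that("contact peptides plant interactions at exact persistence", {
  for (ct in c("hbond", "saltbridge", "hydrophobic")) {
    ens <- gen_contact_peptide(ct, 0.35, n_frames = 100, seed = 6)
    # independent per-frame recount of the planted criterion
    n_on <- sum(vapply(seq_len(n_frames(ens)), function(k) {
      nrow(detect_frame_interactions(frame_coords(ens, k), ens$topology, ct))
    }, 0L))
    expect_equal(n_on, 35)
    expect_equal(sum(attr(ens, "contact_frames")), 35)

    full <- gen_contact_peptide(ct, 1, n_frames = 10, seed = 1)
    g <- build_psn(full, ct, persistence_threshold = 0.2)
    expect_equal(g$edges$persistence, 1)

    none <- gen_contact_peptide(ct, 0, n_frames = 10, seed = 1)
    g0 <- build_psn(none, ct, persistence_threshold = 1e-9)
    expect_equal(nrow(g0$edges), 0)
  }
  expect_error(gen_contact_peptide("pi-stack", 0.5), "arg")
})

test_that("labeled alignments plant candidate and drift columns as specified", {
  # no planted columns: identical targets, no substitution sites
  a0 <- gen_labeled_alignment(4, 4, 30, seed = 1)
  expect_identical(a0$sequences[[a0$target_a]], a0$sequences[[a0$target_b]])
  expect_equal(nrow(substitution_sites(a0)), 0)

  aln <- gen_labeled_alignment(6, 6, 80,
                               planted_candidate_columns = c(3, 17, 40),
                               planted_drift_columns = c(9, 22, 51, 70),
                               seed = 2)
  seqs <- vapply(aln$sequences, identity, "")
  M <- do.call(rbind, strsplit(seqs, ""))
  cold <- aln$labels %in% c("psychrophilic", "psychrotolerant")
  for (j in c(3, 17, 40)) {
    expect_equal(length(unique(M[cold, j])), 1)
    expect_equal(length(unique(M[!cold, j])), 1)
    expect_false(M[cold, j][1] == M[!cold, j][1])
  }
  for (j in c(9, 22, 51, 70)) {
    expect_gt(length(unique(M[!cold, j])), 1)     # heterogeneous mesophiles
    expect_false(M[1, j] == M[7, j])              # targets differ
  }
  other <- setdiff(seq_len(80), c(3, 17, 40, 9, 22, 51, 70))
  expect_true(all(apply(M[, other, drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))

  expect_identical(gen_labeled_alignment(4, 4, 30, 5, 9, seed = 3),
                   gen_labeled_alignment(4, 4, 30, 5, 9, seed = 3))
  expect_error(gen_labeled_alignment(4, 4, 30, c(5), c(5)), "overlap")
})
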