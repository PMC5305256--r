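make_two_atom <- function(d = 1) {
  structure_model(
    data.frame(name = "CA", element = "C", residue_ordinal = 1:2,
               residue_name = "ALA", chain_id = "A"),
    rbind(c(0, 0, 0), c(d, 0, 0)))
}

test_that("RMSD series is zero for self-comparison and after rigid translation", {
  ref <- make_ca_structure(6)
  still <- gen_harmonic_ensemble(harmonic_spec(ref, n_frames = 4, seed = 1))
  expect_equal(rmsd_series(still, ref$coords, "calpha")$value, rep(0, 4))

  shifted <- still
  shifted$xyz <- still$xyz + matrix(rep(c(0.1, 0.02, -0.05), 6),
                                    nrow = 4, ncol = 18, byrow = TRUE)
  expect_lt(max(rmsd_series(shifted, ref$coords, "calpha")$value), 1e-6)
  expect_error(rmsd_series(still, ref$coords, selection = integer(0)), "empty|range")
})

test_that("radius of gyration follows the closed form and is translation invariant", {
  one <- structure_model(
    data.frame(name = "CA", element = "C", residue_ordinal = 1,
               residue_name = "ALA", chain_id = "A"),
    matrix(c(1, 2, 3), nrow = 1))
  e1 <- one_frame_ensemble(one)
  expect_equal(radius_of_gyration_series(e1)$value, 0)

  # two equal-mass atoms 1 nm apart: Rg = 0.5 nm
  e2 <- one_frame_ensemble(make_two_atom(1))
  expect_equal(radius_of_gyration_series(e2)$value, 0.5, tolerance = 1e-12)

  e3 <- e2
  e3$xyz <- e3$xyz + rep(c(5, -2, 1), 2)[c(1, 2, 3, 1, 2, 3)]
  expect_equal(radius_of_gyration_series(e3)$value,
               radius_of_gyration_series(e2)$value)
})

test_that("distance monitors report exact per-frame separations", {
  m <- make_two_atom(0.21)
  ens <- ensemble(m, rbind(as.numeric(t(m$coords)),
                           as.numeric(t(m$coords))))
  d <- distance_monitor(ens, 1, 2)
  expect_equal(d$value, c(0.21, 0.21))

  # atom 2 moving linearly away: monotone series with hand-computed norms
  xyz <- do.call(rbind, lapply(seq(0.2, 0.4, length.out = 5), function(g) {
    c(0, 0, 0, g, 0.1, 0)
  }))
  ens2 <- ensemble(m, xyz)
  d2 <- distance_monitor(ens2, "1:CA", "2:CA")
  expect_equal(d2$value, sqrt(seq(0.2, 0.4, length.out = 5)^2 + 0.01))
  expect_true(all(diff(d2$value) > 0))

  expect_error(distance_monitor(ens2, "1:CA", "9:CA"), "no atom")
})

test_that("windowed RMSF obeys the window arithmetic and the harmonic closed form", {
  ref <- make_ca_structure(40)
  still <- gen_harmonic_ensemble(harmonic_spec(ref, n_frames = 30, seed = 1))
  prof0 <- windowed_rmsf(still, window_ns = 10, exclude_initial_ns = 0)
  expect_true(all(prof0$rmsf_mean == 0))

  # 110 frames at 1 ns, 10 ns windows, 10 ns excluded -> 10 windows
  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.02,
                                             n_frames = 110, seed = 2))
  prof <- windowed_rmsf(ens, window_ns = 10, exclude_initial_ns = 10)
  expect_equal(attr(prof, "n_windows"), 10)

  # long single window: per-residue RMSF ~ sigma*sqrt(3) within 5%
  # (least-squares fitting to the window mean absorbs a small, known
  # fraction of the variance, well inside the tolerance at 40 residues)
  long <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.02,
                                              n_frames = 5000, seed = 3))
  p <- windowed_rmsf(long, window_ns = 5000, exclude_initial_ns = 0)
  expect_equal(mean(p$rmsf_mean), 0.02 * sqrt(3), tolerance = 0.05)

  expect_error(windowed_rmsf(ens, window_ns = 500, exclude_initial_ns = 10),
               "no complete window")
})

test_that("profile averaging uses the across-replicate mean and sd", {
  ref <- make_ca_structure(4)
  mk <- function(vals) {
    structure(data.frame(label = as.character(1:4), rmsf_mean = vals,
                         rmsf_sd = 0),
              class = c("flexibility_profile", "data.frame"),
              window_ns = 10, n_windows = 1, n_replicates = 1)
  }
  single <- average_profiles(list(mk(c(0.1, 0.2, 0.3, 0.4))))
  expect_equal(single$rmsf_mean, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(single$rmsf_sd, rep(0, 4))

  two <- average_profiles(list(mk(rep(0.1, 4)), mk(rep(0.3, 4))))
  expect_equal(two$rmsf_mean, rep(0.2, 4))
  expect_equal(two$rmsf_sd, rep(sd(c(0.1, 0.3)), 4))
  expect_equal(attr(two, "n_replicates"), 2)

  three <- average_profiles(list(mk(1:4 / 10), mk(1:4 / 10), mk(1:4 / 10)))
  expect_equal(three$rmsf_sd, rep(0, 4))

  bad <- mk(rep(0.1, 4)); bad$label <- as.character(5:8)
  expect_error(average_profiles(list(mk(rep(0.1, 4)), bad)), "labels")
})

test_that("profile differences subtract per residue and flag unmapped positions", {
  mk <- function(labels, vals) {
    structure(data.frame(label = labels, rmsf_mean = vals, rmsf_sd = 0),
              class = c("flexibility_profile", "data.frame"),
              window_ns = 10, n_windows = 1, n_replicates = 1)
  }
  a <- mk(c("41", "42", "43"), c(0.08, 0.05, 0.02))
  b <- mk(c("41", "42", "43"), c(0.05, 0.05, 0.02))
  d <- rmsf_difference(a, a)
  expect_true(all(d$difference == 0))
  d2 <- rmsf_difference(a, b)
  expect_equal(d2$difference[d2$label_a == "41"], 0.03)

  # an insertion present in only one profile becomes exactly one gap row
  a2 <- mk(c("51", "52", "52A", "53"), c(0.1, 0.1, 0.2, 0.1))
  b2 <- mk(c("51", "52", "53"), c(0.1, 0.1, 0.1))
  d3 <- rmsf_difference(a2, b2)
  expect_equal(sum(d3$gap), 1)
  expect_equal(d3$label_a[d3$gap], "52A")
  expect_error(rmsf_difference(a, b, residue_map = data.frame(label_a = character(0),
                                                              label_b = character(0))),
               "empty")
})

test_that("covariance trace equals the PCA eigenvalue sum and handles edge cases", {
  ref <- make_ca_structure(12)
  still <- gen_harmonic_ensemble(harmonic_spec(ref, n_frames = 5, seed = 1))
  expect_equal(covariance_trace(still), 0)

  one_frame <- ensemble(ref, matrix(as.numeric(t(ref$coords)), nrow = 1))
  expect_error(covariance_trace(one_frame), "single frame|undefined")

  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.03,
                                             n_frames = 200, seed = 4))
  tr <- covariance_trace(ens)
  ev <- pca_ensemble(ens)$eigenvalues
  expect_equal(tr, sum(ev), tolerance = 1e-9)
})

test_that("descriptors are invariant under a global rigid-body motion", {
  ref <- make_ca_structure(9)
  ens <- gen_harmonic_ensemble(harmonic_spec(ref, isotropic_sigma = 0.04,
                                             n_frames = 40, seed = 9))
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rot <- ens
  rot$xyz <- t(apply(ens$xyz, 1, function(row) {
    as.numeric(t(matrix(row, ncol = 3, byrow = TRUE) %*% t(R) +
                   matrix(rep(c(1, -2, 0.5), each = 9), ncol = 3)))
  }))
  expect_equal(rmsd_series(rot, ref$coords, "calpha")$value,
               rmsd_series(ens, ref$coords, "calpha")$value, tolerance = 1e-8)
  expect_equal(radius_of_gyration_series(rot)$value,
               radius_of_gyration_series(ens)$value, tolerance = 1e-9)
  expect_equal(windowed_rmsf(rot, 40, 0)$rmsf_mean,
               windowed_rmsf(ens, 40, 0)$rmsf_mean, tolerance = 1e-8)
})
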