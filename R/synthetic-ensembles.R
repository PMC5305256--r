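# Synthetic conformational ensembles with analytically known ground truth.
# These stand in for MD trajectories in every parameter-recovery test:
# harmonic ensembles have closed-form RMSF/covariance expectations, basin
# mixtures have prescribed cluster populations and separation.

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a C-alpha-trace toy structure
#'
#' A minimal poly-alanine C-alpha trace laid out on an ideal helix
#' (0.15 nm rise, 0.23 nm radius, 100 degrees twist per residue, giving
#' the canonical ~0.38 nm consecutive C-alpha distance).  The helical
#' layout keeps the trace non-collinear so least-squares fits are well
#' posed.  Used as the reference topology for synthetic ensembles.
#'
#' @param n_residues number of residues.
#' @param rise,radius,twist helix parameters (nm, nm, degrees/residue).
#' @return a `structure_model`.
#' @export
make_ca_structure <- function(n_residues, rise = 0.15, radius = 0.23,
                              twist = 100) {
  .assert(n_residues >= 1, "need at least one residue")
  atoms <- data.frame(
    name = "CA", element = "C",
    residue_ordinal = seq_len(n_residues),
    residue_name = "ALA", chain_id = "A",
    stringsAsFactors = FALSE
  )
  i <- seq_len(n_residues) - 1
  th <- i * twist * pi / 180
  coords <- cbind(x = i * rise, y = radius * cos(th), z = radius * sin(th))
  structure_model(atoms, coords)
}

#' Specification of a harmonic (Gaussian-fluctuation) ensemble
#'
#' Frames are the reference plus independent Gaussian displacements along a
#' prescribed set of orthonormal 3N-modes plus optional isotropic
#' per-coordinate noise:
#' `frame_k = ref + sum_m a_m z_{k,m} v_m + eps_k`, `z, eps ~ N(0,1)`.
#' The expected per-residue RMSF and the covariance trace are then known in
#' closed form (`trace -> sum_m a_m^2 + 3N sigma^2`).
#'
#' @param reference a `structure_model` giving the mean conformation.
#' @param mode_vectors list of orthonormal 3N-vectors (unit norm, mutually
#'   orthogonal), or `NULL` for pure isotropic noise.
#' @param mode_amplitudes standard deviation along each mode, nm.
#' @param isotropic_sigma per-coordinate isotropic noise sd, nm.
#' @param n_frames number of frames to draw.
#' @param seed RNG seed; the generator is a pure function of spec + seed.
#' @export
harmonic_spec <- function(reference, mode_vectors = NULL,
                          mode_amplitudes = numeric(0),
                          isotropic_sigma = 0, n_frames = 100, seed = 1) {
  .assert(inherits(reference, "structure_model"), "reference must be a structure_model")
  nc <- 3 * n_atoms(reference)
  mode_vectors <- mode_vectors %||% list()
  .assert(length(mode_vectors) == length(mode_amplitudes),
          "one amplitude per mode vector required")
  if (length(mode_vectors) > 0) {
    V <- do.call(cbind, mode_vectors)
    .assert(nrow(V) == nc, "mode vectors must have length 3 * n_atoms")
    gram <- crossprod(V)
    .assert(max(abs(gram - diag(ncol(V)))) < 1e-8,
            "mode vectors must be mutually orthonormal")
  }
  .assert(all(mode_amplitudes >= 0), "mode amplitudes must be >= 0")
  .assert(isotropic_sigma >= 0, "isotropic_sigma must be >= 0")
  .assert(n_frames >= 1, "n_frames must be >= 1")
  structure(list(reference = reference, mode_vectors = mode_vectors,
                 mode_amplitudes = mode_amplitudes,
                 isotropic_sigma = isotropic_sigma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "harmonic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a harmonic synthetic ensemble
#'
#' @param spec a [harmonic_spec()].
#' @param frame_interval time per frame, ns.
#' @param replicate_id,system_id identifiers for the result.
#' @return an [ensemble()]; deterministic given the spec's seed.
#' @export
gen_harmonic_ensemble <- function(spec, frame_interval = 1,
                                  replicate_id = "rep1",
                                  system_id = "harmonic") {
  .assert(inherits(spec, "harmonic_spec"), "spec must be a harmonic_spec")
  ref <- as.numeric(t(spec$reference$coords))
  nc <- length(ref)
  nf <- spec$n_frames
  xyz <- .with_seed(spec$seed, {
    out <- matrix(rep(ref, each = nf), nrow = nf)
    if (length(spec$mode_vectors) > 0) {
      Z <- matrix(rnorm(nf * length(spec$mode_vectors)), nrow = nf)
      V <- do.call(cbind, spec$mode_vectors)
      out <- out + Z %*% (t(V) * spec$mode_amplitudes)
    }
    if (spec$isotropic_sigma > 0) {
      out <- out + matrix(rnorm(nf * nc, sd = spec$isotropic_sigma), nrow = nf)
    }
    out
  })
  ensemble(spec$reference, xyz, frame_interval = frame_interval,
           replicate_id = replicate_id, system_id = system_id)
}

#' Specification of a multi-basin mixture ensemble
#'
#' Each frame is drawn from one of several well-separated reference
#' conformations ("basins") with prescribed mixture weights, then jittered
#' isotropically.  With basins separated far beyond the jitter, joint
#' clustering recovers the basins exactly and the cluster populations
#' equal the planted weights up to binomial sampling error — the construction
#' the ensemble-similarity endpoints (identical vs non-overlapping) rely on.
#'
#' @param basin_references list of `structure_model`s sharing a topology.
#' @param weights_per_ensemble list of probability vectors (one per
#'   ensemble to be generated), each of length `length(basin_references)`.
#' @param intra_basin_sigma per-coordinate jitter sd within a basin, nm.
#' @param min_separation minimum pairwise fitted C-alpha RMSD required
#'   between basin references, nm.
#' @param n_frames frames per generated ensemble.
#' @param seed RNG seed.
#' @export
basin_spec <- function(basin_references, weights_per_ensemble,
                       intra_basin_sigma = 0.05, min_separation = 1,
                       n_frames = 1000, seed = 1) {
  .assert(length(basin_references) >= 1, "need at least one basin reference")
  .assert(all(vapply(basin_references, inherits, logical(1), "structure_model")),
          "basin references must be structure_models")
  nb <- length(basin_references)
  for (w in weights_per_ensemble) {
    .assert(length(w) == nb, "each weight vector needs one entry per basin")
    .assert(all(w >= 0), "weights must be >= 0")
    .assert(abs(sum(w) - 1) < 1e-9, "weights must sum to 1 (got %.12f)", sum(w))
  }
  if (nb > 1) {
    xyz <- do.call(rbind, lapply(basin_references,
                                 function(s) as.numeric(t(s$coords))))
    D <- .pairwise_rmsd_cpp(xyz)
    dmin <- min(D[upper.tri(D)])
    .assert(dmin >= min_separation,
            "basin references violate min_separation: fitted RMSD %.4f < %.4f nm",
            dmin, min_separation)
  }
  .assert(intra_basin_sigma >= 0, "intra_basin_sigma must be >= 0")
  .assert(n_frames >= 1, "n_frames must be >= 1")
  structure(list(basin_references = basin_references,
                 weights_per_ensemble = weights_per_ensemble,
                 intra_basin_sigma = intra_basin_sigma,
                 min_separation = min_separation,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "basin_spec")
}

#' Generate one ensemble of a basin-mixture specification
#'
#' @param spec a [basin_spec()].
#' @param ensemble_index which weight vector to realise (1-based).
#' @param frame_interval time per frame, ns.
#' @param system_id identifier for the result.
#' @return an [ensemble()]; the drawn basin per frame is attached as
#'   attribute `"basin_assignment"` (ground truth for recovery tests).
#' @export
gen_basin_mixture <- function(spec, ensemble_index = 1, frame_interval = 1,
                              system_id = "basins") {
  .assert(inherits(spec, "basin_spec"), "spec must be a basin_spec")
  .assert(ensemble_index >= 1 &&
            ensemble_index <= length(spec$weights_per_ensemble),
          "ensemble_index out of range (have %d weight vectors)",
          length(spec$weights_per_ensemble))
  w <- spec$weights_per_ensemble[[ensemble_index]]
  refs <- lapply(spec$basin_references, function(s) as.numeric(t(s$coords)))
  nf <- spec$n_frames
  nc <- length(refs[[1]])
  # one named stream per generated ensemble: offset the seed by the index
  res <- .with_seed(spec$seed + ensemble_index, {
    b <- sample.int(length(refs), nf, replace = TRUE, prob = w)
    xyz <- do.call(rbind, lapply(b, function(k) refs[[k]]))
    if (spec$intra_basin_sigma > 0) {
      xyz <- xyz + matrix(rnorm(nf * nc, sd = spec$intra_basin_sigma), nrow = nf)
    }
    list(b = b, xyz = xyz)
  })
  ens <- ensemble(spec$basin_references[[1]], res$xyz,
                  frame_interval = frame_interval,
                  replicate_id = paste0("ens", ensemble_index),
                  system_id = system_id)
  attr(ens, "basin_assignment") <- res$b
  ens
}

#' Construct well-separated basin reference conformations
#'
#' Deforms a base structure with random Gaussian displacements, scaling the
#' deformation until every pair of references is at least `separation`
#' apart in fitted C-alpha RMSD (rigid-body differences would be removed by
#' the fit, so the references must differ in internal geometry).
#'
#' @param base a `structure_model`.
#' @param n_basins number of references.
#' @param separation minimum pairwise fitted RMSD, nm.
#' @param seed RNG seed.
#' @return list of `structure_model`s.
#' @export
make_basin_references <- function(base, n_basins = 2, separation = 1,
                                  seed = 1) {
  .assert(inherits(base, "structure_model"), "base must be a structure_model")
  nc <- 3 * n_atoms(base)
  .with_seed(seed, {
    delta <- lapply(seq_len(n_basins), function(k) rnorm(nc))
    scale <- separation
    for (i in 1:60) {
      xyz <- do.call(rbind, lapply(seq_len(n_basins), function(k) {
        as.numeric(t(base$coords)) + scale * delta[[k]]
      }))
      if (n_basins == 1) break
      D <- .pairwise_rmsd_cpp(xyz)
      if (min(D[upper.tri(D)]) >= separation) break
      scale <- scale * 1.3
    }
    lapply(seq_len(n_basins), function(k) {
      s <- base
      s$coords <- base$coords + matrix(scale * delta[[k]], ncol = 3, byrow = TRUE)
      s
    })
  })
}
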