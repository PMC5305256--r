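#' Principal component analysis of C-alpha fluctuations
#'
#' Eigendecomposition of the 3N x 3N covariance matrix of the selected
#' coordinates.  Frames are assumed pre-fitted to a common reference (use
#' [superpose_frames()]); a constant trajectory yields all-zero
#' eigenvalues, not an error.  The eigenvalue sum equals the covariance
#' trace of the same data.
#'
#' @param ens an [ensemble()] with at least two frames.
#' @param selection atom selection, default C-alpha.
#' @return a `pca_basis`: list with `mean_structure` (3N vector, nm),
#'   `eigenvectors` (3N x 3N orthonormal matrix, descending eigenvalue
#'   order) and `eigenvalues` (nm^2, non-negative).
#' @export
pca_ensemble <- function(ens, selection = "calpha") {
  .assert(n_frames(ens) >= 2, "PCA needs at least two frames")
  sel <- select_atoms(ens$topology, selection)
  .assert(length(sel) >= 1, "empty selection")
  X <- ens$xyz[, .xyz_idx(sel), drop = FALSE]
  mu <- colMeans(X)
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  structure(list(mean_structure = mu, eigenvectors = e$vectors,
                 eigenvalues = vals),
            class = "pca_basis")
}

#' Root mean square inner product between two essential subspaces
#'
#' Overlap of the subspaces spanned by the first `n_components` principal
#' components of two ensembles:
#' `RMSIP = sqrt( (1/D) * sum_{i<=D} sum_{j<=D} (v_i^a . v_j^b)^2 )`.
#' Ranges from 0 (no correlation between the sampled phase spaces) to 1
#' (completely overlapping subspaces); a basis against itself gives
#' exactly 1.
#'
#' @param basis_a,basis_b `pca_basis` objects of equal dimension.
#' @param n_components number of leading components compared (default 10).
#' @return scalar in `[0, 1]`.
#' @export
rmsip <- function(basis_a, basis_b, n_components = 10) {
  .assert(inherits(basis_a, "pca_basis") && inherits(basis_b, "pca_basis"),
          "inputs must be pca_basis objects")
  Va <- basis_a$eigenvectors
  Vb <- basis_b$eigenvectors
  .assert(nrow(Va) == nrow(Vb),
          "bases have different dimension (%d vs %d)", nrow(Va), nrow(Vb))
  D <- as.integer(n_components)
  .assert(D >= 1 && D <= ncol(Va) && D <= ncol(Vb),
          "n_components exceeds the available components")
  ip <- crossprod(Va[, seq_len(D), drop = FALSE],
                  Vb[, seq_len(D), drop = FALSE])
  val <- sqrt(sum(ip^2) / D)
  val <- min(max(val, 0), 1)
  # the self-overlap of an orthonormal subspace is exactly 1; absorb the
  # last-bit rounding of the double sum so the identity holds exactly
  if (1 - val < 1e-12) val <- 1
  val
}

#' RMSIP matrix across the replicates of a system
#'
#' All-vs-all RMSIP between the PCA bases of a set of replicates, the
#' content of a replicate-sampling heatmap.  Each ensemble is fitted to
#' the shared first-replicate reference before PCA.
#'
#' @param replicates a [replicate_set()] or list of ensembles.
#' @param n_components leading components compared.
#' @param selection atom selection.
#' @return a [similarity_matrix()] with metric `"rmsip"`.
#' @export
rmsip_matrix <- function(replicates, n_components = 10, selection = "calpha") {
  ens <- if (inherits(replicates, "replicate_set")) replicates$ensembles else replicates
  .assert(length(ens) >= 2, "need at least two replicates")
  ref <- ens[[1]]$xyz[1, ]
  bases <- lapply(ens, function(e) {
    pca_ensemble(superpose_frames(e, ref, selection), selection)
  })
  n <- length(ens)
  V <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      V[i, j] <- V[j, i] <- rmsip(bases[[i]], bases[[j]], n_components)
    }
  }
  similarity_matrix(vapply(ens, function(e) e$replicate_id, ""), V, "rmsip")
}
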