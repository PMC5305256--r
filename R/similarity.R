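#' Symmetric replicate-similarity matrix
#'
#' Container for an all-vs-all comparison of replicate ensembles, either
#' as subspace overlap (`rmsip`, diagonal 1) or as Jensen-Shannon
#' divergence of ensemble probability densities (`ces_jsd` / `dres_jsd`,
#' diagonal 0, natural-log bound `ln 2`).
#'
#' @param ids replicate identifiers.
#' @param values symmetric numeric matrix.
#' @param metric one of `"rmsip"`, `"ces_jsd"`, `"dres_jsd"`.
#' @export
similarity_matrix <- function(ids, values, metric) {
  metric <- match.arg(metric, c("rmsip", "ces_jsd", "dres_jsd"))
  values <- as.matrix(values)
  .assert(length(ids) >= 1, "empty id list")
  .assert(nrow(values) == length(ids) && ncol(values) == length(ids),
          "matrix dimensions must match the id list")
  .assert(max(abs(values - t(values))) < 1e-9, "matrix must be symmetric")
  if (metric == "rmsip") {
    .assert(all(abs(diag(values) - 1) < 1e-9), "rmsip diagonal must be 1")
    .assert(all(values >= -1e-9 & values <= 1 + 1e-9), "rmsip values must lie in [0,1]")
  } else {
    .assert(all(abs(diag(values)) < 1e-9), "jsd diagonal must be 0")
    .assert(all(values >= -1e-9 & values <= log(2) + 1e-6),
            "jsd values must lie in [0, ln 2]")
  }
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, metric = metric),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s), %d replicates\n", x$metric,
              length(x$ids)))
  print(round(x$values, 4))
  invisible(x)
}

#' Discrete Jensen-Shannon divergence (natural log)
#'
#' `JSD(P, Q) = H((P+Q)/2) - H(P)/2 - H(Q)/2` with Shannon entropy in
#' nats; bounded by `ln 2 ~ 0.693`.  0 means identical distributions,
#' values near `ln 2` mean disjoint support.
#'
#' @param p,q probability vectors of equal length (each summing to 1).
#' @return scalar in `[0, ln 2]`.
#' @export
jsd_discrete <- function(p, q) {
  .assert(length(p) == length(q), "p and q must have equal length")
  .assert(all(p >= 0) && all(q >= 0), "probabilities must be >= 0")
  .assert(abs(sum(p) - 1) < 1e-6 && abs(sum(q) - 1) < 1e-6,
          "probabilities must sum to 1")
  H <- function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  }
  val <- H((p + q) / 2) - H(p) / 2 - H(q) / 2
  min(max(val, 0), log(2))
}

#' Clustering-based ensemble similarity (CES)
#'
#' Pools the frames of all ensembles, clusters the pooled pairwise fitted
#' C-alpha RMSD matrix by affinity propagation (similarity = negative
#' RMSD, with the given preference on the diagonal), converts each
#' ensemble into a probability vector over the clusters (the fraction of
#' its frames per cluster), and returns the pairwise Jensen-Shannon
#' divergence between those vectors.  Identical ensembles give 0;
#' ensembles confined to disjoint conformational basins give `ln 2`.
#'
#' @param ensembles list of at least two ensembles sharing a topology.
#' @param preference affinity-propagation preference, in the similarity's
#'   negative-nm units (default -10; lower values give fewer clusters).
#' @param selection atom selection for the RMSD, default C-alpha.
#' @param stride keep every `stride`-th frame of each ensemble before
#'   pooling; default chosen so the pool holds at most `max_pooled` frames.
#' @param max_pooled pool-size cap used when `stride` is `NULL`.
#' @param damping,maxit,convits affinity-propagation message damping,
#'   iteration cap, and stable-sweep count for convergence.
#' @param exemplar_merge_tol clusters whose exemplars lie within this RMSD
#'   (nm) are merged after clustering.  Duplicated conformations can elect
#'   coincident exemplars (one per copy), which would split identical
#'   ensembles across artificial cluster pairs; merging coincident
#'   exemplars removes that degeneracy.
#' @return a [similarity_matrix()] with metric `"ces_jsd"`; cluster
#'   assignments and per-ensemble population vectors are attached as
#'   attributes `"assignment"`, `"origin"` and `"populations"`.
#' @export
ces <- function(ensembles, preference = -10, selection = "calpha",
                stride = NULL, max_pooled = 3000,
                damping = 0.9, maxit = 1000, convits = 50,
                exemplar_merge_tol = 1e-6) {
  .assert(is.list(ensembles) && length(ensembles) >= 2,
          "CES needs at least two ensembles")
  ensembles <- .stride_ensembles(ensembles, stride, max_pooled)
  pw <- pairwise_rmsd(ensembles, selection)
  S <- -pw$rmsd
  diag(S) <- preference
  fit <- .affinity_propagation_cpp(S, damping, maxit, convits)
  if (!fit$converged && fit$iterations >= maxit) {
    .stopf("affinity propagation did not converge within %d iterations", maxit)
  }
  assign <- as.integer(fit$assignment)
  ex <- sort(unique(assign))
  if (length(ex) > 1 && exemplar_merge_tol > 0) {
    Dex <- pw$rmsd[ex, ex, drop = FALSE]
    root <- seq_along(ex)
    for (i in seq_len(length(ex) - 1)) {
      for (j in (i + 1):length(ex)) {
        if (Dex[i, j] < exemplar_merge_tol && root[j] != root[i]) {
          root[root == root[j]] <- root[i]
        }
      }
    }
    remap <- setNames(ex[root], ex)
    assign <- unname(remap[as.character(assign)])
  }
  clusters <- sort(unique(assign))
  if (length(clusters) == 1) {
    message("CES: all pooled frames fell into a single cluster; JSD is 0")
  }
  pops <- do.call(rbind, lapply(seq_along(ensembles), function(e) {
    tab <- table(factor(assign[pw$origin == e], levels = clusters))
    as.numeric(tab) / sum(tab)
  }))
  n <- length(ensembles)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) V[i, j] <- V[j, i] <- jsd_discrete(pops[i, ], pops[j, ])
    }
  }
  out <- similarity_matrix(vapply(ensembles, function(e) e$replicate_id, ""),
                           V, "ces_jsd")
  attr(out, "assignment") <- assign
  attr(out, "origin") <- pw$origin
  attr(out, "populations") <- pops
  out
}

.stride_ensembles <- function(ensembles, stride, max_pooled) {
  total <- sum(vapply(ensembles, n_frames, integer(1)))
  if (is.null(stride)) stride <- max(1L, ceiling(total / max_pooled))
  if (stride > 1) {
    ensembles <- lapply(ensembles, function(e) {
      e$xyz <- e$xyz[seq(1, n_frames(e), by = stride), , drop = FALSE]
      e$frame_interval <- e$frame_interval * stride
      e
    })
  }
  ensembles
}

#' Dimensionality-reduction-based ensemble similarity (DRES)
#'
#' Embeds the pooled frames into `dim` dimensions by stochastic proximity
#' embedding of the pooled pairwise fitted C-alpha RMSD matrix, estimates
#' each ensemble's density in the embedded space by Gaussian kernel
#' density estimation (Scott's-rule bandwidth), and estimates the pairwise
#' Jensen-Shannon divergence by Monte-Carlo sampling from the two
#' densities.  Values are clipped to `[0, ln 2]`.  Deterministic for a
#' fixed `seed`.
#'
#' @inheritParams ces
#' @param dim embedding dimension (default 6).
#' @param seed RNG seed for the embedding initialisation and the
#'   Monte-Carlo JSD estimate.
#' @param n_cycles,steps_per_cycle SPE annealing cycles and pair updates
#'   per cycle (default `50 * n` pooled pairs per cycle; enough cycles
#'   that duplicated frames embed at coincident points).
#' @param mc_samples Monte-Carlo sample count per density per pair.
#' @return a [similarity_matrix()] with metric `"dres_jsd"`; the embedded
#'   coordinates are attached as attribute `"embedding"`.
#' @export
dres <- function(ensembles, dim = 6, seed = 1, selection = "calpha",
                 stride = NULL, max_pooled = 3000,
                 n_cycles = 200, steps_per_cycle = NULL, mc_samples = 10000) {
  .assert(is.list(ensembles) && length(ensembles) >= 2,
          "DRES needs at least two ensembles")
  ensembles <- .stride_ensembles(ensembles, stride, max_pooled)
  pw <- pairwise_rmsd(ensembles, selection)
  D <- pw$rmsd
  n <- nrow(D)
  .assert(n >= dim + 1, "pooled frame count must exceed the embedding dimension")
  if (is.null(steps_per_cycle)) steps_per_cycle <- 50L * n
  r0 <- max(D)
  r1 <- as.numeric(quantile(D[upper.tri(D)], 0.01))
  X <- .with_seed(seed, {
    emb <- .spe_embed_cpp(D, as.integer(dim), as.integer(n_cycles),
                          as.integer(steps_per_cycle), 2.0, 0.01, r0, r1)
    ne <- length(ensembles)
    V <- matrix(0, ne, ne)
    for (i in seq_len(ne - 1)) {
      for (j in (i + 1):ne) {
        V[i, j] <- V[j, i] <- .kde_jsd_mc(emb[pw$origin == i, , drop = FALSE],
                                          emb[pw$origin == j, , drop = FALSE],
                                          mc_samples)
      }
    }
    list(emb = emb, V = V)
  })
  out <- similarity_matrix(vapply(ensembles, function(e) e$replicate_id, ""),
                           X$V, "dres_jsd")
  attr(out, "embedding") <- X$emb
  attr(out, "origin") <- pw$origin
  out
}

# Gaussian product-kernel density with per-dimension Scott's-rule bandwidth.
.kde_bandwidth <- function(X) {
  n <- nrow(X)
  d <- ncol(X)
  s <- apply(X, 2, sd)
  .assert(all(s > 0),
          "degenerate KDE bandwidth (all points identical in a dimension); add jitter")
  s * n^(-1 / (d + 4))
}

.kde_logdens <- function(X, h, at) {
  # log density of the KDE built on X (bandwidth h) at the rows of `at`,
  # evaluated in blocks to bound memory
  n <- nrow(X)
  d <- ncol(X)
  lognorm <- -sum(log(h)) - d / 2 * log(2 * pi) - log(n)
  out <- numeric(nrow(at))
  block <- 2000L
  Xs <- sweep(X, 2, h, "/")
  ats <- sweep(at, 2, h, "/")
  x2 <- rowSums(Xs^2)
  for (s in seq(1, nrow(at), by = block)) {
    idx <- s:min(s + block - 1, nrow(at))
    A <- ats[idx, , drop = FALSE]
    # squared scaled distances via the expansion |a-x|^2 = |a|^2 - 2 a.x + |x|^2
    D2 <- outer(rowSums(A^2), x2, "+") - 2 * A %*% t(Xs)
    D2[D2 < 0] <- 0
    m <- apply(-D2 / 2, 1, max)
    out[idx] <- m + log(rowSums(exp(-D2 / 2 - m))) + lognorm
  }
  out
}

.kde_jsd_mc <- function(Xa, Xb, mc_samples) {
  ha <- .kde_bandwidth(Xa)
  hb <- .kde_bandwidth(Xb)
  draw <- function(X, h, m) {
    idx <- sample.int(nrow(X), m, replace = TRUE)
    X[idx, , drop = FALSE] +
      matrix(rnorm(m * ncol(X)), ncol = ncol(X)) %*% diag(h, ncol(X))
  }
  Sa <- draw(Xa, ha, mc_samples)
  Sb <- draw(Xb, hb, mc_samples)
  la_a <- .kde_logdens(Xa, ha, Sa)
  lb_a <- .kde_logdens(Xb, hb, Sa)
  la_b <- .kde_logdens(Xa, ha, Sb)
  lb_b <- .kde_logdens(Xb, hb, Sb)
  logm <- function(l1, l2) {
    m <- pmax(l1, l2)
    m + log(exp(l1 - m) + exp(l2 - m)) - log(2)
  }
  val <- 0.5 * mean(la_a - logm(la_a, lb_a)) +
    0.5 * mean(lb_b - logm(la_b, lb_b))
  min(max(val, 0), log(2))
}

#' Render a similarity matrix as a heatmap with a TSV twin
#'
#' Writes a PNG heatmap of the matrix (colour scale `[0, 1]` for RMSIP,
#' `[0, ln 2]` for JSD metrics) and always writes the numeric TSV next to
#' it.
#'
#' @param matrix a [similarity_matrix()].
#' @param out_path output PNG path; the TSV replaces the extension.
#' @return invisibly, c(png = ..., tsv = ...).
#' @export
similarity_heatmap <- function(matrix, out_path) {
  .assert(inherits(matrix, "similarity_matrix"), "need a similarity_matrix")
  tsv <- sub("\\.[A-Za-z]+$", ".tsv", out_path)
  if (identical(tsv, out_path)) tsv <- paste0(out_path, ".tsv")
  write.table(matrix$values, tsv, sep = "\t", quote = FALSE,
              col.names = NA)
  lim <- if (matrix$metric == "rmsip") c(0, 1) else c(0, log(2))
  n <- length(matrix$ids)
  grDevices::png(out_path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::par(mar = c(5, 5, 3, 2))
  graphics::image(seq_len(n), seq_len(n),
                  t(matrix$values[n:1, , drop = FALSE]),
                  zlim = lim, col = pal, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%s (scale %.2f-%.2f)", matrix$metric,
                                 lim[1], lim[2]))
  graphics::axis(1, at = seq_len(n), labels = matrix$ids, las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(matrix$ids), las = 2)
  graphics::box()
  invisible(c(png = out_path, tsv = tsv))
}
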