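#' Time-series structural descriptors of an ensemble
#'
#' `rmsd_series()` computes the per-frame least-squares-fitted RMSD to a
#' reference over a selection (main chain by default, matching the usual
#' trajectory-stability check), `radius_of_gyration_series()` the
#' mass-weighted radius of gyration per frame, and `distance_monitor()`
#' the distance between two named atoms per frame (e.g. a catalytic ion
#' and its coordinating residue).  All values are in nm, times in ns.
#'
#' @param ens an [ensemble()].
#' @param reference reference coordinates (matrix, `structure_model`, or
#'   `NULL` for the first frame).
#' @param selection atoms used (see [select_atoms()]).
#' @return a `time_series` object (data.frame with `time`, `value` plus
#'   metadata attributes `label`, `unit`, `replicate_id`, `system_id`).
#' @export
rmsd_series <- function(ens, reference = NULL, selection = "mainchain") {
  sel <- select_atoms(ens$topology, selection)
  .assert(length(sel) >= 1, "empty selection")
  ref <- .as_ref_xyz(reference, ens)
  cols <- .xyz_idx(sel)
  vals <- as.numeric(.rmsd_to_ref_cpp(ens$xyz[, cols, drop = FALSE], ref[cols]))
  .time_series(ens, vals, label = "rmsd", unit = "nm")
}

.time_series <- function(ens, values, label, unit) {
  ts <- data.frame(time = (seq_len(n_frames(ens)) - 1) * ens$frame_interval,
                   value = values)
  structure(ts, class = c("time_series", "data.frame"),
            label = label, unit = unit,
            replicate_id = ens$replicate_id, system_id = ens$system_id)
}

#' @rdname rmsd_series
#' @export
radius_of_gyration_series <- function(ens) {
  .assert(n_atoms(ens) >= 1, "ensemble has no atoms")
  m <- .element_mass(ens$topology$atoms$element)
  M <- sum(m)
  vals <- apply(ens$xyz, 1, function(row) {
    P <- matrix(row, ncol = 3, byrow = TRUE)
    com <- colSums(P * m) / M
    sqrt(sum(m * rowSums(sweep(P, 2, com)^2)) / M)
  })
  .time_series(ens, as.numeric(vals), label = "radius_of_gyration", unit = "nm")
}

#' @rdname rmsd_series
#' @param atom_a,atom_b atom selectors, each resolving to exactly one atom:
#'   an atom index, or a string `"LABEL:NAME"` (residue label via the
#'   numbering map, atom name), e.g. `"127:MG"`.
#' @export
distance_monitor <- function(ens, atom_a, atom_b) {
  ia <- .resolve_atom(ens$topology, atom_a)
  ib <- .resolve_atom(ens$topology, atom_b)
  d <- sqrt(rowSums((ens$xyz[, .xyz_idx(ia), drop = FALSE] -
                       ens$xyz[, .xyz_idx(ib), drop = FALSE])^2))
  .time_series(ens, as.numeric(d), label = "distance", unit = "nm")
}

.resolve_atom <- function(topology, sel) {
  if (is.numeric(sel)) {
    .assert(length(sel) == 1 && sel >= 1 && sel <= n_atoms(topology),
            "atom index out of range")
    return(as.integer(sel))
  }
  .assert(is.character(sel) && grepl(":", sel),
          "atom selector must be an index or 'LABEL:NAME'")
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  ord <- topology$residues$ordinal[topology$residues$label == parts[1]]
  hit <- which(topology$atoms$residue_ordinal %in% ord &
                 topology$atoms$name == parts[2])
  if (length(hit) == 0) .stopf("no atom matches selector '%s'", sel)
  if (length(hit) > 1) {
    .stopf("ambiguous selector '%s': matches atoms %s", sel,
           paste(hit, collapse = ", "))
  }
  hit
}

#' Windowed, replicate-averaged per-residue flexibility profiles
#'
#' `windowed_rmsf()` computes the C-alpha root mean square fluctuation over
#' non-overlapping time windows, excluding an initial equilibration span,
#' and averages the per-window profiles (the protocol behind per-residue
#' flexibility comparisons of trajectory replicates; defaults 10 ns windows
#' after 10 ns exclusion).  Within each window frames are fitted to the
#' window-mean structure and the RMSF is taken about that mean.
#' Trailing partial windows are discarded.
#'
#' @param ens an [ensemble()].
#' @param window_ns window length, ns.
#' @param exclude_initial_ns span discarded from the start, ns.
#' @param sd_across `"windows"`: the profile sd is the across-window
#'   standard deviation.
#' @return a `flexibility_profile`: data.frame with `label`, `rmsf_mean`,
#'   `rmsf_sd` (nm) and attributes `window_ns`, `n_windows`, `n_replicates`.
#' @export
windowed_rmsf <- function(ens, window_ns = 10, exclude_initial_ns = 10,
                          sd_across = "windows") {
  sel <- select_atoms(ens$topology, "calpha")
  .assert(length(sel) >= 1, "no C-alpha atoms in topology")
  skip <- floor(exclude_initial_ns / ens$frame_interval)
  wlen <- floor(window_ns / ens$frame_interval)
  .assert(wlen >= 2, "window of %g ns holds < 2 frames at dt = %g ns",
          window_ns, ens$frame_interval)
  avail <- n_frames(ens) - skip
  nwin <- avail %/% wlen
  .assert(nwin >= 1,
          "no complete window: need >= %g ns after excluding %g ns (have %g ns)",
          window_ns, exclude_initial_ns, max(avail, 0) * ens$frame_interval)

  cols <- .xyz_idx(sel)
  per_window <- matrix(NA_real_, nrow = nwin, ncol = length(sel))
  for (w in seq_len(nwin)) {
    rows <- skip + (w - 1) * wlen + seq_len(wlen)
    X <- ens$xyz[rows, cols, drop = FALSE]
    # fit to the window mean, then recompute the mean once
    mu <- colMeans(X)
    X <- bio3d::fit.xyz(fixed = mu, mobile = X,
                        fixed.inds = seq_along(mu),
                        mobile.inds = seq_along(mu))
    mu <- colMeans(X)
    dev2 <- sweep(X, 2, mu)^2
    msf <- colMeans(dev2)
    per_window[w, ] <- sqrt(msf[c(TRUE, FALSE, FALSE)] +
                              msf[c(FALSE, TRUE, FALSE)] +
                              msf[c(FALSE, FALSE, TRUE)])
  }
  labels <- residue_labels(ens$topology)[
    match(ens$topology$atoms$residue_ordinal[sel], ens$topology$residues$ordinal)]
  .flex_profile(labels,
                colMeans(per_window),
                if (nwin > 1) apply(per_window, 2, sd) else rep(0, ncol(per_window)),
                window_ns = window_ns, n_windows = nwin, n_replicates = 1)
}

.flex_profile <- function(labels, mean, sd, window_ns, n_windows, n_replicates) {
  .assert(all(mean >= -1e-12) && all(sd >= -1e-12),
          "RMSF values must be non-negative")
  structure(data.frame(label = labels, rmsf_mean = mean, rmsf_sd = sd,
                       stringsAsFactors = FALSE),
            class = c("flexibility_profile", "data.frame"),
            window_ns = window_ns, n_windows = n_windows,
            n_replicates = n_replicates)
}

#' Average flexibility profiles across replicates
#'
#' Per-residue mean of the supplied profiles; the profile sd becomes the
#' across-replicate standard deviation (the shaded band of a
#' replicate-averaged flexibility figure).
#'
#' @param profiles list of `flexibility_profile`s sharing residue labels.
#' @return a `flexibility_profile` with `n_replicates = length(profiles)`.
#' @export
average_profiles <- function(profiles) {
  .assert(length(profiles) >= 1, "need at least one profile")
  lab <- profiles[[1]]$label
  for (p in profiles[-1]) {
    if (!identical(p$label, lab)) {
      first <- which(p$label != lab)[1]
      .stopf("profiles disagree in residue labels (first difference at '%s' vs '%s')",
             lab[min(first, length(lab))], p$label[min(first, length(p$label))])
    }
  }
  M <- do.call(rbind, lapply(profiles, function(p) p$rmsf_mean))
  .flex_profile(lab, colMeans(M),
                if (nrow(M) > 1) apply(M, 2, sd) else rep(0, ncol(M)),
                window_ns = attr(profiles[[1]], "window_ns"),
                n_windows = attr(profiles[[1]], "n_windows"),
                n_replicates = length(profiles))
}

#' Per-residue difference between two flexibility profiles
#'
#' Computes `a - b` per mapped residue.  Positions present in only one
#' profile (e.g. an insertion in one homolog) are reported as gap rows with
#' `NA` difference, never silently dropped.
#'
#' @param profile_a,profile_b `flexibility_profile`s.
#' @param residue_map optional two-column data.frame (`label_a`,
#'   `label_b`) aligning residue labels between the systems; default maps
#'   equal labels.
#' @return data.frame with `label_a`, `label_b`, `rmsf_a`, `rmsf_b`,
#'   `difference` (nm) and logical `gap`.
#' @export
rmsf_difference <- function(profile_a, profile_b, residue_map = NULL) {
  if (is.null(residue_map)) {
    shared <- intersect(profile_a$label, profile_b$label)
    residue_map <- data.frame(label_a = shared, label_b = shared,
                              stringsAsFactors = FALSE)
  }
  .assert(nrow(residue_map) > 0, "empty residue mapping")
  la <- profile_a$label
  lb <- profile_b$label
  mapped <- data.frame(
    label_a = residue_map$label_a,
    label_b = residue_map$label_b,
    rmsf_a = profile_a$rmsf_mean[match(residue_map$label_a, la)],
    rmsf_b = profile_b$rmsf_mean[match(residue_map$label_b, lb)],
    stringsAsFactors = FALSE
  )
  # unmapped residues of either profile become explicit gap rows
  only_a <- setdiff(la, residue_map$label_a)
  only_b <- setdiff(lb, residue_map$label_b)
  gaps <- rbind(
    if (length(only_a)) data.frame(label_a = only_a, label_b = NA,
                                   rmsf_a = profile_a$rmsf_mean[match(only_a, la)],
                                   rmsf_b = NA, stringsAsFactors = FALSE),
    if (length(only_b)) data.frame(label_a = NA, label_b = only_b,
                                   rmsf_a = NA,
                                   rmsf_b = profile_b$rmsf_mean[match(only_b, lb)],
                                   stringsAsFactors = FALSE)
  )
  out <- rbind(mapped, gaps)
  out$difference <- out$rmsf_a - out$rmsf_b
  out$gap <- is.na(out$label_a) | is.na(out$label_b)
  out
}

#' Covariance trace of the C-alpha coordinate fluctuations
#'
#' Trace of the 3N x 3N C-alpha coordinate covariance matrix, nm^2 — a
#' scalar overall-flexibility metric.  The trace is basis-invariant, so it
#' equals the sum of the principal-component eigenvalues of the same data.
#' Frames should be fitted to a common reference first (see
#' [superpose_frames()]); set `fit = TRUE` to fit to the mean internally.
#'
#' @param ens an [ensemble()].
#' @param selection atom selection, default C-alpha.
#' @param fit fit frames to their mean structure before computing.
#' @return scalar, nm^2.
#' @export
covariance_trace <- function(ens, selection = "calpha", fit = FALSE) {
  .assert(n_frames(ens) >= 2,
          "covariance undefined for a single frame")
  sel <- select_atoms(ens$topology, selection)
  .assert(length(sel) >= 1, "empty selection")
  X <- ens$xyz[, .xyz_idx(sel), drop = FALSE]
  if (fit) {
    X <- bio3d::fit.xyz(fixed = colMeans(X), mobile = X,
                        fixed.inds = seq_len(ncol(X)),
                        mobile.inds = seq_len(ncol(X)))
  }
  sum(apply(X, 2, var))
}

#' Write a profile or time series as TSV
#'
#' @param x a `flexibility_profile`, `time_series`, or plain data.frame.
#' @param path output path; a `#`-prefixed header names the units.
#' @export
write_profile_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "flexibility_profile")) {
    writeLines(sprintf("# per-residue RMSF, nm; window %s ns, %s window(s), %s replicate(s)",
                       attr(x, "window_ns"), attr(x, "n_windows"),
                       attr(x, "n_replicates")), con)
  } else if (inherits(x, "time_series")) {
    writeLines(sprintf("# %s time series; time ns, value %s",
                       attr(x, "label"), attr(x, "unit")), con)
  }
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
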