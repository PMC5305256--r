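# Configuration-driven orchestration of a two-system comparison:
# replicate-sampling similarity first (flagging outlier replicates), then
# flexibility profiling, structure networks, and sequence comparison.
# Every artifact records the config hash and seed so runs are auditable.

.CONFIG_SCHEMA <- list(
  top = c("version", "seed", "output_dir", "systems", "stages"),
  system = c("id", "ensembles"),
  ensemble = c("path", "replicate_id", "frame_interval"),
  stages = c("similarity", "flexibility", "psn", "sequence"),
  similarity = c("enabled", "components", "preference", "dim", "stride",
                 "outlier_jsd", "metrics"),
  flexibility = c("enabled", "window_ns", "exclude_initial_ns", "selection"),
  psn = c("enabled", "classes", "persistence_threshold", "exclude_mainchain"),
  sequence = c("enabled", "alignment", "labels", "target_a", "target_b",
               "conservation_cutoff", "mode")
)

#' Load and validate a pipeline configuration
#'
#' Reads a versioned YAML configuration.  Unknown keys are errors, not
#' warnings (silent typos corrupt comparisons); every referenced input
#' path must exist at validation time.
#'
#' @param path YAML configuration file.
#' @return a validated `pipeline_config` (named list) with the config
#'   hash attached.
#' @export
pipeline_config <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .CONFIG_SCHEMA$top, "top level")
  .assert(identical(cfg$version, 1L) || identical(cfg$version, 1),
          "unsupported config version: %s", cfg$version %||% "missing")
  .assert(length(cfg$systems) >= 1, "config must name at least one system")
  for (sys in cfg$systems) {
    .check_keys(sys, .CONFIG_SCHEMA$system, sprintf("system '%s'", sys$id %||% "?"))
    .assert(!is.null(sys$id), "every system needs an id")
    for (e in sys$ensembles) {
      .check_keys(e, .CONFIG_SCHEMA$ensemble,
                  sprintf("ensemble of system '%s'", sys$id))
      .assert(file.exists(e$path), "ensemble file not found: %s", e$path)
    }
  }
  cfg$stages <- cfg$stages %||% list()
  .check_keys(cfg$stages, .CONFIG_SCHEMA$stages, "stages")
  for (st in names(cfg$stages)) {
    .check_keys(cfg$stages[[st]], .CONFIG_SCHEMA[[st]], sprintf("stage '%s'", st))
  }
  if (isTRUE(cfg$stages$sequence$enabled)) {
    for (f in c("alignment", "labels")) {
      .assert(!is.null(cfg$stages$sequence[[f]]) &&
                file.exists(cfg$stages$sequence[[f]]),
              "sequence stage input '%s' missing or not found", f)
    }
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tmp))
  class(cfg) <- "pipeline_config"
  cfg
}

.check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  .assert(length(extra) == 0, "unknown key(s) in %s: %s", where,
          paste(extra, collapse = ", "))
}

.stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

.provenance_lines <- function(cfg) {
  sprintf("# config_hash: %s  seed: %d", attr(cfg, "config_hash"), cfg$seed)
}

#' Run the comparative-dynamics pipeline
#'
#' Executes the enabled stages in workflow order: replicate-sampling
#' similarity first (RMSIP + CES, optionally DRES; replicates whose mean
#' off-diagonal CES JSD exceeds `outlier_jsd` are flagged, never silently
#' removed), then windowed RMSF flexibility profiles, structure networks
#' per interaction class, and the sequence comparison.  Every output file
#' carries the config hash and seed.  A stage failure aborts with the
#' stage name; artifacts of completed stages are preserved.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @return (invisibly) a list of written artifact paths by stage, plus
#'   the outlier flags.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  cfg <- config
  outdir <- cfg$output_dir %||% "pipeline_out"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- .provenance_lines(cfg)
  artifacts <- list()
  flags <- list()

  run_stage <- function(stage, body) {
    tryCatch(body(), error = function(e) {
      .stopf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
             stage, conditionMessage(e), outdir)
    })
  }

  systems <- lapply(cfg$systems, function(sys) {
    ens <- lapply(sys$ensembles, function(e) {
      read_ensemble(e$path, frame_interval = e$frame_interval %||% 1,
                    replicate_id = e$replicate_id %||% basename(e$path),
                    system_id = sys$id)
    })
    replicate_set(ens, system_id = sys$id)
  })
  names(systems) <- vapply(cfg$systems, `[[`, "", "id")

  sim <- cfg$stages$similarity
  if (isTRUE(sim$enabled)) {
    run_stage("similarity", function() {
      for (sys in systems) {
        .stage_log("similarity",
                   "system %s: components=%s preference=%s dim=%s",
                   sys$system_id, sim$components %||% 10,
                   sim$preference %||% -10, sim$dim %||% 6)
        metrics <- sim$metrics %||% c("rmsip", "ces")
        if ("rmsip" %in% metrics) {
          m <- rmsip_matrix(sys, n_components = sim$components %||% 10)
          p <- file.path(outdir, sprintf("similarity_rmsip_%s.png", sys$system_id))
          files <- similarity_heatmap(m, p)
          .append_provenance(files["tsv"], prov)
          artifacts$similarity <<- c(artifacts$similarity, files)
        }
        if ("ces" %in% metrics) {
          m <- ces(sys$ensembles, preference = sim$preference %||% -10,
                   stride = sim$stride)
          p <- file.path(outdir, sprintf("similarity_ces_%s.png", sys$system_id))
          files <- similarity_heatmap(m, p)
          .append_provenance(files["tsv"], prov)
          artifacts$similarity <<- c(artifacts$similarity, files)
          off <- m$values
          diag(off) <- NA
          mean_jsd <- rowMeans(off, na.rm = TRUE)
          thr <- sim$outlier_jsd %||% 0.4
          out_ids <- m$ids[mean_jsd > thr]
          flags[[sys$system_id]] <<- out_ids
          if (length(out_ids)) {
            .stage_log("similarity",
                       "system %s: replicate(s) %s exceed mean off-diagonal JSD %.2f (flagged, not removed)",
                       sys$system_id, paste(out_ids, collapse = ", "), thr)
          }
        }
        if ("dres" %in% metrics) {
          m <- dres(sys$ensembles, dim = sim$dim %||% 6, seed = cfg$seed,
                    stride = sim$stride)
          p <- file.path(outdir, sprintf("similarity_dres_%s.png", sys$system_id))
          files <- similarity_heatmap(m, p)
          .append_provenance(files["tsv"], prov)
          artifacts$similarity <<- c(artifacts$similarity, files)
        }
      }
    })
  }

  flex <- cfg$stages$flexibility
  if (isTRUE(flex$enabled)) {
    run_stage("flexibility", function() {
      profiles <- lapply(systems, function(sys) {
        .stage_log("flexibility", "system %s: window_ns=%s exclude=%s",
                   sys$system_id, flex$window_ns %||% 10,
                   flex$exclude_initial_ns %||% 10)
        per_rep <- lapply(sys$ensembles, windowed_rmsf,
                          window_ns = flex$window_ns %||% 10,
                          exclude_initial_ns = flex$exclude_initial_ns %||% 10)
        avg <- average_profiles(per_rep)
        p <- file.path(outdir, sprintf("rmsf_%s.tsv", sys$system_id))
        write_profile_tsv(avg, p)
        .append_provenance(p, prov)
        artifacts$flexibility <<- c(artifacts$flexibility, p)
        avg
      })
      if (length(profiles) >= 2) {
        d <- rmsf_difference(profiles[[1]], profiles[[2]])
        p <- file.path(outdir, sprintf("rmsf_difference_%s_minus_%s.tsv",
                                       names(systems)[1], names(systems)[2]))
        write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
        .append_provenance(p, prov)
        artifacts$flexibility <<- c(artifacts$flexibility, p)
      }
    })
  }

  psn_cfg <- cfg$stages$psn
  if (isTRUE(psn_cfg$enabled)) {
    run_stage("psn", function() {
      classes <- psn_cfg$classes %||% c("hydrophobic", "saltbridge")
      graphs <- list()
      for (sys in systems) {
        for (cl in classes) {
          .stage_log("psn", "system %s class %s threshold %s",
                     sys$system_id, cl, psn_cfg$persistence_threshold %||% 0.2)
          g <- build_psn(sys$ensembles[[1]], cl,
                         persistence_threshold = psn_cfg$persistence_threshold %||% 0.2)
          p <- file.path(outdir, sprintf("psn_%s_%s.graphml", sys$system_id, cl))
          write_psn_graphml(g, p)
          hubs <- find_hubs(g)
          hp <- file.path(outdir, sprintf("psn_hubs_%s_%s.tsv", sys$system_id, cl))
          write.table(hubs, hp, sep = "\t", quote = FALSE, row.names = FALSE)
          .append_provenance(hp, prov)
          artifacts$psn <<- c(artifacts$psn, p, hp)
          graphs[[paste(sys$system_id, cl, sep = ".")]] <- g
        }
      }
      if (length(systems) >= 2) {
        for (cl in classes) {
          ga <- graphs[[paste(names(systems)[1], cl, sep = ".")]]
          gb <- graphs[[paste(names(systems)[2], cl, sep = ".")]]
          d <- diff_networks(ga, gb,
                             exclude_mainchain = isTRUE(psn_cfg$exclude_mainchain))
          p <- file.path(outdir, sprintf("psn_diff_%s.tsv", cl))
          con <- file(p, "w")
          writeLines(c(prov, paste("#", paste(names(d$counts), d$counts,
                                              sep = "=", collapse = " "))), con)
          write.table(d$shared, con, sep = "\t", quote = FALSE, row.names = FALSE)
          close(con)
          artifacts$psn <<- c(artifacts$psn, p)
        }
      }
    })
  }

  seq_cfg <- cfg$stages$sequence
  if (isTRUE(seq_cfg$enabled)) {
    run_stage("sequence", function() {
      .stage_log("sequence", "cutoff=%s mode=%s",
                 seq_cfg$conservation_cutoff %||% 0.8, seq_cfg$mode %||% "exact")
      aln <- read_labeled_alignment(seq_cfg$alignment, seq_cfg$labels,
                                    seq_cfg$target_a, seq_cfg$target_b)
      comp <- composition_delta(aln)
      cp <- file.path(outdir, "composition.tsv")
      write_sequence_tsv(comp, cp)
      .append_provenance(cp, prov)
      recs <- classify_substitutions(
        substitution_sites(aln), aln,
        conservation_cutoff = seq_cfg$conservation_cutoff %||% 0.8,
        mode = seq_cfg$mode %||% "exact")
      rp <- file.path(outdir, "substitutions.tsv")
      write_sequence_tsv(recs, rp)
      .append_provenance(rp, prov)
      artifacts$sequence <<- c(artifacts$sequence, cp, rp)
    })
  }

  meta <- file.path(outdir, "run_metadata.yaml")
  writeLines(yaml::as.yaml(list(config_hash = attr(cfg, "config_hash"),
                                seed = cfg$seed,
                                outlier_flags = flags,
                                stages_run = names(artifacts))), meta)
  invisible(list(artifacts = artifacts, outlier_flags = flags,
                 output_dir = outdir, metadata = meta))
}

.append_provenance <- function(path, prov) {
  txt <- readLines(path, warn = FALSE)
  writeLines(c(prov, txt), path)
}

#' Collate pipeline artifacts into a single summary report
#'
#' Writes one markdown document with a section per stage found in the
#' output directory: flexibility profiles and differences, similarity
#' matrices, hub tables, differential-edge summaries, substitution
#' verdicts.
#'
#' @param output_dir directory written by [run_pipeline()].
#' @param path report path (default `report.md` inside `output_dir`).
#' @return the report path, invisibly.
#' @export
generate_report <- function(output_dir, path = file.path(output_dir, "report.md")) {
  .assert(dir.exists(output_dir), "output directory not found: %s", output_dir)
  files <- list.files(output_dir, full.names = TRUE)
  .assert(length(files) > 0, "no stage artifacts in %s", output_dir)
  lines <- c("# Comparative dynamics report", "")
  add_tsv <- function(lines, f, title) {
    c(lines, paste("##", title), "",
      paste0("    ", readLines(f, warn = FALSE)), "")
  }
  sections <- 0
  rmsf <- grep("rmsf_.*\\.tsv$", files, value = TRUE)
  if (length(rmsf)) {
    sections <- sections + 1
    for (f in rmsf) lines <- add_tsv(lines, f, paste("Flexibility:", basename(f)))
  }
  sim <- grep("similarity_.*\\.tsv$", files, value = TRUE)
  if (length(sim)) {
    sections <- sections + 1
    for (f in sim) lines <- add_tsv(lines, f, paste("Sampling similarity:", basename(f)))
  }
  psn <- grep("psn_(hubs|diff).*\\.tsv$", files, value = TRUE)
  if (length(psn)) {
    sections <- sections + 1
    for (f in psn) lines <- add_tsv(lines, f, paste("Structure network:", basename(f)))
  }
  seqf <- grep("(composition|substitutions)\\.tsv$", files, value = TRUE)
  if (length(seqf)) {
    sections <- sections + 1
    for (f in seqf) lines <- add_tsv(lines, f, paste("Sequence:", basename(f)))
  }
  attr(lines, "n_sections") <- sections
  writeLines(lines, path)
  invisible(structure(path, n_sections = sections))
}
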