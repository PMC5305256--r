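#!/usr/bin/env Rscript
# Step 1: build the synthetic two-system study set.
#
# The comparison mirrors a cold-adapted vs warm-adapted enzyme pair:
# two systems with four replicate ensembles each.  The cold-like system
# carries slightly larger fluctuations; in each system one replicate is
# deliberately confined to a different conformational basin, emulating a
# replicate that samples a different region of conformational space and
# should be flagged by the sampling-similarity stage.  A labeled homolog
# alignment with planted adaptation-candidate and drift columns feeds the
# sequence stage.  Everything downstream consumes these files through the
# standard readers only.

suppressMessages(library(cryodyn))

seed <- 101
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

n_res <- 15
n_frames <- 120
base <- make_ca_structure(n_res)
refs <- make_basin_references(base, 2, separation = 3, seed = seed)

sigma <- c(coldlike = 0.035, warmlike = 0.030)  # cold-adapted: softer
for (sys in names(sigma)) {
  for (r in 1:4) {
    if (r == 1) {
      # replicate 1 samples the alternative basin
      spec <- basin_spec(refs, list(c(0, 1)), intra_basin_sigma = sigma[[sys]],
                         min_separation = 3, n_frames = n_frames,
                         seed = seed + r + 50 * (sys == "warmlike"))
      ens <- gen_basin_mixture(spec, 1, system_id = sys)
    } else {
      spec <- basin_spec(refs, list(c(1, 0)), intra_basin_sigma = sigma[[sys]],
                         min_separation = 3, n_frames = n_frames,
                         seed = seed + r + 50 * (sys == "warmlike"))
      ens <- gen_basin_mixture(spec, 1, system_id = sys)
    }
    ens$replicate_id <- paste0("rep", r)
    write_pdb(ens, file.path(outdir, sprintf("%s_rep%d.pdb", sys, r)))
  }
}
message("wrote 2 systems x 4 replicates (", n_frames, " frames, ",
        n_res, " residues) under ", outdir)

aln <- gen_labeled_alignment(
  n_psychro = 7, n_meso = 8, length = 120,
  planted_candidate_columns = c(20, 66, 101),
  planted_drift_columns = c(12, 35, 58, 80, 112),
  seed = seed)
write_alignment_fasta(aln, file.path(outdir, "homologs.fasta"),
                      file.path(outdir, "homologs_labels.tsv"))
message("wrote labeled alignment: 3 planted candidate, 5 planted drift columns")

cfg <- list(
  version = 1L, seed = seed, output_dir = "results/pipeline",
  systems = lapply(names(sigma), function(sys) {
    list(id = sys, ensembles = lapply(1:4, function(r) {
      list(path = file.path(outdir, sprintf("%s_rep%d.pdb", sys, r)),
           replicate_id = paste0("rep", r), frame_interval = 1)
    }))
  }),
  stages = list(
    similarity = list(enabled = TRUE, outlier_jsd = 0.4),
    flexibility = list(enabled = TRUE, window_ns = 20, exclude_initial_ns = 20),
    psn = list(enabled = FALSE),
    sequence = list(enabled = TRUE,
                    alignment = file.path(outdir, "homologs.fasta"),
                    labels = file.path(outdir, "homologs_labels.tsv"),
                    target_a = "cold_1", target_b = "meso_1")))
yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
message("wrote pipeline config: ", file.path(outdir, "config.yaml"))
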