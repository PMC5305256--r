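#!/usr/bin/env Rscript
# Step 2: assess how consistently the replicates of each system sample
# conformational space, with three complementary measures: RMSIP over the
# first ten principal components, clustering-based ensemble similarity
# (CES), and dimensionality-reduction-based ensemble similarity (DRES).
# A replicate whose mean off-diagonal JSD is high samples a different
# region than its siblings and is flagged for exclusion downstream.

suppressMessages(library(cryodyn))

indir <- "results/data"
outdir <- "results/similarity"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
stopifnot(dir.exists(indir))

outliers <- list()
for (sys in c("coldlike", "warmlike")) {
  reps <- lapply(1:4, function(r) {
    read_ensemble(file.path(indir, sprintf("%s_rep%d.pdb", sys, r)),
                  replicate_id = paste0("rep", r), system_id = sys)
  })
  rs <- replicate_set(reps)

  m_rmsip <- rmsip_matrix(rs)
  similarity_heatmap(m_rmsip, file.path(outdir, sprintf("rmsip_%s.png", sys)))
  m_ces <- ces(reps)
  similarity_heatmap(m_ces, file.path(outdir, sprintf("ces_%s.png", sys)))
  m_dres <- dres(reps, seed = 101)
  similarity_heatmap(m_dres, file.path(outdir, sprintf("dres_%s.png", sys)))

  off <- m_ces$values
  diag(off) <- NA
  mean_jsd <- rowMeans(off, na.rm = TRUE)
  flagged <- m_ces$ids[mean_jsd > 0.4]
  outliers[[sys]] <- flagged
  message(sprintf("%s: mean off-diagonal CES JSD per replicate: %s",
                  sys, paste(sprintf("%s=%.3f", m_ces$ids, mean_jsd),
                             collapse = " ")))
  message(sprintf("%s: flagged outlier replicate(s): %s", sys,
                  paste(flagged, collapse = ", ")))
}
yaml::write_yaml(outliers, file.path(outdir, "outlier_replicates.yaml"))
message("similarity matrices and outlier flags written under ", outdir)
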