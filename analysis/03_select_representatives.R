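#!/usr/bin/env Rscript
# Step 3: representative-IED selection per electrode.
#
# All spike-group epochs of an electrode are stacked into a groups x
# (channels * samples) matrix, reduced by PCA to the components explaining
# 90% of the variance, clustered with k-means (k = 3), and the group
# nearest each centroid is retained for model inversion.

library(tuberwave)

manifest <- read.csv("results/cohort_manifest.csv")
rows <- NULL
for (i in seq_len(nrow(manifest))) {
  rec <- preprocess(read_edf(manifest$edf[i],
                             positions = manifest$positions[i],
                             montage = "bipolar"))
  groups <- group_spikes(detect_spikes(rec))
  mat <- stack_groups(rec, groups)
  p <- pca_reduce(mat, 0.90)
  sc <- p$scores
  attr(sc, "group_ids") <- attr(mat, "group_ids")
  reps <- select_representatives(sc, k = 3, seed = manifest$seed[i])
  rows <- rbind(rows, data.frame(
    electrode = manifest$electrode[i],
    n_groups = nrow(mat), n_components = p$n_components,
    explained = sum(p$explained[seq_len(p$n_components)]),
    representative = paste(reps, collapse = ";")))
  message(sprintf(
    "electrode %d: %d groups, %d components for %.0f%% variance, representatives %s",
    manifest$electrode[i], nrow(mat), p$n_components,
    100 * sum(p$explained[seq_len(p$n_components)]),
    paste(reps, collapse = ", ")))
}
write.csv(rows, "results/representatives.csv", row.names = FALSE)
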