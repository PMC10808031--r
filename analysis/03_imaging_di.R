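#!/usr/bin/env Rscript
# Step 3: Distribution Index (D.I. = SD/mean within the eroded nuclear
# ROI) on synthetic nuclear-surface images. Two groups of six individuals
# emulate a homogeneous-lamina genotype (low heterogeneity amplitude) and
# a disorganized one (high amplitude); 12 nuclei are measured per
# individual and the per-individual means are compared by the unpaired
# two-tailed t test, as in the imaging protocol.
#
# Amplitudes 0.23 and 0.42 were calibrated a priori from the analytic
# CV ~ h relation of the multiplicative field so that the two groups sit
# near the D.I. scale reported for intact vs disorganized envelopes
# (~0.23 vs ~0.41).

suppressPackageStartupMessages(library(laminatools))
dir.create("results", showWarnings = FALSE)

groups <- list(control = 0.23, disorganized = 0.42)
n_individuals <- 6L
images_per_ind <- 4L   # 3 nuclei per image -> 12 nuclei per individual

di <- numeric(0); individual <- character(0); group <- character(0)
seed0 <- 500L
for (g in names(groups)) {
  for (ind in seq_len(n_individuals)) {
    for (im in seq_len(images_per_ind)) {
      seed0 <- seed0 + 1L
      s <- synth_nucleus_image(n_nuclei = 3, size = 320, h = groups[[g]],
                               noise_sd = 2, seed = seed0)
      rs <- make_roi(s$image, "lamin")
      for (roi in rs$rois) {
        di <- c(di, compute_di(rs$measure_image, roi)$di)
        individual <- c(individual, sprintf("%s_%d", g, ind))
        group <- c(group, g)
      }
    }
  }
}

agg <- aggregate_individuals(di, individual, group)
write.table(agg$individuals, "results/di_per_individual.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

means <- tapply(agg$individuals$mean_di, agg$individuals$group, mean)
sds <- tapply(agg$individuals$mean_di, agg$individuals$group, sd)
report <- data.frame(group = names(means),
                     n_individuals = as.vector(table(agg$individuals$group)),
                     mean_di = round(as.numeric(means), 3),
                     sd_di = round(as.numeric(sds), 3))
write.table(report, "results/di_group_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(report, row.names = FALSE)
cat(sprintf("\nUnpaired two-tailed t test on individual means: t = %.3f, p = %.2e\n",
            agg$test$statistic, agg$test$p_value))
cat("Higher heterogeneity amplitude raises the D.I., separating the groups\n",
    "well beyond the within-group spread.\n")
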