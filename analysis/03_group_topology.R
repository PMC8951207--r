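#!/usr/bin/env Rscript
# Band-wise, sparsity-wise group comparison of the topology metrics:
# pooled t-tests at every sparsity level, BH FDR within each metric's
# 36-level family, Cohen's d (2t/sqrt(df)), then averaging of each
# subject's metric over the FDR-significant levels and a final comparison
# on the averages - the summary the study design reports per band.
#
# Reads results/cohort/ and results/connectivity/; writes
# results/topology/.

library(plinet)

truth <- read.table("results/cohort/truth.tsv", header = TRUE, sep = "\t")
cv <- read.table("results/connectivity/topology_curves.tsv", header = TRUE,
                 sep = "\t")
grid <- sparsity_grid()
out_dir <- "results/topology"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

per_level <- list()
averaged <- list()
for (met in unique(cv$metric)) {
  d <- cv[cv$metric == met, ]
  M <- matrix(NA_real_, nrow(truth), length(grid))
  M[cbind(match(d$subject, truth$subject), match(d$sparsity, grid))] <-
    d$value
  isA <- truth$group == "A"
  avg <- average_significant(M[isA, ], M[!isA, ], grid,
                             band = "beta1", metric = met)
  per_level[[met]] <- avg$per_level
  if (is.null(avg$comparison)) {
    cat(sprintf("%-8s: no FDR-significant sparsity levels\n", met))
  } else {
    averaged[[met]] <- cbind(avg$comparison,
                             n_significant = length(avg$significant))
    cat(sprintf(
      "%-8s: %2d significant levels; averaged t = %6.2f, p = %.4f, d = %.2f (A %s B)\n",
      met, length(avg$significant), avg$comparison$t, avg$comparison$p,
      avg$comparison$cohens_d,
      ifelse(avg$comparison$t > 0, ">", "<")))
  }
}
write.table(do.call(rbind, per_level),
            file.path(out_dir, "per_level_comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (length(averaged)) {
  write.table(do.call(rbind, averaged),
              file.path(out_dir, "averaged_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
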