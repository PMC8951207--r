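#!/usr/bin/env Rscript
# Rank-correlate the selected metabolites and the depression scores
# against network topology across the sparsity grid; locate the sparsity
# of maximum correlation per feature x metric, and report the depression
# score vs metabolite associations.
#
# Reads results/cohort/, results/connectivity/, results/metabolomics/;
# writes results/correlation/.

library(plinet)

tab <- read_metabolite_table("results/cohort/metabolites.tsv")
scores <- read.table("results/cohort/scores.tsv", header = TRUE, sep = "\t")
cv <- read.table("results/connectivity/topology_curves.tsv", header = TRUE,
                 sep = "\t")
scr <- read.table("results/metabolomics/screen.tsv", header = TRUE,
                  sep = "\t")
class(scr) <- c("screen_result", "data.frame")

out_dir <- "results/correlation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

scan <- metabolite_topology_scan(tab, scr, cv, n_perm = 500, seed = 42)
write.table(scan$map, file.path(out_dir, "scan_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scan$argmax, file.path(out_dir, "scan_argmax.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("maximum-correlation sparsity per selected feature (E_global, L_p):\n")
eg <- scan$argmax[scan$argmax$metric %in% c("E_global", "L_p"), ]
print(eg[order(eg$feature), ], row.names = FALSE, digits = 3)

sc <- score_metabolite_correlation(scores, tab, scr)
write.table(sc, file.path(out_dir, "score_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ndepression score vs selected metabolites:\n")
print(sc[order(sc$p), ], row.names = FALSE, digits = 3)
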