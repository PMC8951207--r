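#!/usr/bin/env Rscript
# Screen differential metabolites: PLS-DA (class regressed on log10,
# unit-variance-scaled intensities), per-feature VIP, univariate pooled
# t-tests with BH FDR, fold changes on raw group means, and the selection
# rule VIP > 1 AND p < 0.05.
#
# Reads results/cohort/; writes results/metabolomics/.

library(plinet)

tab <- read_metabolite_table("results/cohort/metabolites.tsv")
truth <- read.table("results/cohort/truth.tsv", header = TRUE, sep = "\t")

scr <- univariate_screen(tab)
out_dir <- "results/metabolomics"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
write.table(as.data.frame(scr), file.path(out_dir, "screen.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- scr[scr$selected, ]
cat(sprintf("selected %d / %d features (VIP > 1 & p < 0.05):\n",
            nrow(sel), nrow(scr)))
print(sel[order(sel$p), c("feature", "VIP", "t", "p", "p_fdr",
                          "fold_change")], row.names = FALSE, digits = 3)
cat("fold change > 1 marks up-regulation in the depressed-like group\n")
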