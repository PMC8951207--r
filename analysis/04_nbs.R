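#!/usr/bin/env Rscript
# Permutation network-based statistic on the beta-1 PLI matrices:
# edge-wise pooled t-tests, suprathreshold components at |t| > 2, and a
# 2000-permutation max-component-size null. Controls family-wise error
# across the 190 edges at the component level.
#
# Reads results/cohort/ and results/connectivity/; writes results/nbs/.

library(plinet)

truth <- read.table("results/cohort/truth.tsv", header = TRUE, sep = "\t")
mats <- lapply(truth$subject, function(s) {
  read_pli_matrix(file.path("results/connectivity",
                            paste0("pli_beta1_", s, ".tsv")))
})
isA <- truth$group == "A"
res <- nbs_test(mats[isA], mats[!isA], primary_t = 2, n_perm = 2000,
                seed = 42)
print(res)

out_dir <- "results/nbs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (length(res$component_sizes)) {
  summary <- data.frame(component = seq_along(res$component_sizes),
                        size = res$component_sizes, p = res$component_p)
  write.table(summary, file.path(out_dir, "components.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  edges <- do.call(rbind, lapply(seq_along(res$components), function(i) {
    cbind(component = i, res$components[[i]])
  }))
  edges$i <- canonical_channels()[edges$i]
  edges$j <- canonical_channels()[edges$j]
  write.table(edges, file.path(out_dir, "component_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
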