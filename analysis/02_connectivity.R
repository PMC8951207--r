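#!/usr/bin/env Rscript
# Preprocess each subject's recording for the beta-1 band (broadband filter
# + notch, 2-s epochs, average reference, 512 Hz, +/-80 uV rejection,
# Hjorth Laplacian), estimate the phase-lag-index matrix, and evaluate the
# four graph metrics over the 36-level sparsity grid.
#
# The EEG is regenerated deterministically from the cohort manifest, so
# this stage needs only results/cohort/ from 01_simulate_cohort.R.
# Writes results/connectivity/: one PLI matrix per subject and the long
# topology-curve table.

library(plinet)

manifest <- yaml::read_yaml("results/cohort/cohort_manifest.yaml")
manifest$rewire_a <- as.numeric(manifest$rewire_a)
manifest$rewire_b <- as.numeric(manifest$rewire_b)
spec <- do.call(synth_cohort_spec, manifest)
coh <- generate_cohort(spec)

out_dir <- "results/connectivity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
cfg <- run_config(seed = spec$seed)

curves <- vector("list", length(coh$recordings))
for (i in seq_along(coh$recordings)) {
  st <- subject_topology(coh$recordings[[i]], "beta1", cfg,
                         subject = coh$subjects[i])
  write_pli_matrix(st$pli, file.path(out_dir,
                                     paste0("pli_beta1_",
                                            coh$subjects[i], ".tsv")))
  curves[[i]] <- st$curves
  cat(sprintf("%s: %d epochs retained, mean PLI %.3f\n", coh$subjects[i],
              st$n_epochs, mean(st$pli[upper.tri(st$pli)])))
}
cv <- do.call(rbind, curves)
write.table(cv, file.path(out_dir, "topology_curves.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d curve rows for %d subjects\n", nrow(cv),
            length(coh$recordings)))
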