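#!/usr/bin/env Rscript
# Stage 1: generate the study-scale synthetic SNP panel.
#
# Emulates an 11-population chicken breed panel: 119 diploids, ~12,000
# bi-allelic autosomal SNPs over 28 autosomes totalling 930.82 Mb,
# Balding-Nichols divergence between populations, per-population inbreeding
# implanted as long homozygous tracts (inbred lines highest), 3% missing
# calls, and 10 planted dual-signal loci (elevated divergence inside
# population-shared ROH islands). Ground truth is written alongside for the
# later stages to score themselves against.

library(rohsignal)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 1234)
gen <- generate_dataset(cfg, "results/data/panel")

cat("Wrote", gen$paths$vcf, "\n")
cat("  populations:", length(unique(gen$gm$samples$population)),
    "| individuals:", n_samples(gen$gm),
    "| loci:", n_loci(gen$gm), "\n")
cat("  implanted ROH tracts:", nrow(gen$truth$tracts),
    "| planted dual-signal loci:", length(gen$truth$outlier_ids), "\n")
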