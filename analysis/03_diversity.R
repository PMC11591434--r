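#!/usr/bin/env Rscript
# Stage 3: per-population diversity.
#
# Segregating sites, mean minor-allele frequency, private alleles, scaled
# heterozygosity He, nucleotide diversity pi, Watterson's theta, their raw
# difference (the unnormalised Tajima-style statistic) and the pi/theta
# chi-square contrast. Populations with pi > theta carry an excess of
# intermediate-frequency variants; pi < theta an excess of rare variants.

library(rohsignal)

gm <- read_vcf("results/data/panel_filtered.vcf")
gm <- assign_populations(gm, read_popmap("results/data/panel.popmap.tsv"))

div <- diversity_summary(gm)
write.table(div, "results/diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Diversity across", nrow(div), "populations:\n")
print(div[order(-div$pi),
          c("population", "seg_sites", "private_alleles", "he", "pi",
            "theta", "tajima_d_raw")],
      row.names = FALSE, digits = 3)
cat("\nHighest diversity:", div$population[which.max(div$pi)],
    "| lowest:", div$population[which.min(div$pi)], "\n")
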