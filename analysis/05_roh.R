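#!/usr/bin/env Rscript
# Stage 5: runs of homozygosity.
#
# Window-based ROH scan (50-SNP window, <= 1 heterozygote and <= 5 missing
# calls per window, 5% window-hit threshold, 1000-kb maximum gap, segments
# >= 50 SNPs and >= 1000 kb), genomic inbreeding coefficients
# F_ROH = total ROH length / 930.82 Mb, per-SNP ROH incidence across all
# individuals, ROH islands (top 1% incidence), and per-population LD decay.

library(rohsignal)

gm <- read_vcf("results/data/panel_filtered.vcf")
gm <- assign_populations(gm, read_popmap("results/data/panel.popmap.tsv"))

params <- roh_params()   # study parameterisation, 930.82 Mb genome
segments <- scan_roh(gm, params)
write.table(segments, "results/roh_segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("ROH segments identified:", nrow(segments), "\n")

fro <- f_roh_summary(segments, gm, params)
write.table(fro$by_sample, "results/froh_by_sample.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fro$by_population, "results/froh_by_population.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
bp <- fro$by_population[order(-fro$by_population$mean_f_roh), ]
cat("F_ROH by population (highest first):\n")
print(bp, row.names = FALSE, digits = 3)

inc <- roh_incidence(segments, gm)
write.table(inc, "results/roh_incidence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
islands <- roh_islands(inc, top_fraction = 0.01)
write.table(islands, "results/roh_islands.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("ROH islands (top 1% incidence):", nrow(islands), "loci; max incidence",
    sprintf("%.2f%%", max(inc$incidence_pct)), "\n")

ld <- do.call(rbind, lapply(populations(gm), function(pp)
  cbind(population = pp, ld_decay(gm, pp, max_dist_kb = 1000, bin_kb = 100))))
write.table(ld, "results/ld_decay.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
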