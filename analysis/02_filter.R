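#!/usr/bin/env Rscript
# Stage 2: post-variant filtering.
#
# Call-rate thresholds (95% per SNP, 80% per individual), monomorphic
# removal, then windowed LD pruning (50-SNP window, step 5, r^2 > 0.2),
# mirroring the standard reduced-representation workflow. The filtered
# panel is what every downstream stage consumes.

library(rohsignal)

gm <- read_vcf("results/data/panel.vcf")
gm <- assign_populations(gm, read_popmap("results/data/panel.popmap.tsv"))
res <- filter_pipeline(gm, snp_rate = 0.95, ind_rate = 0.80,
                       window_snps = 50, step_snps = 5, r2_threshold = 0.2)

write_vcf(res$gm, "results/data/panel_filtered.vcf")
write.table(res$report, "results/filter_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Filtering:", res$report$n_snps_in, "->", res$report$n_snps_call_rate,
    "(call rate) ->", res$report$n_snps_polymorphic, "(polymorphic) ->",
    res$report$n_snps_ld_pruned, "(LD-pruned) SNPs\n")
cat("Individuals retained:", res$report$n_samples_out, "of",
    res$report$n_samples_in, "\n")
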