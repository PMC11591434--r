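#!/usr/bin/env Rscript
# Stage 4: population structure and relationships.
#
# AMOVA (1000 permutations), Euclidean distances between population
# allele-frequency vectors, pairwise Weir-Cockerham Fst with a 1000-locus
# bootstrap per pair, neighbor-joining trees on both distance types, and
# principal coordinate analysis.

library(rohsignal)

gm <- read_vcf("results/data/panel_filtered.vcf")
gm <- assign_populations(gm, read_popmap("results/data/panel.popmap.tsv"))

am <- amova(gm, n_perm = 1000, seed = 1234)
write.table(am$table, "results/amova.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("AMOVA: %.2f%% among populations, %.2f%% among individuals, %.2f%% within individuals (p = %.4g)\n",
            am$table$percent[1], am$table$percent[2], am$table$percent[3],
            am$table$p_value[1]))

paf <- population_allele_frequencies(gm)
eu <- euclidean_distance_matrix(paf$freq)
fstm <- fst_matrix(gm, n_boot = 1000, seed = 1234)
write.table(fstm$pairs, "results/fst_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(population = rownames(eu), round(eu, 6)),
            "results/euclidean_dist.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pr <- fstm$pairs
cat(sprintf("Pairwise Fst range: %.3f (%s-%s) to %.3f (%s-%s)\n",
            min(pr$fst), pr$pop_a[which.min(pr$fst)], pr$pop_b[which.min(pr$fst)],
            max(pr$fst), pr$pop_a[which.max(pr$fst)], pr$pop_b[which.max(pr$fst)]))

ape::write.tree(neighbor_joining_tree(eu), "results/nj_euclidean.nwk")
ape::write.tree(neighbor_joining_tree(fstm$fst), "results/nj_fst.nwk")

pc <- pcoa(eu)
write.table(data.frame(population = rownames(pc$coords), round(pc$coords, 6)),
            "results/pcoa_coords.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
var_expl <- pc$eigenvalues[pc$eigenvalues > 0]
cat(sprintf("PCoA: first two axes explain %.1f%% of positive-eigenvalue variance\n",
            100 * sum(var_expl[1:2]) / sum(var_expl)))
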