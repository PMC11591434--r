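test_that("Balding-Nichols frequencies: limits, determinism and downstream recovery", {
  cfg0 <- sim_config(n_pops = 2, n_ind_per_pop = 10, pop_names = c("A", "B"),
                     n_loci = 200, chrom_lengths = c(`1` = 1e7),
                     target_fst = 0, f_roh_target = 0, n_outlier_loci = 0,
                     seed = 1)
  fr0 <- simulate_frequencies(cfg0)
  # F = 0: population frequencies equal the ancestral
  expect_equal(unname(fr0$freq[1, ]), fr0$ancestral)
  expect_equal(unname(fr0$freq[2, ]), fr0$ancestral)
  expect_true(all(fr0$ancestral >= 0.05 & fr0$ancestral <= 0.95))
  # determinism: same config -> identical draws
  fr0b <- simulate_frequencies(cfg0)
  expect_identical(fr0, fr0b)
  # F = 0.15 recovered by the Weir-Cockerham estimator downstream
  cfg <- sim_config(n_pops = 2, n_ind_per_pop = 50, pop_names = c("A", "B"),
                    n_loci = 5000, chrom_lengths = c(`1` = 2e8),
                    target_fst = 0.15, f_roh_target = 0, n_outlier_loci = 0,
                    missing_rate = 0, seed = 2)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  est <- pairwise_fst(gm, "A", "B", n_boot = 0)$fst
  expect_gt(est, 0.13); expect_lt(est, 0.17)
})

test_that("genotype draws match generating frequencies, fixation and missing rate", {
  cfg <- sim_config(n_pops = 2, n_ind_per_pop = 60, pop_names = c("A", "B"),
                    n_loci = 600, chrom_lengths = c(`1` = 3e7),
                    target_fst = 0.2, f_roh_target = 0, n_outlier_loci = 0,
                    missing_rate = 0.05, seed = 3)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  expect_equal(mean(is.na(gm$calls)), 0.05, tolerance = 0.1)
  obs <- population_allele_frequencies(gm)$freq
  err <- abs(obs - fr$freq)
  expect_lt(mean(err, na.rm = TRUE), 2 * mean(sqrt(fr$freq * (1 - fr$freq) / 120)))
  # freq 1 -> all dosage 2
  fr$freq[, 1] <- 1
  gm2 <- simulate_genotypes(fr, cfg)
  expect_true(all(gm2$calls[, 1] == 2, na.rm = TRUE))
})

test_that("ROH implantation: zero target is identity; tracts land where truth says", {
  cfg0 <- sim_config(n_pops = 1, n_ind_per_pop = 6, pop_names = "A",
                     n_loci = 500, chrom_lengths = c(`1` = 2e7),
                     target_fst = 0.1, f_roh_target = 0, n_outlier_loci = 0,
                     seed = 4)
  fr <- simulate_frequencies(cfg0)
  gm <- simulate_genotypes(fr, cfg0)
  imp0 <- implant_roh(gm, fr, cfg0)
  expect_identical(imp0$gm$calls, gm$calls)
  expect_equal(nrow(imp0$truth$tracts), 0)

  cfg <- sim_config(n_pops = 1, n_ind_per_pop = 4, pop_names = "A",
                    n_loci = 1000, chrom_lengths = c(`1` = 5e7),
                    target_fst = 0.1, f_roh_target = 0.3, n_outlier_loci = 0,
                    roh_interval_mb = c(4, 10), seed = 5)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  imp <- implant_roh(gm, fr, cfg)
  tr <- imp$truth$tracts
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$start_bp >= 1 & tr$end_bp <= 5e7))
  # inside every truth tract, no heterozygous calls remain
  for (k in seq_len(nrow(tr))) {
    row <- match(tr$sample_id[k], imp$gm$samples$sample_id)
    in_tract <- imp$gm$loci$pos >= tr$start_bp[k] &
      imp$gm$loci$pos <= tr$end_bp[k]
    g <- imp$gm$calls[row, in_tract]
    expect_false(any(g == 1, na.rm = TRUE))
  }
  # outside all tracts of an individual the calls are untouched
  row1 <- imp$gm$samples$sample_id[1]
  t1 <- tr[tr$sample_id == row1, ]
  outside <- rep(TRUE, n_loci(gm))
  for (k in seq_len(nrow(t1)))
    outside <- outside & !(gm$loci$pos >= t1$start_bp[k] &
                             gm$loci$pos <= t1$end_bp[k])
  expect_identical(imp$gm$calls[1, outside], gm$calls[1, outside])
})

test_that("island carriers produce the exact planted incidence identity", {
  # carriers forced homozygous over an island: incidence = carriers / N
  cfg <- sim_config(n_pops = 1, n_ind_per_pop = 119, pop_names = "A",
                    n_loci = 1500, chrom_lengths = c(`1` = 6e7),
                    target_fst = 0.1, f_roh_target = 0,
                    n_outlier_loci = 1, island_span_loci = 80,
                    island_carrier_fraction = 64 / 119,
                    missing_rate = 0, seed = 6)
  fr <- simulate_frequencies(cfg)
  imp <- implant_roh(simulate_genotypes(fr, cfg), fr, cfg)
  expect_length(imp$truth$island_carriers[[1]], 64)
  segs <- suppressMessages(scan_roh(imp$gm, roh_params(genome_size_bp = 6e7)))
  inc <- roh_incidence(segs, imp$gm)
  ctr <- fr$outlier_loci[1]
  expect_equal(round(inc$incidence_pct[ctr], 2), 53.78)
})

test_that("generate_dataset writes a self-consistent, byte-reproducible trio", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_pops = 3, n_ind_per_pop = 6, pop_names = c("A", "B", "C"),
                    n_loci = 300, chrom_lengths = c(`1` = 2e7, `2` = 1e7),
                    target_fst = 0.2, f_roh_target = 0.05, n_outlier_loci = 2,
                    island_span_loci = 30, seed = 7)
  g1 <- generate_dataset(cfg, file.path(dir, "d1"))
  g2 <- generate_dataset(cfg, file.path(dir, "d2"))
  expect_identical(readLines(g1$paths$vcf), readLines(g2$paths$vcf))
  expect_identical(readLines(g1$paths$popmap), readLines(g2$paths$popmap))
  expect_identical(readLines(g1$paths$truth), readLines(g2$paths$truth))
  # reading back reproduces the in-memory dataset and satisfies invariants
  gm <- assign_populations(read_vcf(g1$paths$vcf),
                           read_popmap(g1$paths$popmap))
  expect_identical(unname(gm$calls), unname(g1$gm$calls))
  expect_silent(validate_genotype_matrix(gm))
  truth <- jsonlite::read_json(g1$paths$truth, simplifyVector = TRUE)
  expect_equal(length(truth$outlier_ids), 2)
  expect_equal(nrow(g1$truth$tracts), nrow(as.data.frame(truth$tracts)))
})
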