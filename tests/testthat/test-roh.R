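test_that("scanner degenerate cases: all-het yields nothing, all-homozygous one segment", {
  withr::local_seed(71)
  # fully heterozygous individual -> no segments
  gm_het <- toy_gm(matrix(1L, 1, 500),
                   pos = seq(10000L, by = 10000L, length.out = 500))
  expect_equal(nrow(scan_roh(gm_het, roh_params(genome_size_bp = 5e6))), 0)
  # 500 homozygous SNPs over 5 Mb, no gaps -> exactly one segment, full span
  g <- sample(c(0L, 2L), 500, replace = TRUE)
  gm_hom <- toy_gm(matrix(g, 1), pos = seq(10000L, by = 10000L, length.out = 500))
  seg <- scan_roh(gm_hom, roh_params(genome_size_bp = 5e6))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_pos, 10000L)
  expect_equal(seg$end_pos, 5000000L)
  expect_equal(seg$n_snps, 500L)
})

test_that("implanted tracts are recovered with bounded boundary error", {
  withr::local_seed(72)
  L <- 2000L
  pos <- seq(25000L, by = 25000L, length.out = L)  # 25 kb spacing, 50 Mb
  params <- roh_params(genome_size_bp = 50e6)
  n_found <- 0
  for (rep in 1:25) {
    tract_len <- sample(55:500, 1)
    tract_start <- sample(seq_len(L - tract_len - 1)[-seq_len(60)], 1)
    g <- implant_vector(L, tract_start, tract_len, p_het_bg = 0.6)
    seg <- scan_roh(toy_gm(matrix(g, 1), pos = pos), params)
    t0 <- pos[tract_start]; t1 <- pos[tract_start + tract_len - 1]
    ov <- seg[seg$start_pos <= t1 & seg$end_pos >= t0, , drop = FALSE]
    expect_equal(nrow(ov), 1)
    if (nrow(ov) == 1) {
      n_found <- n_found + 1
      span_bp <- 50 * 25000   # one window span
      expect_lte(abs(ov$start_pos - t0), span_bp)
      expect_lte(abs(ov$end_pos - t1), span_bp)
    }
  }
  expect_equal(n_found, 25)
})

test_that("segment filters and gap splitting apply", {
  withr::local_seed(73)
  pos <- seq(25000L, by = 25000L, length.out = 400L)
  params <- roh_params(genome_size_bp = 1e7)
  # 40-SNP tract (1 Mb): below the 50-SNP minimum -> rejected
  g <- implant_vector(400L, 100L, 40L, p_het_bg = 1)
  expect_equal(nrow(scan_roh(toy_gm(matrix(g, 1), pos = pos), params)), 0)
  # a gap > 1000 kb splits a run in two
  pos2 <- c(seq(25000L, by = 25000L, length.out = 100),
            seq(25000L * 100 + 2e6, by = 25000L, length.out = 100))
  g2 <- sample(c(0L, 2L), 200, replace = TRUE)
  seg2 <- scan_roh(toy_gm(matrix(g2, 1), pos = pos2),
                   roh_params(genome_size_bp = 1e7, min_length_kb = 1000))
  expect_equal(nrow(seg2), 2)
  # segments never span chromosomes and never overlap within an individual
  gm3 <- toy_gm(matrix(sample(c(0L, 2L), 400, replace = TRUE), 2),
                chrom = rep(c("1", "2"), each = 100),
                pos = rep(seq(3e4, by = 3e4, length.out = 100), 2))
  seg3 <- scan_roh(gm3, roh_params(genome_size_bp = 6e6))
  expect_true(all(table(seg3$sample_id, seg3$chrom) <= 1) ||
                all(!mapply(function(s, c) {
                  x <- seg3[seg3$sample_id == s & seg3$chrom == c, ]
                  any(x$start_pos[-1] <= x$end_pos[-nrow(x)])
                }, seg3$sample_id, seg3$chrom)))
})

test_that("F_ROH arithmetic and the overlap guard", {
  seg <- data.frame(sample_id = "s1", chrom = c("1", "2"),
                    start_pos = c(1, 1), end_pos = c(46541000, 46541000))
  expect_equal(f_roh(seg, "s1", roh_params()), 93082000 / 930820000)
  expect_equal(f_roh(seg[0, ], "s1", roh_params()), 0)
  full <- data.frame(sample_id = "s1", chrom = "1", start_pos = 1,
                     end_pos = 930820000)
  expect_equal(f_roh(full, "s1", roh_params()), 1)
  bad <- data.frame(sample_id = "s1", chrom = "1",
                    start_pos = c(1, 500), end_pos = c(1000, 1500))
  expect_error(f_roh(bad, "s1", roh_params()), "overlapping")
})

test_that("planted genomic ROH fractions are recovered by the scanner", {
  cfg <- sim_config(n_pops = 3, n_ind_per_pop = 5,
                    pop_names = c("low", "mid", "high"), n_loci = 2500,
                    chrom_lengths = c(`1` = 5e7, `2` = 5e7),
                    target_fst = 0.1, f_roh_target = c(0.1, 0.3, 0.5),
                    n_outlier_loci = 0, missing_rate = 0.02,
                    roh_interval_mb = c(5, 15), seed = 74)
  fr <- simulate_frequencies(cfg)
  imp <- implant_roh(simulate_genotypes(fr, cfg), fr, cfg)
  segs <- suppressMessages(scan_roh(imp$gm, roh_params(genome_size_bp = 1e8)))
  fro <- f_roh_summary(segs, imp$gm, roh_params(genome_size_bp = 1e8))
  got <- fro$by_population
  targets <- c(low = 0.1, mid = 0.3, high = 0.5)
  for (pp in names(targets))
    expect_lt(abs(got$mean_f_roh[got$population == pp] - targets[[pp]]), 0.05)
})

test_that("ROH incidence equals a brute-force interval-stabbing count", {
  withr::local_seed(75)
  gm <- toy_gm(matrix(0L, 10, 50),
               chrom = rep(c("1", "2"), each = 25),
               pos = rep(seq(1e5, by = 1e5, length.out = 25), 2))
  segments <- do.call(rbind, lapply(1:10, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(sample_id = gm$samples$sample_id[i],
               chrom = sample(c("1", "2"), k, replace = TRUE),
               start_pos = s <- sample(seq(1e5, 2.4e6, by = 1e5), k),
               end_pos = s + sample(3:8, k, replace = TRUE) * 1e5)
  }))
  # de-overlap per individual/chromosome to satisfy the scanner contract
  segments <- segments[!duplicated(segments[c("sample_id", "chrom")]), ]
  inc <- roh_incidence(segments, gm)
  expect_equal(inc$carriers, bf_carriers(segments, gm$loci))
  expect_equal(inc$incidence_pct, 100 * inc$carriers / 10)
  expect_true(all(inc$incidence_pct >= 0 & inc$incidence_pct <= 100))
})

test_that("island selection respects quantile-with-ties semantics", {
  inc <- data.frame(id = sprintf("L%04d", 1:1000), chrom = "1", pos = 1:1000,
                    carriers = 0, incidence_pct = sample(seq(0.1, 100, length.out = 1000)))
  isl <- roh_islands(inc, top_fraction = 0.01)
  expect_equal(nrow(isl), 10)
  expect_equal(sort(isl$incidence_pct), sort(inc$incidence_pct, decreasing = TRUE)[10:1])
  # all tied -> all returned
  inc$incidence_pct <- 50
  expect_equal(nrow(roh_islands(inc, 0.01)), 1000)
})

test_that("LD decay: adjacent duplicated loci give first-bin r2 of 1 and decay is monotone under AR haplotypes", {
  withr::local_seed(76)
  calls <- t(replicate(20, rbinom(2, 2, 0.5)))
  calls <- cbind(calls[, 1], calls[, 1], calls[, 2])
  gm <- toy_gm(calls, pos = c(1000L, 2000L, 900000L))
  ld <- ld_decay(gm, "P1", max_dist_kb = 1000, bin_kb = 50)
  expect_equal(ld$mean_r2[1], 1)
  cfg <- sim_config(n_pops = 1, n_ind_per_pop = 40, pop_names = "A",
                    n_loci = 400, chrom_lengths = c(`1` = 4e6),
                    target_fst = 0.1, f_roh_target = 0, n_outlier_loci = 0,
                    missing_rate = 0, ld_rho = 0.95, seed = 77)
  fr <- simulate_frequencies(cfg)
  gm2 <- simulate_genotypes(fr, cfg)
  ld2 <- ld_decay(gm2, "A", max_dist_kb = 400, bin_kb = 100)
  r2 <- ld2$mean_r2[!is.na(ld2$mean_r2)]
  expect_true(all(diff(r2) < 0))
  # unlinked loci: mean r2 near the finite-sample floor ~ 1/n
  withr::local_seed(78)
  gm3 <- random_gm(40, 300)
  gm3$loci$pos <- seq(10000L, by = 10000L, length.out = 300)
  ld3 <- ld_decay(gm3, "P1", max_dist_kb = 500, bin_kb = 100)
  expect_lt(max(ld3$mean_r2, na.rm = TRUE), 3 / 40)
})
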