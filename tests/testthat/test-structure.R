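test_that("population allele frequencies equal a brute-force census", {
  withr::local_seed(61)
  gm <- random_gm(12, 40, n_pops = 3, missing_rate = 0.1)
  paf <- population_allele_frequencies(gm)
  for (pp in populations(gm)) {
    cs <- bf_census(gm$calls[gm$samples$population == pp, , drop = FALSE])
    expect_equal(unname(paf$freq[pp, cs$n > 0]),
                 (cs$alt / cs$n)[cs$n > 0])
  }
  # {0,1,2} in 3 diploids -> p = 0.5
  gm2 <- toy_gm(rbind(0L, 1L, 2L))
  expect_equal(unname(population_allele_frequencies(gm2)$freq[1, 1]), 0.5)
})

test_that("Euclidean distances: arithmetic, symmetry and a loop oracle", {
  f <- rbind(A = c(0.1, 0.2), B = c(0.4, 0.6), C = c(0.1, 0.2))
  d <- euclidean_distance_matrix(f)
  expect_equal(d["A", "B"], sqrt(0.3^2 + 0.4^2))   # = 0.5
  expect_equal(d["A", "C"], 0)
  expect_identical(d, t(d))
  expect_true(all(diag(d) == 0))
  withr::local_seed(62)
  f4 <- matrix(runif(4 * 25), 4, dimnames = list(LETTERS[1:4], NULL))
  d4 <- euclidean_distance_matrix(f4)
  for (i in 1:3) for (j in (i + 1):4) {
    acc <- 0
    for (l in 1:25) acc <- acc + (f4[i, l] - f4[j, l])^2
    expect_equal(d4[i, j], sqrt(unname(acc)))
  }
})

test_that("per-locus Weir-Cockerham Fst matches the hand-coded component formulas", {
  withr::local_seed(63)
  gm <- random_gm(16, 25, n_pops = 2, missing_rate = 0.08)
  tab <- suppressMessages(per_locus_fst(gm))
  pops <- populations(gm)
  for (l in sample(25, 8)) {
    n <- p <- h <- numeric(2)
    for (k in 1:2) {
      g <- gm$calls[gm$samples$population == pops[k], l]
      g <- g[!is.na(g)]
      n[k] <- length(g); p[k] <- sum(g) / (2 * length(g))
      h[k] <- mean(g == 1)
    }
    if (any(n < 2)) next
    expect_equal(tab$fst[l], bf_wc84_locus(n, p, h)$fst, tolerance = 1e-12)
  }
  # complete differentiation -> 1; equal frequencies -> ~0
  gmf <- toy_gm(rbind(0L, 0L, 0L, 2L, 2L, 2L), pops = rep(c("A", "B"), each = 3))
  expect_equal(per_locus_fst(gmf)$fst, 1)
})

test_that("pairwise Fst: fixation gives 1, panmixia ~0, bootstrap reproducible", {
  gmf <- toy_gm(matrix(rep(c(0L, 0L, 0L, 2L, 2L, 2L), 5), 6, 5),
                pops = rep(c("A", "B"), each = 3))
  expect_equal(pairwise_fst(gmf, "A", "B", n_boot = 0)$fst, 1)

  withr::local_seed(64)
  gm0 <- random_gm(100, 1000, n_pops = 2)   # one panmictic pool split in two
  r0 <- pairwise_fst(gm0, "P1", "P2", n_boot = 200, seed = 9)
  expect_lt(abs(r0$fst), 0.02)
  r0b <- pairwise_fst(gm0, "P1", "P2", n_boot = 200, seed = 9)
  expect_identical(r0, r0b)
  expect_true(r0$ci_lower <= r0$fst + 1e-12 && r0$fst <= r0$ci_upper + 1e-12)
})

test_that("estimated Fst increases with the simulator's divergence parameter", {
  ests <- sapply(c(0.05, 0.15, 0.3), function(F) {
    cfg <- sim_config(n_pops = 2, n_ind_per_pop = 40, pop_names = c("A", "B"),
                      n_loci = 1500, chrom_lengths = c(`1` = 5e7),
                      target_fst = F, f_roh_target = 0, n_outlier_loci = 0,
                      missing_rate = 0, seed = 70 + round(100 * F))
    fr <- simulate_frequencies(cfg)
    gm <- simulate_genotypes(fr, cfg)
    pairwise_fst(gm, "A", "B", n_boot = 0)$fst
  })
  expect_true(all(diff(ests) > 0))
})

test_that("neighbor joining recovers additive metrics exactly and respects labels", {
  # additive 4-taxon tree: ((A:2,B:3):1,(C:4,D:5))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8
  d["B", "D"] <- d["D", "B"] <- 9
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- neighbor_joining_tree(d)
  expect_setequal(tr$tip.label, LETTERS[1:4])
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[LETTERS[1:4], LETTERS[1:4]],
               d, tolerance = 1e-12)
  # label-permutation invariance (same cophenetic distances)
  perm <- c("C", "A", "D", "B")
  tr2 <- neighbor_joining_tree(d[perm, perm])
  expect_equal(as.matrix(ape::cophenetic.phylo(tr2))[LETTERS[1:4], LETTERS[1:4]],
               d, tolerance = 1e-12)
  # 3-taxon closed form: x = (dAB + dAC - dBC) / 2 etc.
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining_tree(d3)
  cp <- as.matrix(ape::cophenetic.phylo(tr3))
  expect_equal(cp[c("A", "B", "C"), c("A", "B", "C")], d3, tolerance = 1e-12)
  expect_error(neighbor_joining_tree(matrix(c(0, 1, 2, 0), 2)), "3 labels")
  dd <- d; dd[1, 2] <- 4
  expect_error(neighbor_joining_tree(dd), "symmetric")
})

test_that("PCoA reconstructs Euclidean-embeddable distances and orders eigenvalues", {
  # 3-4-5 right triangle
  d <- matrix(0, 3, 3, dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  d["p", "q"] <- d["q", "p"] <- 3
  d["p", "r"] <- d["r", "p"] <- 4
  d["q", "r"] <- d["r", "q"] <- 5
  pc <- pcoa(d)
  expect_equal(unname(as.matrix(dist(pc$coords))), unname(d), tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  # random Euclidean configuration reconstructs exactly
  withr::local_seed(65)
  X <- matrix(rnorm(6 * 3), 6)
  rownames(X) <- paste0("t", 1:6)
  d6 <- as.matrix(dist(X))
  pc6 <- pcoa(d6)
  expect_equal(unname(as.matrix(dist(pc6$coords))), unname(d6), tolerance = 1e-9)
  # identical points -> all eigenvalues ~0
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(abs(pcoa(d0)$eigenvalues) < 1e-12))
})

test_that("AMOVA components match the brute-force allele-copy partition", {
  withr::local_seed(66)
  for (rep in 1:3) {
    n_pops <- sample(2:3, 1)
    gm <- random_gm(4 * n_pops, 10, n_pops = n_pops,
                    missing_rate = if (rep == 3) 0.1 else 0)
    am <- amova(gm, n_perm = 0)
    bf <- bf_amova_ss(gm$calls, match(gm$samples$population, populations(gm)))
    expect_equal(am$table$SS[1], bf$ss_ap, tolerance = 1e-9)
    expect_equal(am$table$SS[2], bf$ss_ai, tolerance = 1e-9)
    expect_equal(am$table$SS[3], bf$ss_wi, tolerance = 1e-9)
    expect_equal(am$table$SS[4], bf$ss_tot, tolerance = 1e-9)
    expect_equal(sum(am$table$percent[1:3]), 100, tolerance = 1e-6)
  }
})

test_that("AMOVA degenerate cases behave: identical individuals, fixed populations", {
  gm_id <- toy_gm(matrix(1L, 6, 8), pops = rep(c("A", "B"), each = 3))
  am <- amova(gm_id, n_perm = 0)
  # only within-individual SS: each het call contributes 0.5
  expect_equal(am$table$SS[1:3], c(0, 0, 6 * 8 * 0.5))
  # two populations fixed for alternate alleles: all variance among pops
  gmf <- toy_gm(matrix(rep(c(rep(0L, 4), rep(2L, 4)), 6), 8, 6),
                pops = rep(c("A", "B"), each = 4))
  amf <- amova(gmf, n_perm = 199, seed = 2)
  expect_equal(amf$table$percent[1], 100, tolerance = 1e-9)
  # 8 individuals admit only choose(8,4) = 70 distinct splits, so random
  # permutations tie with the observed extreme split ~1/35 of the time
  expect_lte(amf$table$p_value[1], 0.05)
  expect_error(amova(toy_gm(matrix(0L, 4, 3)), n_perm = 0), "2 populations")
})

test_that("AMOVA permutation p-values: significant under structure, uniform under panmixia", {
  cfg <- sim_config(n_pops = 3, n_ind_per_pop = 10,
                    pop_names = c("A", "B", "C"), n_loci = 300,
                    chrom_lengths = c(`1` = 3e7), target_fst = 0.3,
                    f_roh_target = 0, n_outlier_loci = 0, missing_rate = 0,
                    seed = 81)
  fr <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(fr, cfg)
  am <- amova(gm, n_perm = 199, seed = 3)
  expect_lte(am$table$p_value[1], 0.01)
  # panmictic: p should be far from systematically small
  withr::local_seed(67)
  ps <- replicate(8, {
    gm0 <- random_gm(24, 150, n_pops = 3)
    amova(gm0, n_perm = 99, seed = sample.int(1e6, 1))$table$p_value[1]
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
})
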