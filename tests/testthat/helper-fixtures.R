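# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as literal loops over definitions, never
# calling the package functions they check.

# Build a genotype_matrix from a plain calls matrix (rows = samples).
toy_gm <- function(calls, pops = NULL, chrom = NULL, pos = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) {
    pos <- integer(L)
    for (ch in unique(chrom)) {
      ix <- which(chrom == ch)
      pos[ix] <- seq_along(ix) * 1000L
    }
  }
  if (is.null(pops)) pops <- rep("P1", nrow(calls))
  genotype_matrix(
    calls,
    loci = data.frame(chrom = chrom, pos = pos,
                      id = sprintf("L%03d", seq_len(L)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("s%03d", seq_len(nrow(calls))),
                         population = pops, stringsAsFactors = FALSE))
}

# Random toy genotype matrix with optional missingness.
random_gm <- function(n_ind, n_loci, n_pops = 1, missing_rate = 0,
                      maf_range = c(0.05, 0.95)) {
  p <- runif(n_loci, maf_range[1], maf_range[2])
  calls <- t(replicate(n_ind, rbinom(n_loci, 2, p)))
  if (missing_rate > 0)
    calls[matrix(runif(n_ind * n_loci) < missing_rate, n_ind)] <- NA
  pops <- rep(paste0("P", seq_len(n_pops)), length.out = n_ind)
  toy_gm(calls, pops = sort(pops))
}

# One population sampled from the standard neutral site-frequency spectrum:
# derived-allele count k among 2n copies drawn with probability proportional
# to 1/k, copies assigned to individuals at random. Under this model the
# expected per-site pairwise diversity equals the expected Watterson
# estimate exactly.
neutral_sfs_gm <- function(n_ind, n_loci) {
  ncop <- 2L * n_ind
  k <- sample(seq_len(ncop - 1), n_loci, replace = TRUE,
              prob = 1 / seq_len(ncop - 1))
  calls <- matrix(0L, n_ind, n_loci)
  for (l in seq_len(n_loci)) {
    copies <- integer(ncop)
    copies[sample.int(ncop, k[l])] <- 1L
    calls[, l] <- copies[seq(1, ncop, 2)] + copies[seq(2, ncop, 2)]
  }
  toy_gm(calls)
}

# Brute-force per-site pairwise diversity: mean over loci (>= 2 copies) of
# the fraction of differing allele-copy pairs, enumerating all pairs.
bf_pi <- function(calls) {
  per_locus <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    copies <- unlist(lapply(g, function(x) switch(as.character(x),
      "0" = c(0L, 0L), "1" = c(0L, 1L), "2" = c(1L, 1L))))
    n <- length(copies)
    if (n < 2) return(NA_real_)
    diff_pairs <- 0L; tot <- 0L
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      tot <- tot + 1L
      if (copies[i] != copies[j]) diff_pairs <- diff_pairs + 1L
    }
    diff_pairs / tot
  })
  mean(per_locus, na.rm = TRUE)
}

# Brute-force per-locus allele census for one population's calls.
bf_census <- function(calls) {
  alt <- integer(ncol(calls)); n <- integer(ncol(calls))
  for (l in seq_len(ncol(calls))) for (i in seq_len(nrow(calls))) {
    g <- calls[i, l]
    if (!is.na(g)) { alt[l] <- alt[l] + g; n[l] <- n[l] + 2L }
  }
  list(alt = alt, n = n)
}

# Independent scalar Weir-Cockerham (1984) Fst for one locus, coded from
# the published component formulas (a, b, c).
bf_wc84_locus <- function(n, p, h) {
  r <- length(n)
  n_bar <- mean(n)
  n_c <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  p_bar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / sum(n)
  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, d = a + b + cc, fst = a / (a + b + cc))
}

# Brute-force AMOVA sums of squares: at each locus every called genotype
# contributes two allele copies (heterozygotes split 1/0); the hierarchical
# partition (pop / individual / copy) is computed per locus from literal
# means and summed over loci.
bf_amova_ss <- function(calls, pop_of) {
  ss_ap <- ss_ai <- ss_wi <- ss_tot <- 0
  for (l in seq_len(ncol(calls))) {
    x <- c(); ind <- c(); pop <- c()
    for (i in seq_len(nrow(calls))) {
      g <- calls[i, l]
      if (is.na(g)) next
      cp <- switch(as.character(g), "0" = c(0, 0), "1" = c(1, 0), "2" = c(1, 1))
      x <- c(x, cp); ind <- c(ind, i, i); pop <- c(pop, pop_of[i], pop_of[i])
    }
    if (length(x) == 0) next
    gm_tot <- mean(x)
    ss_tot <- ss_tot + sum((x - gm_tot)^2)
    for (i in unique(ind)) {
      xi <- x[ind == i]
      ss_wi <- ss_wi + sum((xi - mean(xi))^2)
    }
    for (p in unique(pop)) {
      xp <- x[pop == p]
      ss_ap <- ss_ap + length(xp) * (mean(xp) - gm_tot)^2
      for (i in unique(ind[pop == p])) {
        xi <- x[ind == i & pop == p]
        ss_ai <- ss_ai + length(xi) * (mean(xi) - mean(xp))^2
      }
    }
  }
  list(ss_ap = ss_ap, ss_ai = ss_ai, ss_wi = ss_wi, ss_tot = ss_tot)
}

# Brute-force interval stabbing: carriers per locus by scanning every
# segment.
bf_carriers <- function(segments, loci) {
  vapply(seq_len(nrow(loci)), function(l) {
    hit <- segments$chrom == loci$chrom[l] &
      segments$start_pos <= loci$pos[l] & segments$end_pos >= loci$pos[l]
    length(unique(segments$sample_id[hit]))
  }, integer(1))
}

# A heterozygous-background genotype vector with one homozygous tract.
implant_vector <- function(L, tract_start, tract_len, p_het_bg = 1) {
  g <- ifelse(runif(L) < p_het_bg, 1L,
              sample(c(0L, 2L), L, replace = TRUE))
  ix <- tract_start:(tract_start + tract_len - 1)
  g[ix] <- sample(c(0L, 2L), length(ix), replace = TRUE)
  g
}
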