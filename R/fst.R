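# Weir & Cockerham (1984) variance components for Fst, computed per locus
# over any number of populations, plus the finite-sample-uncorrected variant
# used for neutral-distribution fitting (as in OutFLANK).

# Per-population per-locus summaries: n (called diploids), p (alt frequency),
# h (observed heterozygote fraction among called). Each is a pops x loci
# matrix; rownames are the population labels.
pop_locus_stats <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- populations(gm)
  L <- n_loci(gm)
  n <- p <- h <- matrix(NA_real_, length(pops), L,
                        dimnames = list(pops, gm$loci$id))
  for (i in seq_along(pops)) {
    calls <- gm$calls[population_index(gm, pops[i]), , drop = FALSE]
    ni <- colSums(!is.na(calls))
    n[i, ] <- ni
    p[i, ] <- colSums(calls, na.rm = TRUE) / (2 * ni)
    h[i, ] <- colSums(calls == 1, na.rm = TRUE) / ni
  }
  list(n = n, p = p, h = h)
}

# Vectorised WC84 components across loci. Populations with no calls at a
# locus drop out of that locus. Returns per-locus numerator (a) and
# denominator (a + b + c) for both the corrected estimator and the
# uncorrected variant, plus pooled expected heterozygosity and the number of
# populations contributing. Loci with < 2 contributing populations or mean
# sample size <= 1 get NA components.
wc_components <- function(st) {
  n <- st$n; p <- st$p; h <- st$h
  has <- n > 0
  r <- colSums(has)
  n0 <- ifelse(has, n, 0)
  p0 <- ifelse(has, p, 0)
  h0 <- ifelse(has, h, 0)
  n_sum <- colSums(n0)
  n_bar <- n_sum / r
  n_c <- (n_sum - colSums(n0^2) / n_sum) / (r - 1)
  p_bar <- colSums(n0 * p0) / n_sum
  s2 <- colSums(n0 * (p0 - rep(p_bar, each = nrow(p0)))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n0 * h0) / n_sum
  pq <- p_bar * (1 - p_bar)

  a <- n_bar / n_c *
    (s2 - 1 / (n_bar - 1) * (pq - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (pq - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  a_nc <- n_bar / n_c * s2
  b_nc <- pq - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar
  c_nc <- h_bar / 2

  bad <- r < 2 | n_bar <= 1 | !is.finite(n_c) | n_c <= 0
  out <- list(num = a, den = a + b + cc,
              num_nc = a_nc, den_nc = a_nc + b_nc + c_nc,
              het = 2 * pq, r = r)
  for (nm in c("num", "den", "num_nc", "den_nc"))
    out[[nm]][bad] <- NA_real_
  out
}

#' Per-locus multi-population Weir-Cockerham Fst
#'
#' Computes, for every locus, the Weir & Cockerham (1984) Fst estimate over
#' all assigned populations, the finite-sample-uncorrected variant used for
#' neutral-distribution fitting, and the expected heterozygosity at the
#' pooled allele frequency. Loci callable in fewer than two populations are
#' returned as `NA` and counted in a message.
#'
#' @param gm A [genotype_matrix()] with >= 2 populations assigned.
#' @return Data frame with one row per locus: `id`, `chrom`, `pos`, `fst`,
#'   `fst_nocorr`, `het`, `n_pops`.
#' @export
per_locus_fst <- function(gm) {
  pops <- populations(gm)
  if (length(pops) < 2) stop("per-locus Fst needs >= 2 populations")
  wc <- wc_components(pop_locus_stats(gm, pops))
  excluded <- sum(is.na(wc$num))
  if (excluded > 0)
    message("per_locus_fst: ", excluded,
            " locus/loci callable in < 2 populations excluded")
  data.frame(
    id = gm$loci$id, chrom = gm$loci$chrom, pos = gm$loci$pos,
    fst = wc$num / wc$den,
    fst_nocorr = wc$num_nc / wc$den_nc,
    het = wc$het,
    n_pops = wc$r,
    stringsAsFactors = FALSE)
}

#' Pairwise Weir-Cockerham Fst with locus bootstrap
#'
#' The genome-wide estimate combines loci as a ratio of sums (sum of
#' per-locus numerators over sum of per-locus denominators). Confidence
#' intervals come from resampling loci with replacement; the same seed gives
#' bit-identical results.
#'
#' @param gm A [genotype_matrix()] with populations assigned.
#' @param pop_a,pop_b Population labels; each must have >= 2 individuals.
#' @param n_boot Number of bootstrap resamples (default 1000; 0 disables).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level for the percentile interval (default 0.95).
#' @return List with `fst`, `ci_lower`, `ci_upper`, `n_boot`, `n_loci_used`.
#' @export
pairwise_fst <- function(gm, pop_a, pop_b, n_boot = 1000, seed = NULL,
                         conf = 0.95) {
  if (length(population_index(gm, pop_a)) < 2 ||
      length(population_index(gm, pop_b)) < 2)
    stop("pairwise Fst needs >= 2 individuals in each population")
  wc <- wc_components(pop_locus_stats(gm, c(pop_a, pop_b)))
  ok <- !is.na(wc$num) & !is.na(wc$den)
  if (!any(ok)) stop("no locus callable in both populations")
  num <- wc$num[ok]; den <- wc$den[ok]
  fst <- sum(num) / sum(den)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      L <- length(num)
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(L, L, replace = TRUE)
        sum(num[idx]) / sum(den[idx])
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(fst = fst, ci_lower = ci[1], ci_upper = ci[2],
       n_boot = n_boot, n_loci_used = sum(ok))
}

#' All-pairs Fst distance matrix
#'
#' @param gm A [genotype_matrix()] with >= 2 populations assigned.
#' @param n_boot,seed,conf Passed to [pairwise_fst()]; bootstrap resamples
#'   are drawn per pair from a seed derived from `seed` and the pair name.
#' @return List with `fst` (symmetric matrix, zero diagonal) and `pairs`
#'   (data frame of per-pair estimates and CIs).
#' @export
fst_matrix <- function(gm, n_boot = 1000, seed = NULL, conf = 0.95) {
  pops <- populations(gm)
  k <- length(pops)
  if (k < 2) stop("need >= 2 populations")
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    pr <- pairwise_fst(gm, pops[i], pops[j], n_boot = n_boot,
                       seed = derive_seed(seed, paste0(pops[i], "|", pops[j])),
                       conf = conf)
    m[i, j] <- m[j, i] <- pr$fst
    rows[[length(rows) + 1]] <- data.frame(
      pop_a = pops[i], pop_b = pops[j], fst = pr$fst,
      ci_lower = pr$ci_lower, ci_upper = pr$ci_upper,
      n_loci = pr$n_loci_used, stringsAsFactors = FALSE)
  }
  list(fst = m, pairs = do.call(rbind, rows))
}
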