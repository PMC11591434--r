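#' Per-locus allele counts within one population
#'
#' @param gm A [genotype_matrix()].
#' @param pop Population label.
#' @return List with `alt` (alternate-allele copies per locus), `n`
#'   (non-missing allele copies per locus) and `p` (alt frequency, `NaN`
#'   where no copies are callable).
#' @export
allele_counts <- function(gm, pop) {
  calls <- gm$calls[population_index(gm, pop), , drop = FALSE]
  alt <- colSums(calls, na.rm = TRUE)
  n <- 2L * colSums(!is.na(calls))
  list(alt = alt, n = n, p = alt / n)
}

#' Number of segregating sites within a population
#'
#' A locus segregates when both alleles are observed among the population's
#' non-missing calls.
#'
#' @inheritParams allele_counts
#' @return Integer count.
#' @export
segregating_sites <- function(gm, pop) {
  ac <- allele_counts(gm, pop)
  sum(ac$alt > 0 & ac$alt < ac$n)
}

#' Minor allele frequencies within a population
#'
#' Per locus, `min(p, 1 - p)` over the population's non-missing allele
#' counts. Loci with no callable copies in the population are excluded from
#' the mean. The mean alternate-allele and major-allele frequencies are also
#' returned, since reduced-representation panels are sometimes summarised on
#' those scales.
#'
#' @inheritParams allele_counts
#' @return List with `maf` (per-locus vector, `NaN` where uncallable),
#'   `mean_maf`, `mean_alt_freq`, `mean_major_freq`.
#' @export
minor_allele_freq <- function(gm, pop) {
  ac <- allele_counts(gm, pop)
  maf <- pmin(ac$p, 1 - ac$p)
  ok <- ac$n > 0
  list(maf = maf,
       mean_maf = mean(maf[ok]),
       mean_alt_freq = mean(ac$p[ok]),
       mean_major_freq = mean(pmax(ac$p, 1 - ac$p)[ok]))
}

#' Private alleles per population
#'
#' An allele is private to a population when it is observed there and in no
#' other population. Counts are over (locus, allele) pairs; the rate divides
#' by the total number of loci.
#'
#' @param gm A [genotype_matrix()] with populations assigned (>= 2
#'   populations required).
#' @return Data frame with columns `population`, `private_alleles`,
#'   `private_rate`.
#' @export
private_alleles <- function(gm) {
  pops <- populations(gm)
  if (length(pops) < 2) stop("private alleles need >= 2 populations")
  L <- n_loci(gm)
  # presence[p, locus] for each allele
  ref_pres <- matrix(FALSE, length(pops), L)
  alt_pres <- matrix(FALSE, length(pops), L)
  for (i in seq_along(pops)) {
    ac <- allele_counts(gm, pops[i])
    ref_pres[i, ] <- ac$n - ac$alt > 0
    alt_pres[i, ] <- ac$alt > 0
  }
  count_private <- function(pres) {
    tot <- colSums(pres)
    rowSums(pres & rep(tot == 1, each = nrow(pres)))
  }
  priv <- count_private(ref_pres) + count_private(alt_pres)
  data.frame(population = pops,
             private_alleles = as.integer(priv),
             private_rate = priv / L,
             stringsAsFactors = FALSE)
}

#' Per-individual scaled heterozygosity, averaged per population
#'
#' For individual i, `He_i = (nH_i / nind_i) * (nsnps / ntotal)` where
#' `nH_i` is the individual's count of heterozygous calls, `nind_i` its
#' count of non-missing calls, `nsnps` the total number of loci in the
#' dataset and `ntotal` the genome extent covered by the dataset. By default
#' `ntotal = nsnps`, making the scaling factor 1 and He the plain
#' per-individual heterozygous fraction; pass a genome length (in the same
#' units as `nsnps`, i.e. a locus-count-equivalent) to rescale. The
#' population value is the mean over its individuals; individuals with no
#' non-missing calls are excluded with a warning.
#'
#' @inheritParams allele_counts
#' @param ntotal Genome extent covered by the dataset; defaults to the
#'   number of loci.
#' @return List with `he` (population mean) and `he_ind` (named
#'   per-individual values).
#' @export
heterozygosity_he <- function(gm, pop, ntotal = NULL) {
  idx <- population_index(gm, pop)
  nsnps <- n_loci(gm)
  if (is.null(ntotal)) ntotal <- nsnps
  stopifnot(ntotal > 0)
  calls <- gm$calls[idx, , drop = FALSE]
  n_het <- rowSums(calls == 1, na.rm = TRUE)
  n_called <- rowSums(!is.na(calls))
  if (any(n_called == 0)) {
    warning(sum(n_called == 0),
            " individual(s) with no non-missing calls excluded from He")
  }
  ok <- n_called > 0
  he_ind <- (n_het[ok] / n_called[ok]) * (nsnps / ntotal)
  names(he_ind) <- gm$samples$sample_id[idx][ok]
  list(he = mean(he_ind), he_ind = he_ind)
}

#' Nucleotide diversity (pi) within a population
#'
#' Per locus with n >= 2 callable allele copies and alternate frequency p,
#' the unbiased pairwise diversity is `2 p (1 - p) n / (n - 1)` — the
#' probability that two allele copies drawn without replacement differ. Pi
#' is the mean over those loci.
#'
#' @inheritParams allele_counts
#' @return Per-site diversity (unitless, in \[0, 1\]).
#' @export
nucleotide_diversity_pi <- function(gm, pop) {
  ac <- allele_counts(gm, pop)
  ok <- ac$n >= 2
  if (!any(ok)) stop("no locus has >= 2 callable allele copies in ", pop)
  p <- ac$p[ok]
  n <- ac$n[ok]
  mean(2 * p * (1 - p) * n / (n - 1))
}

#' Watterson's theta within a population
#'
#' `theta = S / (a * L)` with S the number of segregating sites, L the
#' number of loci with >= 2 callable allele copies, and
#' `a = sum_{k=1}^{n-1} 1/k` the harmonic number for n allele copies.
#' Missing data make n locus-specific; by default the median per-locus
#' callable copy count is used for the harmonic number, with an option to
#' weight each locus by its own harmonic number instead.
#'
#' @inheritParams allele_counts
#' @param per_locus_n Use each locus's own harmonic number and average
#'   `S_l / a(n_l)` over loci (default `FALSE`: median-n harmonic number).
#' @return Per-site estimate (unitless).
#' @export
watterson_theta <- function(gm, pop, per_locus_n = FALSE) {
  ac <- allele_counts(gm, pop)
  ok <- ac$n >= 2
  if (!any(ok)) stop("no locus has >= 2 callable allele copies in ", pop)
  seg <- ac$alt > 0 & ac$alt < ac$n
  harm <- function(n) sum(1 / seq_len(n - 1))
  if (per_locus_n) {
    mean(ifelse(seg[ok], 1 / vapply(ac$n[ok], harm, numeric(1)), 0))
  } else {
    n_med <- stats::median(ac$n[ok])
    sum(seg[ok]) / (harm(n_med) * sum(ok))
  }
}

#' Raw Tajima-style difference pi - theta
#'
#' The unnormalised statistic: a negative value indicates an excess of
#' low-frequency variants (sweeps, expansion), a positive value an excess of
#' intermediate frequencies (balancing selection, bottleneck recovery). This
#' is not the classical variance-normalised Tajima's D.
#'
#' @param pi Per-site nucleotide diversity.
#' @param theta Per-site Watterson estimate on the same population and loci.
#' @return `pi - theta`.
#' @export
tajima_d_raw <- function(pi, theta) pi - theta

#' Chi-square contrast between pi and theta
#'
#' A one-degree-of-freedom goodness-of-fit contrast on the locus-summed
#' scale: `chi2 = (pi*L - theta*L)^2 / (theta*L)`, with the p-value from the
#' chi-square distribution's upper tail. Labelled `pi_theta_chi2` in all
#' outputs: it is this package's own construction of the pi/theta contrast,
#' not a claim of equivalence to any other program's test.
#'
#' @param pi,theta Per-site values on the same population and locus set.
#' @param L Number of loci the values were averaged over.
#' @return List with `statistic` and `p_value` (`NA` when theta is 0).
#' @export
pi_theta_chi2 <- function(pi, theta, L) {
  stopifnot(L > 0)
  if (theta <= 0) return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- (pi * L - theta * L)^2 / (theta * L)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-population diversity summary table
#'
#' One row per population: segregating sites, mean minor-allele frequency
#' (plus mean major-allele frequency), private-allele count and per-SNP
#' rate, scaled heterozygosity He, nucleotide diversity pi, Watterson's
#' theta, their raw difference, and the pi/theta chi-square contrast.
#'
#' @param gm A [genotype_matrix()] with >= 2 populations assigned.
#' @param ntotal Genome extent for the He scaling; default = number of loci.
#' @return Data frame with one row per population.
#' @export
diversity_summary <- function(gm, ntotal = NULL) {
  pops <- populations(gm)
  priv <- private_alleles(gm)
  rows <- lapply(pops, function(pp) {
    ac <- allele_counts(gm, pp)
    L <- sum(ac$n >= 2)
    maf <- minor_allele_freq(gm, pp)
    pi <- nucleotide_diversity_pi(gm, pp)
    th <- watterson_theta(gm, pp)
    chi <- pi_theta_chi2(pi, th, L)
    data.frame(
      population = pp,
      n_ind = length(population_index(gm, pp)),
      seg_sites = segregating_sites(gm, pp),
      maf_mean = maf$mean_maf,
      major_freq_mean = maf$mean_major_freq,
      private_alleles = priv$private_alleles[priv$population == pp],
      private_rate = priv$private_rate[priv$population == pp],
      he = heterozygosity_he(gm, pp, ntotal)$he,
      pi = pi,
      theta = th,
      tajima_d_raw = tajima_d_raw(pi, th),
      pi_theta_chi2 = chi$statistic,
      pi_theta_chi2_p = chi$p_value,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
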