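#' Restrict a genotype matrix to autosomal loci
#'
#' Chromosome labels are opaque strings; the whitelist defines which are
#' autosomes. An empty result is allowed (with a warning), since downstream
#' stages may be run on subsets.
#'
#' @param gm A [genotype_matrix()].
#' @param autosomes Character vector of chromosome labels to keep.
#' @return The filtered `genotype_matrix`.
#' @export
filter_autosomal_biallelic <- function(gm, autosomes) {
  keep <- gm$loci$chrom %in% autosomes
  if (!any(keep)) warning("no loci on whitelisted chromosomes remain")
  subset_genotypes(gm, loci = which(keep))
}

#' Filter loci and individuals by call rate
#'
#' Loci with a non-missing fraction below `snp_rate` are removed first, then
#' individuals with a non-missing fraction (over the retained loci) below
#' `ind_rate`.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_rate Minimum per-locus call rate, in (0, 1]. Default 0.95.
#' @param ind_rate Minimum per-individual call rate, in (0, 1]. Default 0.80.
#' @return List with elements `gm` (filtered matrix) and `report` (a
#'   one-row data frame of stage counts: loci/samples in and out, and
#'   per-stage drop counts).
#' @export
filter_call_rates <- function(gm, snp_rate = 0.95, ind_rate = 0.80) {
  stopifnot(snp_rate > 0, snp_rate <= 1, ind_rate > 0, ind_rate <= 1)
  n_snps_in <- n_loci(gm)
  n_samples_in <- n_samples(gm)
  called <- !is.na(gm$calls)
  snp_ok <- colMeans(called) >= snp_rate
  gm2 <- subset_genotypes(gm, loci = which(snp_ok))
  ind_ok <- if (n_loci(gm2) == 0) rep(TRUE, n_samples(gm2)) else
    rowMeans(!is.na(gm2$calls)) >= ind_rate
  gm3 <- subset_genotypes(gm2, samples = which(ind_ok))
  report <- data.frame(
    n_snps_in = n_snps_in, n_snps_out = n_loci(gm3),
    n_samples_in = n_samples_in, n_samples_out = n_samples(gm3),
    snps_dropped_call_rate = sum(!snp_ok),
    samples_dropped_call_rate = sum(!ind_ok))
  list(gm = gm3, report = report)
}

#' Remove monomorphic loci
#'
#' A locus is monomorphic when all non-missing calls imply a single allele:
#' all 0 (reference-fixed), all 2 (alternate-fixed), or no calls at all.
#' Missing calls are ignored entirely.
#'
#' @param gm A [genotype_matrix()].
#' @return The filtered `genotype_matrix`.
#' @export
remove_monomorphic <- function(gm) {
  poly <- apply(gm$calls, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) > 0 && (any(g == 1) || (any(g == 0) && any(g == 2)))
  })
  subset_genotypes(gm, loci = which(poly))
}

#' Squared genotypic correlation between two dosage vectors
#'
#' The LD measure used for pruning and decay profiles: the squared Pearson
#' correlation of dosages over pairwise-complete observations. When either
#' vector has zero variance on the complete pairs (or fewer than two pairs
#' remain) the correlation is undefined; 0 is returned, since a locus that is
#' monomorphic within the window cannot be in LD.
#'
#' @param x,y Integer dosage vectors of equal length (`NA` = missing).
#' @return Squared correlation in \[0, 1\].
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(0)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Greedy pruning of loci in linkage disequilibrium, per chromosome and in
#' position order: a locus is removed when its squared genotypic correlation
#' with any retained earlier locus lying within the preceding
#' `window_snps - 1` retained positions exceeds `r2_threshold` (the later
#' locus of an offending pair is always the one removed). The output
#' therefore satisfies an exhaustive audit: no retained pair co-occurring in
#' any placement of a `window_snps`-wide window has r^2 above the threshold.
#' The result is deterministic for a fixed input ordering and does not
#' depend on `step_snps`, which is accepted for interface compatibility with
#' the usual window/step parameterisation.
#'
#' @param gm A [genotype_matrix()].
#' @param window_snps Window width in SNPs (default 50).
#' @param step_snps Window step in SNPs (default 5); see above.
#' @param r2_threshold Pruning threshold on r^2 (default 0.2).
#' @return List with `gm` (pruned matrix) and `kept` (integer indices into
#'   the input loci that were retained).
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_threshold = 0.2) {
  stopifnot(window_snps >= 2, step_snps >= 1,
            r2_threshold > 0, r2_threshold < 1)
  kept <- integer(0)
  for (ch in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == ch)
    m <- length(idx)
    # r2 among loci of this chromosome, pairwise-complete; zero-variance -> NA
    r2 <- suppressWarnings(
      stats::cor(gm$calls[, idx, drop = FALSE],
                 use = "pairwise.complete.obs")^2)
    r2[is.na(r2)] <- 0
    ret <- integer(0)
    for (j in seq_len(m)) {
      recent <- utils::tail(ret, window_snps - 1L)
      if (length(recent) == 0 || all(r2[recent, j] <= r2_threshold))
        ret <- c(ret, j)
    }
    kept <- c(kept, idx[ret])
  }
  kept <- sort(kept)
  list(gm = subset_genotypes(gm, loci = kept), kept = kept)
}

#' Run the full post-variant filtering pipeline
#'
#' Applies, in order: autosomal restriction (if a whitelist is given),
#' per-locus then per-individual call-rate filters, monomorphic removal, and
#' windowed LD pruning. The stage ordering mirrors the usual
#' reduced-representation SNP workflow.
#'
#' @param gm A [genotype_matrix()] with populations assigned.
#' @param autosomes Optional chromosome whitelist.
#' @param snp_rate,ind_rate Call-rate thresholds (defaults 0.95 / 0.80).
#' @param window_snps,step_snps,r2_threshold LD-pruning parameters
#'   (defaults 50 / 5 / 0.2).
#' @return List with `gm` (final matrix) and `report` (data frame of counts
#'   for every stage).
#' @export
filter_pipeline <- function(gm, autosomes = NULL,
                            snp_rate = 0.95, ind_rate = 0.80,
                            window_snps = 50, step_snps = 5,
                            r2_threshold = 0.2) {
  n0 <- n_loci(gm)
  if (!is.null(autosomes)) gm <- filter_autosomal_biallelic(gm, autosomes)
  n_auto <- n_loci(gm)
  cr <- filter_call_rates(gm, snp_rate, ind_rate)
  gm <- remove_monomorphic(cr$gm)
  n_poly <- n_loci(gm)
  pr <- ld_prune(gm, window_snps, step_snps, r2_threshold)
  report <- data.frame(
    n_snps_in = n0,
    n_snps_autosomal = n_auto,
    n_snps_call_rate = cr$report$n_snps_out,
    n_samples_in = cr$report$n_samples_in,
    n_samples_out = cr$report$n_samples_out,
    n_snps_polymorphic = n_poly,
    n_snps_ld_pruned = n_loci(pr$gm))
  message(sprintf(
    "filter_pipeline: %d -> %d (autosomal) -> %d (call rate) -> %d (polymorphic) -> %d (LD-pruned) SNPs; %d -> %d samples",
    n0, n_auto, cr$report$n_snps_out, n_poly, n_loci(pr$gm),
    report$n_samples_in, report$n_samples_out))
  list(gm = pr$gm, report = report)
}
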