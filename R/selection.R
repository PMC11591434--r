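#' Fit the neutral Fst distribution
#'
#' Models uncorrected per-locus Fst as a scaled chi-square:
#' `fst * df / fst_bar ~ chi-square(df)`, the working assumption behind
#' neutral-outlier tests of the OutFLANK kind. Loci with pooled expected
#' heterozygosity below `het_min` are excluded (low-het loci have unstable
#' Fst estimates), then `trim_fraction` is trimmed from each tail of the
#' remaining Fst distribution and the two parameters are estimated by
#' maximum likelihood on the central loci, using the chi-square density
#' truncated to the trim bounds so the trimming itself does not bias the
#' fit.
#'
#' @param fst_nocorr Per-locus uncorrected Fst values (from
#'   [per_locus_fst()]).
#' @param het Per-locus pooled expected heterozygosity.
#' @param trim_fraction Fraction trimmed from each tail (default 0.05).
#' @param het_min Minimum heterozygosity to enter the fit (default 0.1).
#' @return List with `df_hat`, `fst_bar`, `n_used`, `convergence`.
#' @export
fit_neutral_fst <- function(fst_nocorr, het, trim_fraction = 0.05,
                            het_min = 0.1) {
  ok <- is.finite(fst_nocorr) & is.finite(het) & het >= het_min &
    fst_nocorr > 0
  x_all <- fst_nocorr[ok]
  if (length(x_all) < 100)
    stop("fewer than 100 loci remain after the heterozygosity filter")
  lo <- stats::quantile(x_all, trim_fraction, names = FALSE)
  hi <- stats::quantile(x_all, 1 - trim_fraction, names = FALSE)
  x <- x_all[x_all >= lo & x_all <= hi]
  if (hi - lo < .Machine$double.eps * 100 || stats::sd(x) == 0)
    stop("degenerate Fst distribution: no spread after trimming")

  # negative log-likelihood of x under scaled chi-square truncated to [lo, hi]
  nll <- function(par) {
    df <- exp(par[1]); mu <- exp(par[2])
    s <- df / mu
    z <- stats::pchisq(hi * s, df) - stats::pchisq(lo * s, df)
    if (!is.finite(z) || z <= 0) return(1e10)
    -sum(stats::dchisq(x * s, df, log = TRUE) + log(s)) + length(x) * log(z)
  }
  init <- c(log(2 * mean(x)^2 / stats::var(x)), log(mean(x)))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("neutral-Fst fit did not converge (optim code ", fit$convergence,
         "; value ", signif(fit$value, 6), ")")
  list(df_hat = exp(fit$par[1]), fst_bar = exp(fit$par[2]),
       n_used = length(x), convergence = fit$convergence)
}

#' Right-tail p-values against the fitted neutral Fst distribution
#'
#' `p = P(chi-square(df_hat) >= fst * df_hat / fst_bar)`: loci with Fst far
#' above the neutral mean get small p-values. Negative or missing Fst
#' values are bounded at p = 1.
#'
#' @param fst_nocorr Per-locus uncorrected Fst values.
#' @param df_hat,fst_bar Fitted parameters from [fit_neutral_fst()].
#' @return Numeric vector of p-values in (0, 1].
#' @export
fst_pvalues <- function(fst_nocorr, df_hat, fst_bar) {
  stopifnot(df_hat > 0, fst_bar > 0)
  p <- rep(1, length(fst_nocorr))
  ok <- is.finite(fst_nocorr) & fst_nocorr > 0
  p[ok] <- stats::pchisq(fst_nocorr[ok] * df_hat / fst_bar, df_hat,
                         lower.tail = FALSE)
  p
}

#' Intersect high-ROH-incidence loci with Fst outliers
#'
#' The selection-signature set: loci in both the top fraction of ROH
#' incidence and the top fraction of smallest neutral-Fst p-values. Both
#' index sets must refer to the same locus table.
#'
#' @param roh_top Integer locus indices (e.g. from [select_top_fraction()]
#'   on incidence).
#' @param fst_top Integer locus indices (on p-values, direction lowest).
#' @param loci Locus table (`id`, `chrom`, `pos`).
#' @param incidence_pct,fst,p_value Per-locus vectors carried onto the
#'   output records.
#' @return Data frame of signatures sorted by chromosome then position:
#'   `id`, `chrom`, `pos`, `roh_incidence_pct`, `fst`, `p_value`.
#' @export
intersect_signatures <- function(roh_top, fst_top, loci, incidence_pct,
                                 fst, p_value) {
  sel <- sort(intersect(roh_top, fst_top))
  out <- data.frame(
    id = loci$id[sel], chrom = loci$chrom[sel], pos = loci$pos[sel],
    roh_incidence_pct = incidence_pct[sel],
    fst = fst[sel], p_value = p_value[sel],
    stringsAsFactors = FALSE)
  chrom_rank <- match(out$chrom, unique(loci$chrom))
  out <- out[order(chrom_rank, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full selection scan
#'
#' Per-locus multi-population Weir-Cockerham Fst, neutral-distribution fit,
#' right-tail p-values, percentile selection on both axes and their
#' intersection.
#'
#' @param gm A [genotype_matrix()] with >= 2 populations.
#' @param incidence Data frame from [roh_incidence()] on the same loci.
#' @param fst_top_fraction Fraction of smallest p-values (default 0.01).
#' @param roh_top_fraction Fraction of highest incidences (default 0.05).
#' @param trim_fraction,het_min Passed to [fit_neutral_fst()].
#' @return List with `signatures` (data frame), `fst_table` (per-locus fst,
#'   fst_nocorr, het, p_value), `fit` (neutral-fit parameters), and the two
#'   selected index sets `roh_top`, `fst_top`.
#' @export
selection_scan <- function(gm, incidence, fst_top_fraction = 0.01,
                           roh_top_fraction = 0.05, trim_fraction = 0.05,
                           het_min = 0.1) {
  stopifnot(nrow(incidence) == n_loci(gm))
  fst_tab <- per_locus_fst(gm)
  fit <- fit_neutral_fst(fst_tab$fst_nocorr, fst_tab$het,
                         trim_fraction, het_min)
  fst_tab$p_value <- fst_pvalues(fst_tab$fst_nocorr, fit$df_hat, fit$fst_bar)
  roh_top <- select_top_fraction(incidence$incidence_pct, roh_top_fraction,
                                 direction = "highest")
  fst_top <- select_top_fraction(fst_tab$p_value, fst_top_fraction,
                                 direction = "lowest")
  sig <- intersect_signatures(roh_top, fst_top, gm$loci,
                              incidence$incidence_pct, fst_tab$fst,
                              fst_tab$p_value)
  list(signatures = sig, fst_table = fst_tab, fit = fit,
       roh_top = roh_top, fst_top = fst_top)
}

#' Annotate signatures against local feature intervals
#'
#' Features are read from a local BED or GFF/GTF file with
#' [rtracklayer::import()]. Each signature reports the names of features
#' overlapping its position extended by `window_kb`, plus the nearest
#' feature and its distance in bp (0 when inside a feature).
#'
#' @param signatures Data frame from [intersect_signatures()].
#' @param features Path to a BED/GFF file, or a `GRanges` object.
#' @param window_kb Half-window around each signature, in kb (default 0).
#' @return `signatures` with added columns `overlapping_features`,
#'   `nearest_feature`, `nearest_distance_bp`.
#' @export
annotate_signatures <- function(signatures, features, window_kb = 0) {
  if (is.character(features)) {
    if (!file.exists(features)) stop("feature file not found: ", features)
    features <- tryCatch(rtracklayer::import(features),
                         error = function(e)
                           stop("failed to parse feature file '", features,
                                "': ", conditionMessage(e)))
  }
  feat_names <- feature_names(features)
  if (nrow(signatures) == 0) {
    signatures$overlapping_features <- character(0)
    signatures$nearest_feature <- character(0)
    signatures$nearest_distance_bp <- numeric(0)
    return(signatures)
  }
  sig_gr <- GenomicRanges::GRanges(
    seqnames = signatures$chrom,
    ranges = IRanges::IRanges(start = signatures$pos, width = 1))
  win_gr <- GenomicRanges::resize(sig_gr, width = 2 * window_kb * 1000 + 1,
                                  fix = "center")
  ov <- GenomicRanges::findOverlaps(win_gr, features)
  overlaps <- vapply(seq_len(nrow(signatures)), function(i) {
    hit <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    paste(feat_names[hit], collapse = ",")
  }, character(1))
  near <- GenomicRanges::distanceToNearest(sig_gr, features)
  nearest_feature <- rep(NA_character_, nrow(signatures))
  nearest_distance <- rep(NA_real_, nrow(signatures))
  qh <- S4Vectors::queryHits(near)
  nearest_feature[qh] <- feat_names[S4Vectors::subjectHits(near)]
  nearest_distance[qh] <- S4Vectors::mcols(near)$distance
  signatures$overlapping_features <- overlaps
  signatures$nearest_feature <- nearest_feature
  signatures$nearest_distance_bp <- nearest_distance
  signatures
}

# Pick a human-readable name per feature from whatever metadata the file has.
feature_names <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("name", "Name", "gene_name", "gene_id", "ID"))
    if (col %in% names(mc)) {
      nm <- as.character(mc[[col]])
      if (!all(is.na(nm))) return(ifelse(is.na(nm), "feature", nm))
    }
  paste0("feature_", seq_along(gr))
}
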