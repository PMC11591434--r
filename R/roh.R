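#' Parameters for the window-based ROH scanner
#'
#' Defaults reproduce the usual reduced-representation livestock settings:
#' a 50-SNP sliding window allowing 1 heterozygous and 5 missing calls, a
#' SNP declared ROH-eligible when at least 5% of the windows covering it are
#' homozygous, runs split at inter-SNP gaps above 1000 kb, and segments
#' required to carry at least 50 SNPs over at least 1000 kb. The density
#' bound (maximum kb per SNP inside a segment) is disabled by default:
#' sparse panels (tens of kb between SNPs) would otherwise reject every
#' segment. The genome size (930.82 Mb, the chicken autosome total) is the
#' denominator of the inbreeding coefficient F_ROH.
#'
#' @param window_snps Window width in SNPs.
#' @param window_het Maximum heterozygous calls per homozygous window.
#' @param window_missing Maximum missing calls per homozygous window.
#' @param window_threshold Minimum fraction of covering windows that must be
#'   homozygous for a SNP to be ROH-eligible.
#' @param max_gap_kb Maximum gap between consecutive run SNPs, in kb.
#' @param min_snps_per_segment Minimum SNPs per reported segment.
#' @param min_length_kb Minimum segment length, in kb.
#' @param max_density_kb_per_snp Maximum segment kb per SNP (`Inf` disables).
#' @param genome_size_bp Autosomal genome size in bp.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50, window_het = 1, window_missing = 5,
                       window_threshold = 0.05, max_gap_kb = 1000,
                       min_snps_per_segment = 50, min_length_kb = 1000,
                       max_density_kb_per_snp = Inf,
                       genome_size_bp = 930820000) {
  stopifnot(window_snps >= 1, window_het >= 0, window_missing >= 0,
            window_threshold > 0, window_threshold <= 1,
            max_gap_kb > 0, min_snps_per_segment >= 1, min_length_kb >= 0,
            genome_size_bp > 0)
  structure(list(window_snps = window_snps, window_het = window_het,
                 window_missing = window_missing,
                 window_threshold = window_threshold,
                 max_gap_kb = max_gap_kb,
                 min_snps_per_segment = min_snps_per_segment,
                 min_length_kb = min_length_kb,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 genome_size_bp = genome_size_bp),
            class = "roh_params")
}

# Scan one individual's genotypes on one chromosome (positions sorted
# ascending). Returns a data frame of segments (possibly empty).
scan_roh_chrom <- function(g, pos, params) {
  m <- length(g)
  w <- min(params$window_snps, m)   # truncated window on short chromosomes
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  n_win <- m - w + 1L
  # window sums of het / missing indicators via cumulative sums
  ch <- cumsum(c(0L, het))
  cm <- cumsum(c(0L, mis))
  win_het <- ch[(w + 1):(m + 1)] - ch[1:n_win]
  win_mis <- cm[(w + 1):(m + 1)] - cm[1:n_win]
  homo_win <- win_het <= params$window_het & win_mis <= params$window_missing
  # windows covering SNP j start in [j - w + 1, j] intersected with [1, n_win]
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(n_win, seq_len(m))
  cover <- hi - lo + 1L
  chw <- cumsum(c(0L, homo_win))
  hits <- chw[hi + 1L] - chw[lo]
  eligible <- (hits / cover) >= params$window_threshold & !het

  if (!any(eligible)) return(NULL)
  # maximal runs of eligible SNPs, split at large gaps
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    brk <- which(gaps > params$max_gap_kb * 1000)
    piece_start <- c(i0, idx[brk + 1L])
    piece_end <- c(idx[brk], i1)
    for (pc in seq_along(piece_start)) {
      a <- piece_start[pc]; b <- piece_end[pc]
      n_snp <- b - a + 1L
      len_kb <- (pos[b] - pos[a] + 1) / 1000
      if (n_snp < params$min_snps_per_segment) next
      if (len_kb < params$min_length_kb) next
      if (len_kb / n_snp > params$max_density_kb_per_snp) next
      segs[[length(segs) + 1L]] <- c(a, b)
    }
  }
  if (length(segs) == 0) return(NULL)
  segs <- do.call(rbind, segs)
  data.frame(start_idx = segs[, 1], end_idx = segs[, 2])
}

#' Scan runs of homozygosity
#'
#' Per individual and chromosome, a window of `window_snps` consecutive SNPs
#' slides across the panel (chromosomes shorter than the window are scanned
#' with a single truncated window, so every SNP is covered by at least one
#' window). A window is homozygous if it contains at most `window_het`
#' heterozygous and at most `window_missing` missing calls. A SNP is
#' ROH-eligible when the fraction of windows covering it that are homozygous
#' reaches `window_threshold`. Maximal runs of eligible, non-heterozygous
#' SNPs become segments, split where the inter-SNP gap exceeds `max_gap_kb`;
#' segments failing the minimum SNP count, minimum length or density bound
#' are discarded. Segment coordinates are the positions of the first and
#' last SNP of the run.
#'
#' @param gm A [genotype_matrix()] with loci position-sorted per chromosome.
#' @param params A [roh_params()] list.
#' @return Data frame of segments: `sample_id`, `chrom`, `start_pos`,
#'   `end_pos` (1-based inclusive bp), `n_snps`, `length_kb`.
#' @export
scan_roh <- function(gm, params = roh_params()) {
  validate_genotype_matrix(gm)
  chroms <- unique(gm$loci$chrom)
  out <- list()
  for (ch in chroms) {
    idx <- which(gm$loci$chrom == ch)
    pos <- gm$loci$pos[idx]
    if (length(idx) < params$window_snps)
      message("scan_roh: chromosome ", ch, " has ", length(idx),
              " SNPs (< window); scanned with one truncated window")
    for (s in seq_len(n_samples(gm))) {
      segs <- scan_roh_chrom(gm$calls[s, idx], pos, params)
      if (is.null(segs)) next
      out[[length(out) + 1L]] <- data.frame(
        sample_id = gm$samples$sample_id[s],
        chrom = ch,
        start_pos = pos[segs$start_idx],
        end_pos = pos[segs$end_idx],
        n_snps = segs$end_idx - segs$start_idx + 1L,
        length_kb = (pos[segs$end_idx] - pos[segs$start_idx] + 1) / 1000,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_snps = integer(0), length_kb = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` = total ROH length (bp) / autosomal genome size. Overlapping
#' segments within the individual are an error — the scanner cannot produce
#' them, so their presence indicates a corrupted segment table.
#'
#' @param segments Segment table from [scan_roh()].
#' @param sample_id Individual to summarise.
#' @param params A [roh_params()] list (provides `genome_size_bp`).
#' @return Fraction in \[0, 1\].
#' @export
f_roh <- function(segments, sample_id, params = roh_params()) {
  seg <- segments[segments$sample_id == sample_id, , drop = FALSE]
  if (nrow(seg) == 0) return(0)
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_pos), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start_pos[-1] <= s$end_pos[-nrow(s)]))
      stop("overlapping ROH segments for sample ", sample_id,
           " on chromosome ", ch)
  }
  sum(seg$end_pos - seg$start_pos + 1) / params$genome_size_bp
}

#' Per-sample and per-population F_ROH tables
#'
#' @param segments Segment table from [scan_roh()].
#' @param gm The scanned [genotype_matrix()] (defines the full sample list,
#'   so ROH-free individuals appear with F_ROH = 0).
#' @param params A [roh_params()] list.
#' @return List with `by_sample` and `by_population` data frames.
#' @export
f_roh_summary <- function(segments, gm, params = roh_params()) {
  by_sample <- data.frame(
    sample_id = gm$samples$sample_id,
    population = gm$samples$population,
    f_roh = vapply(gm$samples$sample_id, f_roh, numeric(1),
                   segments = segments, params = params),
    stringsAsFactors = FALSE)
  rownames(by_sample) <- NULL
  pops <- unique(by_sample$population)
  seg_pop <- by_sample$population[match(segments$sample_id,
                                        by_sample$sample_id)]
  by_population <- data.frame(
    population = pops,
    mean_f_roh = vapply(pops, function(pp)
      mean(by_sample$f_roh[by_sample$population == pp]), numeric(1)),
    n_segments = vapply(pops, function(pp)
      sum(seg_pop == pp, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE)
  rownames(by_population) <- NULL
  list(by_sample = by_sample, by_population = by_population)
}

#' Per-locus ROH incidence
#'
#' For each locus, the number of individuals whose ROH segments cover its
#' position (carriers), and that count as a percentage of all individuals
#' in the dataset.
#'
#' @param segments Segment table from [scan_roh()].
#' @param gm The scanned [genotype_matrix()].
#' @return Data frame: `id`, `chrom`, `pos`, `carriers`, `incidence_pct`.
#' @export
roh_incidence <- function(segments, gm) {
  N <- n_samples(gm)
  carriers <- integer(n_loci(gm))
  if (nrow(segments) > 0) {
    for (ch in unique(gm$loci$chrom)) {
      idx <- which(gm$loci$chrom == ch)
      pos <- gm$loci$pos[idx]
      seg <- segments[segments$chrom == ch, , drop = FALSE]
      if (nrow(seg) == 0) next
      # interval stabbing by cumulative start/end counts; segments of one
      # individual never overlap, so counts sum over individuals correctly
      starts <- findInterval(pos, sort(seg$start_pos))
      ends <- findInterval(pos - 1L, sort(seg$end_pos))
      carriers[idx] <- starts - ends
    }
  }
  data.frame(id = gm$loci$id, chrom = gm$loci$chrom, pos = gm$loci$pos,
             carriers = carriers,
             incidence_pct = 100 * carriers / N,
             stringsAsFactors = FALSE)
}

#' ROH islands: top loci by ROH incidence
#'
#' Loci whose incidence reaches the `1 - top_fraction` quantile; ties at the
#' threshold are all included (so with constant incidence every locus is an
#' island — documented tie behaviour of quantile selection).
#'
#' @param incidence Data frame from [roh_incidence()].
#' @param top_fraction Fraction of loci to select (default 0.01).
#' @return The island subset of `incidence`, ordered by chrom, pos.
#' @export
roh_islands <- function(incidence, top_fraction = 0.01) {
  sel <- select_top_fraction(incidence$incidence_pct, top_fraction,
                             direction = "highest")
  incidence[sel, , drop = FALSE]
}

#' LD decay profile for one population
#'
#' All intra-chromosomal locus pairs within `max_dist_kb` are binned by
#' physical distance; the mean squared genotypic correlation
#' ([genotype_r2()]) is reported per bin.
#'
#' @param gm A [genotype_matrix()] with populations assigned.
#' @param pop Population label.
#' @param max_dist_kb Maximum pair distance in kb (default 1000).
#' @param bin_kb Bin width in kb (default 50).
#' @return Data frame: `bin_start_kb`, `bin_end_kb`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, pop, max_dist_kb = 1000, bin_kb = 50) {
  idx <- population_index(gm, pop)
  calls <- gm$calls[idx, , drop = FALSE]
  n_bins <- ceiling(max_dist_kb / bin_kb)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (ch in unique(gm$loci$chrom)) {
    li <- which(gm$loci$chrom == ch)
    if (length(li) < 2) next
    pos <- gm$loci$pos[li]
    r2 <- suppressWarnings(
      stats::cor(calls[, li, drop = FALSE], use = "pairwise.complete.obs")^2)
    r2[is.na(r2)] <- 0
    dmat <- abs(outer(pos, pos, "-")) / 1000
    ut <- upper.tri(dmat)
    keep <- ut & dmat <= max_dist_kb & dmat > 0
    if (!any(keep)) next
    b <- pmin(n_bins, ceiling(dmat[keep] / bin_kb))
    bsum <- rowsum(r2[keep], b)
    sums[as.integer(rownames(bsum))] <-
      sums[as.integer(rownames(bsum))] + bsum[, 1]
    counts <- counts + tabulate(b, nbins = n_bins)
  }
  data.frame(bin_start_kb = (seq_len(n_bins) - 1) * bin_kb,
             bin_end_kb = seq_len(n_bins) * bin_kb,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}
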