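#' Construct a genotype matrix object
#'
#' The central container of the package: an individuals x loci matrix of
#' diploid alternate-allele dosages (0, 1, 2 or `NA` for missing), together
#' with locus metadata (chromosome, 1-based position, marker id, alleles) and
#' sample metadata (sample id, population label).
#'
#' @param calls Integer matrix, samples in rows and loci in columns. Entries
#'   must be 0, 1, 2 or `NA`.
#' @param loci Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`;
#'   one row per locus, ordered as the columns of `calls`. Within each
#'   chromosome positions must be strictly increasing.
#' @param samples Data frame with columns `sample_id` and `population`
#'   (`population` may be `NA` before a population map is attached); one row
#'   per row of `calls`. Sample ids must be unique.
#'
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `loci`, `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   calls = rbind(c(0L, 1L), c(2L, NA)),
#'   loci = data.frame(chrom = "1", pos = c(100L, 200L),
#'                     id = c("m1", "m2"), ref = "A", alt = "G"),
#'   samples = data.frame(sample_id = c("s1", "s2"), population = "P1")
#' )
#' n_loci(gm)
#' @export
genotype_matrix <- function(calls, loci, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  gm <- structure(list(calls = calls, loci = loci, samples = samples),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  rownames(gm$calls) <- gm$samples$sample_id
  colnames(gm$calls) <- gm$loci$id
  gm
}

#' Validate a genotype matrix
#'
#' Checks dimension consistency, the dosage domain, uniqueness of sample ids
#' and the per-chromosome position sorting invariant. Called by every
#' constructor and reader; exported so that external code handing the package
#' a hand-built object can check it too.
#'
#' @param gm A `genotype_matrix`.
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  loci <- gm$loci
  samples <- gm$samples
  required <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(required %in% names(loci)))
    stop("loci table must have columns: ", paste(required, collapse = ", "))
  if (nrow(samples) != nrow(calls) || nrow(loci) != ncol(calls))
    stop("calls dimensions do not match samples/loci tables")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0)
    stop("non-missing calls must be 0, 1 or 2; found ", bad[1])
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  if (nrow(loci) > 0) {
    if (any(loci$pos < 1)) stop("locus positions must be >= 1")
    if (any(!is.na(loci$ref) & !is.na(loci$alt) & loci$ref == loci$alt))
      stop("ref and alt alleles must differ")
    for (ch in unique(loci$chrom)) {
      p <- loci$pos[loci$chrom == ch]
      if (any(diff(p) <= 0))
        stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  npop <- length(unique(stats::na.omit(x$samples$population)))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d chromosomes, %d populations)\n",
              nrow(x$calls), ncol(x$calls),
              length(unique(x$loci$chrom)), npop))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci / samples
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_loci <- function(gm) ncol(gm$calls)

#' @rdname n_loci
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param samples Optional logical/integer/character index over samples.
#' @param loci Optional logical/integer/character index over loci.
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(loci)) loci <- seq_len(ncol(gm$calls))
  if (is.character(samples)) samples <- match(samples, gm$samples$sample_id)
  if (is.character(loci)) loci <- match(loci, gm$loci$id)
  out <- structure(list(
    calls = gm$calls[samples, loci, drop = FALSE],
    loci = gm$loci[loci, , drop = FALSE],
    samples = gm$samples[samples, , drop = FALSE]
  ), class = "genotype_matrix")
  rownames(out$loci) <- NULL
  rownames(out$samples) <- NULL
  validate_genotype_matrix(out)
}

#' Rows (sample indices) belonging to one population
#' @param gm A `genotype_matrix`.
#' @param pop Population label.
#' @return Integer vector of sample indices; errors if the label is unknown.
#' @export
population_index <- function(gm, pop) {
  idx <- which(gm$samples$population == pop)
  if (length(idx) == 0) stop("unknown population: ", pop)
  idx
}

#' Population labels present in a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of distinct labels, in order of first appearance.
#' @export
populations <- function(gm) {
  unique(stats::na.omit(gm$samples$population))
}
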