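# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that seeded stages never disturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a bounded sub-seed from a global seed and a stage name, so that each
# pipeline stage draws from its own named substream. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Select the top fraction of loci by score, ties included
#'
#' Quantile-threshold selection: the threshold is the `1 - fraction` (or
#' `fraction`, for `direction = "lowest"`) quantile of the scores and every
#' locus at or beyond the threshold is returned, so ties at the threshold are
#' all included. With all-distinct scores and `fraction * length(values)` an
#' integer, exactly that many loci are returned.
#'
#' @param values Numeric scores (`NA` allowed; never selected).
#' @param fraction Fraction to select, in (0, 1).
#' @param direction `"highest"` (default) or `"lowest"`.
#' @return Integer indices of the selected loci.
#' @export
select_top_fraction <- function(values, fraction, direction = c("highest", "lowest")) {
  stopifnot(fraction > 0, fraction < 1)
  direction <- match.arg(direction)
  ok <- !is.na(values)
  if (direction == "highest") {
    thr <- stats::quantile(values[ok], 1 - fraction, names = FALSE)
    which(ok & values >= thr)
  } else {
    thr <- stats::quantile(values[ok], fraction, names = FALSE)
    which(ok & values <= thr)
  }
}
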