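#' Per-population alternate-allele frequencies
#'
#' @param gm A [genotype_matrix()] with populations assigned.
#' @return List with `freq` (populations x loci matrix of alt-allele
#'   frequencies, `NaN` where a population has no callable copies) and `n`
#'   (matrix of callable allele-copy counts).
#' @export
population_allele_frequencies <- function(gm) {
  pops <- populations(gm)
  if (length(pops) == 0) stop("no populations assigned")
  st <- pop_locus_stats(gm, pops)
  list(freq = st$p, n = 2 * st$n)
}

#' Euclidean distance matrix between population frequency vectors
#'
#' `d(a, b) = sqrt(sum_l (p_a - p_b)^2)` over the loci where both
#' populations have callable data.
#'
#' @param freq Populations x loci frequency matrix, as returned in
#'   `population_allele_frequencies()$freq`.
#' @return Symmetric matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(freq) {
  k <- nrow(freq)
  if (is.null(k) || k < 2) stop("need >= 2 populations")
  d <- matrix(0, k, k, dimnames = list(rownames(freq), rownames(freq)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    ok <- is.finite(freq[i, ]) & is.finite(freq[j, ])
    if (!any(ok)) stop("no shared callable loci between ",
                       rownames(freq)[i], " and ", rownames(freq)[j])
    d[i, j] <- d[j, i] <- sqrt(sum((freq[i, ok] - freq[j, ok])^2))
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. Negative branch lengths (a
#' finite-sample artifact) are set to zero with the deficit transferred to
#' the adjacent branch, the standard practice for presentation trees.
#'
#' @param d Symmetric distance matrix with labels (>= 3 taxa).
#' @return An [ape::phylo] tree; write with [ape::write.tree()] for Newick.
#' @export
neighbor_joining_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 labels")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    # push the deficit onto the sibling/parent edges sharing the child node,
    # preserving path lengths through that node where possible
    node <- tr$edge[e, 1]
    adj <- which(tr$edge[, 1] == node & seq_along(tr$edge.length) != e)
    if (length(adj) > 0)
      tr$edge.length[adj] <- pmax(0, tr$edge.length[adj] + deficit)
  }
  tr
}

#' Principal coordinate analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered `-d^2 / 2` matrix via
#' [stats::cmdscale()]. Axes are ordered by descending eigenvalue; axes with
#' non-positive eigenvalues are excluded from the coordinates but all
#' eigenvalues are reported. When `d` is Euclidean-embeddable the full-rank
#' coordinates reproduce the input distances.
#'
#' @param d Symmetric distance matrix with labels.
#' @param k Number of axes to return (default: all positive-eigenvalue axes).
#' @return List with `coords` (labels x axes matrix) and `eigenvalues`
#'   (all n - 1 values, non-increasing).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(k)) k <- n - 1
  stopifnot(k < n)
  # cmdscale warns whenever k exceeds the positive-eigenvalue rank, which is
  # routine here since we request all axes and drop the non-positive ones
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- sc$eig
  pos <- sum(eig > 1e-12)
  coords <- sc$points
  if (ncol(coords) > pos) coords <- coords[, seq_len(pos), drop = FALSE]
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coords = coords, eigenvalues = eig[order(-eig)][seq_len(n - 1)])
}

# Allele-level sums of squares for AMOVA, per locus, summed over loci.
# pop_of: integer population assignment per individual (1..P).
# Returns the three sums of squares and the stratum degrees of freedom
# computed on the individuals that carry data.
amova_ss <- function(calls, pop_of, P) {
  N <- nrow(calls)
  called <- !is.na(calls)
  x <- ifelse(called, calls, 0)            # alt copies per individual (0..2)
  cop <- 2 * called                        # allele copies contributed

  tot_alt <- colSums(x)
  tot_cop <- colSums(cop)
  ok <- tot_cop > 0
  p_tot <- tot_alt[ok] / tot_cop[ok]

  # SS within individuals: a heterozygote's two copies differ from its own
  # mean 0.5 by 0.25 each
  ss_wi <- sum(x[, ok] == 1, na.rm = TRUE) / 2

  pop_alt <- rowsum(x, pop_of, reorder = TRUE)
  pop_cop <- rowsum(cop, pop_of, reorder = TRUE)
  p_pop <- pop_alt[, ok, drop = FALSE] / pop_cop[, ok, drop = FALSE]

  # SS among populations: sum_p n_p (p_p - p_tot)^2 per locus
  dev <- sweep(p_pop, 2, p_tot)
  dev[!is.finite(dev)] <- 0
  ss_ap <- sum(pop_cop[, ok, drop = FALSE] * dev^2)

  # SS total: sum over copies (x - p_tot)^2 = n_tot p_tot (1 - p_tot)
  ss_tot <- sum(tot_cop[ok] * p_tot * (1 - p_tot))
  ss_ai <- ss_tot - ss_ap - ss_wi

  list(ss_ap = ss_ap, ss_ai = ss_ai, ss_wi = ss_wi, ss_tot = ss_tot)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Three-level decomposition of allele-level variance: among populations,
#' among individuals within populations, and within individuals, computed
#' from squared allele-copy differences summed over loci (Excoffier-style
#' variance components). Significance of the among-population component is
#' assessed by permuting individuals across populations; the permutation
#' p-value uses the `(exceedances + 1) / (n_perm + 1)` correction.
#'
#' @param gm A [genotype_matrix()] with >= 2 populations, each with >= 2
#'   individuals.
#' @param n_perm Number of permutations (default 1000; 0 disables testing).
#' @param seed Optional integer seed.
#' @return List with `table` (data frame: stratum, df, SS, variance
#'   component, percentage, phi, p-value) and `phi` (named vector of
#'   Phi_ST, Phi_IS, Phi_IT).
#' @export
amova <- function(gm, n_perm = 1000, seed = NULL) {
  pops <- populations(gm)
  P <- length(pops)
  if (P < 2) stop("AMOVA needs >= 2 populations")
  sizes <- table(factor(gm$samples$population, levels = pops))
  if (any(sizes < 2)) stop("AMOVA needs >= 2 individuals per population")
  pop_of <- match(gm$samples$population, pops)
  calls <- gm$calls
  N <- nrow(calls)

  ss <- amova_ss(calls, pop_of, P)
  df_ap <- P - 1
  df_ai <- N - P
  df_wi <- N
  ms_ap <- ss$ss_ap / df_ap
  ms_ai <- ss$ss_ai / df_ai
  ms_wi <- ss$ss_wi / df_wi
  n_c <- (N - sum(sizes^2) / N) / (P - 1)   # average pop size correction

  sigma_wi <- ms_wi
  sigma_ai <- (ms_ai - ms_wi) / 2
  sigma_ap <- (ms_ap - ms_ai) / (2 * n_c)
  total <- sigma_ap + sigma_ai + sigma_wi
  pct <- 100 * c(sigma_ap, sigma_ai, sigma_wi) / total
  phi_st <- sigma_ap / total
  phi_is <- sigma_ai / (sigma_ai + sigma_wi)
  phi_it <- (sigma_ap + sigma_ai) / total

  p_ap <- NA_real_
  if (n_perm > 0) {
    # total SS and within-individual SS are invariant under permuting
    # individuals across populations, so only the among-population SS needs
    # recomputing per permutation
    called <- !is.na(calls)
    x <- ifelse(called, calls, 0)
    cop <- 2 * called
    tot_cop <- colSums(cop)
    okl <- tot_cop > 0
    p_tot <- colSums(x)[okl] / tot_cop[okl]
    x <- x[, okl, drop = FALSE]
    cop <- cop[, okl, drop = FALSE]
    perm_ss_ap <- function(assign) {
      pop_alt <- rowsum(x, assign, reorder = TRUE)
      pop_cop <- rowsum(cop, assign, reorder = TRUE)
      dev <- pop_alt / pop_cop - rep(p_tot, each = P)
      dev[!is.finite(dev)] <- 0
      sum(pop_cop * dev^2)
    }
    exceed_ap <- with_seed(seed, {
      ex <- 0L
      for (b in seq_len(n_perm)) {
        ssb_ap <- perm_ss_ap(sample(pop_of))
        ssb_ai <- ss$ss_tot - ssb_ap - ss$ss_wi
        sb_ap <- (ssb_ap / df_ap - ssb_ai / df_ai) / (2 * n_c)
        if (sb_ap >= sigma_ap - 1e-12) ex <- ex + 1L
      }
      ex
    })
    p_ap <- (exceed_ap + 1) / (n_perm + 1)
  }

  tab <- data.frame(
    stratum = c("among_populations", "among_individuals_within_populations",
                "within_individuals", "total"),
    df = c(df_ap, df_ai, df_wi, df_ap + df_ai + df_wi),
    SS = c(ss$ss_ap, ss$ss_ai, ss$ss_wi, ss$ss_tot),
    variance = c(sigma_ap, sigma_ai, sigma_wi, total),
    percent = c(pct, 100),
    phi = c(phi_st, phi_is, phi_it, NA),
    p_value = c(p_ap, NA, NA, NA),
    stringsAsFactors = FALSE)
  list(table = tab,
       phi = c(phi_ST = phi_st, phi_IS = phi_is, phi_IT = phi_it))
}
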