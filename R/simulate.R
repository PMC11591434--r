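# Default chromosome lengths: 28 autosomes with the approximate relative
# sizes of the chicken karyotype, rescaled so the total is exactly 930.82 Mb.
default_chrom_lengths <- function() {
  mb <- c(197, 149, 111, 91, 60, 36, 36, 30, 24, 21, 20, 20, 19, 16, 13, 3,
          11, 11, 10, 14, 7, 5, 6, 6, 3, 5, 8, 5)
  bp <- round(mb * 1e6 * 930.82e6 / sum(mb * 1e6))
  stats::setNames(bp, as.character(seq_along(bp)))
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate an 11-population livestock SNP panel: Table-of-breeds
#' sample sizes summing to 119 diploid individuals, ~12,000 bi-allelic
#' autosomal SNPs over 28 autosomes totalling 930.82 Mb, Balding-Nichols
#' divergence spanning weakly to strongly differentiated populations
#' (inbred lines most diverged), per-population genomic inbreeding from
#' near zero to inbred-line levels (implanted as long homozygous tracts),
#' 3% missing genotypes, and a small set of planted loci that are
#' simultaneously high-Fst and inside population-shared ROH islands.
#'
#' @param n_pops Number of populations.
#' @param n_ind_per_pop Integer vector (recycled) of diploids per population.
#' @param pop_names Population labels.
#' @param n_loci Number of SNP loci.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param target_fst Per-population Balding-Nichols divergence parameter F
#'   (recycled); F = 0 means the population sits at the ancestral frequency.
#' @param f_roh_target Per-population fraction of the genome implanted as
#'   runs of homozygosity (recycled).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param n_outlier_loci Number of planted divergence-outlier loci.
#' @param outlier_multiplier Multiplier on F at outlier loci (capped at
#'   0.95).
#' @param island_span_loci Number of consecutive loci in each planted ROH
#'   island (one island is centred on each outlier locus).
#' @param island_carrier_fraction Fraction of all individuals whose island
#'   loci are forced homozygous.
#' @param ld_rho Within-chromosome AR(1) haplotype correlation used to
#'   induce linkage disequilibrium (0 = independent loci).
#' @param roh_interval_mb Length-2 vector: min and max implanted tract
#'   length in Mb.
#' @param missing_rate,seed Self-explanatory; every random draw flows from
#'   `seed` via named substreams.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    n_pops = 11,
    n_ind_per_pop = c(8, 13, 12, 10, 11, 10, 6, 12, 11, 16, 10),
    pop_names = c("IG", "NAG", "OSM", "RYU", "TJI", "TKU", "UK",
                  "WPR", "PNP", "WLG", "WLT"),
    n_loci = 12000,
    chrom_lengths = default_chrom_lengths(),
    target_fst = c(0.35, 0.30, 0.15, 0.30, 0.25, 0.25, 0.20,
                   0.15, 0.60, 0.45, 0.20),
    f_roh_target = c(0.12, 0.12, 0.02, 0.12, 0.12, 0.10, 0.12,
                     0.05, 0.35, 0.30, 0.05),
    missing_rate = 0.03,
    n_outlier_loci = 10,
    outlier_multiplier = 5,
    island_span_loci = 60,
    island_carrier_fraction = 0.5,
    ld_rho = 0,
    roh_interval_mb = c(5, 25),
    seed = 1L) {
  n_ind_per_pop <- rep_len(n_ind_per_pop, n_pops)
  target_fst <- rep_len(target_fst, n_pops)
  f_roh_target <- rep_len(f_roh_target, n_pops)
  pop_names <- rep_len(pop_names, n_pops)[seq_len(n_pops)]
  stopifnot(all(target_fst >= 0), all(target_fst < 1),
            all(f_roh_target >= 0), all(f_roh_target < 1),
            missing_rate >= 0, missing_rate < 1,
            ld_rho >= 0, ld_rho < 1, !is.null(seed))
  structure(list(
    n_pops = n_pops, n_ind_per_pop = n_ind_per_pop, pop_names = pop_names,
    n_loci = n_loci, chrom_lengths = chrom_lengths,
    target_fst = target_fst, f_roh_target = f_roh_target,
    missing_rate = missing_rate, n_outlier_loci = n_outlier_loci,
    outlier_multiplier = outlier_multiplier,
    island_span_loci = island_span_loci,
    island_carrier_fraction = island_carrier_fraction,
    ld_rho = ld_rho, roh_interval_mb = roh_interval_mb,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate ancestral and per-population allele frequencies
#'
#' Loci are spread over the chromosomes proportionally to length with
#' strictly increasing positions. Ancestral frequencies are
#' Uniform(0.05, 0.95); each population's frequency is a Balding-Nichols
#' draw `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral
#' value, so F is the expected Fst of that population against the ancestor.
#' Planted outlier loci use `F * outlier_multiplier` (capped at 0.95) and
#' are placed so that an island of `island_span_loci` consecutive loci
#' around each outlier fits inside one chromosome without overlapping
#' another island.
#'
#' @param config A [sim_config()].
#' @return List with `loci` (locus table), `ancestral`, `freq`
#'   (populations x loci), `outlier_loci` (indices), `islands` (data frame
#'   of island locus ranges).
#' @export
simulate_frequencies <- function(config) {
  with_seed(derive_seed(config$seed, "frequencies"), {
    cl <- config$chrom_lengths
    n_per <- stats::setNames(
      as.integer(round(config$n_loci * cl / sum(cl))), names(cl))
    n_per[1] <- n_per[1] + config$n_loci - sum(n_per)
    chrom <- rep(names(cl), n_per)
    pos <- unlist(lapply(names(cl), function(ch)
      sort(sample.int(cl[[ch]], n_per[[ch]]))), use.names = FALSE)
    loci <- data.frame(
      chrom = chrom, pos = pos,
      id = sprintf("marker%06d", seq_len(config$n_loci)),
      ref = "A", alt = "G", stringsAsFactors = FALSE)

    ancestral <- stats::runif(config$n_loci, 0.05, 0.95)

    outlier <- integer(0)
    islands <- data.frame(island = integer(0), start_locus = integer(0),
                          end_locus = integer(0), chrom = character(0),
                          carrier_fraction = numeric(0))
    if (config$n_outlier_loci > 0) {
      half <- floor(config$island_span_loci / 2)
      cand <- which(unlist(lapply(split(seq_along(chrom), chrom)[unique(chrom)],
        function(ix) seq_along(ix) > half & seq_along(ix) <= length(ix) - half),
        use.names = FALSE))
      taken <- rep(FALSE, config$n_loci)
      for (k in seq_len(config$n_outlier_loci)) {
        free <- cand[!taken[cand]]
        if (length(free) == 0) stop("no room left to place outlier islands")
        ctr <- sample(free, 1)
        s <- ctr - half; e <- min(config$n_loci, ctr + half)
        outlier <- c(outlier, ctr)
        islands <- rbind(islands, data.frame(
          island = k, start_locus = s, end_locus = e, chrom = chrom[ctr],
          carrier_fraction = config$island_carrier_fraction))
        taken[max(1, s - config$island_span_loci):
                min(config$n_loci, e + config$island_span_loci)] <- TRUE
      }
      outlier <- sort(outlier)
      islands <- islands[order(islands$start_locus), ]
      islands$island <- seq_len(nrow(islands))
    }

    freq <- matrix(NA_real_, config$n_pops, config$n_loci,
                   dimnames = list(config$pop_names, loci$id))
    for (i in seq_len(config$n_pops)) {
      F <- rep(config$target_fst[i], config$n_loci)
      F[outlier] <- pmin(0.95, F[outlier] * config$outlier_multiplier)
      p <- ancestral
      drift <- F > 0
      freq[i, !drift] <- p[!drift]
      freq[i, drift] <- stats::rbeta(sum(drift),
                                     p[drift] * (1 - F[drift]) / F[drift],
                                     (1 - p[drift]) * (1 - F[drift]) / F[drift])
    }
    list(loci = loci, ancestral = ancestral, freq = freq,
         outlier_loci = outlier, islands = islands)
  })
}

#' Simulate diploid genotypes from population frequencies
#'
#' Hardy-Weinberg draws per individual; with `ld_rho > 0`, each haplotype is
#' generated from a Gaussian copula with AR(1) correlation `ld_rho` along
#' each chromosome, inducing linkage disequilibrium that decays with locus
#' distance while preserving the per-locus frequencies. Calls are masked as
#' missing at `missing_rate`.
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param config The same [sim_config()].
#' @return A [genotype_matrix()] with populations assigned.
#' @export
simulate_genotypes <- function(freqs, config) {
  with_seed(derive_seed(config$seed, "genotypes"), {
    N <- sum(config$n_ind_per_pop)
    L <- config$n_loci
    pop_of <- rep(seq_len(config$n_pops), config$n_ind_per_pop)
    calls <- matrix(0L, N, L)
    if (config$ld_rho == 0) {
      for (i in seq_len(N)) {
        p <- freqs$freq[pop_of[i], ]
        calls[i, ] <- stats::rbinom(L, 2L, p)
      }
    } else {
      rho <- config$ld_rho
      chrom <- freqs$loci$chrom
      for (i in seq_len(N)) {
        p <- freqs$freq[pop_of[i], ]
        hap <- matrix(0L, 2, L)
        for (h in 1:2) {
          z <- numeric(L)
          for (ch in unique(chrom)) {
            ix <- which(chrom == ch)
            e <- stats::rnorm(length(ix))
            zz <- numeric(length(ix))
            zz[1] <- e[1]
            for (l in seq_along(ix)[-1])
              zz[l] <- rho * zz[l - 1] + sqrt(1 - rho^2) * e[l]
            z[ix] <- zz
          }
          hap[h, ] <- as.integer(z < stats::qnorm(p))
        }
        calls[i, ] <- hap[1, ] + hap[2, ]
      }
    }
    if (config$missing_rate > 0) {
      mask <- matrix(stats::runif(N * L) < config$missing_rate, N, L)
      calls[mask] <- NA_integer_
    }
    samples <- data.frame(
      sample_id = sprintf("%s_%02d", config$pop_names[pop_of],
                          unlist(lapply(config$n_ind_per_pop, seq_len))),
      population = config$pop_names[pop_of], stringsAsFactors = FALSE)
    genotype_matrix(calls, freqs$loci, samples)
  })
}

#' Implant runs of homozygosity and shared ROH islands
#'
#' For each individual, disjoint genomic intervals totalling its
#' population's `f_roh_target` fraction of the genome are chosen (tract
#' lengths uniform in `roh_interval_mb`); every genotype inside is forced
#' homozygous, heterozygotes resolved by a fair coin. Planted islands are
#' forced homozygous in a `island_carrier_fraction` random subset of all
#' individuals. The returned truth records the exact implanted intervals
#' for boundary-recovery tests.
#'
#' @param gm A [genotype_matrix()] from [simulate_genotypes()].
#' @param freqs Output of [simulate_frequencies()] (for island definitions).
#' @param config The same [sim_config()].
#' @return List with `gm` (modified matrix) and `truth`: per-individual
#'   implanted intervals (`sample_id`, `chrom`, `start_bp`, `end_bp`),
#'   island carrier ids per island, outlier locus ids, and the config echo.
#' @export
implant_roh <- function(gm, freqs, config) {
  with_seed(derive_seed(config$seed, "implant"), {
    cl <- config$chrom_lengths
    genome <- sum(cl)
    pop_of <- match(gm$samples$population, config$pop_names)
    calls <- gm$calls
    loci <- gm$loci
    tracts <- list()
    force_homo <- function(row, lmask) {
      g <- calls[row, ]
      het <- !is.na(g) & g == 1L & lmask
      g[het] <- 2L * stats::rbinom(sum(het), 1L, 0.5)
      calls[row, ] <<- g
    }
    for (i in seq_len(nrow(calls))) {
      target <- config$f_roh_target[pop_of[i]] * genome
      if (target <= 0) next
      placed <- lapply(names(cl), function(ch) cbind(numeric(0), numeric(0)))
      names(placed) <- names(cl)
      total <- 0
      tries <- 0
      while (total < target && tries < 2000) {
        tries <- tries + 1
        len <- stats::runif(1, config$roh_interval_mb[1],
                            config$roh_interval_mb[2]) * 1e6
        # clip the last tract so the implanted total matches the target
        len <- min(len, target - total)
        ch <- sample(names(cl), 1, prob = cl)
        if (len >= cl[[ch]]) next
        start <- floor(stats::runif(1, 1, cl[[ch]] - len))
        end <- start + len
        prev <- placed[[ch]]
        if (nrow(prev) > 0 && any(start <= prev[, 2] & end >= prev[, 1]))
          next
        placed[[ch]] <- rbind(prev, c(start, end))
        total <- total + len
        lmask <- loci$chrom == ch & loci$pos >= start & loci$pos <= end
        force_homo(i, lmask)
        tracts[[length(tracts) + 1L]] <- data.frame(
          sample_id = gm$samples$sample_id[i], chrom = ch,
          start_bp = start, end_bp = end, stringsAsFactors = FALSE)
      }
    }
    carriers <- list()
    if (nrow(freqs$islands) > 0) {
      N <- nrow(calls)
      for (k in seq_len(nrow(freqs$islands))) {
        isl <- freqs$islands[k, ]
        who <- sort(sample.int(N, round(isl$carrier_fraction * N)))
        lmask <- seq_len(ncol(calls)) >= isl$start_locus &
          seq_len(ncol(calls)) <= isl$end_locus
        for (row in who) force_homo(row, lmask)
        carriers[[k]] <- gm$samples$sample_id[who]
      }
    }
    gm$calls <- calls
    truth <- list(
      tracts = if (length(tracts)) do.call(rbind, tracts) else
        data.frame(sample_id = character(0), chrom = character(0),
                   start_bp = numeric(0), end_bp = numeric(0)),
      islands = freqs$islands,
      island_carriers = carriers,
      outlier_loci = freqs$outlier_loci,
      outlier_ids = freqs$loci$id[freqs$outlier_loci],
      config = unclass(config))
    list(gm = gm, truth = truth)
  })
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()] and
#' [implant_roh()], then writes `<prefix>.vcf`, `<prefix>.popmap.tsv` and
#' `<prefix>.truth.json`. Identical configs (including seed) produce
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix.
#' @return Invisibly, a list with the `gm`, `truth` and the three file
#'   paths.
#' @export
generate_dataset <- function(config, out_prefix) {
  freqs <- simulate_frequencies(config)
  gm <- simulate_genotypes(freqs, config)
  imp <- implant_roh(gm, freqs, config)
  paths <- list(vcf = paste0(out_prefix, ".vcf"),
                popmap = paste0(out_prefix, ".popmap.tsv"),
                truth = paste0(out_prefix, ".truth.json"))
  write_vcf(imp$gm, paths$vcf)
  write_popmap(stats::setNames(imp$gm$samples$population,
                               imp$gm$samples$sample_id), paths$popmap)
  truth <- imp$truth
  truth$realized_freq <- round(freqs$freq, 4)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(gm = imp$gm, truth = imp$truth, paths = paths))
}
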