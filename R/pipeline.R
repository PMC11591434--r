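# Default pipeline configuration. Unknown keys in a user config are
# rejected so typos cannot silently disable a stage.
pipeline_defaults <- function() {
  list(
    out_dir = "rohsignal_out",
    seed = 1L,
    input = list(vcf = NULL, popmap = NULL),
    simulate = list(),                    # sim_config() arguments
    filter = list(autosomes = NULL, snp_rate = 0.95, ind_rate = 0.80,
                  window_snps = 50, step_snps = 5, r2_threshold = 0.2),
    diversity = list(ntotal = NULL),
    structure = list(n_boot = 1000, n_perm = 1000),
    roh = list(),                         # roh_params() arguments
    lddecay = list(max_dist_kb = 1000, bin_kb = 50, populations = NULL),
    selscan = list(fst_top_fraction = 0.01, roh_top_fraction = 0.05,
                   trim_fraction = 0.05, het_min = 0.1,
                   features = NULL, window_kb = 0))
}

merge_config <- function(user, defaults, path = "config") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop("unknown ", path, " key(s): ", paste(bad, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k %in% c("input", "filter", "diversity", "structure", "lddecay",
                 "selscan")) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in order: input (read a VCF + population map, or generate a
#' synthetic dataset when no input is configured), post-variant filtering,
#' per-population diversity, population structure (AMOVA, distance
#' matrices, neighbor-joining trees, PCoA), ROH scanning with F_ROH /
#' incidence / islands, LD decay, and the selection-signature scan. Every
#' stage writes its tables (TSV with header; trees as Newick) into
#' `out_dir`, and an effective-config provenance file is written alongside.
#' All randomness flows from the single `seed` via named per-stage
#' substreams, so a rerun with the same config is identical.
#'
#' @param config A named list (see `pipeline_defaults` in the source for
#'   the full key set) or the path to a YAML file holding one. Unknown keys
#'   are rejected.
#' @return Invisibly, a list with the filtered `gm`, per-stage results and
#'   the output directory.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, pipeline_defaults())
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (!is.null(cfg$input$vcf)) {
      if (is.null(cfg$input$popmap))
        stop("input$popmap is required when input$vcf is given")
      if (!file.exists(cfg$input$popmap))
        stop("popmap file not found: ", cfg$input$popmap)
      gm <- read_vcf(cfg$input$vcf, autosomes = cfg$filter$autosomes)
      gm <- assign_populations(gm, read_popmap(cfg$input$popmap))
    } else {
      sim_args <- cfg$simulate
      sim_args$seed <- derive_seed(cfg$seed, "simulate")
      sc <- do.call(sim_config, sim_args)
      gen <- generate_dataset(sc, file.path(out, "synthetic"))
      gm <- gen$gm
      truth <- gen$truth
    }

    stage <- "filter"
    fl <- filter_pipeline(gm, autosomes = cfg$filter$autosomes,
                          snp_rate = cfg$filter$snp_rate,
                          ind_rate = cfg$filter$ind_rate,
                          window_snps = cfg$filter$window_snps,
                          step_snps = cfg$filter$step_snps,
                          r2_threshold = cfg$filter$r2_threshold)
    gm <- fl$gm
    write_tsv(fl$report, file.path(out, "filter_report.tsv"))
    write_vcf(gm, file.path(out, "filtered.vcf"))

    stage <- "diversity"
    div <- diversity_summary(gm, ntotal = cfg$diversity$ntotal)
    write_tsv(div, file.path(out, "diversity.tsv"))

    stage <- "structure"
    paf <- population_allele_frequencies(gm)
    eu <- euclidean_distance_matrix(paf$freq)
    fstm <- fst_matrix(gm, n_boot = cfg$structure$n_boot,
                       seed = derive_seed(cfg$seed, "fst_boot"))
    write_tsv(as.data.frame(cbind(population = rownames(eu), round(eu, 6))),
              file.path(out, "euclidean_dist.tsv"))
    write_tsv(as.data.frame(cbind(population = rownames(fstm$fst),
                                  round(fstm$fst, 6))),
              file.path(out, "fst_dist.tsv"))
    write_tsv(fstm$pairs, file.path(out, "fst_pairs.tsv"))
    ape::write.tree(neighbor_joining_tree(eu),
                    file.path(out, "nj_euclidean.nwk"))
    ape::write.tree(neighbor_joining_tree(fstm$fst),
                    file.path(out, "nj_fst.nwk"))
    pc <- pcoa(eu)
    write_tsv(data.frame(population = rownames(pc$coords),
                         round(pc$coords, 6)),
              file.path(out, "pcoa_coords.tsv"))
    write_tsv(data.frame(axis = seq_along(pc$eigenvalues),
                         eigenvalue = pc$eigenvalues),
              file.path(out, "pcoa_eigenvalues.tsv"))
    am <- amova(gm, n_perm = cfg$structure$n_perm,
                seed = derive_seed(cfg$seed, "amova"))
    write_tsv(am$table, file.path(out, "amova.tsv"))

    stage <- "roh"
    rp <- do.call(roh_params, cfg$roh)
    segments <- scan_roh(gm, rp)
    write_tsv(segments, file.path(out, "roh_segments.tsv"))
    bed <- data.frame(chrom = segments$chrom,
                      start = segments$start_pos - 1L,
                      end = segments$end_pos,
                      name = segments$sample_id)
    utils::write.table(bed, file.path(out, "roh_segments.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    fr <- f_roh_summary(segments, gm, rp)
    write_tsv(fr$by_sample, file.path(out, "froh_by_sample.tsv"))
    write_tsv(fr$by_population, file.path(out, "froh_by_population.tsv"))
    inc <- roh_incidence(segments, gm)
    write_tsv(inc, file.path(out, "roh_incidence.tsv"))
    write_tsv(roh_islands(inc), file.path(out, "roh_islands.tsv"))

    stage <- "lddecay"
    ld_pops <- cfg$lddecay$populations
    if (is.null(ld_pops)) ld_pops <- populations(gm)
    ld_tab <- do.call(rbind, lapply(ld_pops, function(pp) {
      d <- ld_decay(gm, pp, max_dist_kb = cfg$lddecay$max_dist_kb,
                    bin_kb = cfg$lddecay$bin_kb)
      cbind(population = pp, d)
    }))
    write_tsv(ld_tab, file.path(out, "ld_decay.tsv"))

    stage <- "selscan"
    sel <- selection_scan(gm, inc,
                          fst_top_fraction = cfg$selscan$fst_top_fraction,
                          roh_top_fraction = cfg$selscan$roh_top_fraction,
                          trim_fraction = cfg$selscan$trim_fraction,
                          het_min = cfg$selscan$het_min)
    sig <- sel$signatures
    if (!is.null(cfg$selscan$features))
      sig <- annotate_signatures(sig, cfg$selscan$features,
                                 window_kb = cfg$selscan$window_kb)
    write_tsv(sel$fst_table, file.path(out, "selection_fst.tsv"))
    write_tsv(sig, file.path(out, "selection_signatures.tsv"))

    provenance <- list(
      package = "rohsignal",
      version = as.character(utils::packageVersion("rohsignal")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC"),
      config = cfg)
    jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)

    list(gm = gm, truth = truth, filter = fl$report, diversity = div,
         euclidean = eu, fst = fstm, pcoa = pc, amova = am,
         segments = segments, froh = fr, incidence = inc,
         selection = sel, signatures = sig, out_dir = out)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message("run_pipeline: all stages complete; outputs in ", out)
  invisible(res)
}
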