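#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip compressed) with [vcfR] and
#' converts genotypes to alternate-allele dosages. Phasing is discarded;
#' half-missing calls (one known allele) are treated as missing. Records that
#' are not single-base bi-allelic SNPs (multi-allelic ALT, indel alleles) are
#' dropped, as are records duplicating an already-seen (chromosome, position)
#' pair; counts of dropped records are reported on standard error.
#'
#' @param path Path to the VCF file.
#' @param autosomes Optional character vector of chromosome labels to keep
#'   (labels are opaque strings). `NULL` keeps all chromosomes.
#' @param strict_biallelic Drop records with more than one ALT allele
#'   (default `TRUE`). When `FALSE`, multi-allelic records still cannot be
#'   represented and an error is raised if any are present.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, autosomes = NULL, strict_biallelic = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    gt_samples <- colnames(vcf@gt)[-1]
    if (length(gt_samples) == 0) stop("VCF contains no samples")
    return(genotype_matrix(
      calls = matrix(integer(0), nrow = length(gt_samples), ncol = 0),
      loci = data.frame(chrom = character(0), pos = integer(0),
                        id = character(0), ref = character(0),
                        alt = character(0), stringsAsFactors = FALSE),
      samples = data.frame(sample_id = gt_samples,
                           population = NA_character_,
                           stringsAsFactors = FALSE)))
  }
  if (ncol(vcf@gt) < 2) stop("VCF contains no samples")

  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    if (!strict_biallelic)
      stop("multi-allelic records present and strict_biallelic = FALSE; ",
           "dosage encoding requires bi-allelic records")
    keep <- keep & !multi
  }
  indel <- nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 | fix$ALT == "." |
    is.na(fix$ALT)
  keep <- keep & !indel
  n_multi <- sum(multi)
  n_indel <- sum(indel & !multi)
  if (!is.null(autosomes)) keep <- keep & fix$CHROM %in% autosomes

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # stable sort by chromosome (order of first appearance) then position
  pos <- as.integer(fix$POS)
  chrom_rank <- match(fix$CHROM, unique(fix$CHROM))
  ord <- order(chrom_rank, pos)
  fix <- fix[ord, , drop = FALSE]
  pos <- pos[ord]
  gt <- gt[ord, , drop = FALSE]
  dup <- duplicated(paste(fix$CHROM, pos))
  if (any(dup)) {
    fix <- fix[!dup, , drop = FALSE]
    pos <- pos[!dup]
    gt <- gt[!dup, , drop = FALSE]
  }
  if (n_multi + n_indel + sum(dup) > 0)
    message(sprintf(
      "read_vcf: dropped %d multi-allelic, %d indel/invalid, %d duplicate-position records",
      n_multi, n_indel, sum(dup)))

  calls <- gt_to_dosage(gt)
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM[blank], "_", pos[blank])
  genotype_matrix(
    calls = t(calls),
    loci = data.frame(chrom = fix$CHROM, pos = pos, id = ids,
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
    samples = data.frame(sample_id = colnames(gt),
                         population = NA_character_,
                         stringsAsFactors = FALSE))
}

# GT string matrix (loci x samples) -> integer dosage matrix.
# Accepts phased or unphased separators; any call with a missing allele is NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || any(al == ".") || any(is.na(suppressWarnings(as.integer(al)))))
      return(NA_integer_)
    sum(as.integer(al))
  }, integer(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix to a VCF file
#'
#' Emits VCF 4.2 with a GT-only FORMAT field; missing dosages are written as
#' `./.`. Paths ending in `.gz` are gzip-compressed. `read_vcf()` after
#' `write_vcf()` is the identity on samples, loci and calls.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  calls <- gm$calls
  enc <- matrix("./.", nrow = nrow(calls), ncol = ncol(calls))
  ok <- !is.na(calls)
  enc[ok] <- gt_code[as.character(calls[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohsignal",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t"))
  body <- character(0)
  if (ncol(calls) > 0) {
    gt_cols <- apply(enc, 2, paste, collapse = "\t")
    body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref,
                  gm$loci$alt, ".", "PASS", ".", "GT", gt_cols, sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a population map
#'
#' A population map is a two-column delimited text file (sample id, then
#' population label), separated by tabs or any whitespace. Lines starting
#' with `#` are ignored.
#'
#' @param path Path to the map file.
#' @return Named character vector mapping sample id to population label.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("popmap file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#"),
    error = function(e) stop("popmap is empty or unreadable: ", path))
  if (ncol(tab) < 2)
    stop("popmap must have two columns (sample, population): ", path)
  ids <- as.character(tab[[1]])
  pops <- as.character(tab[[2]])
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    p <- unique(pops[ids == d])
    if (length(p) > 1)
      stop("sample '", d, "' mapped to conflicting populations: ",
           paste(p, collapse = ", "))
    stop("sample '", d, "' listed more than once in popmap")
  }
  stats::setNames(pops, ids)
}

#' Attach population labels to a genotype matrix
#'
#' Samples absent from the map are dropped with a warning naming how many
#' were removed (the map must either cover a sample or it is excluded).
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Named character vector from [read_popmap()].
#' @return The `genotype_matrix` with `samples$population` filled in.
#' @export
assign_populations <- function(gm, popmap) {
  hit <- gm$samples$sample_id %in% names(popmap)
  if (!all(hit)) {
    warning(sum(!hit), " sample(s) absent from popmap were dropped: ",
            paste(utils::head(gm$samples$sample_id[!hit], 5), collapse = ", "))
    gm <- subset_genotypes(gm, samples = which(hit))
  }
  gm$samples$population <- unname(popmap[gm$samples$sample_id])
  gm
}

#' Write a population map
#' @param popmap Named character vector (names = sample ids).
#' @param path Output path; written as two-column TSV.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(
    data.frame(sample = names(popmap), population = unname(popmap)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Shared TSV writer: all tabular outputs are TSV with a header row.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
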