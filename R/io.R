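#' Read/write the plain-text interchange formats
#'
#' Genotypes travel as TSV (rows = individuals, first column `id`, remaining
#' columns = marker dosages, missing = `NA`) with a companion marker-map TSV
#' (`marker`, `chrom`, `pos_cM`); plot records as long CSV; marker effects
#' and variance components as TSV.
#'
#' @param geno A `geno_matrix`.
#' @param file,geno_file,map_file File paths.
#' @name io
NULL

#' @rdname io
#' @export
write_geno_tsv <- function(geno, geno_file, map_file = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  df <- data.frame(id = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, geno_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(map_file))
    utils::write.table(geno$map, map_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(geno_file)
}

#' @rdname io
#' @export
read_geno_tsv <- function(geno_file, map_file = NULL) {
  df <- utils::read.delim(geno_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- df[[1]]
  map <- if (!is.null(map_file))
    utils::read.delim(map_file, stringsAsFactors = FALSE) else NULL
  new_geno_matrix(dos, map)
}

#' @rdname io
#' @param plots A `plot_records` data.frame.
#' @export
write_plots_csv <- function(plots, file) {
  utils::write.csv(as.data.frame(plots), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_plots_csv <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  class(d) <- c("plot_records", "data.frame")
  d
}

#' @rdname io
#' @param effects A `marker_effects` object.
#' @export
write_effects_tsv <- function(effects, file) {
  stopifnot(inherits(effects, "marker_effects"))
  df <- data.frame(marker = effects$markers,
                   additive = unname(effects$additive),
                   dominance = if (is.null(effects$dominance)) NA
                               else unname(effects$dominance),
                   stringsAsFactors = FALSE)
  if (!is.null(effects$inclusion))
    df$inclusion_prob <- unname(effects$inclusion$additive)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export genotypes as a minimal VCF
#'
#' Writes a VCFv4.2 file with one diploid GT column per individual
#' (`0/0`, `0/1`, `1/1`; `./.` for missing). Positions are the cM positions
#' scaled to integer base pairs (1 cM = 1e6 bp), alleles fixed to A/B
#' placeholders, which is sufficient for dosage-level round-trips.
#'
#' @param geno A `geno_matrix`.
#' @param file Output path (plain text, uncompressed).
#' @export
write_geno_vcf <- function(geno, file) {
  stopifnot(inherits(geno, "geno_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hybridgp",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosage)),
                     collapse = "\t")), con)
  D <- t(geno$dosage)  # markers x individuals
  gts <- matrix(gt_code[as.character(D)], nrow = nrow(D))
  gts[is.na(gts)] <- "./."
  lines <- paste(geno$map$chrom, as.integer(round(geno$map$pos_cM * 1e6)),
                 geno$map$marker, "A", "B", ".", "PASS", ".", "GT",
                 apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(file)
}
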