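## Plain-text interchange: genotype CSV + marker map CSV, phenotype TSV,
## and scan-result TSVs. All files round-trip through these readers.

#' Write genotypes to CSV
#'
#' Writes `<prefix>_geno.csv` (columns `ril_id`, `family_id`, then one
#' column per marker with codes 0/1/2 and empty cells for missing) and
#' `<prefix>_map.csv` (`marker_id`, `chrom`, `pos`).
#'
#' @param geno a [NamGenotypes-class].
#' @param prefix path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
writeGenotypes <- function(geno, prefix) {
  stopifnot(is(geno, "NamGenotypes"))
  gf <- paste0(prefix, "_geno.csv")
  mf <- paste0(prefix, "_map.csv")
  df <- data.frame(ril_id = rilIds(geno), family_id = familyIds(geno),
                   genoCodes(geno), check.names = FALSE)
  utils::write.csv(df, gf, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(markerMap(geno), mf, row.names = FALSE, quote = FALSE)
  invisible(c(gf, mf))
}

#' Read genotypes from CSV
#'
#' @param genoFile genotype CSV written by [writeGenotypes()].
#' @param mapFile matching marker map CSV.
#' @return A [NamGenotypes-class].
#' @export
readGenotypes <- function(genoFile, mapFile) {
  df <- utils::read.csv(genoFile, check.names = FALSE,
                        na.strings = c("", "NA"))
  map <- utils::read.csv(mapFile)
  codes <- as.matrix(df[, !(names(df) %in% c("ril_id", "family_id")),
                        drop = FALSE])
  rownames(codes) <- df$ril_id
  NamGenotypes(codes, df$family_id, map)
}

#' Write a phenotype table to TSV
#'
#' Columns `ril_id`, `env`, `block`, `yield`, `is_check` (plus `family_id`
#' when present).
#'
#' @param pheno the phenotype data.frame.
#' @param file output path.
#' @export
writePhenotypes <- function(pheno, file) {
  cols <- intersect(c("ril_id", "family_id", "env", "block", "yield",
                      "is_check"), names(pheno))
  utils::write.table(pheno[cols], file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read a phenotype table from TSV
#'
#' @param file path written by [writePhenotypes()].
#' @return data.frame.
#' @export
readPhenotypes <- function(file) {
  utils::read.delim(file, na.strings = c("", "NA"))
}

#' Write a scan result to TSV
#'
#' Writes the per-marker table and, alongside it, a long-format
#' `<file>.effects.tsv` with one row per marker-family allele effect.
#'
#' @param scan a [ScanResult-class].
#' @param file output path for the marker table.
#' @export
writeScanResult <- function(scan, file) {
  stopifnot(is(scan, "ScanResult"))
  utils::write.table(scanTable(scan), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  fe <- familyEffects(scan)
  long <- data.frame(marker_id = rep(colnames(fe), each = nrow(fe)),
                     family_id = rep(rownames(fe), ncol(fe)),
                     effect = as.vector(fe))
  long <- long[!is.na(long$effect), , drop = FALSE]
  utils::write.table(long, paste0(file, ".effects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
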