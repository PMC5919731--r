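#' @import methods
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' NamGenotypes: RIL genotypes of a nested association mapping population
#'
#' Container for the genotype codes of recombinant inbred lines (RILs) from a
#' NAM population: a set of biparental families that share one common parent.
#' Codes are relative to the common parent: 2 = homozygous for the common
#' parent's allele, 0 = homozygous for the family founder's allele,
#' 1 = heterozygous. `NA` marks missing calls.
#'
#' @slot codes integer matrix, RILs in rows (rownames = RIL ids), markers in
#'   columns (colnames = marker ids); entries in \{0, 1, 2, NA\}.
#' @slot familyIds character vector, one family label per RIL.
#' @slot map data.frame with columns `marker_id`, `chrom`, `pos`, one row per
#'   marker in column order of `codes`.
#'
#' @seealso [NamGenotypes()], [simulateGenotypes()], [recodeParentalOrigin()]
#' @export
setClass("NamGenotypes",
  representation(
    codes = "matrix",
    familyIds = "character",
    map = "data.frame"
  )
)

setValidity("NamGenotypes", function(object) {
  msg <- character()
  cd <- object@codes
  if (!is.numeric(cd)) msg <- c(msg, "codes must be a numeric matrix")
  bad <- cd[!is.na(cd)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (length(object@familyIds) != nrow(cd))
    msg <- c(msg, "familyIds must have one entry per RIL")
  if (is.null(rownames(cd)) || is.null(colnames(cd)))
    msg <- c(msg, "codes must carry RIL ids (rownames) and marker ids (colnames)")
  if (nrow(object@map) != ncol(cd))
    msg <- c(msg, "map must have one row per marker")
  if (!all(c("marker_id", "chrom", "pos") %in% names(object@map)))
    msg <- c(msg, "map needs columns marker_id, chrom, pos")
  else if (!identical(as.character(object@map$marker_id), colnames(cd)))
    msg <- c(msg, "map$marker_id must match colnames(codes) in order")
  if (length(msg)) msg else TRUE
})

#' Construct a NamGenotypes object
#'
#' @param codes RIL x marker matrix of codes in \{0,1,2,NA\} with rownames
#'   (RIL ids) and colnames (marker ids).
#' @param familyIds character vector of family labels, one per RIL.
#' @param map data.frame `marker_id`, `chrom`, `pos` (one row per marker). If
#'   missing, a single-chromosome map with unit spacing is created.
#' @return A [NamGenotypes-class] object.
#' @export
NamGenotypes <- function(codes, familyIds, map = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  if (is.null(rownames(codes)))
    rownames(codes) <- paste0("RIL", seq_len(nrow(codes)))
  if (is.null(colnames(codes)))
    colnames(codes) <- paste0("M", seq_len(ncol(codes)))
  if (is.null(map)) {
    map <- data.frame(marker_id = colnames(codes), chrom = 1L,
                      pos = seq_len(ncol(codes)))
  }
  new("NamGenotypes", codes = codes, familyIds = as.character(familyIds),
      map = map)
}

#' @describeIn NamGenotypes Genotype code matrix (RIL x marker).
#' @param object,x A `NamGenotypes` object.
#' @export
genoCodes <- function(object) object@codes

#' @describeIn NamGenotypes RIL identifiers.
#' @export
rilIds <- function(object) rownames(object@codes)

#' @describeIn NamGenotypes Family label per RIL.
#' @export
familyIds <- function(object) object@familyIds

#' @describeIn NamGenotypes Marker map (`marker_id`, `chrom`, `pos`).
#' @export
markerMap <- function(object) object@map

#' @describeIn NamGenotypes Marker identifiers.
#' @export
markerIds <- function(object) colnames(object@codes)

setMethod("show", "NamGenotypes", function(object) {
  fam <- unique(object@familyIds)
  cat("NamGenotypes:", nrow(object@codes), "RILs x", ncol(object@codes),
      "markers in", length(fam), "families\n")
  cat("  chromosomes:", length(unique(object@map$chrom)),
      "| missing calls:", sum(is.na(object@codes)), "\n")
})

#' ParentalIncidence: marker-by-family founder-allele incidence
#'
#' For one marker, the RIL x family matrix Z whose entry for a RIL in family f
#' is the RIL's founder-allele dosage (2 - code) in column f and zero
#' elsewhere; columns of families where the marker does not segregate are all
#' zero. This is the incidence of the marker-by-family interaction used by the
#' multiparental association model, which lets one locus carry a different
#' effect in every family.
#'
#' @slot Z numeric RIL x family matrix of founder-allele dosages.
#' @slot markerId the marker this incidence belongs to.
#' @slot segregating labels of families polymorphic at this marker.
#' @export
setClass("ParentalIncidence",
  representation(Z = "matrix", markerId = "character",
                 segregating = "character")
)

setValidity("ParentalIncidence", function(object) {
  z <- object@Z[!is.na(object@Z)]
  if (length(z) && (any(z < 0) || any(z > 2)))
    return("founder-allele dosages must lie in [0, 2]")
  TRUE
})

#' @describeIn ParentalIncidence The RIL x family dosage matrix.
#' @param object A `ParentalIncidence` object.
#' @export
incidenceMatrix <- function(object) object@Z

#' @describeIn ParentalIncidence Families segregating at the marker.
#' @export
segregatingFamilies <- function(object) object@segregating

setMethod("show", "ParentalIncidence", function(object) {
  cat("ParentalIncidence for marker", object@markerId, ":",
      nrow(object@Z), "RILs x", ncol(object@Z), "families;",
      length(object@segregating), "segregating\n")
})

#' Kinship: genomic relationship matrix
#'
#' Additive genomic relationship matrix K = c M M' built from the
#' column-centered genotype codes M, with the scale constant c chosen so that
#' the mean diagonal equals 1 (so the polygenic variance component is on the
#' phenotypic scale).
#'
#' @slot K symmetric RIL x RIL relationship matrix.
#' @slot scaleConstant the constant c in K = c M M'.
#' @export
setClass("Kinship",
  representation(K = "matrix", scaleConstant = "numeric")
)

setValidity("Kinship", function(object) {
  K <- object@K
  msg <- character()
  if (nrow(K) != ncol(K)) msg <- c(msg, "K must be square")
  else if (max(abs(K - t(K))) > 1e-8) msg <- c(msg, "K must be symmetric")
  if (abs(mean(diag(K)) - 1) > 1e-6)
    msg <- c(msg, "mean diagonal of K must equal 1 after scaling")
  if (length(msg)) msg else TRUE
})

#' @describeIn Kinship The relationship matrix.
#' @param object A `Kinship` object.
#' @export
kinshipMatrix <- function(object) object@K

setMethod("show", "Kinship", function(object) {
  cat("Kinship:", nrow(object@K), "x", ncol(object@K),
      "| scale constant", signif(object@scaleConstant, 4),
      "| mean diag", signif(mean(diag(object@K)), 4), "\n")
})

#' ScanResult: per-marker association scan results
#'
#' One row per marker tested: likelihood-ratio statistic, p-value under the
#' configured null law, -log10 p, and the number of families the marker was
#' tested in. Per-family allele-effect estimates (BLUPs of the family-specific
#' marker effect, kg/ha per founder-allele dosage) are stored as a
#' family x marker matrix with NA for non-segregating families.
#'
#' @slot results data.frame: `marker_id`, `chrom`, `pos`, `env`, `lrt`,
#'   `pvalue`, `neglog10p`, `n_families`, plus `adj_r2` for stability scans.
#' @slot familyEffects numeric family x marker matrix of allele effects.
#' @slot threshold genome-wide Bonferroni threshold on the -log10 p scale.
#' @slot environment label of the environment (or phenotype) scanned.
#' @slot alphaLevel the family-wise error rate behind `threshold`.
#' @export
setClass("ScanResult",
  representation(results = "data.frame", familyEffects = "matrix",
                 threshold = "numeric", environment = "character",
                 alphaLevel = "numeric")
)

setValidity("ScanResult", function(object) {
  r <- object@results
  need <- c("marker_id", "lrt", "pvalue", "neglog10p")
  if (!all(need %in% names(r)))
    return("results must contain marker_id, lrt, pvalue, neglog10p")
  if (any(r$lrt < -1e-8, na.rm = TRUE)) return("lrt must be non-negative")
  if (any(r$pvalue <= 0 | r$pvalue > 1, na.rm = TRUE))
    return("p-values must lie in (0, 1]")
  TRUE
})

#' @describeIn ScanResult Per-marker result table.
#' @param object A `ScanResult` object.
#' @export
scanTable <- function(object) object@results

#' @describeIn ScanResult Family x marker allele-effect matrix.
#' @export
familyEffects <- function(object) object@familyEffects

#' @describeIn ScanResult Bonferroni threshold on the -log10 p scale.
#' @export
scanThreshold <- function(object) object@threshold

setMethod("show", "ScanResult", function(object) {
  r <- object@results
  cat("ScanResult (", object@environment, "): ", nrow(r), " markers, ",
      sum(r$neglog10p >= object@threshold), " above the Bonferroni line (",
      signif(object@threshold, 4), ")\n", sep = "")
  if (nrow(r)) {
    top <- r[which.max(r$neglog10p), ]
    cat("  top marker:", top$marker_id, " -log10p =",
        signif(top$neglog10p, 4), "\n")
  }
})

#' FwFit: Finlay-Wilkinson joint-regression fits
#'
#' Per-RIL slope (the FW stability index), intercept, deviation mean square
#' and number of environments, from ordinary least squares of each RIL's
#' yields on a centered environmental productivity index. A slope of 1 is
#' dynamic stability (the RIL tracks the trial average), below 1 is buffered
#' against environment, above 1 is environmentally sensitive.
#'
#' @slot table data.frame: `ril_id`, `family_id`, `slope`, `intercept`,
#'   `deviation_mse`, `n_env` (slope is NA when `n_env` < the minimum).
#' @slot index data.frame of the environmental index: `env`, `mean`,
#'   `centered`.
#' @export
setClass("FwFit",
  representation(table = "data.frame", index = "data.frame")
)

setValidity("FwFit", function(object) {
  if (!all(c("ril_id", "slope", "intercept", "deviation_mse", "n_env") %in%
           names(object@table)))
    return("table must contain ril_id, slope, intercept, deviation_mse, n_env")
  if (nrow(object@index) &&
      abs(sum(object@index$centered)) > 1e-6 * max(1, max(abs(object@index$mean))))
    return("centered environmental index must sum to zero")
  TRUE
})

#' @describeIn FwFit Per-RIL slope table.
#' @param object A `FwFit` object.
#' @export
fwTable <- function(object) object@table

#' @describeIn FwFit The environmental index used for the regression.
#' @export
fwIndex <- function(object) object@index

setMethod("show", "FwFit", function(object) {
  sl <- object@table$slope
  cat("FwFit:", nrow(object@table), "RILs over", nrow(object@index),
      "environments; mean slope", signif(mean(sl, na.rm = TRUE), 4),
      "(", sum(is.na(sl)), "undefined )\n")
})

#' EffectPanel: family x environment allele effects for one marker
#'
#' The per-environment association scans provide, for one marker, a
#' family x environment matrix of estimated allele effects together with the
#' number of RILs observed in each family-environment cell (the weights of
#' the meta-analysis). Cells with zero weight carry no information and are
#' excluded from every sum.
#'
#' @slot markerId the marker the panel belongs to.
#' @slot effects numeric family x environment matrix of allele effects
#'   (kg/ha per founder-allele dosage); NA where unobserved.
#' @slot weights matrix of the same shape: RIL counts per cell.
#' @slot parentOfFamily named character vector mapping family -> founder
#'   parent (the incidence of the parent-mean model).
#' @export
setClass("EffectPanel",
  representation(markerId = "character", effects = "matrix",
                 weights = "matrix", parentOfFamily = "character")
)

setValidity("EffectPanel", function(object) {
  msg <- character()
  if (!identical(dim(object@effects), dim(object@weights)))
    msg <- c(msg, "effects and weights must have the same shape")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (!all(rownames(object@effects) %in% names(object@parentOfFamily)))
    msg <- c(msg, "every family needs a parent in parentOfFamily")
  if (length(msg)) msg else TRUE
})

#' @describeIn EffectPanel Family x environment effect matrix.
#' @param object An `EffectPanel` object.
#' @export
panelEffects <- function(object) object@effects

#' @describeIn EffectPanel Observation-count weight matrix.
#' @export
panelWeights <- function(object) object@weights

setMethod("show", "EffectPanel", function(object) {
  cat("EffectPanel for marker", object@markerId, ":",
      nrow(object@effects), "families x", ncol(object@effects),
      "environments;", sum(object@weights > 0), "observed cells\n")
})
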