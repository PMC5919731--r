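## Genotype preparation: deterministic within-family modal imputation,
## parental-origin (marker-by-family) recoding, and the genomic
## relationship matrix.

#' Impute missing genotype calls by the within-family mode
#'
#' Each missing call is replaced by the modal code of the RIL's family at
#' that marker; when a whole family-marker cell is missing the family's
#' overall modal code is used. Ties break toward the lower code, so the
#' procedure is fully deterministic.
#'
#' @param geno a [NamGenotypes-class] object.
#' @return The same object with no missing calls.
#' @examples
#' g <- simulateGenotypes(namDesign(n_families = 2, n_rils_per_family = 6,
#'                                  n_markers = 8, n_chromosomes = 2, seed = 3))
#' gm <- injectMissing(g, 0.2, seed = 4)
#' sum(is.na(genoCodes(imputeMissing(gm))))
#' @export
imputeMissing <- function(geno) {
  stopifnot(is(geno, "NamGenotypes"))
  codes <- genoCodes(geno)
  if (!anyNA(codes)) return(geno)
  fam <- familyIds(geno)
  for (f in unique(fam)) {
    rows <- which(fam == f)
    block <- codes[rows, , drop = FALSE]
    if (!anyNA(block)) next
    famMode <- .modeLow(block[!is.na(block)])
    naCols <- which(colSums(is.na(block)) > 0)
    for (k in naCols) {
      v <- block[, k]
      obs <- v[!is.na(v)]
      fill <- if (length(obs)) .modeLow(obs) else famMode
      v[is.na(v)] <- fill
      block[, k] <- v
    }
    codes[rows, ] <- block
  }
  initialize(geno, codes = codes)
}

## modal value with ties broken toward the lower code
.modeLow <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

#' Recode a marker into parental-origin incidence
#'
#' For marker `marker`, builds the RIL x family matrix Z whose entry for a
#' RIL in family f is its founder-allele dosage (2 - code) in column f and
#' zero elsewhere. Columns of families where the marker does not segregate
#' are zeroed: such a family carries no contrast between parental alleles,
#' so it contributes nothing to the family-specific marker effect. A family
#' counts as segregating when both homozygote codes appear or any
#' heterozygote appears.
#'
#' @param geno a [NamGenotypes-class] object without missing calls (run
#'   [imputeMissing()] first).
#' @param marker marker id or column index.
#' @return A [ParentalIncidence-class] object.
#' @export
recodeParentalOrigin <- function(geno, marker) {
  stopifnot(is(geno, "NamGenotypes"))
  codes <- genoCodes(geno)
  .stopIf(anyNA(codes),
          "missing genotype calls present: run imputeMissing() first")
  if (is.character(marker)) marker <- match(marker, colnames(codes))
  .stopIf(is.na(marker) || marker < 1 || marker > ncol(codes),
          "unknown marker")
  fam <- familyIds(geno)
  famLevels <- unique(fam)
  z <- .markerZ(codes[, marker], fam, famLevels)
  new("ParentalIncidence", Z = z$Z, markerId = colnames(codes)[marker],
      segregating = z$segregating)
}

## core of the recoding, shared with the scan loop: one marker's code
## vector -> RIL x family dosage matrix + segregating family labels
.markerZ <- function(code, fam, famLevels) {
  n <- length(code)
  dos <- 2 - code
  famIdx <- match(fam, famLevels)
  seg <- vapply(seq_along(famLevels), function(f) {
    v <- code[famIdx == f]
    any(v == 1) || (any(v == 0) && any(v == 2))
  }, logical(1))
  Z <- matrix(0, n, length(famLevels),
              dimnames = list(names(code), famLevels))
  keep <- seg[famIdx]
  Z[cbind(which(keep), famIdx[keep])] <- dos[keep]
  list(Z = Z, segregating = famLevels[seg])
}

#' Genomic relationship matrix
#'
#' Computes K = c M M' where M is the genotype code matrix centered by
#' marker mean over all RILs, and c scales the result so the mean diagonal
#' equals 1. K is symmetric positive semi-definite and captures genetic
#' similarity among RILs, including the family structure of the NAM design;
#' it parameterizes the polygenic covariance of the association model.
#'
#' @param geno a [NamGenotypes-class] object without missing calls.
#' @return A [Kinship-class] object.
#' @export
computeKinship <- function(geno) {
  stopifnot(is(geno, "NamGenotypes"))
  codes <- genoCodes(geno)
  .stopIf(anyNA(codes),
          "missing genotype calls present: run imputeMissing() first")
  .stopIf(nrow(codes) < 2, "degenerate input: kinship needs >= 2 RILs")
  M <- scale(codes, center = TRUE, scale = FALSE)
  MMt <- tcrossprod(M)
  md <- mean(diag(MMt))
  .stopIf(md <= 0, "degenerate input: all markers are monomorphic")
  K <- MMt / md
  K <- (K + t(K)) / 2
  new("Kinship", K = K, scaleConstant = 1 / md)
}
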