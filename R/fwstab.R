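## Finlay-Wilkinson joint regression: per-RIL slopes on an environmental
## productivity index, and the stability GWAS using the slope as phenotype.

#' Environmental productivity index
#'
#' The index of environment j is the mean yield of all non-check records
#' observed there; the centered version (mean removed across environments)
#' is the regressor of the joint regression. Environments are ordered by
#' label for determinism.
#'
#' @param pheno a (check-adjusted) phenotype table.
#' @return data.frame `env`, `mean`, `centered` with `sum(centered) == 0`.
#' @export
environmentIndex <- function(pheno) {
  pheno <- pheno[.plotRows(pheno), , drop = FALSE]
  means <- tapply(pheno$yield, pheno$env, mean)
  .stopIf(length(means) < 2,
          "invalid design: need at least 2 environments for an index")
  means <- means[order(names(means))]
  data.frame(env = names(means), mean = as.numeric(means),
             centered = as.numeric(means - mean(means)),
             row.names = NULL)
}

#' Finlay-Wilkinson joint regression
#'
#' Regresses each RIL's yields (averaged per environment) on the centered
#' environmental index by ordinary least squares, using only the
#' environments where the RIL was observed. The slope is the FW stability
#' index: 1 means the RIL tracks the trial average (dynamic stability),
#' 0 means complete environmental insensitivity (static stability). RILs
#' observed in fewer than `minEnv` environments get an undefined slope; two
#' points would fit perfectly and carry no deviation information.
#'
#' @param pheno a (check-adjusted) phenotype table.
#' @param index optional index from [environmentIndex()]; computed from
#'   `pheno` when missing — it must come from the same records for the
#'   mean slope to anchor at 1.
#' @param geno optional [NamGenotypes-class] used to attach family labels.
#' @param minEnv minimum number of environments for a defined slope.
#' @return An [FwFit-class] object.
#' @export
fwRegression <- function(pheno, index = NULL, geno = NULL, minEnv = 3) {
  pheno <- pheno[.plotRows(pheno), , drop = FALSE]
  if (is.null(index)) index <- environmentIndex(pheno)
  x <- stats::setNames(index$centered, index$env)
  ## per RIL x environment mean yield
  cell <- stats::aggregate(yield ~ ril_id + env, data = pheno, FUN = mean)
  cell$x <- x[cell$env]
  .stopIf(anyNA(cell$x), "index does not cover every environment in pheno")
  sp <- split(cell[c("yield", "x")], cell$ril_id)
  fitOne <- function(df) {
    ne <- nrow(df)
    if (ne < minEnv)
      return(c(slope = NA_real_, intercept = NA_real_,
               deviation_mse = NA_real_, n_env = ne))
    xb <- mean(df$x); yb <- mean(df$yield)
    sxx <- sum((df$x - xb)^2)
    b <- sum((df$x - xb) * (df$yield - yb)) / sxx
    res <- df$yield - (yb + b * (df$x - xb))
    c(slope = b, intercept = yb - b * xb,
      deviation_mse = sum(res^2) / (ne - 2), n_env = ne)
  }
  tab <- as.data.frame(do.call(rbind, lapply(sp, fitOne)))
  tab <- data.frame(ril_id = names(sp), tab, row.names = NULL)
  tab$family_id <- if (!is.null(geno))
    familyIds(geno)[match(tab$ril_id, rilIds(geno))]
  else NA_character_
  tab <- tab[c("ril_id", "family_id", "slope", "intercept",
               "deviation_mse", "n_env")]
  new("FwFit", table = tab, index = index)
}

#' Stability GWAS on the Finlay-Wilkinson slope
#'
#' Runs the multiparental association scan with the per-RIL FW slope as the
#' phenotype (one record per RIL, intercept-only fixed effects), and adds
#' the per-marker adjusted R-squared of an ordinary regression of the slope
#' on the founder-allele dosages of the segregating families — a plain
#' variance-explained summary to set the mixed-model signal in context.
#'
#' @param geno a [NamGenotypes-class] without missing calls.
#' @param fwfit an [FwFit-class] from [fwRegression()].
#' @param alphaLevel family-wise error rate for the Bonferroni threshold.
#' @param ... passed to [genomeScan()] (`kinship`, `markers`, `method`,
#'   `pvalueLaw`).
#' @return A [ScanResult-class] whose table carries an extra `adj_r2`
#'   column.
#' @export
stabilityGwas <- function(geno, fwfit, alphaLevel = 0.05, ...) {
  stopifnot(is(fwfit, "FwFit"))
  tab <- fwTable(fwfit)
  slopes <- stats::setNames(tab$slope, tab$ril_id)
  slopes <- slopes[!is.na(slopes)]
  .stopIf(length(slopes) < 3, "fewer than 3 RILs with a defined FW slope")
  scan <- genomeScan(geno, slopes, alphaLevel = alphaLevel, ...)
  scan@results$adj_r2 <- .slopeAdjR2(geno, slopes,
                                     scan@results$marker_id)
  scan@environment <- "fw_slope"
  scan@results$env <- "fw_slope"
  validObject(scan)
  scan
}

## adjusted R^2 of slope ~ founder dosage (segregating-family columns)
.slopeAdjR2 <- function(geno, slopes, markerIdsUsed) {
  ids <- intersect(rilIds(geno), names(slopes))
  codes <- genoCodes(geno)[ids, , drop = FALSE]
  fam <- familyIds(geno)[match(ids, rilIds(geno))]
  famLevels <- unique(fam)
  yv <- slopes[ids]
  vapply(markerIdsUsed, function(m) {
    z <- .markerZ(codes[, m], fam, famLevels)
    if (!length(z$segregating)) return(0)
    Zs <- z$Z[, z$segregating, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Zs), yv)
    p <- fit$rank - 1
    n <- length(yv)
    rss <- sum(fit$residuals^2)
    tss <- sum((yv - mean(yv))^2)
    if (tss <= 0 || n - p - 1 <= 0) return(0)
    1 - (rss / (n - p - 1)) / (tss / (n - 1))
  }, numeric(1), USE.NAMES = FALSE)
}
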