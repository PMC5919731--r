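## GEI meta-analysis: per-environment family allele effects are combined
## across environments; a parent-mean model fitted by weighted least
## squares is the null, and the alternative adds a rank-one multiplicative
## family-by-environment term extracted from the first component of the
## singular value decomposition of the residual matrix (the AMMI/GGE
## construction). The two models are compared by a likelihood-ratio test.

## per-environment scans shared by collectEffects and geiScan
.perEnvEffects <- function(geno, pheno, markers = NULL, kinship = NULL,
                           method = "fast", pvalueLaw = "chi2_0.5df",
                           effects = "gls") {
  pheno <- pheno[.plotRows(pheno), , drop = FALSE]
  envs <- sort(unique(pheno$env))
  .stopIf(length(envs) < 2, "need >= 2 environments for the meta-analysis")
  if (is.null(kinship)) kinship <- computeKinship(geno)
  fam <- familyIds(geno)
  famLevels <- unique(fam)
  counts <- matrix(0, length(famLevels), length(envs),
                   dimnames = list(famLevels, envs))
  scans <- stats::setNames(vector("list", length(envs)), envs)
  for (e in envs) {
    scans[[e]] <- genomeScan(geno, pheno, env = e, kinship = kinship,
                             markers = markers, method = method,
                             pvalueLaw = pvalueLaw, effects = effects)
    sub <- pheno[pheno$env == e, , drop = FALSE]
    ids <- intersect(rilIds(geno), unique(sub$ril_id))
    tb <- table(factor(fam[match(ids, rilIds(geno))], levels = famLevels))
    counts[, e] <- as.numeric(tb)
  }
  list(scans = scans, counts = counts, envs = envs, famLevels = famLevels)
}

## assemble one marker's EffectPanel from per-environment scans
.assemblePanel <- function(perEnv, markerId, parentOfFamily = NULL) {
  famLevels <- perEnv$famLevels
  envs <- perEnv$envs
  A <- matrix(NA_real_, length(famLevels), length(envs),
              dimnames = list(famLevels, envs))
  N <- matrix(0, length(famLevels), length(envs),
              dimnames = list(famLevels, envs))
  for (e in envs) {
    ## per-environment scans may cover a family subset (unbalanced trials):
    ## match on family names, not positions
    eff <- familyEffects(perEnv$scans[[e]])[, markerId]
    seg <- names(eff)[!is.na(eff)]
    A[seg, e] <- eff[seg]
    N[seg, e] <- perEnv$counts[seg, e]
  }
  N[is.na(A)] <- 0
  if (is.null(parentOfFamily))
    parentOfFamily <- stats::setNames(famLevels, famLevels)
  new("EffectPanel", markerId = markerId, effects = A, weights = N,
      parentOfFamily = parentOfFamily)
}

#' Collect per-environment allele effects for one marker
#'
#' Runs the association scan in every environment and gathers the
#' family-specific allele-effect estimates into a family x environment
#' panel, weighted by the number of RILs observed in each
#' family-environment combination. Cells where the family is absent from
#' the environment or the marker does not segregate in the family get zero
#' weight.
#'
#' @param geno a [NamGenotypes-class] without missing calls.
#' @param pheno a check-adjusted multi-environment phenotype table.
#' @param marker marker id (or index).
#' @param kinship optional precomputed [Kinship-class].
#' @param parentOfFamily optional named map family -> founder parent;
#'   defaults to one parent per family as in a NAM design.
#' @param method,pvalueLaw passed to the per-environment scans.
#' @param effects `"gls"` (default) enters unshrunk whitened fixed-effect
#'   estimates into the panel; `"blup"` uses the shrinkage estimates, which
#'   can collapse to exact zeros at the variance boundary and degenerate
#'   the rank-one decomposition.
#' @return An [EffectPanel-class] object.
#' @export
collectEffects <- function(geno, pheno, marker, kinship = NULL,
                           parentOfFamily = NULL, method = "fast",
                           pvalueLaw = "chi2_0.5df",
                           effects = c("gls", "blup")) {
  effects <- match.arg(effects)
  if (is.numeric(marker)) marker <- markerIds(geno)[marker]
  perEnv <- .perEnvEffects(geno, pheno, markers = marker, kinship = kinship,
                           method = method, pvalueLaw = pvalueLaw,
                           effects = effects)
  panel <- .assemblePanel(perEnv, marker, parentOfFamily)
  .stopIf(sum(rowSums(panel@weights) > 0) < 2,
          "insufficient segregation: marker informative in < 2 families")
  panel
}

#' Weighted least-squares fit of the parent-mean (null) model
#'
#' Fits the additive model in which a marker carries one true effect per
#' founder parent, constant over environments: the weighted least-squares
#' solution minimizes `sum N[f,j] * (A[f,j] - delta_parent(f))^2` over the
#' observed cells. Residuals on unobserved cells are zero by convention.
#'
#' @param panel an [EffectPanel-class].
#' @return A `MetaFit` list: `delta` (named per parent), `residuals`
#'   (family x environment matrix), `weightedRss`, `nCells`, and the
#'   `panel`.
#' @export
fitMetaNull <- function(panel) {
  stopifnot(is(panel, "EffectPanel"))
  A <- panel@effects
  N <- panel@weights
  obs <- N > 0 & !is.na(A)
  .stopIf(!any(obs), "degenerate input: all panel weights are zero")
  parent <- panel@parentOfFamily[rownames(A)]
  parents <- unique(parent)
  delta <- vapply(parents, function(p) {
    rows <- which(parent == p)
    w <- N[rows, , drop = FALSE]
    a <- A[rows, , drop = FALSE]
    o <- obs[rows, , drop = FALSE]
    sw <- sum(w[o])
    if (sw == 0) return(NA_real_)
    sum((w * a)[o]) / sw
  }, numeric(1))
  names(delta) <- parents
  E <- A - delta[parent]
  E[!obs] <- 0
  structure(list(delta = delta, residuals = E,
                 weightedRss = sum((N * E^2)[obs]),
                 nCells = sum(obs), panel = panel),
            class = "MetaFit")
}

#' @export
print.MetaFit <- function(x, ...) {
  cat("MetaFit:", length(x$delta), "parent effects over", x$nCells,
      "observed cells; weighted RSS =", signif(x$weightedRss, 5), "\n")
  invisible(x)
}

#' Rank-one multiplicative interaction from the residual SVD
#'
#' Extracts the first singular component of the (zero-filled) residual
#' matrix of the parent-mean fit: gamma = u1 d1 v1', the best rank-one
#' approximation of the residuals in Frobenius norm (Eckart-Young). The
#' fraction of residual variation captured, `pcLoad = d1^2 / sum(d^2)`,
#' summarizes how strongly the family-by-environment interaction is
#' one-dimensional. The sign convention makes the first nonzero family
#' loading positive.
#'
#' @param fit a `MetaFit` from [fitMetaNull()].
#' @return A `Rank1Interaction` list: `u` (family loadings), `d1`, `v`
#'   (environment loadings), `gamma`, `pcLoad`, `residuals`
#'   (residuals after removing gamma).
#' @export
rank1Interaction <- function(fit) {
  stopifnot(inherits(fit, "MetaFit"))
  E <- fit$residuals
  .stopIf(nrow(E) < 2 || ncol(E) < 2,
          "invalid shape: need >= 2 families and >= 2 environments")
  sv <- svd(E)
  u <- sv$u[, 1]
  v <- sv$v[, 1]
  d1 <- sv$d[1]
  nz <- which(abs(u) > 1e-12)
  if (length(nz) && u[nz[1]] < 0) {
    u <- -u
    v <- -v
  }
  gamma <- d1 * tcrossprod(u, v)
  dimnames(gamma) <- dimnames(E)
  tot <- sum(sv$d^2)
  structure(list(u = stats::setNames(u, rownames(E)), d1 = d1,
                 v = stats::setNames(v, colnames(E)),
                 gamma = gamma,
                 pcLoad = if (tot > 0) d1^2 / tot else 0,
                 residuals = E - gamma),
            class = "Rank1Interaction")
}

#' @export
print.Rank1Interaction <- function(x, ...) {
  cat("Rank1Interaction: d1 =", signif(x$d1, 5),
      "| PC load =", signif(x$pcLoad, 4), "\n")
  invisible(x)
}

#' Likelihood-ratio test of the multiplicative interaction
#'
#' Compares the parent-mean model against the model augmented with the
#' rank-one interaction, using Gaussian likelihoods with profiled variance
#' on the weighted residual sums of squares: LRT = n * ln(RSS0 / RSS1)
#' over the n observed cells. Degrees of freedom follow the free-parameter
#' count of a rank-one bilinear term, (parents - 1) + (environments - 1)
#' + 1, computed from the parents and environments actually observed for
#' the marker; `df` can be overridden. Markers reaching `threshold` on the
#' -log10 p scale are flagged; the default of 50 is deliberately extreme
#' because the SVD-maximized statistic is anticonservative against a
#' nominal chi-square reference (see the package vignette).
#'
#' @param nullFit a `MetaFit`.
#' @param alt the matching `Rank1Interaction`.
#' @param threshold -log10 p flagging threshold (default 50).
#' @param df optional degrees-of-freedom override.
#' @return one-row data.frame: `marker_id`, `lrt`, `df`, `pvalue`,
#'   `neglog10p`, `pc_load`, `n_parents`, `n_env`, `significant`.
#' @export
geiLrt <- function(nullFit, alt, threshold = 50, df = NULL) {
  stopifnot(inherits(nullFit, "MetaFit"),
            inherits(alt, "Rank1Interaction"))
  panel <- nullFit$panel
  N <- panel@weights
  obs <- N > 0 & !is.na(panel@effects)
  rss0 <- nullFit$weightedRss
  rss1 <- sum((N * alt$residuals^2)[obs])
  n <- nullFit$nCells
  parent <- panel@parentOfFamily[rownames(N)]
  nPar <- length(unique(parent[rowSums(obs) > 0]))
  nEnv <- sum(colSums(obs) > 0)
  if (is.null(df)) df <- max(1L, (nPar - 1L) + (nEnv - 1L) + 1L)
  if (rss0 <= 0) {
    lrt <- 0; pvalue <- 1; nl <- 0
  } else if (rss1 <= rss0 * 1e-12) {
    ## the interaction absorbs the residual entirely: p-value underflow
    lrt <- Inf; pvalue <- 1e-320; nl <- 320
  } else {
    lrt <- max(0, n * log(rss0 / rss1))
    logp <- stats::pchisq(lrt, df = df, lower.tail = FALSE, log.p = TRUE)
    nl <- .neglog10FromLogP(logp)
    pvalue <- max(exp(logp), 1e-320)
  }
  data.frame(marker_id = panel@markerId, lrt = lrt, df = df,
             pvalue = pvalue, neglog10p = nl, pc_load = alt$pcLoad,
             n_parents = nPar, n_env = nEnv,
             significant = nl >= threshold, row.names = NULL)
}

#' Genome-wide GEI meta-analysis scan
#'
#' For every marker: per-environment association scans, weighted
#' least-squares parent-mean fit, rank-one SVD interaction, and the
#' likelihood-ratio test of the multiplicative term. Markers informative
#' in fewer than 2 families or 2 environments are reported with an NA
#' statistic.
#'
#' @param geno a [NamGenotypes-class] without missing calls.
#' @param pheno a check-adjusted multi-environment phenotype table.
#' @param markers marker ids or indices (default: all).
#' @param threshold -log10 p flagging threshold (default 50).
#' @param kinship optional precomputed [Kinship-class].
#' @param parentOfFamily optional family -> parent map.
#' @param method,pvalueLaw passed to the per-environment scans.
#' @param effects effect estimates entering the panels; see
#'   [collectEffects()].
#' @return data.frame with one row per marker (columns as in [geiLrt()],
#'   plus `chrom` and `pos`).
#' @export
geiScan <- function(geno, pheno, markers = NULL, threshold = 50,
                    kinship = NULL, parentOfFamily = NULL,
                    method = "fast", pvalueLaw = "chi2_0.5df",
                    effects = c("gls", "blup")) {
  stopifnot(is(geno, "NamGenotypes"))
  effects <- match.arg(effects)
  if (is.null(markers)) markers <- markerIds(geno)
  if (is.numeric(markers)) markers <- markerIds(geno)[markers]
  perEnv <- .perEnvEffects(geno, pheno, markers = markers,
                           kinship = kinship, method = method,
                           pvalueLaw = pvalueLaw, effects = effects)
  map <- markerMap(geno)
  rows <- lapply(markers, function(m) {
    panel <- .assemblePanel(perEnv, m, parentOfFamily)
    obs <- panel@weights > 0
    if (sum(rowSums(obs) > 0) < 2 || sum(colSums(obs) > 0) < 2) {
      return(data.frame(marker_id = m, lrt = NA_real_, df = NA_integer_,
                        pvalue = NA_real_, neglog10p = NA_real_,
                        pc_load = NA_real_, n_parents = sum(rowSums(obs) > 0),
                        n_env = sum(colSums(obs) > 0), significant = FALSE))
    }
    nf <- fitMetaNull(panel)
    geiLrt(nf, rank1Interaction(nf), threshold = threshold)
  })
  out <- do.call(rbind, rows)
  i <- match(out$marker_id, map$marker_id)
  cbind(out[, "marker_id", drop = FALSE],
        chrom = map$chrom[i], pos = map$pos[i],
        out[, setdiff(names(out), "marker_id")])
}
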