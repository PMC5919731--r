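## Multiparental mixed-model association: check-based field adjustment,
## REML null fits, per-marker likelihood-ratio tests with family-specific
## allele effects, and genome scans.

#' Adjust plot yields by check cultivars
#'
#' In an augmented design the repeated check cultivars estimate field
#' (block) effects. Each non-check yield is reduced by the difference
#' between its block's check mean and its environment's check mean; check
#' records are then dropped. The adjustment removes block-to-block field
#' variation while leaving the environment means untouched.
#'
#' @param pheno data.frame with columns `ril_id`, `env`, `block`, `yield`,
#'   `is_check` (as produced by [simulatePhenotypes()]).
#' @return The adjusted phenotype table without check records.
#' @export
adjustByChecks <- function(pheno) {
  need <- c("ril_id", "env", "block", "yield", "is_check")
  .stopIf(!all(need %in% names(pheno)),
          "phenotype table needs columns ", paste(need, collapse = ", "))
  chk <- pheno[as.logical(pheno$is_check), , drop = FALSE]
  blockKey <- interaction(pheno$env, pheno$block, drop = TRUE, sep = ":")
  chkKey <- interaction(chk$env, chk$block, drop = TRUE, sep = ":")
  missing <- setdiff(levels(blockKey), unique(as.character(chkKey)))
  .stopIf(length(missing) > 0,
          "missing checks: no check plots in block(s) ",
          paste(missing, collapse = ", "))
  envMean <- tapply(chk$yield, chk$env, mean)
  blkMean <- tapply(chk$yield, as.character(chkKey), mean)
  adj <- as.numeric(blkMean[as.character(blockKey)]) -
    as.numeric(envMean[pheno$env])
  out <- pheno
  out$yield <- pheno$yield - adj
  out <- out[!as.logical(out$is_check), , drop = FALSE]
  out$is_check <- NULL
  rownames(out) <- NULL
  out
}

#' Bonferroni threshold on the -log10 p scale
#'
#' @param alphaLevel family-wise error rate.
#' @param nMarkers number of tests.
#' @return `-log10(alphaLevel / nMarkers)`.
#' @examples
#' bonferroniThreshold(0.05, 4312)
#' @export
bonferroniThreshold <- function(alphaLevel, nMarkers) {
  .stopIf(alphaLevel <= 0 || alphaLevel >= 1,
          "alphaLevel must be in (0, 1)")
  -log10(alphaLevel / nMarkers)
}

#' REML fit of the polygenic null model
#'
#' Fits y = X beta + psi + e with psi ~ N(0, K s2p), e ~ N(0, I s2e) by
#' restricted maximum likelihood, profiling the single ratio s2p/s2e over a
#' bounded one-dimensional search after rotating by the eigenvectors of K.
#'
#' @param y numeric response (named by RIL id when available).
#' @param K a [Kinship-class] object or a symmetric PSD matrix aligned
#'   with `y`.
#' @param X fixed-effect design matrix (default: intercept only). Block
#'   effects are normally removed beforehand by [adjustByChecks()].
#' @return A `VarComp` list: `sigma2_psi`, `sigma2_eps`, `loglik`
#'   (restricted), `beta`, `lambda` (the fitted ratio) plus cached
#'   decompositions reused by [testMarker()].
#' @export
fitNull <- function(y, K, X = NULL) {
  if (is(K, "Kinship")) K <- kinshipMatrix(K)
  y <- stats::setNames(as.numeric(y), names(y))
  n <- length(y)
  .stopIf(n < 3, "degenerate input: need at least 3 observations")
  .stopIf(nrow(K) != n || ncol(K) != n, "K must be n x n, aligned with y")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  eig <- eigen(K, symmetric = TRUE)
  .stopIf(min(eig$values) < -1e-6 * max(abs(eig$values), 1),
          "numerical error: K is not positive semi-definite")
  d <- pmax(eig$values, 0)
  Ut <- t(eig$vectors)
  yt <- drop(Ut %*% y)
  Xt <- Ut %*% X
  obj <- function(t) -.diagReml(yt, Xt, d, exp(t))$loglik
  opt <- stats::optimize(obj, interval = .RATIO_LOG_BOUNDS, tol = 1e-8)
  lambda <- exp(opt$minimum)
  ## the boundary lambda -> 0 is outside the log grid; keep it if better
  fit0 <- .diagReml(yt, Xt, d, 0)
  fitL <- .diagReml(yt, Xt, d, lambda)
  if (fit0$loglik > fitL$loglik) {
    lambda <- 0
    fitL <- fit0
  }
  w <- 1 / (lambda * d + 1)
  Tmat <- sqrt(w) * Ut          # V0^{-1/2}: whitening transform
  structure(list(
    sigma2_psi = lambda * fitL$s2e,
    sigma2_eps = fitL$s2e,
    sigma2_alpha = NA_real_,
    loglik = fitL$loglik,
    beta = fitL$beta,
    lambda = lambda,
    n = n, p = ncol(X),
    y = y, X = X, K = K,
    ytil = drop(Tmat %*% y),
    Xtil = Tmat %*% X,
    Tmat = Tmat,
    logdetV0 = -sum(log(w))
  ), class = "VarComp")
}

#' @export
print.VarComp <- function(x, ...) {
  cat("VarComp (REML): sigma2_psi =", signif(x$sigma2_psi, 4),
      "| sigma2_eps =", signif(x$sigma2_eps, 4),
      "| ratio =", signif(x$lambda, 4),
      "| logLik =", signif(x$loglik, 6), "\n")
  invisible(x)
}

## Core marker test against a fitted null; Z restricted to segregating
## family columns, rows aligned with nullFit$y.
.testMarkerCore <- function(Zseg, nullFit, method, pvalueLaw) {
  if (is.null(Zseg) || ncol(Zseg) == 0 || all(Zseg == 0)) {
    return(list(lrt = 0, pvalue = 1, neglog10p = 0,
                family_effects = numeric(0), family_effects_gls = numeric(0),
                n_families = 0L, sigma2_alpha = 0, loglik1 = nullFit$loglik))
  }
  L0 <- nullFit$loglik
  ## unshrunk fixed-effect (GLS) estimates under the null covariance:
  ## OLS of the whitened response on [X, Z]; never exactly zero, which
  ## matters downstream when effect panels are decomposed by SVD
  Ztil <- nullFit$Tmat %*% Zseg
  glsFit <- stats::lm.fit(cbind(nullFit$Xtil, Ztil), nullFit$ytil)
  glsEff <- glsFit$coefficients[-seq_len(ncol(nullFit$Xtil))]
  names(glsEff) <- colnames(Zseg)
  if (method == "fast") {
    prep <- .wbPrep(nullFit$ytil, nullFit$Xtil, Ztil)
    obj <- function(t) -.wbReml(prep, exp(t), nullFit$logdetV0)$loglik
    opt <- stats::optimize(obj, interval = .RATIO_LOG_BOUNDS, tol = 1e-8)
    la <- exp(opt$minimum)
    fit1 <- .wbReml(prep, la, nullFit$logdetV0)
    if (fit1$loglik < L0) {      # boundary: marker variance at zero
      la <- 0
      fit1 <- list(loglik = L0, beta = nullFit$beta,
                   s2e = nullFit$sigma2_eps)
    }
    L1 <- fit1$loglik
    if (la > 0) {
      rtil <- nullFit$ytil - nullFit$Xtil %*% fit1$beta
      t1 <- crossprod(Ztil, rtil)
      alpha <- drop(la * (t1 - la * prep$ZtZ %*% fit1$Mi %*% t1))
    } else alpha <- rep(0, ncol(Zseg))
    s2a <- la * fit1$s2e
  } else {
    y <- nullFit$y; X <- nullFit$X; K <- nullFit$K
    start <- c(log(max(nullFit$lambda, 1e-4)), log(1e-2))
    obj <- function(par) {
      par <- pmin(pmax(par, .RATIO_LOG_BOUNDS[1]), .RATIO_LOG_BOUNDS[2])
      -.denseReml(y, X, K, Zseg, exp(par[1]), exp(par[2]))$loglik
    }
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    par <- pmin(pmax(opt$par, .RATIO_LOG_BOUNDS[1]), .RATIO_LOG_BOUNDS[2])
    lp <- exp(par[1]); la <- exp(par[2])
    fit1 <- .denseReml(y, X, K, Zseg, lp, la)
    L1 <- max(fit1$loglik, L0)
    ## BLUP at the optimum: alpha = la * Z' Vr^-1 (y - X beta)
    n <- length(y)
    Vr <- diag(n) + lp * K + la * tcrossprod(Zseg)
    r <- y - drop(X %*% fit1$beta)
    alpha <- drop(la * crossprod(Zseg, solve(Vr, r)))
    s2a <- la * fit1$s2e
  }
  lrt <- max(0, 2 * (L1 - L0))
  pv <- .lrtPvalue(lrt, pvalueLaw)
  names(alpha) <- colnames(Zseg)
  list(lrt = lrt, pvalue = pv$pvalue, neglog10p = pv$neglog10p,
       family_effects = alpha, family_effects_gls = glsEff,
       n_families = ncol(Zseg), sigma2_alpha = s2a, loglik1 = max(L1, L0))
}

#' Likelihood-ratio test of one marker
#'
#' Compares the restricted log-likelihood of the model with the
#' marker-by-family term Z alpha (L1) against the polygenic null (L0):
#' LRT = -2(L0 - L1), clipped at zero. Because the marker variance is
#' tested on the boundary of its parameter space, p-values default to the
#' survival function of a chi-square distribution with 0.5 degrees of
#' freedom (equivalently a gamma with shape 1/4 and scale 2); the 50:50
#' \{chi2_0, chi2_1\} mixture is available as `pvalueLaw = "mixture_0_1"`.
#'
#' @param incidence a [ParentalIncidence-class] for the marker, rows
#'   aligned with the observations of `nullFit`.
#' @param nullFit a `VarComp` from [fitNull()].
#' @param method `"full"` re-optimizes both variance ratios per marker
#'   (dense likelihood evaluations); `"fast"` keeps the polygenic ratio at
#'   its null estimate and profiles only the marker variance through the
#'   Woodbury identity.
#' @param pvalueLaw `"chi2_0.5df"` (default) or `"mixture_0_1"`.
#' @return list with `marker_id`, `lrt`, `pvalue`, `neglog10p`,
#'   `family_effects` (BLUPs, kg/ha per founder-allele dosage, one per
#'   segregating family), `n_families`, `sigma2_alpha`.
#' @export
testMarker <- function(incidence, nullFit,
                       method = c("full", "fast"),
                       pvalueLaw = c("chi2_0.5df", "mixture_0_1")) {
  stopifnot(is(incidence, "ParentalIncidence"),
            inherits(nullFit, "VarComp"))
  method <- match.arg(method)
  pvalueLaw <- match.arg(pvalueLaw)
  .stopIf(nrow(incidence@Z) != nullFit$n,
          "incidence rows must align with the null-fit observations")
  Zseg <- incidence@Z[, incidence@segregating, drop = FALSE]
  out <- .testMarkerCore(Zseg, nullFit, method, pvalueLaw)
  out$marker_id <- incidence@markerId
  out
}

## Build per-RIL responses for one environment from a (check-adjusted)
## phenotype table: mean over a RIL's plots in that environment.
.responseByRil <- function(pheno, env = NULL) {
  pheno <- pheno[.plotRows(pheno), , drop = FALSE]
  if (!is.null(env)) pheno <- pheno[pheno$env == env, , drop = FALSE]
  else {
    ue <- unique(pheno$env)
    .stopIf(length(ue) > 1,
            "phenotype table spans several environments: pass env=")
  }
  .stopIf(nrow(pheno) == 0, "no phenotype records for the requested scan")
  tapply(pheno$yield, pheno$ril_id, mean)
}

## Subset a kinship matrix to a RIL set and restore mean(diag) = 1.
.subsetKinship <- function(K, ids) {
  Ks <- K[ids, ids, drop = FALSE]
  Ks / mean(diag(Ks))
}

#' Genome-wide multiparental association scan
#'
#' Tests every marker (or a subset) against the polygenic null in one
#' environment, or against an arbitrary per-RIL phenotype such as the
#' Finlay-Wilkinson slope. The Bonferroni threshold is computed from the
#' number of markers actually tested.
#'
#' @param geno a [NamGenotypes-class] without missing calls.
#' @param pheno either a check-adjusted phenotype table (see
#'   [adjustByChecks()]) or a numeric vector named by RIL id.
#' @param env environment to scan when `pheno` covers several.
#' @param alphaLevel family-wise error rate for the Bonferroni threshold.
#' @param kinship optional precomputed [Kinship-class] for `geno` (it is
#'   subset and rescaled to the phenotyped RILs); computed when missing.
#' @param markers marker ids or indices to test (default: all).
#' @param method,pvalueLaw passed to the marker test; scans default to the
#'   fast profiled mode.
#' @param effects which per-family allele-effect estimates to store:
#'   shrinkage BLUPs (`"blup"`, default) or unshrunk whitened fixed-effect
#'   estimates (`"gls"`), which the GEI meta-analysis uses because
#'   boundary-shrunk BLUPs collapse to exact zeros.
#' @return A [ScanResult-class] object.
#' @export
genomeScan <- function(geno, pheno, env = NULL, alphaLevel = 0.05,
                       kinship = NULL, markers = NULL,
                       method = c("fast", "full"),
                       pvalueLaw = c("chi2_0.5df", "mixture_0_1"),
                       effects = c("blup", "gls")) {
  stopifnot(is(geno, "NamGenotypes"))
  method <- match.arg(method)
  pvalueLaw <- match.arg(pvalueLaw)
  effects <- match.arg(effects)
  codes <- genoCodes(geno)
  .stopIf(anyNA(codes), "missing genotype calls: run imputeMissing() first")

  y <- if (is.numeric(pheno) && !is.null(names(pheno))) pheno
       else .responseByRil(pheno, env)
  y <- y[!is.na(y)]
  ids <- intersect(rilIds(geno), names(y))
  .stopIf(length(ids) < 3, "fewer than 3 RILs with both genotype and phenotype")
  codes <- codes[ids, , drop = FALSE]
  fam <- familyIds(geno)[match(ids, rilIds(geno))]
  famLevels <- unique(fam)
  y <- y[ids]

  K <- if (is.null(kinship)) {
    kinshipMatrix(computeKinship(NamGenotypes(codes, fam, markerMap(geno))))
  } else {
    .subsetKinship(kinshipMatrix(kinship), ids)
  }
  nullFit <- fitNull(y, K)

  if (is.null(markers)) markers <- seq_len(ncol(codes))
  if (is.character(markers)) markers <- match(markers, colnames(codes))
  .stopIf(anyNA(markers), "unknown marker in `markers`")

  mids <- colnames(codes)[markers]
  res <- vector("list", length(markers))
  effMat <- matrix(NA_real_, length(famLevels), length(markers),
                   dimnames = list(famLevels, mids))
  for (i in seq_along(markers)) {
    z <- .markerZ(codes[, markers[i]], fam, famLevels)
    Zseg <- z$Z[, z$segregating, drop = FALSE]
    t <- .testMarkerCore(Zseg, nullFit, method, pvalueLaw)
    res[[i]] <- c(lrt = t$lrt, pvalue = t$pvalue,
                  neglog10p = t$neglog10p, n_families = t$n_families)
    eff <- if (effects == "blup") t$family_effects else t$family_effects_gls
    if (length(eff)) effMat[names(eff), i] <- eff
  }
  res <- as.data.frame(do.call(rbind, res))
  map <- markerMap(geno)[markers, , drop = FALSE]
  envLabel <- if (!is.null(env)) env
              else if (is.numeric(pheno)) "phenotype"
              else unique(pheno$env[.plotRows(pheno)])[1]
  results <- data.frame(marker_id = mids, chrom = map$chrom, pos = map$pos,
                        env = envLabel, res, row.names = NULL)
  new("ScanResult", results = results, familyEffects = effMat,
      threshold = bonferroniThreshold(alphaLevel, length(markers)),
      environment = as.character(envLabel), alphaLevel = alphaLevel)
}
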