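## Restricted maximum likelihood machinery for the multiparental mixed
## model  y = X beta + Z alpha + psi + e,  alpha ~ N(0, I s2a),
## psi ~ N(0, K s2p), e ~ N(0, I s2e).
##
## All likelihoods use the same REML convention (fixed effects profiled,
## the constant log|X'X| omitted — it cancels in every likelihood-ratio
## statistic because X is shared between null and alternative):
##   l = -1/2 [ (n-p)(log(2 pi s2hat) + 1) + log|Vr| + log|X' Vr^-1 X| ]
## where Vr = V / s2e is the relative covariance and s2hat = RSS/(n-p).
##
## The null model is profiled over the single ratio lambda = s2p/s2e using
## the eigendecomposition of K (the covariance is diagonal after rotating
## by K's eigenvectors). Marker models add lambda_a = s2a/s2e on the
## low-rank term Z Z'; the fast path keeps lambda fixed at its null
## estimate and exploits the Woodbury identity, so each marker costs one
## small f x f problem (f = number of segregating families). The full path
## re-optimizes both ratios with dense Cholesky likelihood evaluations.

## ---- diagonal path (null model after eigen-rotation) ----

.diagReml <- function(yt, Xt, d, lambda) {
  n <- length(yt)
  p <- ncol(Xt)
  w <- 1 / (lambda * d + 1)
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  XtWy <- crossprod(XtW, yt)
  cX <- chol(XtWX)
  beta <- backsolve(cX, backsolve(cX, XtWy, transpose = TRUE))
  r <- yt - Xt %*% beta
  rss <- max(sum(w * r^2), 1e-300)
  s2 <- rss / (n - p)
  logdetVr <- -sum(log(w))
  logdetX <- 2 * sum(log(diag(cX)))
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + logdetVr + logdetX)
  list(loglik = ll, beta = drop(beta), s2e = s2, rss = rss, w = w)
}

## ---- Woodbury path (marker term at fixed polygenic ratio) ----

## Precompute the cross-products that do not depend on lambda_a.
.wbPrep <- function(ytil, Xtil, Ztil) {
  YX <- cbind(ytil, Xtil)
  list(S = crossprod(YX), Za = crossprod(Ztil, YX),
       ZtZ = crossprod(Ztil), n = nrow(YX), p = ncol(Xtil))
}

.wbReml <- function(prep, la, logdetV0) {
  f <- nrow(prep$ZtZ)
  M <- diag(f) + la * prep$ZtZ
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(list(loglik = -Inf))
  Mi <- chol2inv(cM)
  Q <- prep$S - la * crossprod(prep$Za, Mi %*% prep$Za)
  n <- prep$n; p <- prep$p
  yVy <- Q[1, 1]
  XVy <- Q[-1, 1]
  XVX <- Q[-1, -1, drop = FALSE]
  cX <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(cX)) return(list(loglik = -Inf))
  beta <- backsolve(cX, backsolve(cX, XVy, transpose = TRUE))
  rss <- max(yVy - sum(beta * XVy), 1e-300)
  s2 <- rss / (n - p)
  logdetVr <- logdetV0 + 2 * sum(log(diag(cM)))
  logdetX <- 2 * sum(log(diag(cX)))
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + logdetVr + logdetX)
  list(loglik = ll, beta = drop(beta), s2e = s2, rss = rss, Mi = Mi)
}

## ---- dense path (full re-optimization of both ratios) ----

.denseReml <- function(y, X, K, Z, lp, la) {
  n <- length(y)
  p <- ncol(X)
  Vr <- diag(n) + lp * K
  if (!is.null(Z) && la > 0) Vr <- Vr + la * tcrossprod(Z)
  R <- tryCatch(chol(Vr), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  A <- backsolve(R, cbind(y, X), transpose = TRUE)
  Q <- crossprod(A)
  yVy <- Q[1, 1]
  XVy <- Q[-1, 1]
  XVX <- Q[-1, -1, drop = FALSE]
  cX <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(cX)) return(list(loglik = -Inf))
  beta <- backsolve(cX, backsolve(cX, XVy, transpose = TRUE))
  rss <- max(yVy - sum(beta * XVy), 1e-300)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                  2 * sum(log(diag(R))) + 2 * sum(log(diag(cX))))
  list(loglik = ll, beta = drop(beta), s2e = s2, rss = rss)
}

## search bounds for variance ratios, on the log scale
.RATIO_LOG_BOUNDS <- log(c(1e-5, 1e5))

## p-value of a boundary LRT under the configured null law
.lrtPvalue <- function(lrt, law = c("chi2_0.5df", "mixture_0_1")) {
  law <- match.arg(law)
  if (lrt <= 0) return(list(pvalue = 1, neglog10p = 0))
  if (law == "chi2_0.5df") {
    logp <- stats::pchisq(lrt, df = 0.5, lower.tail = FALSE, log.p = TRUE)
  } else {
    logp <- log(0.5) +
      stats::pchisq(lrt, df = 1, lower.tail = FALSE, log.p = TRUE)
  }
  nl <- .neglog10FromLogP(logp)
  list(pvalue = max(exp(logp), 1e-320), neglog10p = nl)
}
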