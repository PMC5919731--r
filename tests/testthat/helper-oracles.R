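## Independent oracles and small fixture builders shared across tests.

## best rank-1 approximation by alternating least squares (oracle for the
## SVD route; random restarts guard against bad starts)
alsRank1 <- function(E, tol = 1e-12, maxIters = 50000, restarts = 3) {
  best <- NULL
  bestRss <- Inf
  for (r in seq_len(restarts)) {
    set.seed(100 + r)
    u <- rnorm(nrow(E))
    G <- tcrossprod(u, rep(0, ncol(E)))
    for (i in seq_len(maxIters)) {
      v <- drop(crossprod(E, u)) / sum(u^2)
      u <- drop(E %*% v) / sum(v^2)
      Gnew <- tcrossprod(u, v)
      if (max(abs(Gnew - G)) < tol) {
        G <- Gnew
        break
      }
      G <- Gnew
    }
    rss <- sum((E - G)^2)
    if (rss < bestRss) {
      bestRss <- rss
      best <- G
    }
  }
  best
}

## weighted least squares parent effects by dense normal equations
wlsDeltaOracle <- function(A, N, parent) {
  obs <- which(N > 0 & !is.na(A))
  a <- A[obs]
  w <- N[obs]
  famOfCell <- rownames(A)[row(A)[obs]]
  W <- outer(parent[famOfCell], unique(parent), "==") * 1
  delta <- solve(t(W) %*% (W * w), t(W) %*% (w * a))
  setNames(drop(delta), unique(parent))
}

## exhaustive Ward-D agglomeration via the Lance-Williams update on
## (non-squared) Euclidean distances; returns merge heights and the leaf
## sets merged at each step
bruteWard <- function(X) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    pairs <- which(upper.tri(D), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] %in% active & pairs[, 2] %in% active, ,
                   drop = FALSE]
    vals <- D[pairs]
    k <- which.min(vals)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    heights[s] <- D[i, j]
    merges[[s]] <- sort(c(clusters[[i]], clusters[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    for (m in setdiff(active, c(i, j))) {
      nk <- sizes[m]
      D[i, m] <- D[m, i] <-
        ((ni + nk) * D[i, m] + (nj + nk) * D[j, m] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

## leaf sets merged at each step of an hclust tree, for comparison
hclustMerges <- function(hc) {
  n <- length(hc$order)
  out <- vector("list", n - 1)
  members <- function(k) if (k < 0) -k else out[[k]]
  for (s in seq_len(n - 1)) {
    out[[s]] <- sort(c(members(hc$merge[s, 1]), members(hc$merge[s, 2])))
  }
  out
}

## small trial over the first nE preset environments
presetTrial <- function(nE, residual_sd = 0, block_sd = 0,
                        n_blocks = 2, presence = NULL) {
  envs <- soynamEnvironments()
  e <- envs$env[seq_len(nE)]
  trialDesign(environments = e,
              env_effects = setNames(envs$mean_yield[seq_len(nE)], e),
              presence = presence, n_blocks_per_env = n_blocks,
              block_sd = block_sd, residual_sd = residual_sd)
}

## compact NAM population for unit tests
smallPop <- function(n_families = 4, n_rils = 25, n_markers = 40,
                     seed = 11) {
  simulateGenotypes(namDesign(n_families = n_families,
                              n_rils_per_family = n_rils,
                              n_markers = n_markers,
                              n_chromosomes = 2, seed = seed))
}
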