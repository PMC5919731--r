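test_that("check adjustment removes block offsets and drops checks", {
  base <- expand.grid(ril_id = paste0("R", 1:4), env = c("E1", "E2"),
                      block = 1:2, stringsAsFactors = FALSE)
  base$yield <- 1000
  base$is_check <- FALSE
  chk <- expand.grid(ril_id = "check_1", env = c("E1", "E2"), block = 1:2,
                     stringsAsFactors = FALSE)
  chk$yield <- 900
  chk$is_check <- TRUE
  ## all checks equal: nothing changes
  adj <- adjustByChecks(rbind(base, chk))
  expect_equal(adj$yield, base$yield, tolerance = 1e-12)
  expect_false(any(adj$ril_id == "check_1"))
  ## one block's checks +100: that block's RILs come down by 100
  chk2 <- chk
  chk2$yield[chk2$env == "E1" & chk2$block == 1] <- 1000
  adj2 <- adjustByChecks(rbind(base, chk2))
  shifted <- adj2$env == "E1" & adj2$block == 1
  expect_equal(adj2$yield[shifted], rep(950, 4), tolerance = 1e-12)
  expect_equal(adj2$yield[adj2$env == "E1" & adj2$block == 2],
               rep(1050, 4), tolerance = 1e-12)
  ## a block without checks is a named error
  noChk <- rbind(base, chk[chk$block == 1, ])
  expect_error(adjustByChecks(noChk), "E1:2|E2:2")
})

test_that("check adjustment shrinks the variance of noisy block effects", {
  g <- smallPop()
  td <- presetTrial(2, residual_sd = 100, block_sd = 400, n_blocks = 4)
  sim <- simulatePhenotypes(g, td, seed = 31)
  adj <- adjustByChecks(sim$pheno)
  raw <- sim$pheno[!sim$pheno$is_check, ]
  for (e in td$environments) {
    expect_lt(var(adj$yield[adj$env == e]),
              var(raw$yield[raw$env == e]))
  }
})

test_that("half-df chi-square survival matches gamma quadrature", {
  grid <- c(0.05, 0.5, 1, 2.7, 5, 10, 20)
  for (q in grid) {
    byQuad <- integrate(function(x) dgamma(x, shape = 0.25, scale = 2),
                        lower = q, upper = Inf, rel.tol = 1e-12)$value
    expect_equal(pchisq(q, df = 0.5, lower.tail = FALSE), byQuad,
                 tolerance = 1e-8)
  }
})

test_that("Bonferroni thresholds follow the closed form", {
  expect_equal(bonferroniThreshold(0.05, 4312), 4.9357, tolerance = 1e-4)
  expect_equal(bonferroniThreshold(0.05, 1), 1.30103, tolerance = 1e-5)
})

test_that("null REML finds no polygenic variance in pure noise", {
  ## pure-noise phenotypes against a real family-structured K: the fitted
  ## polygenic-to-residual ratio should sit at or near the zero boundary
  g <- smallPop(n_families = 4, n_rils = 20, n_markers = 60, seed = 19)
  K <- kinshipMatrix(computeKinship(g))
  lams <- vapply(1:50, function(s) {
    set.seed(s)
    fitNull(rnorm(80), K)$lambda
  }, numeric(1))
  expect_lt(median(lams), 0.1)
})

test_that("null REML recovers a known variance ratio", {
  g <- smallPop(n_families = 5, n_rils = 60, n_markers = 80, seed = 21)
  K <- kinshipMatrix(computeKinship(g))
  n <- nrow(K)
  L <- t(chol(K + 1e-6 * diag(n)))
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    y <- 2 * drop(L %*% rnorm(n)) + rnorm(n)   # ratio s2p/s2e = 4
    lam <- fitNull(y, K)$lambda
    if (lam >= 2 && lam <= 8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("monomorphic markers test as exactly null", {
  g <- smallPop(n_families = 2, n_rils = 15, n_markers = 20)
  codes <- genoCodes(g)
  codes[, 1] <- 2
  g2 <- NamGenotypes(codes, familyIds(g))
  set.seed(5)
  y <- setNames(rnorm(nrow(codes)), rilIds(g2))
  nf <- fitNull(y, kinshipMatrix(computeKinship(g2)))
  t1 <- testMarker(recodeParentalOrigin(g2, 1), nf)
  expect_identical(t1$lrt, 0)
  expect_identical(t1$pvalue, 1)
  expect_length(t1$family_effects, 0)
})

test_that("scan LRT is invariant to shifting and rescaling the phenotype", {
  g <- smallPop(n_families = 3, n_rils = 20, n_markers = 15)
  td <- presetTrial(2, residual_sd = 300, block_sd = 50)
  sim <- simulatePhenotypes(g, td, qtls = list(qtlSpec(7, 200)), seed = 9)
  adj <- adjustByChecks(sim$pheno)
  s1 <- scanTable(genomeScan(g, adj, env = td$environments[1]))
  adj2 <- adj
  adj2$yield <- 2 * adj$yield + 500
  s2 <- scanTable(genomeScan(g, adj2, env = td$environments[1]))
  expect_equal(s1$lrt, s2$lrt, tolerance = 1e-5)
})

test_that("full and fast marker tests agree on signal and effect signs", {
  g <- smallPop(n_families = 3, n_rils = 25, n_markers = 20)
  td <- presetTrial(2, residual_sd = 250)
  sim <- simulatePhenotypes(g, td, qtls = list(qtlSpec(4, 300)), seed = 13)
  adj <- adjustByChecks(sim$pheno)
  e1 <- td$environments[1]
  y <- tapply(adj$yield[adj$env == e1], adj$ril_id[adj$env == e1], mean)
  ids <- intersect(rilIds(g), names(y))
  sub <- NamGenotypes(genoCodes(g)[ids, ], familyIds(g)[match(ids, rilIds(g))],
                      markerMap(g))
  nf <- fitNull(y[ids], computeKinship(sub))
  pin <- recodeParentalOrigin(sub, 4)
  tFast <- testMarker(pin, nf, method = "fast")
  tFull <- testMarker(pin, nf, method = "full")
  expect_gt(tFast$lrt, bonferroniThreshold(0.05, 20))
  expect_gt(tFull$lrt, 0.5 * tFast$lrt)
  expect_lt(tFull$lrt, 2 * tFast$lrt + 5)
  expect_true(all(tFast$family_effects > 0))
  expect_true(all(tFull$family_effects > 0))
  ## unshrunk GLS effects approximate the injected 300 kg/ha better than 2 SE
  expect_lt(max(abs(tFast$family_effects_gls - 300)), 200)
})

test_that("a one-family population reduces to a single-population scan", {
  g <- smallPop(n_families = 2, n_rils = 40, n_markers = 12)
  codes <- genoCodes(g)[familyIds(g) == "F1", ]
  g1 <- NamGenotypes(codes, rep("F1", nrow(codes)))
  set.seed(77)
  dos <- 2 - codes[, 5]
  y <- setNames(100 * dos + rnorm(nrow(codes), 0, 50), rownames(codes))
  sc <- genomeScan(g1, y)
  fe <- familyEffects(sc)
  expect_identical(nrow(fe), 1L)
  expect_identical(which.max(scanTable(sc)$neglog10p), 5L)
})

test_that("genome scans are deterministic and carry the Bonferroni line", {
  g <- smallPop(n_families = 2, n_rils = 15, n_markers = 10)
  set.seed(3)
  y <- setNames(rnorm(30, 3000, 100), rilIds(g))
  s1 <- genomeScan(g, y, alphaLevel = 0.05)
  s2 <- genomeScan(g, y, alphaLevel = 0.05)
  expect_identical(scanTable(s1), scanTable(s2))
  expect_equal(scanThreshold(s1), -log10(0.05 / 10), tolerance = 1e-12)
  s3 <- genomeScan(g, y, markers = 1)
  expect_equal(scanThreshold(s3), 1.30103, tolerance = 1e-5)
})
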