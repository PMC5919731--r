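mkPheno <- function(yields, envs, rils) {
  data.frame(ril_id = rep(rils, times = length(envs)),
             env = rep(envs, each = length(rils)),
             block = 1L,
             yield = as.vector(yields),
             is_check = FALSE)
}

test_that("environment index is the centered vector of environment means", {
  ph <- mkPheno(cbind(c(2900, 3100), c(4800, 5200)), c("E1", "E2"),
                c("R1", "R2"))
  idx <- environmentIndex(ph)
  expect_equal(idx$mean, c(3000, 5000))
  expect_equal(idx$centered, c(-1000, 1000))
  expect_equal(sum(idx$centered), 0)
  expect_error(environmentIndex(ph[ph$env == "E1", ]), "2 environments")
})

test_that("the mean genotype has slope 1 and a constant genotype slope 0", {
  means <- c(2500, 3200, 4100, 5000)
  y <- rbind(means,                       # tracks the environment exactly
             rep(3300, 4),                # static genotype
             2 * means - mean(means))     # hypersensitive genotype
  ph <- mkPheno(y, paste0("E", 1:4), c("track", "flat", "steep"))
  fw <- fwTable(fwRegression(ph))
  expect_equal(fw$slope[fw$ril_id == "track"], 1, tolerance = 1e-12)
  expect_equal(fw$deviation_mse[fw$ril_id == "track"], 0, tolerance = 1e-10)
  expect_equal(fw$slope[fw$ril_id == "flat"], 0, tolerance = 1e-12)
  expect_equal(fw$slope[fw$ril_id == "steep"], 2, tolerance = 1e-12)
})

test_that("per-RIL OLS matches the closed form", {
  ## yields (-2,0,2)*s + mu against centered index (-1000,0,1000)
  for (s in c(50, 300)) {
    ph <- mkPheno(cbind(c(-2 * s + 4000, 3000), c(4000, 3000),
                        c(2 * s + 4000, 3000)),
                  paste0("E", 1:3), c("A", "B"))
    idx <- data.frame(env = paste0("E", 1:3), mean = c(3000, 3500, 4000),
                      centered = c(-1000, 0, 1000))
    fw <- fwTable(fwRegression(ph, index = idx))
    expect_equal(fw$slope[fw$ril_id == "A"], 0.002 * s, tolerance = 1e-12)
    expect_equal(fw$intercept[fw$ril_id == "A"], 4000, tolerance = 1e-9)
  }
})

test_that("slopes are undefined below the environment minimum", {
  ph <- mkPheno(cbind(c(3000, 2900), c(3500, 3600), c(4000, NA)),
                paste0("E", 1:3), c("R1", "R2"))
  ph <- ph[!is.na(ph$yield), ]
  fw <- fwTable(fwRegression(ph))
  expect_false(is.na(fw$slope[fw$ril_id == "R1"]))
  expect_true(is.na(fw$slope[fw$ril_id == "R2"]))
  expect_identical(fw$n_env[fw$ril_id == "R2"], 2)
})

test_that("balanced fits anchor the mean slope at one", {
  g <- smallPop()
  td <- presetTrial(5, residual_sd = 250, block_sd = 80)
  sim <- simulatePhenotypes(g, td, sens = sensitivitySpec(slope_sd = 0.2),
                            seed = 17)
  fw <- fwTable(fwRegression(adjustByChecks(sim$pheno)))
  expect_equal(mean(fw$slope), 1, tolerance = 1e-8)
})

test_that("slopes respond continuously to dropping one environment", {
  g <- smallPop(n_families = 2, n_rils = 10, n_markers = 10)
  td <- presetTrial(5, residual_sd = 100)
  sim <- simulatePhenotypes(g, td, sens = sensitivitySpec(slope_sd = 0.1),
                            seed = 23)
  adj <- adjustByChecks(sim$pheno)
  fwAll <- fwTable(fwRegression(adj))
  drop1 <- adj[adj$env != td$environments[5], ]
  fwDrop <- fwTable(fwRegression(drop1))
  expect_false(anyNA(fwDrop$slope))
  expect_lt(max(abs(fwAll$slope - fwDrop$slope)), 0.5)
})

test_that("a zero-variance slope phenotype yields an all-null scan", {
  g <- smallPop(n_families = 2, n_rils = 12, n_markers = 8)
  tab <- data.frame(ril_id = rilIds(g), family_id = familyIds(g),
                    slope = 1, intercept = 3000, deviation_mse = 0,
                    n_env = 5L)
  idx <- data.frame(env = paste0("E", 1:5), mean = 3000 + (1:5) * 100,
                    centered = (1:5) * 100 - 300)
  fw <- new("FwFit", table = tab, index = idx)
  sc <- scanTable(stabilityGwas(g, fw))
  expect_true(all(sc$lrt == 0))
  expect_true(all(sc$pvalue == 1))
})

test_that("adjusted R2 of slope on dosage matches a no-noise construction", {
  g <- smallPop(n_families = 2, n_rils = 100, n_markers = 10, seed = 31)
  codes <- genoCodes(g)
  dos <- 2 - codes[, 4]
  n <- length(dos)
  ## residual orthogonal to the design [1, family-wise dosage], scaled so
  ## the regression explains exactly a fraction rho of the slope variance
  fam <- familyIds(g)
  Zfam <- cbind(dos * (fam == "F1"), dos * (fam == "F2"))
  set.seed(32)
  e <- rnorm(n)
  Q <- qr.Q(qr(cbind(1, Zfam)))
  e <- drop(e - Q %*% crossprod(Q, e))
  sig <- 0.1 * (dos - mean(dos))
  rho <- 0.6
  e <- e * sqrt(sum(sig^2) * (1 - rho) / (rho * sum(e^2)))
  slope <- 1 + sig + e
  tab <- data.frame(ril_id = rilIds(g), family_id = fam,
                    slope = slope, intercept = 3000, deviation_mse = 0,
                    n_env = 5L)
  idx <- data.frame(env = paste0("E", 1:3), mean = c(2900, 3000, 3100),
                    centered = c(-100, 0, 100))
  fw <- new("FwFit", table = tab, index = idx)
  sc <- scanTable(stabilityGwas(g, fw))
  adjExpected <- 1 - (1 - rho) * (n - 1) / (n - 2 - 1)
  expect_equal(sc$adj_r2[4], adjExpected, tolerance = 1e-6)
  expect_lt(abs(sc$adj_r2[4] - rho), 0.02)
})
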