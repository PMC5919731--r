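## Published summaries of the SoyNAM multi-environment yield trial used as
## the "soynam-like" simulation preset: 18 location-year environments, their
## average RIL grain yield (kg/ha), the number of RILs with plot data and the
## number of check plots.

#' SoyNAM-like environment summary table
#'
#' The 18 location-year environments of the reference soybean NAM yield
#' trial, with average RIL grain yield, number of RILs with non-missing plot
#' data, and number of check plots. Used by [soynamTrialDesign()] to build a
#' realistic unbalanced multi-environment trial design.
#'
#' @return data.frame with columns `env`, `location`, `year`, `mean_yield`
#'   (kg/ha), `n_rils`, `n_checks`.
#' @examples
#' soynamEnvironments()[, c("env", "mean_yield")]
#' @export
soynamEnvironments <- function() {
  data.frame(
    env = c("IL2011", "NE2011",
            "IA2012", "IL2012", "IN2012", "KS2012", "MI2012", "MO2012",
            "NE2012", "OHmc2012", "OHmi2012",
            "IA2013", "IL2013", "IN2013", "KS2013", "MO2013",
            "OHmc2013", "OHmi2013"),
    location = c("IL", "NE", "IA", "IL", "IN", "KS", "MI", "MO", "NE",
                 "OHmc", "OHmi", "IA", "IL", "IN", "KS", "MO", "OHmc",
                 "OHmi"),
    year = c(2011L, 2011L, rep(2012L, 9L), rep(2013L, 7L)),
    mean_yield = c(2780, 5057,
                   2776, 3386, 4231, 3871, 2364, 3414, 4728, 3394, 2823,
                   2871, 3115, 5050, 2747, 4091, 3629, 4420),
    n_rils = c(2500L, 2500L,
               5111L, 5138L, 5041L, 3158L, 816L, 819L, 5127L, 1606L, 1626L,
               5100L, 5137L, 5136L, 3230L, 804L, 1619L, 1571L),
    n_checks = c(419L, 419L,
                 825L, 825L, 825L, 525L, 125L, 125L, 825L, 250L, 253L,
                 825L, 825L, 825L, 510L, 137L, 262L, 253L),
    stringsAsFactors = FALSE
  )
}

#' SoyNAM-like trial design preset
#'
#' Builds a [trialDesign()] whose 18 environments carry the preset mean
#' yields and whose family-by-environment presence pattern mirrors the
#' unbalancedness of the reference trial: in each environment the fraction of
#' the population with plot data determines how many families are grown
#' there (families are dropped from the end of the family list, so the same
#' families recur across partial environments, as in the real trial where
#' partial RIL sets were grown at the smaller locations).
#'
#' @param n_families number of NAM families in the simulated population.
#' @param n_blocks_per_env blocks per environment (modified augmented
#'   design without replication of RILs within environment).
#' @param block_sd,residual_sd standard deviations (kg/ha) of block and plot
#'   residual effects.
#' @param n_checks number of check cultivars replicated in every block.
#' @return A `TrialDesign` list; see [trialDesign()].
#' @examples
#' td <- soynamTrialDesign(n_families = 10)
#' range(td$env_effects)
#' @export
soynamTrialDesign <- function(n_families = 39, n_blocks_per_env = 6,
                              block_sd = 150, residual_sd = 400,
                              n_checks = 3) {
  envs <- soynamEnvironments()
  total <- max(envs$n_rils)
  presence <- matrix(0, n_families, nrow(envs),
                     dimnames = list(NULL, envs$env))
  for (j in seq_len(nrow(envs))) {
    k <- max(1L, round(n_families * envs$n_rils[j] / total))
    presence[seq_len(min(k, n_families)), j] <- 1
  }
  trialDesign(
    environments = envs$env,
    env_effects = stats::setNames(envs$mean_yield, envs$env),
    presence = presence,
    n_blocks_per_env = n_blocks_per_env,
    block_sd = block_sd,
    check_ids = paste0("check_", seq_len(n_checks)),
    residual_sd = residual_sd
  )
}
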