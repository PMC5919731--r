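## internal helpers shared across modules

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

## -log10 p from a log-scale survival probability, numerically stable far
## into the tail; capped so downstream tables stay finite.
.neglog10FromLogP <- function(logp, cap = 320) {
  out <- -logp / log(10)
  pmin(out, cap)
}

.stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)

## non-check rows of a phenotype table (tables produced by adjustByChecks
## have the checks already removed and may omit the column)
.plotRows <- function(pheno) {
  if ("is_check" %in% names(pheno)) !as.logical(pheno$is_check)
  else rep(TRUE, nrow(pheno))
}
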