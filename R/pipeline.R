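## End-to-end orchestration: impute -> recode/kinship -> check adjustment
## -> per-environment scans -> FW -> stability GWAS -> GEI meta-scan ->
## environment clustering, with all outputs written as plain TSV plus a
## JSON run manifest.

#' Pipeline configuration
#'
#' @param alphaLevel family-wise error rate for Bonferroni thresholds.
#' @param geiThreshold -log10 p flagging threshold of the GEI meta-scan.
#' @param pvalueLaw null law of the marker LRT: `"chi2_0.5df"` or
#'   `"mixture_0_1"`.
#' @param scanMethod `"fast"` or `"full"` marker-test mode.
#' @param minEnvForFw minimum environments for a defined FW slope.
#' @param seed seed recorded in the manifest.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(alphaLevel = 0.05, geiThreshold = 50,
                           pvalueLaw = "chi2_0.5df", scanMethod = "fast",
                           minEnvForFw = 3, seed = 1) {
  .stopIf(alphaLevel <= 0 || alphaLevel >= 1, "alphaLevel must be in (0,1)")
  .stopIf(geiThreshold <= 0, "geiThreshold must be > 0")
  structure(list(alphaLevel = alphaLevel, geiThreshold = geiThreshold,
                 pvalueLaw = match.arg(pvalueLaw,
                                       c("chi2_0.5df", "mixture_0_1")),
                 scanMethod = match.arg(scanMethod, c("fast", "full")),
                 minEnvForFw = as.integer(minEnvForFw),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full stability / GEI analysis pipeline
#'
#' Validates that phenotype RILs are known to the genotype object, then
#' executes the whole analysis and writes per-stage TSVs, a JSON manifest
#' (package version, seed, configuration) and a plain-text summary of the
#' markers above each threshold to `outDir`. Outputs are deterministic
#' given the inputs and configuration.
#'
#' @param geno a [NamGenotypes-class] (missing calls allowed; imputed).
#' @param pheno a raw phenotype table with check plots.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the fitted objects (`scanByEnv`,
#'   `fw`, `fwScan`, `gei`, `envTree`, `manifest`).
#' @export
runPipeline <- function(geno, pheno, outDir,
                        config = pipelineConfig()) {
  stopifnot(is(geno, "NamGenotypes"), inherits(config, "PipelineConfig"))
  orphans <- setdiff(unique(pheno$ril_id[.plotRows(pheno)]), rilIds(geno))
  .stopIf(length(orphans) > 0,
          "validation error: phenotype RIL(s) unknown to the genotypes: ",
          paste(utils::head(orphans, 10), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  message("[namgei] imputing ", sum(is.na(genoCodes(geno))),
          " missing calls")
  geno <- imputeMissing(geno)
  kin <- computeKinship(geno)
  message("[namgei] adjusting yields by checks")
  adj <- adjustByChecks(pheno)

  envs <- sort(unique(adj$env))
  message("[namgei] per-environment scans over ", length(envs),
          " environments x ", length(markerIds(geno)), " markers")
  scanByEnv <- lapply(stats::setNames(envs, envs), function(e) {
    genomeScan(geno, adj, env = e, alphaLevel = config$alphaLevel,
               kinship = kin, method = config$scanMethod,
               pvalueLaw = config$pvalueLaw)
  })
  for (e in envs)
    writeScanResult(scanByEnv[[e]], file.path(outDir,
                                              paste0("scan_", e, ".tsv")))

  message("[namgei] Finlay-Wilkinson regression")
  fw <- fwRegression(adj, geno = geno, minEnv = config$minEnvForFw)
  utils::write.table(fwTable(fw), file.path(outDir, "fw.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  fwScan <- stabilityGwas(geno, fw, alphaLevel = config$alphaLevel,
                          kinship = kin, method = config$scanMethod,
                          pvalueLaw = config$pvalueLaw)
  writeScanResult(fwScan, file.path(outDir, "fw_gwas.tsv"))

  message("[namgei] GEI meta-analysis scan")
  gei <- geiScan(geno, adj, threshold = config$geiThreshold,
                 kinship = kin, method = config$scanMethod,
                 pvalueLaw = config$pvalueLaw)
  utils::write.table(gei, file.path(outDir, "gei.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  message("[namgei] clustering environments")
  prof <- envProfiles(adj)
  envTree <- clusterEnvironments(prof)
  exportNewick(envTree, file.path(outDir, "env_tree.nwk"))
  utils::write.table(
    data.frame(step = seq_along(envTree$height), height = envTree$height),
    file.path(outDir, "env_merge_heights.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(package = "namgei",
                   version = as.character(utils::packageVersion("namgei")),
                   seed = config$seed,
                   config = unclass(config),
                   n_rils = length(rilIds(geno)),
                   n_markers = length(markerIds(geno)),
                   environments = envs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  fwHits <- scanTable(fwScan)
  fwHits <- fwHits$marker_id[fwHits$neglog10p >= scanThreshold(fwScan)]
  geiHits <- gei$marker_id[which(gei$significant)]
  summaryLines <- c(
    sprintf("namgei run: %d RILs, %d markers, %d environments",
            length(rilIds(geno)), length(markerIds(geno)), length(envs)),
    sprintf("FW-stability GWAS hits (Bonferroni %.3f): %s",
            scanThreshold(fwScan),
            if (length(fwHits)) paste(fwHits, collapse = ", ") else "none"),
    sprintf("GEI meta-scan hits (-log10p >= %g): %s", config$geiThreshold,
            if (length(geiHits)) paste(geiHits, collapse = ", ") else "none"))
  writeLines(summaryLines, file.path(outDir, "summary.txt"))

  invisible(list(scanByEnv = scanByEnv, fw = fw, fwScan = fwScan,
                 gei = gei, envTree = envTree, manifest = manifest))
}
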