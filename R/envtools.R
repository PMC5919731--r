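## Environment summaries and hierarchical clustering of environments.

#' Per-environment family-mean yield profiles
#'
#' Represents each environment by the vector of its per-family mean yields
#' (non-check records). Families absent from an environment are filled
#' with that environment's overall mean yield, so profiles stay comparable
#' under unbalanced designs. Environments with no records are dropped with
#' a warning.
#'
#' @param pheno a phenotype table with `family_id` (checks are ignored).
#' @return numeric environment x family matrix, rows ordered by
#'   environment label.
#' @export
envProfiles <- function(pheno) {
  pheno <- pheno[.plotRows(pheno), , drop = FALSE]
  .stopIf(!"family_id" %in% names(pheno),
          "phenotype table needs a family_id column for profiles")
  pheno <- pheno[!is.na(pheno$family_id), , drop = FALSE]
  envs <- sort(unique(pheno$env))
  .stopIf(length(envs) < 2, "need >= 2 environments to build profiles")
  fams <- sort(unique(pheno$family_id))
  prof <- matrix(NA_real_, length(envs), length(fams),
                 dimnames = list(envs, fams))
  cell <- stats::aggregate(yield ~ env + family_id, data = pheno,
                           FUN = mean)
  prof[cbind(match(cell$env, envs), match(cell$family_id, fams))] <-
    cell$yield
  envMean <- tapply(pheno$yield, pheno$env, mean)[envs]
  for (j in seq_along(envs)) {
    miss <- is.na(prof[j, ])
    if (any(miss)) prof[j, miss] <- envMean[j]
  }
  prof
}

#' Ward clustering of environments
#'
#' Agglomerative hierarchical clustering of environment profiles with the
#' classical Ward-D criterion on Euclidean distances (the `"ward.D"`
#' linkage of `hclust`, applied to non-squared distances). Rows are
#' ordered by label before clustering so ties resolve deterministically.
#'
#' @param profiles environment x feature matrix from [envProfiles()].
#' @return An object of class `hclust` with environment labels.
#' @export
clusterEnvironments <- function(profiles) {
  .stopIf(nrow(profiles) < 2, "need >= 2 environments to cluster")
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  stats::hclust(stats::dist(profiles, method = "euclidean"),
                method = "ward.D")
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object, e.g. from [clusterEnvironments()].
#' @param file path to write; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
exportNewick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
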