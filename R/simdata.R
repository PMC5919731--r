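## Synthetic NAM populations and multi-environment phenotypes.
##
## The generator mirrors the structure the downstream analyses assume:
## biparental families sharing one common parent, F5-derived RILs (so
## expected genotype frequencies 15/32 : 1/16 : 15/32 for founder-hom :
## het : common-hom at segregating loci), environments with distinct mean
## productivities, unbalanced family presence, check plots in every block,
## and per-RIL environmental sensitivities (Finlay-Wilkinson slopes)
## centered at 1. Markers are drawn independently within family: the
## marker-by-marker tests downstream do not depend on linkage.

#' NAM population design
#'
#' @param n_families number of biparental families (>= 2).
#' @param n_rils_per_family RILs per family (>= 1).
#' @param n_markers total number of biallelic markers (>= n_chromosomes).
#' @param n_chromosomes chromosomes; markers are assigned contiguously.
#' @param common_parent_id label of the shared parent.
#' @param founder_ids labels of the family founders (one per family,
#'   distinct, none equal to the common parent).
#' @param prob_segregating probability that a marker segregates in a given
#'   family (founders differ at that locus); non-segregating family-marker
#'   cells are fixed for the common parent's allele.
#' @param seed integer seed making the population reproducible.
#' @return A `NamDesign` list.
#' @examples
#' d <- namDesign(n_families = 2, n_rils_per_family = 10, n_markers = 5, seed = 7)
#' @export
namDesign <- function(n_families = 39, n_rils_per_family = 140,
                      n_markers = 4312, n_chromosomes = 20,
                      common_parent_id = "CP",
                      founder_ids = paste0("F", seq_len(n_families)),
                      prob_segregating = 1, seed = 1) {
  .stopIf(n_families < 2, "invalid design: n_families must be >= 2")
  .stopIf(n_rils_per_family < 1,
          "invalid design: n_rils_per_family must be >= 1")
  .stopIf(n_markers < n_chromosomes,
          "invalid design: n_markers must be >= n_chromosomes")
  .stopIf(length(founder_ids) != n_families,
          "invalid design: one founder id per family required")
  .stopIf(anyDuplicated(founder_ids) > 0 || common_parent_id %in% founder_ids,
          "invalid design: founder ids must be distinct and differ from the common parent")
  .stopIf(prob_segregating <= 0 || prob_segregating > 1,
          "invalid design: prob_segregating must be in (0, 1]")
  structure(list(n_families = as.integer(n_families),
                 n_rils_per_family = as.integer(n_rils_per_family),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 common_parent_id = common_parent_id,
                 founder_ids = founder_ids,
                 prob_segregating = prob_segregating,
                 seed = as.integer(seed)),
            class = "NamDesign")
}

#' Multi-environment trial design
#'
#' @param environments environment labels (>= 2).
#' @param env_effects mean productivity of each environment (kg/ha), named
#'   by environment.
#' @param presence family x environment matrix of inclusion fractions in
#'   [0, 1]; each RIL of family f is grown in environment j with probability
#'   `presence[f, j]`. Defaults to a fully balanced trial.
#' @param n_blocks_per_env number of blocks per environment (>= 1).
#' @param block_sd standard deviation of block effects (kg/ha).
#' @param check_ids labels of the check cultivars replicated in every block
#'   (non-empty).
#' @param check_offsets fixed yield offsets of the checks (kg/ha), recycled
#'   over `check_ids`.
#' @param residual_sd plot residual standard deviation (kg/ha).
#' @return A `TrialDesign` list.
#' @export
trialDesign <- function(environments, env_effects,
                        presence = NULL, n_blocks_per_env = 2,
                        block_sd = 0, check_ids = c("check_1", "check_2"),
                        check_offsets = c(0, 150, -150),
                        residual_sd = 0) {
  .stopIf(length(environments) < 2,
          "invalid design: at least 2 environments required")
  .stopIf(n_blocks_per_env < 1, "invalid design: need >= 1 block")
  .stopIf(length(check_ids) < 1, "invalid design: check_ids must be non-empty")
  env_effects <- env_effects[environments]
  .stopIf(anyNA(env_effects), "env_effects must be named by environment")
  if (!is.null(presence)) {
    .stopIf(ncol(presence) != length(environments),
            "presence needs one column per environment")
    .stopIf(any(presence < 0 | presence > 1),
            "presence fractions must lie in [0, 1]")
  }
  structure(list(environments = environments,
                 env_effects = env_effects,
                 presence = presence,
                 n_blocks_per_env = as.integer(n_blocks_per_env),
                 block_sd = block_sd,
                 check_ids = check_ids,
                 check_offsets = rep_len(check_offsets, length(check_ids)),
                 residual_sd = residual_sd),
            class = "TrialDesign")
}

#' QTL specification for the phenotype generator
#'
#' A QTL contributes `dosage * (family_effect + interaction_scale *
#' env_loading)` kg/ha to the yield of a RIL, where dosage is the RIL's
#' founder-allele dosage at the marker. With `interaction_scale = 0` the QTL
#' is purely additive across environments; a positive scale adds a rank-one
#' (multiplicative) family-by-environment interaction, mirroring the
#' structure the AMMI-style meta-analysis tests for.
#'
#' @param marker_index column index of the causal marker.
#' @param family_effects per-family main effect (kg/ha per founder allele),
#'   recycled over families.
#' @param env_loadings unitless per-environment loadings (centered to mean
#'   zero internally so the interaction carries no main effect).
#' @param interaction_scale kg/ha scale of the multiplicative term (>= 0).
#' @return A `QtlSpec` list.
#' @export
qtlSpec <- function(marker_index, family_effects, env_loadings = 0,
                    interaction_scale = 0) {
  .stopIf(interaction_scale < 0, "interaction_scale must be >= 0")
  .stopIf(marker_index < 1, "marker_index must be a positive index")
  structure(list(marker_index = as.integer(marker_index),
                 family_effects = family_effects,
                 env_loadings = env_loadings,
                 interaction_scale = interaction_scale),
            class = "QtlSpec")
}

#' Environmental-sensitivity specification
#'
#' Per-RIL Finlay-Wilkinson slopes are drawn as `slope_mean +
#' N(0, slope_sd)` plus, for each entry of `slope_qtl`, `effect * (dosage -
#' 1)` at the named marker (centering at dosage 1 keeps the population mean
#' sensitivity at `slope_mean`).
#'
#' @param slope_mean mean sensitivity (default 1: the average genotype
#'   tracks the environmental index one-for-one).
#' @param slope_sd standard deviation of the polygenic sensitivity (>= 0).
#' @param slope_qtl optional data.frame `marker_index`, `effect` of markers
#'   that shift the slope per founder-allele dosage.
#' @return A `SensitivitySpec` list.
#' @export
sensitivitySpec <- function(slope_mean = 1, slope_sd = 0, slope_qtl = NULL) {
  .stopIf(slope_sd < 0, "slope_sd must be >= 0")
  structure(list(slope_mean = slope_mean, slope_sd = slope_sd,
                 slope_qtl = slope_qtl),
            class = "SensitivitySpec")
}

#' Simulate NAM genotypes
#'
#' Draws RIL genotype codes (2 = common-parent homozygote, 0 = founder
#' homozygote, 1 = heterozygote) independently per marker within each family
#' at the F5 expected frequencies P(het) = 1/16 and P(each homozygote) =
#' 15/32, so the common-parent allele frequency is 1/2 in expectation at
#' every segregating locus. Markers are split over chromosomes in contiguous
#' blocks.
#'
#' @param design a [namDesign()].
#' @return A [NamGenotypes-class] object.
#' @examples
#' g <- simulateGenotypes(namDesign(n_families = 2, n_rils_per_family = 5,
#'                                  n_markers = 10, n_chromosomes = 2, seed = 1))
#' table(genoCodes(g))
#' @export
simulateGenotypes <- function(design) {
  stopifnot(inherits(design, "NamDesign"))
  nf <- design$n_families
  nr <- design$n_rils_per_family
  nm <- design$n_markers
  n <- nf * nr
  .withSeed(design$seed, {
    codes <- matrix(NA_real_, n, nm)
    probs <- c(15 / 32, 1 / 16, 15 / 32)  # founder-hom, het, common-hom
    for (f in seq_len(nf)) {
      rows <- ((f - 1) * nr + 1):(f * nr)
      seg <- if (design$prob_segregating < 1)
        stats::runif(nm) < design$prob_segregating else rep(TRUE, nm)
      block <- matrix(2, nr, nm)  # non-segregating loci fixed common-hom
      nseg <- sum(seg)
      if (nseg)
        block[, seg] <- sample(c(0, 1, 2), nr * nseg, TRUE, probs)
      codes[rows, ] <- block
    }
    fam <- rep(design$founder_ids, each = nr)
    rownames(codes) <- paste0(rep(design$founder_ids, each = nr), "_RIL",
                              rep(seq_len(nr), nf))
    ## contiguous chromosome blocks, near-equal sizes
    sizes <- diff(round(seq(0, nm, length.out = design$n_chromosomes + 1)))
    chrom <- rep(seq_len(design$n_chromosomes), times = sizes)
    pos <- unlist(lapply(sizes, seq_len), use.names = FALSE)
    colnames(codes) <- sprintf("Gm%02d_%d", chrom, pos)
    map <- data.frame(marker_id = colnames(codes), chrom = chrom, pos = pos)
    NamGenotypes(codes, fam, map)
  })
}

#' Simulate multi-environment yield phenotypes
#'
#' One plot record per retained RIL-environment combination plus check plots
#' in every block. The yield of RIL i in environment j is
#' `env_effect_j * b_i + sum_q dosage_iq * (family_effect_qf +
#' interaction_scale_q * env_loading_qj) + block + residual`, where `b_i` is
#' the RIL's environmental sensitivity from `sens`. Checks have sensitivity
#' 1, a fixed cultivar offset and no genotype.
#'
#' @param geno a [NamGenotypes-class] object.
#' @param trial a [trialDesign()].
#' @param qtls list of [qtlSpec()] entries (may be empty).
#' @param sens a [sensitivitySpec()].
#' @param seed integer seed.
#' @return list with `pheno` (data.frame `ril_id`, `family_id`, `env`,
#'   `block`, `yield`, `is_check`), `true_slopes` (named per RIL), and
#'   `qtls` (the specs, with centered loadings, for test harnesses).
#' @export
simulatePhenotypes <- function(geno, trial, qtls = list(),
                               sens = sensitivitySpec(), seed = 1) {
  stopifnot(is(geno, "NamGenotypes"), inherits(trial, "TrialDesign"))
  envs <- trial$environments
  .stopIf(length(envs) < 1, "invalid design: empty environment list")
  codes <- genoCodes(geno)
  fam <- familyIds(geno)
  famLevels <- unique(fam)
  n <- nrow(codes)
  nE <- length(envs)
  for (q in qtls)
    .stopIf(q$marker_index > ncol(codes),
            "QTL marker index outside the map")

  .withSeed(seed, {
    ## per-RIL sensitivity
    b <- rep(sens$slope_mean, n) + stats::rnorm(n, 0, sens$slope_sd)
    if (!is.null(sens$slope_qtl)) {
      for (r in seq_len(nrow(sens$slope_qtl))) {
        mi <- sens$slope_qtl$marker_index[r]
        dos <- 2 - codes[, mi]
        b <- b + sens$slope_qtl$effect[r] * (dos - 1)
      }
    }
    names(b) <- rilIds(geno)

    ## genetic yield contributions: main (per RIL) and interaction
    ## (per RIL x env)
    gmain <- numeric(n)
    ginter <- matrix(0, n, nE)
    qtlsOut <- list()
    for (q in qtls) {
      dos <- 2 - codes[, q$marker_index]
      fe <- rep_len(q$family_effects, length(famLevels))
      names(fe) <- famLevels
      gmain <- gmain + dos * fe[fam]
      vl <- rep_len(q$env_loadings, nE)
      if (q$interaction_scale > 0) {
        vl <- vl - mean(vl)
        ginter <- ginter + outer(dos, q$interaction_scale * vl)
      }
      q$env_loadings <- vl
      q$family_effects <- fe
      qtlsOut <- c(qtlsOut, list(q))
    }

    ## presence thinning
    presence <- trial$presence
    if (is.null(presence))
      presence <- matrix(1, length(famLevels), nE)
    rownames(presence) <- famLevels[seq_len(nrow(presence))]
    famIdx <- match(fam, famLevels)

    nb <- trial$n_blocks_per_env
    blockEff <- matrix(stats::rnorm(nE * nb, 0, trial$block_sd), nE, nb)

    records <- vector("list", nE)
    for (j in seq_len(nE)) {
      keep <- stats::runif(n) < presence[famIdx, j]
      idx <- which(keep)
      blk <- ((seq_along(idx) - 1L) %% nb) + 1L
      yRil <- trial$env_effects[j] * b[idx] + gmain[idx] + ginter[idx, j] +
        blockEff[j, blk] +
        stats::rnorm(length(idx), 0, trial$residual_sd)
      ril <- data.frame(ril_id = rilIds(geno)[idx],
                        family_id = fam[idx],
                        env = envs[j], block = blk, yield = yRil,
                        is_check = FALSE)
      ## checks: every check cultivar in every block
      ck <- expand.grid(check = seq_along(trial$check_ids),
                        block = seq_len(nb))
      yCk <- trial$env_effects[j] + trial$check_offsets[ck$check] +
        blockEff[j, ck$block] +
        stats::rnorm(nrow(ck), 0, trial$residual_sd)
      chk <- data.frame(ril_id = trial$check_ids[ck$check],
                        family_id = NA_character_,
                        env = envs[j], block = ck$block, yield = yCk,
                        is_check = TRUE)
      records[[j]] <- rbind(ril, chk)
    }
    pheno <- do.call(rbind, records)
    rownames(pheno) <- NULL
    list(pheno = pheno, true_slopes = b, qtls = qtlsOut)
  })
}

#' Inject missing genotype calls
#'
#' Sets each genotype call to NA independently with probability `rate`,
#' reproducibly given `seed`. Used to exercise the imputation step.
#'
#' @param geno a [NamGenotypes-class] object.
#' @param rate missingness fraction in [0, 1).
#' @param seed integer seed.
#' @return A [NamGenotypes-class] object with missing calls.
#' @export
injectMissing <- function(geno, rate, seed = 1) {
  stopifnot(is(geno, "NamGenotypes"))
  .stopIf(rate < 0 || rate >= 1, "invalid argument: rate must be in [0, 1)")
  if (rate == 0) return(geno)
  codes <- genoCodes(geno)
  .withSeed(seed, {
    mask <- stats::runif(length(codes)) < rate
    codes[mask] <- NA_real_
  })
  initialize(geno, codes = codes)
}
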