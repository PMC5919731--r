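---
title: "Mapping yield stability and genotype-by-environment interaction in NAM populations"
author: "namgei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping yield stability and GEI in NAM populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namgei)
```

# The problem

A nested association mapping (NAM) population crosses many diverse founder
parents to one shared elite parent and derives recombinant inbred lines
(RILs) from each biparental family. Grown across many location-year
environments, such a population lets us ask not only *which genomic regions
move grain yield*, but *which regions change their effect with the
environment* — genotype-by-environment interaction (GEI) — and *which
regions make a line's yield track (or ignore) environmental quality* —
yield stability. `namgei` implements that analysis end to end: a
multiparental mixed-model association scan, a Finlay–Wilkinson (FW)
stability GWAS, and an AMMI-style meta-analysis of per-environment allele
effects, plus a synthetic-data generator so every stage is testable without
any external download.

# The multiparental association model

Within one environment, check-adjusted plot yields are modeled as

$$ y = X\beta + Z\alpha + \psi + e, \qquad
   \alpha \sim N(0, I\sigma^2_\alpha),\;
   \psi \sim N(0, K\sigma^2_\psi),\;
   e \sim N(0, I\sigma^2_e). $$

`Z` is the *marker-by-family* incidence: genotype codes (2 = homozygous for
the common parent, 0 = homozygous founder, 1 = heterozygous) are recoded so
that a RIL of family *f* carries its founder-allele dosage `2 - code` in
column *f*. One locus therefore carries a separate random effect per
family, which accommodates markers linked in coupling in one family and
repulsion in another, and founder alleles that genuinely differ between
families. Families where a marker does not segregate carry no contrast and
their columns are zeroed.

The polygenic covariance is the genomic relationship matrix `K = c MM'`
from marker-mean-centered codes `M`. Two conventions are deliberate:

* **Scaling.** `c` is chosen so the mean diagonal of `K` is 1, putting
  `sigma2_psi` on the phenotypic scale. The scale of `K` is not identified
  by the model itself, so some convention is required.
* **Centering.** Codes are centered by the marker mean over *all* RILs,
  not within family; `K` then captures both family structure and
  within-family relatedness, which is what the polygenic term is for.

Each marker is tested with `LRT = -2(L0 - L1)`, comparing restricted
log-likelihoods with and without `Z alpha`, both with fixed effects
profiled out (the shared `log|X'X|` constant cancels). Because
`sigma2_alpha` is tested on the boundary of its parameter space, the null
law is not a 1-df chi-square; p-values use the survival function of a
chi-square with 0.5 degrees of freedom (a gamma with shape 1/4, scale 2),
with the 50:50 \{chi2(0), chi2(1)\} mixture available via
`pvalueLaw = "mixture_0_1"`. Genome-wide significance uses a Bonferroni
threshold `-log10(alpha / m)` over the `m` markers actually tested.

**Numerics.** The null fit rotates the data by the eigenvectors of `K` and
profiles the single ratio `sigma2_psi / sigma2_e` by a bounded
one-dimensional search on the log scale over `[1e-5, 1e5]` (the exact zero
boundary is checked separately). Per-marker tests come in two modes:

* `method = "full"` re-optimizes both variance ratios per marker with
  dense Cholesky likelihood evaluations — the reference mode;
* `method = "fast"` (the scan default) fixes the polygenic ratio at its
  null estimate and profiles only the marker ratio through the Woodbury
  identity, so each marker costs one small `f x f` problem. This is the
  usual "population parameters previously determined" compromise; the two
  modes agree on rankings and effect signs, and the fast mode makes
  thousand-marker scans take seconds.

# Check adjustment

The trials follow a modified augmented design: unreplicated RIL plots with
repeated check cultivars in every block. `adjustByChecks()` subtracts from
each plot the difference between its block's check mean and its
environment's check mean, removing block-level field variation while
leaving environment means intact; the association model then needs only an
intercept. A block without checks is an error, not a silent pass-through.

# The Finlay–Wilkinson stability GWAS

The environmental index is the mean yield of all non-check plots per
environment; each RIL's per-environment means are regressed by OLS on the
centered index, using only the environments where the RIL was observed.
The slope *is* the stability phenotype: 1 means the line tracks the trial
average (dynamic stability), 0 means environmental insensitivity (static
stability), above 1 means hypersensitivity. Three choices matter:

* **Two-step rather than iterative joint regression.** With thousands of
  RILs the index is essentially design-driven; alternating updates change
  nothing detectable and cost determinism.
* **Slope, not slope minus one and not the deviation mean square**, enters
  the GWAS. The slope distribution on realistic simulations is unimodal
  with mean 1, so family effects on the slope read directly as deviations
  from dynamic stability.
* **A slope requires at least 3 environments** (`minEnv = 3`): two points
  fit perfectly and carry no deviation information. Such RILs get `NA` and
  are excluded from the scan.

`stabilityGwas()` reuses the full mixed-model machinery with the slope as
a one-record-per-RIL phenotype, and additionally reports a per-marker
adjusted R² from a plain regression of the slope on founder dosages, as a
model-free variance-explained summary.

# The GEI meta-analysis

For one marker, per-environment scans provide a family x environment panel
of allele-effect estimates `A` with weights `N` (RILs observed per
family-environment cell). The null model says the marker has one true
effect per founder parent, constant over environments:
`alpha = W delta + e`, fitted by weighted least squares. The alternative
adds a rank-one multiplicative term taken from the first singular component
of the residual matrix (the AMMI construction):
`alpha = W delta + gamma + eps` with `gamma = u1 d1 v1'`. The two are
compared by a Gaussian likelihood ratio with profiled variance,
`LRT = n ln(RSS0 / RSS1)` over the `n` observed cells, with weighted sums
of squares.

Design choices made where the design was genuinely open:

* **Unshrunk panel effects.** The effects entering the panel are whitened
  fixed-effect (GLS) estimates computed under the null covariance, not the
  shrinkage BLUPs the scan reports. Boundary REML shrinks a null marker's
  effects to *exact* zeros; a marker nonzero in exactly one environment
  then has an exactly rank-one residual panel, and because the LRT depends
  only on the *shape* of the residuals, its statistic is infinite. With
  unshrunk estimates every cell retains its sampling noise, the statistic
  behaves continuously, and injected interaction QTL dominate the scan.
  `effects = "blup"` restores the shrinkage variant for comparison.
* **Degrees of freedom.** The reference chi-square uses the free-parameter
  count of a rank-one bilinear term,
  `(parents - 1) + (environments - 1) + 1`, computed from the parents and
  environments actually observed for that marker, and can be overridden.
* **Zero-filled SVD.** Cells never observed contribute zero residual and
  zero weight; the SVD runs on the zero-filled matrix. This is the
  simplest convention consistent with weighting by observation counts.
* **An extreme empirical flagging threshold (50 on -log10 p).** The
  SVD-maximized statistic is strongly anticonservative against its nominal
  chi-square reference — on null Gaussian 10 x 6 panels most p-values fall
  below 0.05 — because the rank-one term is chosen to maximize captured
  variance. The package therefore treats the chi-square p-value as a
  ranking score, flags only markers at `-log10 p >= 50` (configurable),
  and the test suite verifies that null panels and purely additive
  simulations never reach that line while constructed multiplicative
  signals exceed it.

The reported `pc_load = d1^2 / sum(d^2)` is the fraction of residual
(interaction) variation captured by the first component; on noise-free
rank-one constructions it is exactly 1, and on noisy panels it falls
between 0 and 1.

# Environment clustering

Environments are summarized by their vector of per-family mean yields
(defined even under unbalanced RIL sets); absent families are imputed with
the environment mean. Profiles are clustered with the classical Ward-D
criterion on (non-squared) Euclidean distances, rows pre-sorted by label so
ties resolve deterministically. The dendrogram exports to Newick.

# What the generator emulates — and what it does not

`simulateGenotypes()` draws F5-derived RIL codes independently per marker
within family at the selfing expectations `15/32 : 1/16 : 15/32`
(founder-hom : het : common-hom), assigns markers to chromosomes in
contiguous blocks, and is fully seed-deterministic. The realized
heterozygosity of real F5 material is not published for the reference
population; the F5 expectation (1/16) is used without claiming it matches.

`simulatePhenotypes()` builds plot records as
`env_effect * sensitivity + sum(dosage * (family_effect +
interaction_scale * env_loading)) + block + residual`, with check plots
(three cultivars replicated in every block by default) and per-RIL
sensitivities centered at 1. The `soynamTrialDesign()` preset carries the
18 published environment means (2364–5057 kg/ha), an unbalanced
family-presence pattern mirroring the published per-environment RIL
counts, and default block and residual SDs of 150 and 400 kg/ha — typical
plot-level values for soybean yield trials.

Deliberately **not** emulated: linkage and LD decay (markers are
independent within family — the tests are marker-by-marker, so no target
depends on LD), realistic recombination maps, maturity covariates, and
spatial field trends beyond block effects. Passing tests therefore show
the *statistical machinery* is correct under the assumed generating model;
they do not certify behavior under LD-driven confounding or maturity
gradients in real data, and FW slopes are not adjusted for maturity.

# Problem sizes and simulation conditions used by the tests

The acceptance suite runs scaled-down populations of 10 families x 50
RILs (about a tenth of the reference population) with 100–2300 markers,
2–15 environments drawn from the preset means, residual SDs of 200–400
kg/ha and block SD 120 kg/ha. Power checks use 20 independent seeds and
require 18 successes; the null calibration check uses 2000 held-out null
markers over a polygenic background built from 300 small-effect markers
whose effects are shared across families (the regime the `K = MM'`
polygenic term represents — per-family background effects would need a
family-block kernel instead and are a different, deliberately untested
regime). The FW slope-recovery condition uses 15 environments at residual
SD 200 kg/ha with polygenic slope SD 0.15.

# Known limitations

* The meta-analysis p-value is a ranking score, not a calibrated error
  rate; interpretation should lean on the empirical threshold and on
  `pc_load`.
* The fast scan mode underestimates per-marker variance-component
  uncertainty relative to full re-optimization; the full mode is available
  where that matters.
* Modal imputation is deterministic and family-aware but deliberately
  simple; heavy missingness in small families degrades to the family mode.
* Kinship uses raw centered codes; a parental-origin kinship is a
  plausible alternative that was not adopted, and is worth a sensitivity
  analysis on real data.

# A minimal run

```{r example, eval = FALSE}
g <- simulateGenotypes(namDesign(n_families = 10, n_rils_per_family = 50,
                                 n_markers = 500, n_chromosomes = 10,
                                 seed = 1))
td <- soynamTrialDesign(n_families = 10)
sim <- simulatePhenotypes(g, td, qtls = list(qtlSpec(250, 150)),
                          sens = sensitivitySpec(slope_sd = 0.15), seed = 2)
res <- runPipeline(injectMissing(g, 0.02, seed = 3), sim$pheno,
                   outDir = "namgei-run", config = pipelineConfig(seed = 1))
res$fwScan
head(res$gei[order(-res$gei$lrt), ])
```
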