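---
title: "Methods: comparing quantitative and neutral divergence among populations"
author: "qstfst authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing quantitative and neutral divergence among populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstfst)
```

## The question the package answers

When populations of one species occupy contrasting habitats, their
life-history traits (clutch size, egg mass, incubation time, offspring size,
growth rate) may diverge.  Two forces can produce that divergence: genetic
drift, and local selection.  The standard way to separate them is to compare
the among-population fraction of *quantitative* genetic variance, Q~ST~,
with the among-population fraction of *neutral* molecular variance, F~ST~:

* Q~ST~ ≈ F~ST~ — divergence is indistinguishable from drift;
* Q~ST~ > F~ST~ — more trait divergence than drift allows (directional
  selection);
* Q~ST~ < F~ST~ — less trait divergence than drift allows (stabilizing
  selection).

`qstfst` implements that comparison end to end for a common study layout:
a nested half-sib common-garden breeding experiment for the quantitative
side, multiallelic (microsatellite-style) genotypes for the neutral side,
and monthly climate series for characterising the habitats themselves.
Because real deposited datasets are not always retrievable, the package
also ships simulators with the same statistical structure the analysis
assumes, so every stage is testable without any download.

## The quantitative side: nested variance components and Q~ST~

The breeding design mates `S` sires to `D` dams each within every
population (default 8 populations × 4 sires × 4 dams = 128 families, the
design scale of the motivating study).  Each family contributes one record
per trait.  `fit_nested_ranef()` fits the two-level random-intercept model

$$ y_{ijk} = \mu + \beta x_{ijk} + p_i + s_{ij} + e_{ijk} $$

with population effects $p_i \sim N(0, V_b)$, sire-within-population
effects $s_{ij} \sim N(0, V_{male})$, residuals $e_{ijk} \sim N(0, V_{res})$
and an optional fixed covariate $x$ (female total length in mm for brood
size; log10 rearing density for growth), via REML in `lme4`.  The
within-population variance is $V_w = V_{male} + V_{res}$ — the sire variance
is added back to the residual variance rather than multiplied up to an
additive-genetic scale, which makes $V_w$ a phenotypic-scale quantity and
Q~ST~ conservative.  Then

$$ Q_{ST} = \frac{V_b}{2 V_w + V_b}. $$

With components $(V_b, V_{male}, V_{res}) = (1, 0.25, 0.75)$ the true value
is exactly 1/3, which is what the parameter-recovery checks target.

Numerical choices:

* REML is fitted with `lme4`'s default profiled bobyqa optimisation.  The
  profiled deviance for a two-component nested design at this size is
  smooth and unimodal in practice, so no multi-start scheme is used; fits
  that fail or do not converge fall back to a method-of-moments estimator
  (unbalanced nested ANOVA with Henderson-style expected mean squares),
  flagged in the output.  The two agree within a few percent on large
  balanced designs (asserted in the tests).
* Variance components are non-negative by construction in `lme4`;
  components below `1e-8` of the total variance are reported as exact
  zeros with a boundary flag.
* Covariates enter as fixed effects inside the mixed model
  (`adjust = "model"`), keeping the variance partition coherent;
  pre-residualisation (`adjust = "residualize"`) is available for
  sensitivity comparison, and is also what the method-of-moments fallback
  uses.
* All-identical responses are a degenerate case: all components zero,
  flagged, and excluded from downstream Q~ST~ (which is undefined at
  $V_b = V_w = 0$).

`pairwise_qst()` computes Q~ST~ for every unordered population pair by
refitting the nested model on the pair's records (`method = "subset"`,
default).  A two-population random effect estimates $V_b$ from two levels,
so single-pair values are noisy; they are used here only through their
*ranks* in the matrix comparison, which is exactly how the downstream test
consumes them.  A `method = "global"` alternative (pairwise mean contrasts
over a shared global $V_w$) is provided for sensitivity.

## The neutral side: Weir–Cockerham theta and marker quality control

`global_fst()`/`pairwise_fst()` implement the Weir & Cockerham (1984)
unbiased estimator θ for multiallelic loci: per locus and allele the
among-population (a), among-individual (b) and within-individual (c)
variance components are computed from sample sizes, allele frequencies and
observed heterozygote proportions, and the multilocus estimate is the
ratio of sums $\sum a / \sum (a+b+c)$ across alleles and loci — not the
mean of per-locus ratios (the tests assert the two differ on constructed
data).  Slightly negative estimates are legitimate for an unbiased
estimator and are reported unclipped.  Genotypes with either allele
missing are excluded at that locus; populations fixed for different
alleles give θ = 1 exactly.

Marker quality control mirrors what practitioners run before trusting an
F~ST~ matrix:

* **Heterozygosity** (`het_stats()`): observed H~O~ and the unbiased
  expected heterozygosity $H_E = \frac{2n}{2n-1}(1 - \sum_k p_k^2)$ per
  population × locus.
* **Exact Hardy–Weinberg tests** (`hwe_exact_test()`): the conditional
  distribution of a genotype table given its allele counts (Levene's
  distribution) equals the distribution induced by pairing the $2n$
  observed allele copies uniformly at random.  The Markov chain therefore
  walks on allele pairings with genotype-switch proposals; the uniform
  pairing distribution is the target, so every switch is accepted and
  detailed balance holds by construction, with no case analysis of
  acceptance ratios.  Defaults are 10^6^ steps after 10^5^ dememorization
  steps (the classic heavyweight settings); the p-value is the proportion
  of visited tables with conditional probability ≤ the observed table's
  (ties count as extreme, compared with a small numerical tolerance), and
  a batch-means Monte-Carlo standard error is reported.
  `hwe_exact_enumeration()` enumerates all tables exactly for small
  problems and is the oracle the chain is validated against.
* **Linkage disequilibrium** (`ld_test()`): the genotypic
  log-likelihood-ratio (G) statistic on the two-locus genotype table,
  with a null distribution from permuting one locus's genotypes among
  individuals within population (batches × iterations permutations, a
  batch-structured standard error), and Fisher's combination
  $\chi^2 = -2\sum \ln p$ on $2k$ df across populations.  Populations
  monomorphic at either locus are skipped and the df reduced accordingly.
* **Ordination** (`genotype_pca()`): individuals are coded as 0/1/2
  allele-dosage counts over every (locus, allele) column, columns are
  mean-centred, missing genotypes imputed at the column mean, and the
  centred matrix decomposed by SVD; scores are labelled by population.

## Life-history trait statistics

`fit_trait_glm()` fits ordinary least squares
`response ~ covariate + population (+ covariate:population)` and reports
sequential (entry-order) F-tests — the layout of the conventional
common-garden tables; marginal tests are available by flag.  Tukey HSD
comparisons (`tukey_hsd()`) and covariate-adjusted least-square means with
95% confidence intervals (`lsmeans_populations()`) are computed through
`emmeans`, the successor of the `lsmeans` package; the Tukey–Kramer form
is used throughout because group sizes are unbalanced in practice, and
LS-means are evaluated at the grand covariate mean (the conventional
default), with an extrapolation flag when a population's covariate range
excludes that mean.  Two-sided tests and α = 0.05 throughout, with no
multiplicity correction beyond Tukey.

Trade-offs are analysed on *size-corrected* traits: `size_corrected()`
returns standardized residuals (mean 0, SD 1) of a trait regressed on
female total length, and `trait_correlation()` reports the Pearson
correlation with its t-based two-sided p.  Growth comparisons are
restricted (`filter_growth_broods()`) to broods rearing between 5 and 19
individuals inclusive, limiting the bias from extreme rearing densities,
and densities are log10-transformed before use as a covariate.
`trait_pca()` summarises trait covariance by correlation-matrix PCA,
flagging loadings above 0.4 in magnitude; the largest-magnitude loading
per axis is made positive so results are platform-stable.
`habitat_contrast()` compares the population-level adjusted means between
two habitat classes with a one-way ANOVA on the population means
(numerator df 1, denominator df `n_populations - 2`; for 8 populations
that is 6 — reported as determined by the data).

## Environmental predictability

`colwell_stats()` computes Colwell's (1974) information-theoretic
seasonality statistics for a monthly series: values are binned into
`n_bins = 10` states, a 12 × bins contingency table of month-of-year
against state is formed, and from the entropies of its margins and cells

$$ C = 1 - \frac{H(Y)}{\log k}, \qquad
   M = \frac{H(X) + H(Y) - H(XY)}{\log k}, \qquad P = C + M $$

give constancy (uniformity of the variable through the year), contingency
(repeatability of the seasonal pattern) and predictability.  `P = C + M`
is exact by construction, the statistics are invariant to affine
transformation of the series (bins follow the observed range) and to the
logarithm base (normalisation by `log k`).  "Bins of equal sizes" is read
as equal-*width* intervals over the observed range — the hydrostats
convention — with the maximum value assigned to the top bin;
equal-frequency binning is available by flag for sensitivity.  A constant
series occupies a single state and returns (P, C, M) = (1, 1, 0) with a
degenerate-range flag.  `summarize_site()` assembles the per-site feature
vector (per variable: max, min, mean, C, M, P; plus 0/1 flow and
deep-water-proximity flags and altitude) and `env_pca()` ordinates sites
on the correlation matrix of those features, dropping constant features
with a warning.

## Comparing the two matrices

`spearman_permutation()` correlates the lower triangles of the Q~ST~ and
F~ST~ matrices by Spearman's rank correlation (ties mid-ranked) and
evaluates significance by permutation.  Distance-matrix cells are not
independent, so the default permutation unit is the *population label*:
one matrix's rows and columns are jointly permuted (Mantel-style).  A
naive pair-level permutation is provided for comparison with generic rank
permutation tests but is anti-conservative for matrix data and flagged as
such in the documentation.  The two-sided p-value is smoothed as
$(1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(n_{perm} + 1)$ so it is never
exactly zero; `n_perm = 9999` by default and a seed is mandatory.  For
five or fewer populations all label permutations can be enumerated
(`exact = TRUE`), and the Monte-Carlo p converges to that enumeration (a
tested property).  Per pair, `classify_selection()` labels the regime
(directional / stabilizing / indistinguishable within a tolerance band).

## What the simulators emulate — and what they do not

`simulate_genotypes()` uses the Balding–Nichols model: ancestral allele
frequencies from a symmetric Dirichlet, per-population frequencies from a
Dirichlet with concentration $p(1-F)/F$, genotypes by random union of
gametes within populations.  This gives a *known* target divergence — the
expected Weir–Cockerham θ equals `divergence_f` — and Hardy–Weinberg
proportions hold within populations by construction, so the HWE tests'
null calibration can be checked on generator output.  Real microsatellite
data differ: stepwise mutation, null alleles, scoring error and
non-equilibrium demography are all absent, so passing tests validate the
estimators, not those data pathologies.

`simulate_experiment()` generates the two experiment tables.  Every trait
value is population effect + sire effect + residual + `tl_slope`·(TL −
mean TL); female total length is log-normal (positive support, CV ≈ 8%
around 85 mm) and the slope acts on *centred* TL so configured population
means stay interpretable.  Cross-trait correlations (the egg size–number
trade-off `tradeoff_rho`, default −0.4; negative brood-size links to
incubation time and fry release length) are induced by giving the
population, sire and residual draws one shared correlation matrix — this
makes the configured correlation survive any variance partition, which is
what lets a configured `tradeoff_rho = −0.9` be recovered from
size-corrected generator output within Monte-Carlo error.  Counts are
rounded and floored at 1 (a small acknowledged bias), broods are truncated
at `brood_cap = 32` for rearing (the husbandry rule of the motivating
design), and growth is density-dependent with slope `density_slope` mm per
log10(individuals), centred at the design's expected density.  Default
trait means and variances are set at the field-realistic scale of a small
mouthbrooding cichlid (clutches of ~35 eggs of ~0.02 g dry mass, broods of
~18 fry released at ~10.5 mm after ~17 days, growing ~5 mm to day 35 and
~12 mm to day 70); the source study does not publish female-length or
within-brood variance parameters, so these defaults are package choices,
configurable per trait.  Survival is not modelled (densities equal the
reared brood), and dams are unreplicated within sires, so dam effects are
inseparable from residuals — matching the design's constraints, not
extending them.

`simulate_climate()` is a 12-month seasonal baseline plus i.i.d. Gaussian
noise (default 15 years, matching a typical monthly climate extraction
window).  It has no trends, autocorrelation or spatial structure; it
exists to exercise the Colwell statistics across regimes (constant,
deterministic-seasonal, noisy-seasonal, i.i.d.).

All generators draw from one seeded stream per call and attach the spec
actually used to their output; fixed seeds give byte-identical outputs.

## The pipeline

`run_pipeline()` executes simulate → popgen → life-history → variance
components/Q~ST~ → environment → comparison, writing every stage output as
a plain CSV/TSV/JSON file so each stage can be re-run independently, plus
a machine-readable `summary.json` and a run log.  Stage seeds are derived
deterministically from the global seed and a stage label, so the whole
bundle is byte-identical under an identical configuration and seed; a
stage failure halts the run naming the stage, leaving completed outputs
and a failure marker.  Five traits get Q~ST~ matrices and comparisons:
female-size-controlled brood size, incubation time, fry length at
release, and density-controlled growth to days 35 and 70.

The pipeline's Monte-Carlo defaults are deliberately desk-scale — HWE
chains of 2 × 10^4^ steps, LD tests of 10 × 100 permutations, 999
comparison permutations — so a full bundle builds in well under a minute;
the single-test functions keep the classic heavyweight defaults (10^6^
HWE steps, 100 × 1000 LD iterations, 9999 permutations).  The validation
suite sizes its simulations similarly: 200 replicates for Q~ST~ recovery,
100 for θ recovery, the full enumerable table space (n ≤ 20) for the HWE
oracle, 500 replicates for permutation calibration, 1000 for Tukey size.

## Known limitations

* Pairwise Q~ST~ from two-population refits has large sampling variance;
  interpret single pairs only through ranks or wide intervals.
* Q~ST~ here is phenotypic-scale (sire variance is not multiplied by 4 to
  an additive-genetic scale); comparisons with F~ST~ are therefore
  conservative when non-additive or environmental variance is present.
* No null-allele correction, bottleneck tests or assignment clustering on
  the marker side; no survival or repeated-measures modelling on the
  experimental side.
* The method-of-moments fallback residualises covariates before
  partitioning, which slightly biases components when the covariate is
  strong; the REML path is the default for exactly that reason.
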