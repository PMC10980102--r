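---
title: "Identifying treatment-specific causal expression biomarkers for survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying treatment-specific causal expression biomarkers for survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In a randomized two-arm oncology trial, patients receive one of two targeted
therapies on top of chemotherapy. Tumor gene expression measured before
treatment may modify the benefit of each therapy, but an observed
association between a gene's expression and overall survival (OS) can be
driven by confounding — tumor micro-environment, mutation background,
technical structure — rather than by the gene itself. `survMR` implements a
Mendelian-randomization (MR) workflow that uses germline cis-eQTLs as
instrumental variables to separate causal expression–OS effects from
confounded associations, arm by arm, and then replicates them in a second
cohort that has genotypes but no RNA-seq.

The pipeline has six stages, each exposed as ordinary functions and
orchestrated by `run_discovery()` / `run_validation()`:

1. **Preprocessing** (`preprocess_expression()`): sample QC (more than 50%
   zero-count genes; duplicated samples), gene filters (across-sample SD at
   least 0.5, at most 30% zero counts), upper-quartile normalization, log2
   transform; chromosome-Y k-means sex verification and PCA as QC
   side-channels.
2. **cis-eQTL mapping** (`map_cis_eqtl()`, `permute_gene_pvalue()`):
   covariate-adjusted OLS for every gene–variant pair within 1 Mb of the
   TSS; gene-level significance by permutation of the
   covariate-residualized expression (10,000 permutations by default,
   direct estimator `(1 + hits) / (1 + B)`); eGenes selected at gene-level
   p < 0.05.
3. **Gene–OS screen** (`screen_gene_os()`): genes are k-means-clustered
   (k = 4) and each cluster enters one multivariable Aalen additive-hazard
   fit per treatment arm, together with the clinical covariates; genes with
   p < 0.1 continue.
4. **Instrument validity** (`pleiotropy_screen()`, `prune_ivs()`): a
   per-variant Cox proportional-hazards GWAS on OS (arms pooled) excludes
   variants with Wald p < 1e-4 as potentially pleiotropic; the survivors
   are clustered by LD (complete linkage on 1 − r², clusters at r² > 0.1)
   and one proxy per cluster — the smallest eQTL p — is kept.
5. **One-sample MR** (`predict_expression_one_sample()`, `one_sample_mr()`):
   predicted expression `g_hat = Q W` (dosages times marginal eQTL slopes)
   replaces measured expression in an arm-specific multivariable additive
   hazard fit; genes with p < 0.05 are called causal, with the sign of the
   aggregated increment statistic as the effect direction.
6. **Two-sample MR and enrichment** (`predict_expression_two_sample()`,
   `two_sample_mr()`, `enrich_causal_genes()`): in the validation cohort,
   `g_hat* = Q* (Q'Q)^{-1} Q' g` transfers a joint least-squares fit of the
   discovery expression onto validation dosages; a causal gene replicates at
   p < 0.05 with concordant direction. Finally each causal gene is
   dichotomized at the all-sample median into beneficial / non-beneficial
   expression and a consensus molecular subtype (CMS1–4) is called enriched
   when strictly more than 70% of its patients fall on one side.

## The additive-hazard engine

The causal tests use Aalen's additive hazard model,
`h(t | x) = x' alpha(t)`, with an intercept column playing the role of the
baseline hazard. The estimator is nonparametric in time: at each ordered
event time `t_k` the increment of the cumulative coefficient vector is the
least-squares solve

```
dB(t_k) = (X_r' X_r)^{-1} X_r' dN(t_k)
```

over the at-risk design `X_r`, with tied events handled in a single solve
(`dN` carries multiplicities). The covariance of the increments is
accumulated with the optional-variation estimator
`(X_r'X_r)^{-1} (sum_{i in events} x_i x_i') (X_r'X_r)^{-1}`. Estimation
stops at the end of the identifiable range — the last event time at which
the at-risk Gram matrix is invertible at a reciprocal condition number of
1e-10 — and later events are dropped with a logged count. The intercept-only
model reduces exactly to the Nelson–Aalen estimator, which the tests verify.

Additive hazards matter here for two reasons: the effect is collapsible (so
covariate adjustment does not change the estimand, which a causal analysis
needs), and the coefficients may vary with time, relaxing proportionality.

**Per-covariate test.** A covariate's cumulative effect is summarized as
`U_j = sum_k K(t_k) dB_j(t_k)` with variance `sum_k K(t_k)^2 dOmega_jj(t_k)`
and a standard-normal reference. The default weight is `K(t) = Y(t)`, the
number at risk — Aalen's classical choice. We initially used a constant
weight, but the optional-variation variance of late increments grows like
`1 / Y(t)^2`, so the handful of events in a nearly exhausted risk set
dominates the variance of the unweighted statistic and destroys power (in
our planted-effect simulations, power dropped from about 0.9 to 0.5). The
number-at-risk weight down-weights exactly those unstable tails; the
constant weight remains available via `aalen_test(..., weights =
"constant")`. Any weight leaves the statistic scale invariant, and the
p-value is unchanged under uniform rescaling of `K`.

The Cox proportional-hazards model is used only for the per-variant
pleiotropy screen, where a relative-risk scan is conventional; it is fit
with Breslow ties via the `survival` package, with non-convergence and
monotone likelihood flagged and the affected variant excluded
conservatively.

## The two-sample projection

The validation cohort has genotypes only, so the exposure is transferred:
`g_hat* = Q* (Q'Q)^{-1} Q' g` is the joint OLS fit of the measured
discovery expression `g` on the discovery proxy dosages `Q`, applied to the
validation dosages `Q*`. Two practical points:

* **Centering.** The projection formula presumes centered variables: on raw
  dosages the sample mean of `g` (log2 expression sits around 9) dominates
  `Q'g` and the fitted weights lose the eQTL signs entirely. The pipeline
  therefore centers dosages at their *discovery* column means (the same
  means applied to `Q*`) and expression at its discovery mean, added back to
  the predictions (`center = TRUE`). The literal formula is available with
  `center = FALSE`, where it satisfies the textbook projection identities
  (`Q* = Q` returns the OLS fitted values; `g` orthogonal to `col(Q)`
  predicts zero), which the tests check to 1e-10.
* **Weight asymmetry.** One-sample MR uses marginal eQTL slopes as weights;
  two-sample MR uses the joint fit. The asymmetry is kept deliberately —
  the marginal weights are what an external eQTL summary table provides,
  while the joint fit is the natural estimator when individual-level
  discovery data are in hand.
* **Allele harmonization.** `harmonize_alleles()` recodes validation
  dosages (`2 - dosage`) where the effect/other alleles are swapped, and
  aborts listing the variants when the allele pairs are irreconcilable.
  Flipping a variant's coding together with its weight sign changes `g_hat`
  only by an additive constant, which the intercept absorbs; the tests
  assert the resulting p-values are identical.

## The synthetic-data generator

Real trial data cannot ship with the package, so every stage is validated
against a generator with queryable ground truth (`sim_config()`,
`simulate_study()`).

* **Genotypes.** Variants come in per-gene LD blocks from a Gaussian copula:
  each of the two allele copies is a latent exchangeable-correlation normal
  vector thresholded at the allele frequency, giving Hardy–Weinberg dosages
  with controllable within-block r². Population allele frequencies are
  drawn once per configuration seed, so discovery and validation cohorts
  are samples from one population — an earlier version redrew them per
  cohort, which scrambles cross-cohort LD contrasts and randomizes the sign
  of the transferred predictor. Variants with empirical MAF below 0.05 are
  resampled (the common-variant filter).
* **Expression.** Negative-binomial counts with log link:
  `log mu = intercept + sum(beta * dosage) + gamma' covariates + subtype
  shift`. The dispersion parameter is the NB size; the default of 4
  (biological CV about 0.5) reflects strongly overdispersed FFPE tumor
  RNA-seq and keeps baseline log2 SDs clear of the 0.5 gene filter.
* **Survival.** Event times from `h(t) = lambda0 + x' alpha`, sampled
  exactly by exponential inversion (piecewise-exponential inversion when a
  time-varying multiplier grid is supplied); independent exponential
  censoring; arms assigned 1:1. Defaults: `lambda0 = 0.1` per month and
  censoring rate 0.025 per month, i.e. roughly 80% deaths — the mature
  follow-up of a metastatic colorectal cancer trial. Expression enters the
  hazard as a z-score clipped at ±1.5 SD, the generator's positivity
  device: an additive model with an unbounded covariate eventually produces
  a negative hazard, so the generator verifies `h > 0` row by row and
  rejects configurations that cannot satisfy it at the clip boundary.
* **Instrument strength.** The default eQTL effect scale (`eqtl_effect_sd =
  0.18`, signed offset 2.5 SD) is calibrated so that the *post-pruning*
  genetic predictor explains about R² = 0.2 of log2 expression — pruning
  often collapses correlated causal variants into one proxy, so the
  realized instrument strength, not the generating one, is what matters.
* **Subtypes.** CMS labels are drawn from configurable proportions and act
  on expression through per-subtype log2-mean shifts applied before count
  generation, so planted enrichment rates are recoverable downstream.

**What the generator does not emulate:** realistic human LD maps and allele
frequency spectra, imputation uncertainty, tumor purity, batch structure,
and trans effects. Passing tests therefore demonstrate that the estimators
and the pipeline logic are correct under the assumed model class, not that
the workflow is robust to every failure mode of real tumor data.

## Numerical and design choices

* The SD < 0.5 gene filter is evaluated on `log2(count + 1)` (a switch
  allows raw counts): an SD threshold of 0.5 is only meaningful on a log
  scale. Whether filtering precedes normalization is equally unstated in
  common practice; here sample QC runs first, then gene filtering, then
  normalization, and the order is enforced through a scale flag.
* Upper-quartile normalization uses the 75th percentile of *nonzero* counts
  with linear interpolation, then rescales by the across-sample mean
  quartile; it is invariant to per-sample rescaling up to that single
  global factor.
* Permutation p-values residualize expression (and dosages) on the
  covariates once and permute the residuals; all cis variants share one
  t-distribution df, so ranking by |correlation| is exact. A per-gene seed
  derived from the global seed and the gene id keeps results independent of
  scheduling. Optional adaptive early stopping (`adaptive_stop`) ends a
  gene after a fixed number of exceedances without changing the estimator's
  form.
* LD pruning cuts the complete-linkage tree strictly below height
  `1 - r2_threshold`, so a pair at exactly r² = 0.1 is *not* merged; the
  proxy is the variant with the smallest eQTL p (ties broken by order).
* Every stated threshold is strict in the published direction: SD < 0.5
  removed, > 30% zeros removed, abundance SD > 0.12 kept, gene-level
  p < 0.05, screen p < 0.1, pleiotropy p < 1e-4 excluded, enrichment rate
  strictly above 0.70.
* Samples exactly at the median expression are assigned to the "low" side
  of the dichotomization; "beneficial" is the side whose direction of
  effect lengthens OS (negative hazard direction means high expression is
  beneficial).
* A singular `Q'Q` in the two-sample projection falls back to a logged
  ridge solve with penalty `1e-8 * trace(Q'Q) / p`.
* Collinear predicted expressions in a multivariable MR fit drop the later
  gene, logged in the result's `dropped` attribute.

## Validation strategy and problem sizes

The test suite checks each estimator against an independent oracle
(per-event-time least-squares solves, Nelson–Aalen by definition,
brute-force partial-likelihood grids, pseudoinverse projections, exact
permutation enumeration at n = 7) and then exercises the pipeline
statistically: type-I error of the full one-sample MR on null cohorts of
300 patients per arm (rejection rate at the 5% level within [0.03, 0.08]
over 500 replicates); detection power at least 0.8 and two-sample
replication at least 0.70 for a planted effect of 0.6 × lambda0 with
R² ≈ 0.2 instruments at 400 patients per arm (200 replicates); pleiotropy
exclusion of a planted direct-effect variant in at least 95% of replicates;
eGene null calibration over 500 genes at 1,000 permutations; and exact
recovery of a planted subtype-enrichment pattern in at least 95% of
replicates at about 100 patients per subtype. The type-I experiment runs
the causal stage on every instrumented gene rather than only those passing
the p < 0.1 screen: under the null the screen admits too few genes to
estimate a rejection rate precisely, and conditioning on a screen computed
from independent noise does not change the level of the instrument-based
test, which is the property under audit; the screen's own calibration is
tested separately. These problem sizes keep the full suite within a few
minutes on one core while leaving each binomial check with useful
resolution.

## Limitations

The workflow assumes the instruments act on OS only through the indexed
gene (no horizontal pleiotropy beyond what the Cox screen removes), linear
instrument–expression and expression–hazard relations, and a shared eQTL
architecture between cohorts. The additive-hazard causal test returns a
direction and a p-value, not a calibrated effect size per expression unit.
CMS labels are taken as given; classifying samples into subtypes is out of
scope, as are genotype imputation, expression deconvolution, and
trans-eQTLs.
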