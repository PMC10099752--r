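---
title: "Developmental trajectory profiles and distal diagnostic outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental trajectory profiles and distal diagnostic outcomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models the package implements, the
assumptions behind them, and the design decisions that were genuinely open
— so that results can be interpreted with the right caveats.

## The analytic chain

The package follows one analytic arc: childhood questionnaire scores →
trait-by-trait association screening → joint developmental profiles →
profile-specific odds of an adolescent emotional-disorder diagnosis.

1. **Scoring** (`score_scale`, `standardize`, `ordinal_alpha`)
2. **Association screen** (`fit_logistic`, `cluster_robust_vcov`, `bh_fdr`,
   `run_screen`)
3. **Parallel-process latent growth model** (`fit_growth`)
4. **Latent profile analysis embedding the growth processes**
   (`fit_mixture`, `entropy`, `enumerate_classes`)
5. **Manual 3-step ML distal-outcome estimation**
   (`classification_table`, `fit_distal`, `re_reference`)
6. **Orchestration and reporting** (`run_all`, `descriptives`,
   `attrition_check`)

## Scale scoring

Subscale scores are prorated item means: a child must answer at least half
of a subscale's items (`min_items_fraction = 0.5`, the common convention
for the CBCL family of instruments) or the score is missing. Reverse-keyed
items are flipped as `min + max − x` before averaging. Standardization to
mean 0 / SD 1 uses the non-missing values of the analysis sample at each
wave; both "full sample per wave" (default) and per-model standardization
are possible by choosing when to call `standardize()`.

Ordinal Cronbach's alpha applies the standardized-alpha formula
k·r̄ / (1 + (k−1)·r̄) to the matrix of pairwise polychoric correlations.
Polychorics use the two-step estimator — thresholds from the marginal
cumulative proportions, then the correlation by maximizing the
bivariate-normal likelihood of the contingency table with bounded scalar
optimization (tolerance 1e-6 on ρ). Two-step was chosen over joint ML for
speed; at questionnaire sample sizes the difference is far below the
estimate's sampling error (the recovery test asks for |ρ̂ − ρ| < 0.03 at
n = 5,000).

## Association screen

Each trait–outcome association is a separate logistic regression of the
binary diagnosis on the standardized trait plus sex and birth year, with
case-wise deletion per model. Decisions:

* **Birth year enters linearly** (centered). Nothing in the design forces a
  categorical coding, and with ~11 birth cohorts a linear trend is the
  parsimonious default.
* **Cluster-robust SEs**: the sandwich A⁻¹BA⁻¹ over mother-level score
  sums, with the finite-sample factor G/(G−1) on by default
  (`cadjust = TRUE`). With singleton clusters and the factor off this is
  exactly HC0, which the tests verify against the `sandwich` package.
* **FDR family**: all traits within one screen invocation (one outcome,
  one stratum). Running several outcomes means several families; callers
  who want a single family across outcomes can pool p-values and call
  `bh_fdr` directly.
* **Separation** is declared when any coefficient exceeds 20 in absolute
  value — meaningful because inputs are standardized; IRLS runs with a
  tight convergence tolerance (1e-12) so the deterministic arithmetic
  checks reproduce printed-table cross-products to high precision.

## Parallel-process latent growth model

Emotional and behavioral problem scores at 18 months, 3 and 5 years load on
a latent intercept (loading 1) and slope with fixed time scores
λ = (0, 1.5, 3.5) **years since the first measurement**, so slopes are
per-year change on the standardized score scale. The time coding was an
open choice; years-since-baseline makes the intercept the 18-month level
and keeps slopes interpretable.

Parameters are the 4 factor means α, the 4×4 factor covariance Ψ, and 6
residual variances Θ (wave- and process-specific, no cross-process residual
covariances — the residual structure was not derivable from the design, so
the most common LGM convention is the default). The implied moments are
μ = Λα and Σ = ΛΨΛᵀ + Θ.

Estimation maximizes the FIML log-likelihood — each row contributes the
normal log-density of its observed coordinates — over an unconstrained
parameterization: log-Cholesky for Ψ (guaranteeing positive
semidefiniteness) and log variances for Θ. Rows are grouped by missingness
pattern so the likelihood and its **analytic gradient** cost O(patterns)
matrix operations plus one pass of sufficient statistics. BFGS with these
gradients converges in about a second at n = 5,000; standard errors come
from the inverse observed information (numerical Hessian of the analytic
gradient at the optimum). Convergence is accepted when the per-100-row
scaled gradient max-norm is below 1e-6 (re-polished once if not).

## Latent profile analysis with embedded growth processes

The 12 indicators per child are modelled as a K-class multivariate normal:

* CBCL block (6): growth-structured moments with **class-specific factor
  means α_k** and **shared Ψ, Θ**;
* 8-year block (6): class means ν_k with shared diagonal variances;
* **zero covariance between the blocks given class** (local independence).

Sharing all covariance structure across classes is the standard LPA
convention (classes differ in means); it is also what keeps the smallest
profiles estimable at ~1% of the sample. Local independence between the
growth block and the 8-year scales given class is the major structural
assumption: "alongside the growth processes" is implemented as joint class
indicators, not as cross-block regressions. Violations (e.g. residual
correlation between 5-year CBCL and 8-year symptoms within class) would
sharpen posteriors artificially.

**Estimation** is generalized EM. The E-step evaluates observed-coordinate
marginal densities (FIML); because covariances are shared, each missingness
pattern needs one Cholesky factor reused across classes. The M-step updates
π and the 8-year parameters in closed form and improves the growth-block
parameters with up to 8 BFGS steps on the expected complete-data
log-likelihood (same analytic-gradient machinery as `fit_growth`), which
keeps the observed log-likelihood non-decreasing — asserted by the test
suite on every fitted trace. Convergence: relative log-likelihood change
below 1e-8, at most 500 iterations. With K = 1 the M-step is run to
convergence, which makes the K = 1 fit coincide with `fit_growth` (a
cross-module identity the tests check to 1e-4).

**Initialization and multistart.** Mixture likelihoods with one dominant
class (~85% here) are heavily multimodal: plain k-means splits the dominant
class and EM then converges to solutions that absorb the small profiles.
The package therefore:

1. builds each start from fine-grained k-means (2K–8K cells, granularity
   varying across starts) agglomerated to K groups by Ward's method, so
   tail cells survive as their own groups;
2. initializes covariance components from **within-partition** variances
   (marginal variances contain the between-class separation and blur the
   classes from the first E-step);
3. runs each start briefly (30 iterations) on a fresh random subsample of
   4,000 rows when n is large, ranks all candidates by their full-data
   log-likelihood, and polishes the best 4 on the full data to convergence.

Starts that collapse (a class with under one expected member) are
discarded; if all collapse, the fit errors. The best start's seed is stored
in the fitted object and in the pipeline manifest. Classes are relabeled in
decreasing-π order with ties broken by the first implied mean coordinate.

**Enumeration** reports, per K: log-likelihood, parameter count
(10K + 21), BIC = −2ℓ + p·log n, adjusted BIC with (n + 2)/24 in place of
n, AIC, entropy E = 1 − Σᵢₖ(−p_ik log p_ik)/(n log K), the fraction
modally assigned to the smallest profile, and an `accepted` flag for the
\>1% smallest-profile rule. The report deliberately does not auto-select K
beyond that flag: fit indices, entropy and interpretability are left to
the analyst, with `run_all()` defaulting to the smallest accepted K by BIC.

## 3-step ML distal-outcome estimation

Step 1 fits the mixture ignoring the outcome. Step 2 computes modal
assignments W and the classification table q_jk = Σᵢ p_ik·1[Wᵢ = j] / Σᵢ
p_ik (columns sum to 1). Step 3 fixes Q and maximizes

ℓ(π*, θ) = Σᵢ log Σₖ π*ₖ · q_{Wᵢ|k} · Bern(yᵢ; logit⁻¹(θₖ + xᵢβ))

by quasi-Newton with analytic scores. Numerical choices: log q entries are
clipped at −15 (zero cells otherwise produce −∞); the class logits and
mixing logits are boxed at ±15, so a class with no observed cases reports
the boundary rather than diverging; covariates enter with class-invariant
slopes (the class-specific alternative is a model change, not a switch).
Standard errors come from the observed information, with an optional
mother-clustered sandwich on top (`cluster_ids`), mirroring how clustering
enters the screen — in the uncertainty, not the point estimates.

The ML variant (not the weighted BCH correction) is implemented because the
corrected-likelihood form is what the 3-step description specifies; with
entropy near 1 the corrected and naive estimators coincide (tested), and
under misclassification the naive estimator is attenuated toward the null
while the corrected one is approximately unbiased (tested at moderate
entropy across 50 replicates).

Pairwise odds ratios are exact transforms, OR(j,k) = exp(θⱼ − θₖ), so
transitivity OR(j,k)·OR(k,m) = OR(j,m) holds to machine precision and
re-referencing is exact; confidence intervals use the delta method on θ
contrasts.

## The synthetic cohort generator

`generate_cohort()` emulates the measurement design the analyses assume:

* **Five developmental profiles** with population shares taken as exact
  count ratios 3087 : 69522 : 4045 : 1074 : 4158 (they sum to 81,886, so
  the shares sum to one exactly). Profile 2 is the large normative class.
* **Outcome model**: diagnosis ~ Bernoulli(logit⁻¹(β₀ + δ_class +
  0.14·female)), with δ equal to the log of each profile's design odds
  ratio (2.15, 1, 3.49, 5.00, 1.37) and β₀ = −3.66 chosen so the implied
  overall prevalence matches 3.0% (3,339 of 110,367). The sex effect 0.14
  is the cross-product log odds ratio implied by the demographic table's
  sex-by-outcome counts.
* **Growth structure**: within-class factor draws from a 4×4 covariance
  (intercept SD 0.30, slope SD 0.08 per year, modest cross-process
  correlations), residual SD √0.20 per wave-process, 8-year within-class SD
  √0.25. These defaults were calibrated once so that the five-profile
  structure is identifiable at realistic sample sizes — the implied
  classification entropy is ≈ 0.88, in the range reported for published
  developmental profile solutions — and were not revisited afterwards.
* **Trajectory shapes** qualitatively match the profile descriptions
  (behavioral-elevated increasing; low decreasing; emotional steeply
  increasing with elevated 8-year anxiety; combined increasing with broadly
  elevated 8-year symptoms; moderate behavioral decreasing). They are
  package defaults, not estimates of any cohort's parameters.
* **Sibling clustering**: 15% of mothers contribute two children; a second
  sibling inherits the first's latent class with probability 0.3, so
  mother-clustered standard errors have real dependence to correct.
* **Attrition**: wave response rates (0.90, 0.77, 0.59, 0.43, 0.43) for
  the 6-month to 8-year waves, MCAR by default; the MAR mechanism makes
  attendance odds decrease with a maternal covariate and outside the
  reference class, so FIML-versus-listwise contrasts are testable.
* **Registry events**: diagnosed children receive ICD-10 codes drawn from
  depressive / anxiety / both / other pools at the published subcategory
  mix; 13.8% additionally receive a childhood (age < 10) code, producing
  the childhood-onset-persistent group; a small fraction of undiagnosed
  children receive childhood-only codes; ADHD appears as F90 events that
  must *not* count toward the emotional outcome.

**What the generator does not emulate** — and hence what green tests do not
establish about real data: maternal-report bias and reporter drift across
waves; item-level measurement (scores are generated directly on the scale
metric); non-normal within-class distributions; class-specific covariance
structure; calendar mechanics of registry coverage; selection into the
cohort. Parameter-recovery results certify the estimators under the model's
own assumptions, not the robustness of the design to their violation.

ICD-10 range semantics: "F32–F34.1" includes F32.x, F33.x, F34.0 and
F34.1; a bare category code (e.g. "F34" with no subcategory digit) counts
only when its whole category lies inside the range, since a bare F34 cannot
be confirmed to be at or below F34.1. Codes that parse but qualify for
neither subcategory (e.g. F31, F92.0) fall into the "other" subcategory of
the combined outcome.

## Problem sizes and reproducibility

Simulation-based tests use sizes chosen to give the assertions comfortable
Monte-Carlo margins while keeping the suite quick: scale/screen checks at
n ≈ 3,000–8,000; growth-model recovery at n = 5,000; mixture recovery at
n = 500–20,000; the five-profile mixing-proportion recovery at n = 20,000
across five seeds; and the distal-outcome recovery at the design's
n = 10,000. Because the combined-symptom profile is 1.3% of the sample with
~12% outcome prevalence, a single n = 10,000 cohort yields only ~15 cases
in that profile and the recovered log odds ratio has simulation SE ≈ 0.27;
the recovery experiment therefore averages the log odds ratio over five
replicate cohorts, reporting exp(mean log OR) — the same estimand with
~2.2× smaller simulation error. Every stochastic stage takes an explicit
seed; `run_all()` records all seeds in its manifest, and regenerating with
the same configuration reproduces result files byte-identically.

## Known limitations

* The growth model is linear; latent-basis or quadratic growth is out of
  scope, so profiles whose real shape is nonlinear would be approximated by
  their best linear summary.
* Class-specific covariance matrices and covariates predicting class
  membership (R3STEP-style) are not implemented.
* Entropy-based corrections other than the ML 3-step (e.g. BCH weights)
  are not provided.
* The mixture's standard errors are not reported per parameter; uncertainty
  is quantified where it is consumed — in the distal-outcome stage, where
  the observed-information (optionally mother-clustered) covariance of the
  class logits feeds all reported confidence intervals.
* Polychoric estimation assumes an underlying bivariate normal per item
  pair; strong skew with few categories can bias alpha.
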