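# trajprofile

Tools for studying how temperamental, emotional and behavioral
characteristics measured across childhood (6 months to 8 years) relate to
clinically registered mood and anxiety ("emotional") disorders in
adolescence (10–18 years). The package targets the analysis design of large
pregnancy cohorts with registry linkage — maternally reported questionnaire
waves, sibling clustering within mothers, substantial wave attrition, and
ICD-10 diagnoses as the distal outcome — and ships a synthetic cohort
generator that emulates that design, so the entire pipeline runs and is
tested without access to restricted data.

## What it implements

**Scale scoring and screening.** Instrument subscales (ICQ, EAS, NHiPIC-30,
CBCL, SMFQ, SCARED, RS-DBD) are scored by prorated item means, standardized
to mean 0 / SD 1, and screened against the binary outcome in separate
logistic regressions with sex and birth year as covariates. Dependence
between siblings is handled by Huber–White sandwich standard errors
clustered on maternal identity,

&nbsp;&nbsp;&nbsp;&nbsp;V = A⁻¹ B A⁻¹,&nbsp; B = G/(G−1) · Σ_g s_g s_gᵀ,

with A the observed information and s_g the score sum of cluster g.
Multiple testing is controlled with the Benjamini–Hochberg false discovery
rate. Internal consistency of ordinal scales is summarized by ordinal
Cronbach's alpha (standardized alpha over the polychoric correlation
matrix, two-step maximum-likelihood polychorics).

**Parallel-process latent growth model.** Emotional (internalizing) and
behavioral (externalizing) CBCL scores at 18 months, 3 and 5 years load on
latent intercepts and slopes with fixed time scores λ = (0, 1.5, 3.5)
years, giving implied moments μ = Λα, Σ = ΛΨΛᵀ + Θ. Estimation is
full-information maximum likelihood (FIML): each child contributes the
normal density of the coordinates it was observed on, so attrition is
handled under MAR.

**Latent profile analysis with embedded growth processes.** A K-class
multivariate-normal mixture over the 6 repeated CBCL scores (class-specific
growth factor means α_k, shared Ψ, Θ) together with 6 symptom scales at 8
years (class means ν_k, shared diagonal variances), fitted by generalized
EM with FIML E-steps and multistart initialization. Class enumeration
reports BIC, sample-size-adjusted BIC, AIC, entropy and the >1%
smallest-profile rule.

**3-step ML distal-outcome estimation.** Modal class assignments W and the
classification-error table q_jk = P(W = j | class k) from the fitted
posterior are fixed, and class-specific outcome logits θ_k are estimated
from

&nbsp;&nbsp;&nbsp;&nbsp;ℓ = Σ_i log Σ_k π*_k · q_{W_i|k} · Bernoulli(y_i; logit⁻¹ θ_k),

which corrects the attenuation that naive classify-then-regress suffers
under imperfect classification. Profile-versus-profile odds ratios
OR(j, k) = exp(θ_j − θ_k) come with delta-method confidence intervals and
can be re-referenced exactly.

**Synthetic cohorts.** `generate_cohort()` simulates children from five
latent developmental profiles (population shares 84.9%, 3.77%, 4.94%,
1.31%, 5.08%), with linear within-class growth, sibling clustering, wave
attrition (MCAR or MAR), sex and birth-year covariates, a distal diagnosis
drawn from class-specific log-odds, and registry-style ICD-10 events;
`code_outcomes()` translates events into the combined emotional-disorder
outcome (F30–F39, F40–F41, F92–F93 at age ≥ 10), its depressive
(F32–F34.1) and anxiety (F40–F41, F93.0–2) subcategories, and
childhood/adolescent onset classes.

## Worked example

```r
library(trajprofile)

cohort <- generate_cohort(cohort_config(n_children = 10000, seed = 42))
cohort
#> Synthetic cohort: 10000 children, 8696 mothers
#> Diagnosed with emotional disorder: 339 (3.39%)
#> Latent classes:
#> profile1 profile2 profile3 profile4 profile5
#>   0.0362   0.8504   0.0528   0.0138   0.0468

run_screen(cohort, traits = c("icq_neg_6m", "cbcl_int_3y",
                              "cbcl_int_5y", "smfq_dep_8y"))
#>         trait odds_ratio ci_low ci_high    p_fdr n_used
#> 1  icq_neg_6m       0.91  0.811    1.02 1.49e-01   9054
#> 2 cbcl_int_3y       1.32  1.157    1.51 7.23e-05   5888
#> 3 cbcl_int_5y       1.38  1.195    1.59 4.24e-05   4250
#> 4 smfq_dep_8y       1.15  0.947    1.39 1.59e-01   4303
```

Odds ratios are per SD of the standardized trait, with mother-clustered
robust confidence intervals and BH-adjusted p-values; emotional problems at
3 and 5 years are associated with the adolescent diagnosis while the
6-month temperament score is not, in this realization.

```r
ch <- cohort$children
X  <- as.matrix(ch[, c("cbcl_int_18m", "cbcl_int_3y", "cbcl_int_5y",
                       "cbcl_ext_18m", "cbcl_ext_3y", "cbcl_ext_5y",
                       "smfq_dep_8y", "scared_anx_8y", "rsdbd_cd_8y",
                       "rsdbd_odd_8y", "rsdbd_hyp_8y", "rsdbd_inat_8y")])
keep <- rowSums(!is.na(X)) > 0
fit  <- fit_mixture(X[keep, ], K = 5, n_starts = 10, seed = 42)
fit
#> Growth-structured latent profile model: K = 5 , n = 9681
#> log-likelihood: -51502.37 ( 39 EM iterations, converged )
#> Mixing proportions:
#> class1 class2 class3 class4 class5
#> 0.8455 0.0530 0.0495 0.0364 0.0155
#> Entropy: 0.885

distal <- fit_distal(fit$modal, classification_table(fit),
                     ch$emotional_disorder[keep],
                     cluster_ids = ch$mother_id[keep])
distal
#> 3-step distal outcome model: K = 5 , reference = class 1
#> Class-specific outcome logits:
#> [1] -3.5190 -2.5249 -3.0266 -3.0964 -1.9962
#> Odds ratios versus reference:
#>        comparison odds_ratio ci_low ci_high
#>  class2 vs class1       2.70  1.775    4.11
#>  class3 vs class1       1.64  0.704    3.80
#>  class4 vs class1       1.53  0.718    3.24
#>  class5 vs class1       4.58  2.388    8.80
```

The five generating profiles are recovered (compare the fitted mixing
proportions with the class shares above); the smallest fitted class (1.6%
of the sample) is the combined-symptom profile, and its corrected odds
ratio versus the large normative class is 4.58 (design value 5.0). The
whole chain — simulate, score, screen, enumerate K, fit, 3-step — can also
be run in one call with `run_all()` or from the shell via
`inst/scripts/run_pipeline.R`.

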