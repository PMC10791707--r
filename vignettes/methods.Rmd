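---
title: "Methods: drug-target and nonlinear MR with individual-level data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-target and nonlinear MR with individual-level data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtmr)
```

# The model and its assumptions

`dtmr` estimates the causal effect of a continuous exposure biomarker
(the motivating case is serum uric acid, mg/dL, as modulated by the
*XDH* gene product) on binary disease outcomes, using genetic variants
in a single cis region as instrumental variables. The identifying
assumptions are the usual instrumental-variable triplet: the variants
are (i) associated with the exposure, (ii) independent of
exposure–outcome confounders, and (iii) affect the outcome only through
the exposure. Restricting instruments to the drug-target gene region
("drug-target MR") makes assumption (iii) biologically interpretable —
the estimate proxies pharmacological modulation of that one gene
product — at the price of weaker instruments than a polygenic score.

With individual-level data the package uses a **one-sample weighted
allele score** design. Writing $g_{ik}\in\{0,1,2\}$ for the effect
allele count of variant $k$ in individual $i$ and $\beta_k$ for the
per-allele exposure effect estimated in the cohort's own covariate-
adjusted GWAS,

$$\mathrm{score}_i=\sum_k \beta_k\, g_{ik},$$

so the score is expressed in exposure units. The causal log odds ratio
per exposure unit is the **ratio of coefficients**
$\theta=\Gamma/\gamma$, where $\gamma$ is the OLS coefficient of the
score in the exposure regression and $\Gamma$ the logistic log-odds
coefficient of the score in the outcome regression, both adjusted for
the same covariates as the GWAS (enforced by construction in
`linear_mr()`; deviations require an explicit override). With unshrunk
in-sample weights $\gamma\approx 1$, a useful internal consistency
check. For mutually uncorrelated valid instruments the score estimate
is asymptotically the inverse-variance-weighted (IVW) combination of
per-variant Wald ratios; `ivw_mr()` implements the latter so the
equivalence can be verified rather than assumed.

## Uncertainty for the ratio

The default standard error is the second-order delta method
$se^2_\theta = se_\Gamma^2/\gamma^2+\Gamma^2 se_\gamma^2/\gamma^4$;
the first-order form $se_\Gamma/|\gamma|$ (always no larger) is
available by flag, as is a Fieller interval for weak-instrument
robustness (computed under an independence approximation for numerator
and denominator). Confidence intervals and p-values use the normal
approximation on $\theta/se$. A weak-instrument warning attaches to any
estimate whose denominator F-statistic $(\gamma/se_\gamma)^2$ falls
below 10. Reporting is per 0.1 exposure-unit *decrease* by default
(the drug-effect direction for an inhibitor of an exposure-raising
enzyme): $\mathrm{OR}=\exp(-0.1\,\theta)$, a sign flip applied only at
reporting time; $\theta$ is always stored per unit increase.

## Nonlinear (stratified) MR

Stratum-specific effects across quantile groups of a modifier
(a lipid biomarker, or the exposure itself) are estimated by re-fitting
both score regressions within each stratum. Stratifying on the observed
modifier would condition on a collider if the score affects the
modifier; two standard constructions avoid this:

* **Residual method** (`residual_stratify()`): stratify on
  `modifier − score·coef − covariate contributions` from an OLS fit,
  with the fitted intercept retained so residuals keep the biomarker's
  location. Quantile groups are equal-sized up to one individual
  (rank-based assignment, equivalent to type-7 quantile cutpoints for
  distinct values; ties broken by row order). Because strata are formed
  on residuals, the observed ranges of adjacent strata overlap, and the
  stratum summaries deliberately report observed values.
* **Doubly-ranked method** (`doubly_ranked_stratify()`): rank by score,
  cut into consecutive pre-strata of size `n_strata`, rank by modifier
  within each pre-stratum, send the j-th ranked member to stratum j.
  The final partial pre-stratum distributes its members, in modifier
  order, to the lowest-indexed strata — the method's published
  description leaves this choice open, so it is fixed and documented
  here. All ties break by row order, making assignments deterministic.

Nonlinearity is then assessed by **Cochran's Q**
($Q=\sum_j w_j(\theta_j-\bar\theta)^2$, $w_j = 1/se_j^2$, df $=J-1$)
and a **quadratic-trend test**: weighted least squares of $\theta_j$ on
the stratum means $m_j$ of the observed stratifier with known-variance
weights. The reported `p_trend` tests the *linear* slope in $m_j$ — a
linear trend in stratum-level log odds ratios corresponds to a
quadratic overall exposure–outcome relationship, which is why the test
carries the "quadratic-trend" name; with at least four strata an
explicit quadratic coefficient on $m_j^2$ is also reported, since
published descriptions are ambiguous about which of the two is meant.
Regression on the stratum index instead of $m_j$ is available by flag.
The residual method's **constant genetic effect** assumption is checked
by Cochran's Q on per-stratum score–exposure coefficients computed in
doubly-ranked strata, which remain valid under effect heterogeneity.
Strata whose outcome has a single class yield flagged missing estimates
and are excluded from Q and trend with a warning rather than failing
the analysis; how such strata should best be handled is genuinely open,
and the flag keeps the choice visible.

No multiple-testing correction is applied across outcomes, stratifiers
or tests; the pipeline reports the number of tests performed so users
can apply their own.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a biobank
cohort without reproducing any real data:

* **Genotypes**: dosages from thresholding standard-normal latents at
  Hardy–Weinberg cutpoints, so `E[dosage] = 2·MAF` exactly. Variants in
  a named LD block share a latent factor
  ($z=\sqrt\rho f+\sqrt{1-\rho}u$), giving exchangeable latent
  correlation $\rho$ and a smaller dosage-scale correlation
  (empirically ≈ 0.9 ρ for common variants — the package tests verify
  dosage correlation > 0.8 at ρ = 0.95).
* **Exposure**: `intercept + Σ β_k g_k + covariate effects +
  κ·U + noise`, with `U ~ N(0,1)` an unobserved confounder shared with
  the outcomes. Covariates are age, sex, five ancestry PCs, a
  genotyping-array label and an assessment-centre label.
* **Biomarkers**: linear-Gaussian in the centred exposure with
  configurable loadings, covariate effects and noise; a log-normal
  option produces TG-like heavy tails (off by default). Published
  biobank-scale marginal means and SDs are used as defaults for the
  lipid panel, but the *joint* lipid–exposure dependence is not
  publicly documented at individual level, so loadings are free
  configuration with modest defaults.
* **Outcomes**: Bernoulli draws from a logistic model whose exposure
  coefficient may be constant, piecewise-constant over quantile bands
  of a modifier biomarker, or polynomial in the modifier. Prevalent-
  case flags (diagnosed before exposure measurement) are independent of
  genotype by default so the prevalent-case filter can be exercised
  without biasing the GWAS; a switch makes them exposure-dependent for
  stress tests.
* **Determinism**: every column draws from its own substream whose seed
  is a hash of the master seed and a label, so identical
  (config, seed) pairs are byte-identical and adding a variant or an
  outcome leaves all other columns unchanged.

What the generator does **not** emulate: realistic LD maps, imputation
uncertainty, population stratification beyond supplied PC covariates,
ICD-coded outcome derivation, and genotype QC artefacts. Passing tests
on synthetic cohorts therefore show the estimators are correctly
implemented and calibrated under the assumed data-generating model, not
that the assumptions hold in any particular real cohort.

## Non-collapsibility and the marginal effect scale

A subtlety that matters for validating any binary-outcome MR method:
the logistic link is non-collapsible. If the outcome is generated from
a logistic model in the exposure with conditional coefficient
$\theta_c$, a logistic regression on the genetic score — which explains
only a small fraction of exposure variance — recovers an *attenuated*
slope, because the remaining exposure variation is marginalised into
the error. The Wald ratio thus identifies a marginal, population-
averaged log odds ratio, and "the true OR" must be defined on that
scale for a recovery study to be meaningful. The generator therefore
supports `mr_effect(..., scale = "marginal")`: it computes the
pseudo-true logistic slope of outcome on score under the mixture model
(Gauss–Hermite quadrature plus a Newton solve of the population score
equations — fully deterministic) and inverts it to find the conditional
coefficient whose induced estimand equals the requested value. The
attainable marginal slope saturates at roughly
$1/(0.588\,\sigma_{resid})$, so marginal calibration constrains the
residual exposure noise: the recovery design uses a noise SD of 0.55
(plus a confounder SD contribution of 0.35) so that an OR of 0.85 per
0.1-unit decrease is attainable. Marginal calibration is restricted to
constant effects with no covariate effects on exposure or outcome;
richer configurations use the conditional scale, where no closed truth
for the ratio estimand is claimed.

# Fixed validation designs

`mr_scenario()` returns the package's study designs; they are fixed a
priori and used unchanged by the test suite and `scripts/acceptance.R`.
Problem sizes were chosen by power analysis, not by iterating on test
outcomes:

| design | n | instruments explain | purpose |
|---|---|---|---|
| `linear_recovery` | 20,000 | ~1% | recovery of OR 0.85/0.1-unit decrease (marginal scale); 95% CI coverage; 200 replicates |
| `ivw_equivalence` | 50,000 | ~2% | score-Wald vs IVW relative difference over 20 seeds |
| `null_heterogeneity` | 10,000 | ~3% | size and p-uniformity of Q/trend; null calibration of the assumption checks; 500 replicates |
| `quartile_effect` | 20,000 | ~3% | power for a top-TG-quartile-only effect (conditional log-odds 2.36/unit) and for its trend; always-directional strong positive control |
| `constant_effect_violation` | 10,000 | ~3% | per-allele effect ∝ 1 + 0.5 z(TG); detection power of the constant-effect check |
| `age_collider` | 10,000 | ~3% | age gains 0.3 years/allele; detection power of the negative-control check |

Three instruments mirror the motivating design of a three-SNP cis
score. The instrument strengths are deliberately larger than a
realistic biobank-scale cis signal (which explains ~0.02% of variance
at n ≈ 475,000): validation at desk-scale n requires the same
*instrument F* regime, not the same R², and these choices put
per-stratum F between roughly 50 and 150 — strong instruments, where
the delta-method inference the package reports is appropriate. The
exposure SD in the recovery design (≈ 0.66) is below the biobank-like
default (≈ 1.35) because of the marginal-attainability constraint
described above; at the default noise level an OR of 0.85 per 0.1
mg/dL is not expressible as a logistic structural model at any
conditional coefficient, which is itself a useful caution when
interpreting odds ratios reported on small exposure scales.

# Numerical choices

* OLS via QR (`lm.fit`); two-sided p-values from the t distribution
  with residual df (not the normal approximation) — matters only at
  small n but fixes reproducibility. Rows with any missing regressor
  are dropped per fit and `n_used` records it. Categorical covariates
  are one-hot encoded against the first level.
* Logistic fits via Fisher scoring with relative deviance tolerance
  1e-8 and at most 100 iterations; non-convergence and fitted
  probabilities pinned at 0/1 with large coefficients raise a
  separation error rather than returning unstable estimates.
  Monomorphic variants yield flagged records, never a crashed scan.
* Clumping ties (equal p-values) break lexicographically on variant
  ID; with distinct p-values the result is input-order invariant
  (tested against brute-force enumeration). LD is computed in-sample
  from analysis-cohort dosages — a documented divergence from designs
  that use an external reference panel, which is out of scope here.
* The gene-specific Bonferroni threshold is `0.05 / #variants tested`
  (e.g. 9.47e-6 for a 5279-variant region).
* The incremental F convention for instrument strength is the
  covariate-adjusted joint F defined in `instrument_strength()`;
  published drug-target analyses do not always state whether their F
  was covariate-adjusted, so the convention is declared rather than
  inferred.
* Stratum assignment is rank-based with row-order tie-breaks
  everywhere, so all stratifications are deterministic. `n_strata` is
  refused when strata would hold fewer than 2 individuals, and at
  analysis scale (n ≥ 100) when it exceeds n/10.
* All simulator randomness flows through labelled substreams of one
  master seed (a 31-multiplier string hash modulo 2³¹−1).

# Known limitations

* One-sample designs with in-sample unshrunk weights carry finite-
  sample winner's-curse-type bias of order 1/F; at the validated
  instrument strengths this is negligible, but the package does not
  implement cross-validated or externally weighted scores.
* Pleiotropy-robust estimators (MR-Egger, weighted median, constrained
  maximum likelihood) are out of scope; the package's pleiotropy
  handling is the exclusion-list mechanism plus the score-biomarker
  and negative-control regression checks.
* Fractional-polynomial dose–response curves and joint stratification
  on multiple modifiers are not implemented.
* The Fieller interval treats numerator and denominator as
  independent, which is approximate in one-sample data.
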