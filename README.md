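# dtmr: drug-target and nonlinear Mendelian randomization with individual-level data

`dtmr` implements a complete individual-level drug-target Mendelian
randomization (MR) workflow of the kind used to ask whether
pharmacological modulation of a gene product (for example lowering serum
uric acid through *XDH*/xanthine-oxidase inhibition) would causally
change disease risk — and whether that effect is uniform or concentrated
in strata of an effect-modifying biomarker such as the lipid panel.

It is written for biostatisticians and genetic epidemiologists who have
(or want to emulate) biobank-style data: a genotype dosage matrix, a
continuous exposure biomarker, covariates, and binary disease outcomes.
Because such data are access-restricted, the package ships a fully
seeded synthetic-cohort generator with the same statistical structure,
so every stage of the pipeline is testable and its statistical
properties can be verified by simulation.

## The method

1. **Exposure GWAS in a cis region.** For each variant in a window
   around the drug-target gene (conventionally ±500 kb), fit
   `exposure ~ dosage + covariates` by OLS after excluding prevalent
   cases; the per-allele coefficients β<sub>k</sub> become score
   weights. Gene-specific Bonferroni (`0.05 / #variants`) and
   genome-wide (`5e-8`) significance thresholds are supported.
2. **Instrument selection.** Greedy LD clumping (keep the smallest
   p-value, drop everything with in-sample dosage r² above the
   threshold), a caller-supplied pleiotropy exclusion list, instrument
   strength (incremental F-statistic and R²), and negative-control
   checks against age and sex.
3. **Weighted genetic score.** `score_i = Σ_k β_k g_ik` with
   `g ∈ {0,1,2}`.
4. **Linear MR by the ratio of coefficients (Wald ratio).** With
   γ the OLS effect of the score on the exposure and Γ the logistic
   log-odds effect of the score on the outcome, the causal log odds
   ratio per exposure unit is θ = Γ/γ, with second-order delta-method
   standard error `se² = se_Γ²/γ² + Γ²·se_γ²/γ⁴`. Results are reported
   as an odds ratio per 0.1 exposure-unit *decrease* by default
   (`OR = exp(−0.1·θ)`). For independent valid instruments this is
   asymptotically the inverse-variance-weighted (IVW) combination of
   per-variant ratios, and `ivw_mr()` provides that cross-check.
5. **Nonlinear MR.** Individuals are stratified into quantile groups of
   a modifier biomarker either by the **residual method** (stratify on
   the biomarker minus the score's and covariates' contributions, to
   avoid collider bias) or the **doubly-ranked method** (rank by score
   into pre-strata, then by the biomarker within pre-strata). The Wald
   ratio is re-estimated per stratum; nonlinearity is tested by
   Cochran's Q (`Q = Σ w_j (θ_j − θ̄)²`, `w_j = 1/se_j²`) and by a
   weighted quadratic-trend test of θ_j on the stratum means of the
   observed stratifier. The constant-genetic-effect assumption behind
   the residual method is checked by comparing per-stratum score-exposure
   coefficients across doubly-ranked strata.

## Worked example

```r
library(dtmr)

cfg    <- sim_config(n_individuals = 20000, seed = 42)  # 12-variant cis region
cohort <- simulate_cohort(cfg)
covs   <- c("age","sex","pc1","pc2","pc3","pc4","pc5","array","centre")

gwas_cohort <- filter_cohort(cohort, "gout")   # drop prevalent gout cases
gwas <- run_region_gwas(gwas_cohort, cohort$variants$id, covs)
iv   <- clump(gwas, gwas_cohort$genotypes,
              p_threshold = bonferroni_threshold(nrow(gwas)),
              r2_threshold = 0.1)

linear_mr(cohort, iv, c("gout", "ami", "cerebral_infarction"), covs)
#> Linear MR (Wald ratio), OR per 0.1 exposure-unit decrease:
#>              outcome     n n_cases n_controls  gamma gamma_se big_gamma
#>                 gout 19706     694      19012 0.9982  0.04766    0.9149
#>                  ami 19940     545      19395 1.0064  0.04768    0.4582
#>  cerebral_infarction 19951     335      19616 1.0052  0.04759    0.5415
#>  big_gamma_se     or ci_low ci_high   p_value flags
#>        0.2108 0.9124 0.8747  0.9518 2.141e-05
#>        0.2360 0.9555 0.9124  1.0006 5.315e-02
#>        0.2993 0.9476 0.8936  1.0047 7.143e-02

nonlinear_mr(cohort, iv, "ami", "tg", covs)
#> Nonlinear MR: ami across residual-strata of 'tg' (19940 individuals)
#>  stratum    n n_cases stratifier_mean stratifier_min stratifier_max     or
#>        1 4985     104           41.92        -195.00          104.9 0.9718
#>        2 4985     119          126.72          86.69          165.8 0.9690
#>        3 4985     139          184.51         143.28          226.8 0.9797
#>        4 4985     183          268.80         205.62          497.0 0.9051
#>  ci_low ci_high p_value
#>  0.8686  1.0874 0.61839
#>  0.8764  1.0714 0.53913
#>  0.9077  1.0575 0.59968
#>  0.8239  0.9944 0.03779
#> Heterogeneity: Q = 1.842 (df 3), p = 0.606
#> Trend: slope = 0.002949 (se 0.00315), p_trend = 0.349
#> Constant genetic effect: Q p = 0.19 (no violation detected)
```

Reading the output: the score lowers the exposure-unit-scaled gout odds
(OR 0.91 per 0.1-unit decrease, p ≈ 2e-5 — the simulated positive
control), the average AMI effect is null, but the default generator
concentrates the AMI effect in the top TG quartile, where the stratum
estimate is OR 0.91 (p = 0.038). `gamma ≈ 1` is expected: with
unshrunk in-sample GWAS weights the score is calibrated in exposure
units. Observed TG ranges overlap across strata because quartiles are
formed on residuals, not observed values.

A JSON-config command-line wrapper is in `inst/scripts/dtmr.R`
(`run-all` and `simulate` subcommands); `run_full_pipeline()` is the
equivalent R entry point and writes per-stage TSVs, a `report.json` and
a seeded `manifest.json`.

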