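# mrforge

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
the full sensitivity program a modern MR study runs around its primary
estimate. The package grew out of analyses linking genetically predicted
venous thromboembolism risk to long COVID, and implements that style of
study end to end: instrument selection, harmonization, five univariable
estimators with an automatic dispatch rule, pleiotropy/collider/reverse-
causation sensitivity analyses, multivariable MR, approximate-Bayes-factor
colocalization, and a synthetic summary-statistics generator with known
ground truth so every stage is testable without consortium data access.

## What it computes

For instruments j with exposure effects γ̂ⱼ (SE σ_Xj) and outcome effects
Γ̂ⱼ (SE σ_Yj) on a shared effect allele, the causal log-odds effect θ is
estimated by:

- **Wald ratio** (1 variant): θ̂ = Γ̂/γ̂, SE σ_Y/|γ̂|
- **IVW** (≥2): origin-constrained WLS with weights 1/σ_Yj²;
  multiplicative random effects inflate the SE by max(1, √(Q/(L−1)))
- **MR-Egger** (≥3): WLS with intercept after orienting γ̂ⱼ ≥ 0; the
  intercept tests directional pleiotropy
- **Weighted median / weighted mode** (≥3): robust to up to half
  (respectively a plurality) of invalid weight, with parametric-bootstrap
  SEs (mandatory seed)

Dispatch: 1 variant → Wald; 2–3 → fixed-effects IVW; >3 → IVW with
multiplicative random effects. Around the primary estimate: LD-clumped
instrument grids over P and r² thresholds, Steiger directionality
filtering, a Slope-Hunter-style EM collider-slope correction for
conditional phenotypes, reverse MR, a six-criterion robustness checklist,
multivariable IVW for direct effects, and five-hypothesis colocalization
with the conditional probability PP₄/(PP₃+PP₄). Methodological details and
design decisions are in `vignettes/mr-workflow.Rmd`.

## Worked example

The numbered scripts under `analysis/` run the whole workflow from files.
`analysis/01_simulate.R` writes a synthetic study — 35 genome-wide
significant instruments at FinnGen scale, an outcome GWAS of 3,018 cases /
994,582 controls, true causal effect θ = 0.19 (OR 1.21) — and
`analysis/02_primary_mr.R` analyzes it:

```
selected 35 instruments, mean F = 198.7
MR (ivw_mre, 35 variants): OR 1.221 [95%CI 1.149-1.297], P = 9.75e-11
MR (egger, 35 variants): OR 1.191 [95%CI 1.032-1.376], P = 0.017
  intercept 0.0045 (SE 0.0121), P_intercept = 0.711
MR (weighted_median, 35 variants): OR 1.248 [95%CI 1.130-1.378], P = 1.21e-05
MR (weighted_mode, 35 variants): OR 1.253 [95%CI 1.073-1.464], P = 0.00448
```

Read: each unit increase in the log-odds of the genetically predicted
exposure multiplies the outcome odds by ~1.22 (the generating truth is
1.21); the Egger intercept near zero with P = 0.71 shows no evidence of
directional pleiotropy, and the robust estimators agree in direction and
magnitude. `analysis/03_sensitivity.R` then reports the 4×4 parameter
grid, Steiger filtering, the collider correction, reverse MR, and the
checklist (all six criteria pass on this dataset); `04_mvmr.R`,
`05_coloc.R` and `06_calibration.R` cover the multivariable, colocalization
and calibration analyses. All outputs are plain-text tables under
`results/`.

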