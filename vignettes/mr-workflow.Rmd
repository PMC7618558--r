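---
title: "Two-sample Mendelian randomization with mrforge: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mrforge implements the summary-statistics machinery of a two-sample
Mendelian randomization (MR) study of a binary exposure on a binary
outcome — the motivating application is genetically predicted venous
thromboembolism risk and long COVID — together with the sensitivity
program such a study needs: pleiotropy-robust estimators, instrument-
selection grids, directionality (Steiger) filtering, collider-bias slope
correction for conditional phenotypes, multivariable MR, and
approximate-Bayes-factor colocalization. A synthetic summary-statistics
generator with known ground truth makes the whole pipeline testable
without access to consortium GWAS data.

## The causal model and its estimators

Two-sample MR uses per-variant association summaries from two independent
GWAS. For instrument $j$, let $\hat\gamma_j$ (SE $\sigma_{Xj}$) be its
effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{Yj}$) its effect on
the outcome, both per copy of the same effect allele, on the log-odds
scale for binary traits. Under the instrumental-variable assumptions
(relevance, independence, exclusion restriction) each variant identifies
the causal log-odds effect $\theta = \Gamma_j / \gamma_j$.

* **Wald ratio** (one variant): $\hat\theta = \hat\Gamma/\hat\gamma$ with
  first-order SE $\sigma_Y/|\hat\gamma|$. The exposure-side noise is
  second order for strong instruments; the package's tests verify
  agreement with the full delta method within 10% whenever
  $|\hat\gamma|/\sigma_X > 10$.
* **IVW**: weighted least squares of $\hat\Gamma$ on $\hat\gamma$ through
  the origin with weights $1/\sigma_{Yj}^2$. Fixed effects use the WLS
  standard error; multiplicative random effects inflate it by
  $\max\{1, \sqrt{Q/(L-1)}\}$, where $Q$ is Cochran's statistic, so
  heterogeneity can widen but never narrow the interval.
* **MR-Egger**: the same regression with an intercept, after orienting
  all variants so $\hat\gamma_j \ge 0$ (Egger is not
  orientation-invariant). The intercept estimates directional pleiotropy;
  both SEs are inflated by $\max\{1, \sqrt{Q_E/(L-2)}\}$.
* **Weighted median**: the weighted empirical median of the per-variant
  ratios with weights $\hat\gamma_j^2/\sigma_{Yj}^2$, using the
  half-weight cumulative convention $S_j = \sum_{k\le j} w_k - w_j/2$
  with linear interpolation; consistent while valid instruments carry
  more than half of the weight.
* **Weighted mode**: the argmax of a weighted normal-kernel density over
  the ratios, bandwidth $\varphi \cdot 0.9\min(s, \mathrm{IQR}/1.349)
  L^{-1/5}$ on the weighted ratio sample with $\varphi = 1$ by default;
  consistent while the largest weight share is valid.

The **dispatch rule** used throughout the analyses: one variant, Wald
ratio; two or three, fixed-effects IVW; more than three, IVW with
multiplicative random effects. Median and mode SEs come from a
parametric bootstrap redrawing $(\hat\gamma_j, \hat\Gamma_j)$ from
normal distributions at the reported SEs; the seed is a mandatory
argument so no analysis is silently nondeterministic. The mode's
bootstrap is summarized by the MAD of the bootstrap modes, the
originating implementation's convention, because the bootstrap mode
distribution occasionally jumps to a distant density bump.

## Instrument selection

Instruments are variants passing a significance threshold (default
genome-wide, $5\times10^{-8}$) after a minor-allele-frequency filter
(default 1%), pruned by greedy LD clumping: rank by p-value (ties broken
by chromosome, position, then identifier, so results are reproducible),
accept the best remaining variant, and discard everything on the same
chromosome within the window (default 10 Mb) with $r^2$ at or above the
threshold (default 0.001). Variants missing from the LD panel are
treated as uncorrelated with a warning, mirroring reference-panel
coverage gaps. Instrument strength is summarized by the per-variant
F statistic $(\hat\gamma/\sigma_X)^2$ and its mean.

Gene-specific *cis* instruments restrict to the gene body ± 200 kb (or
the body alone for intragenic-only analyses) and fall back through
significance tiers $5\times10^{-8}$, $5\times10^{-6}$, $5\times10^{-4}$;
a gene with nothing at the most lenient tier is reported as a typed
"no valid cis instrument" outcome rather than an error. Genes whose
instruments are exactly the same variant set merge into one locus.

## Harmonization

Exposure and outcome records are matched on variant identifier and
aligned to the exposure's effect allele, flipping the outcome beta and
complementing its frequency when the alleles are swapped (directly or as
reverse complements). Palindromic variants (A/T, C/G) carry no strand
information in their allele labels, so they are kept only when the
allele frequency is outside the ambiguous band — default (0.42, 0.58) —
on both traits *and* the minor allele points the same way on both;
otherwise they are dropped and counted. Harmonization is idempotent and
conserves counts: matched variants = harmonized + dropped palindromic +
dropped incompatible.

## Sensitivity program

* **Parameter grid**: the primary analysis re-run over p-value thresholds
  $5\times10^{-4}/10^{-6}/10^{-8}/10^{-10}$ and $r^2$ thresholds
  $10^{-4}/10^{-3}/10^{-2}/10^{-1}$. Cells with no instruments are marked
  empty and excluded from consistency judgments rather than failing.
* **Steiger filtering**: per variant and trait, variance explained is
  approximated by $r^2 = z^2/(z^2 + n - 2)$ on the observed scale (no
  prevalence input needed); variants explaining more outcome than
  exposure variance are removed as reverse-causation candidates.
* **Collider-bias (Slope-Hunter-style) correction**: a progression
  phenotype ascertained conditional on an index event inherits a spurious
  slope $b$ between incidence and progression effects. Among
  incidence-associated variants the package fits a two-component mixture
  by EM — an "incidence-only" component with $\beta_P = b\,\beta_I +
  \varepsilon$ and a free bivariate-normal component absorbing variants
  with true progression effects — and de-biases all progression effects
  as $\beta_P - \hat b\,\beta_I$ with delta-method SEs. Because the free
  component can also fit the incidence-only cluster, the likelihood is
  multimodal; the EM therefore runs from a robust deterministic start
  (responsibilities from residuals around the weighted-median ratio
  slope) plus random restarts and keeps the best log-likelihood. With
  that start the fitted slope is stable across restart seeds to ~1e-3.
* **Reverse MR**: the forward machinery with roles swapped, trying
  $5\times10^{-8}$ then $5\times10^{-6}$ for the (typically weaker)
  outcome instruments, returning a typed non-result when neither tier
  yields instruments.
* **Robustness checklist**: six criteria — (1) no Egger evidence of
  pleiotropy (or a significant intercept excused by a significant causal
  slope) with all three robust estimators sign-consistent; (2)/(3) sign
  consistency across the $r^2$ and p-value grid margins at the primary
  settings; (4) sign-consistent collider-corrected estimate; (5)
  sign-consistent Steiger-filtered estimate or no removals; (6) no
  significant positive reverse association. Missing inputs are reported
  as "not-evaluated", never silently true.

## Multivariable MR

For two exposures, instruments are the union of variants genome-wide
significant in either GWAS, clumped jointly on the smaller of the two
p-values. Direct effects come from no-intercept WLS of the outcome
effects on both exposures' effects with weights $1/\sigma_{Yj}^2$ and
multiplicative random-effects SE inflation. An exposure whose effects
are identically zero is dropped (the model then collapses to univariable
IVW for the other exposure); genuinely collinear designs are a hard
error reporting the condition number. A conditional instrument-strength
diagnostic is reported per exposure as the mean squared standardized
residual after weighted regression on the other exposure — a heuristic,
not the Sanderson–Windmeijer statistic.

## Colocalization

Per variant and trait, the Wakefield approximate Bayes factor is
$\log\mathrm{ABF} = \tfrac12[\log(1-r) + r z^2]$ with shrinkage
$r = W/(W + \sigma^2)$; the prior effect SD $\sqrt W$ defaults to 0.2
for both quantitative and case-control traits (log-odds scale). The five
hypothesis masses (no causal variant; trait 1 only; trait 2 only;
distinct variants; one shared variant) use the standard single-causal-
variant sums with per-variant priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$, computed entirely in log space with log-sum-exp so
$|z|$ beyond 40 cannot overflow; the distinct-variant sum uses an exact
log-difference, which correctly degenerates to zero mass for
single-variant regions. The conditional colocalization probability is
$PP_4/(PP_3 + PP_4)$, reported as a typed "not evaluable" outcome when
the denominator is zero.

## The synthetic generator: what it emulates, and what it does not

Summary statistics are simulated directly — no individual-level
genotypes. Default conditions emulate the motivating study: 35
instruments with log-odds effects $\gamma_j \sim N(0, 0.12^2)$ against a
21,021-case / 391,160-control exposure GWAS; an outcome GWAS of 3,018
cases / 994,582 controls; causal effect $\theta = 0.19 = \log 1.21$;
balanced pleiotropy $\alpha_j \sim N(0, 0.01^2)$ (about a third of the
typical outcome-side SE); null variants in AR(1) LD blocks of ten with
$\rho = 0.9$. Per-variant SEs follow the binary-trait approximation
$\sigma \approx \sqrt{n / (2\,\mathrm{maf}(1-\mathrm{maf})\,
n_\mathrm{case} n_\mathrm{control})}$, stated openly as an
approximation. Effects too small to clear genome-wide significance with
a 2-SE margin are redrawn so the instrument count stays fixed without
winner's-curse selection on the sampling noise; the implied mean F is in
the low hundreds, on the order of the strong instruments that motivated
the design. Directional pleiotropy (`mu_alpha`) acts in the
exposure-increasing allele orientation — with symmetric instrument signs
a constant pleiotropic mean would otherwise cancel out of IVW, which is
not the phenomenon MR-Egger targets. Pleiotropy is independent of
instrument strength by default (InSIDE holds); `cor_gamma` creates
violations for negative tests. Sample overlap can be emulated by
correlating the two GWAS' sampling noise (default 0).

The conditional-phenotype generator plants a collider slope $b$ (default
−0.4) with 500 incidence-associated variants at an infection-scale GWAS
(122,616 cases / 2,475,240 controls), the exposure affecting incidence
with slope $\kappa = 0.3$, and 15% of incidence variants carrying true
progression effects. The regional generator places one causal variant
per trait in an AR(1) region and back-computes betas at a uniform SE of
$1/\sqrt{n}$ (default $n = 10{,}000$); a literal unit SE would make every
ABF order one and the null hypothesis win at any z-score.

Not emulated: realistic human LD maps, allele-frequency spectra tied to
real variants, ancestry structure, imputation error, case-control
ascertainment subtleties, or cross-cohort heterogeneity. Passing tests
therefore demonstrate algorithmic correctness and statistical
calibration under the stated generative model, not performance on any
particular real dataset.

## Numerical choices

* Ties in clumping break on (p-value, chromosome, position, identifier);
  output order is acceptance order.
* Random-effects SE inflation is truncated below at 1 in IVW, Egger, and
  multivariable IVW.
* p-values are two-sided normal except Cochran's Q (chi-square with
  $L-1$ df); generated p-values are floored at the smallest normal
  double, since $|z| \gtrsim 38$ underflows and a literal zero would
  (rightly) fail record validation.
* The mode's density argmax uses a 512-point grid over the ratio range
  extended by three bandwidths; tests confirm stability within one grid
  step under 10-fold refinement. Degenerate (zero-spread) ratio sets fall
  back to an epsilon bandwidth.
* The Slope-Hunter EM clamps the mixing proportion to [0.001, 0.999] and
  adds a 1e-10 ridge to the free component's covariance; convergence is
  declared at a log-likelihood change below 1e-6 and non-convergence is
  flagged, never an error.
* All results serialize with at least 15 significant digits so a written
  table re-reads to full precision.

## Study sizes and what the validation shows

The repeated-simulation studies (`study_*` functions; run by
`scripts/acceptance.R` and the test suite) use: 500 random instrument
sets for the weighted-least-squares and weighted-quantile oracles and
100 small regions for the colocalization enumeration oracle; 1,000
replicates for null coverage (2,000 for the Egger intercept type-I
error); 500 replicates for IVW recovery of $\theta = 0.19$ and 300 each
for the directional-pleiotropy and median-breakdown experiments; 100
collider replicates; 200 regions per colocalization condition; and 200
Steiger replicates. Bootstrap SEs inside these studies use 200
replicates (the per-analysis default is 5,000).

The median-breakdown experiment puts 49% of instrument weight on
invalid instruments sharing a large directional effect in a
strong-instrument regime (per-ratio noise 0.01). At the 50% breakdown
boundary the weighted median is not exactly unbiased at finite noise —
the estimate sits near the top of the valid cluster, here ~0.03 above
$\theta$ — which is the expected boundary behavior, and far smaller than
the IVW bias (~0.6) under the same contamination.

## Known limitations

* **Mode CIs are conservative.** The parametric-bootstrap SD of the
  KDE-argmax exceeds its true sampling SD by roughly a quarter in the
  default null scenario (measured directly against the generating
  model), so the mode's empirical 95% coverage is about 0.98. This is a
  known property of the mode estimator's bootstrap interval, not a
  failure of the bootstrap's implementation; the mode should be read as
  a direction-and-magnitude sensitivity check rather than a calibrated
  test.
* **Wald ratio ignores pleiotropy variance.** With balanced pleiotropy
  at the default level, single-variant CIs are slightly anti-conservative
  (coverage ~0.93).
* The Slope-Hunter-style correction is the essential mixture estimand,
  not a line-by-line port of the published software; its fitted slope is
  comparable qualitatively.
* Steiger's $z^2/(z^2+n-2)$ variance-explained approximation is used on
  the observed scale for binary traits; with very unequal case fractions
  across traits the comparison can be mis-scaled.
* LD-aware estimators are out of scope: clumping assumes retained
  instruments are approximately independent; colocalization assumes a
  single causal variant per trait.

## A minimal session

```{r example}
library(mrforge)

truth <- sim_truth(theta = 0.19, seed = 1)
sim <- simulate_pair(truth)

exposure <- maf_filter(sim$exposure, 0.01)
ins <- select_instruments(exposure, sim$ld, p_threshold = 5e-8,
                          r2_threshold = 1e-3)
h <- harmonize_pair(ins$variants, sim$outcome)

dispatch_mr(h)                      # IVW, multiplicative random effects
mr_egger(h)
weighted_median(h, reps = 5000, seed = 7)
steiger_filter(h)$steiger$n_removed
```

The numbered scripts under `analysis/` run the same workflow from files
on disk — generation, primary MR, the sensitivity program, multivariable
MR, colocalization, and calibration — writing plain-text tables under
`results/`.
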