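---
title: "Methods: bidirectional two-sample MR screening with mrscreen"
author: "mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure (here: a circulating inflammatory cytokine, in SD
units) on an outcome (an autoimmune thyroid disease, on the log odds-ratio
scale) from two independent GWAS. For instrument $j$ the exposure GWAS
supplies $\hat\gamma_j \sim N(\gamma_j, \sigma_{x j}^2)$ and the outcome
GWAS $\hat\Gamma_j \sim N(\Gamma_j, \sigma_{y j}^2)$, with

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\alpha_j$ is the direct (pleiotropic) effect of variant $j$ on the
outcome. A variant is a *valid* instrument when $\alpha_j = 0$, it is
robustly associated with the exposure, and it is independent of
confounders. The per-variant Wald ratio is
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order delta
standard error $\sigma_{y j} / |\hat\gamma_j|$; all pooled estimators act
on these ratios.

* **IVW.** Fixed effects: the precision-weighted mean
  $\hat\theta = \sum w_j \hat\beta_j / \sum w_j$, $w_j$ the inverse ratio
  variances, algebraically the zero-intercept weighted regression of
  $\hat\Gamma$ on $\hat\gamma$. Multiplicative random effects scale the SE
  by $\max(1, \sqrt{Q/(J-1)})$ and never deflate it. The pipeline's
  primary estimate uses the heterogeneity switch: random effects when
  Cochran's $Q$ has $p < 0.05$, fixed otherwise.
* **MR-Egger.** Weighted least squares of $\hat\Gamma_j$ on
  $\hat\gamma_j$ with a free intercept after orienting every
  $\hat\gamma_j \ge 0$; the intercept estimates the mean directional
  pleiotropy and its $t_{J-2}$ test is the pleiotropy diagnostic. SEs are
  inflated by $\max(1, \sqrt{Q/(J-2)})$; inference is $t$-based because
  $J$ is small in practice.
* **Weighted median.** The 0.5 crossing of the inverse-variance-weighted
  ordered ratios, linearly interpolated; consistent while valid
  instruments carry more than half the weight. Its SE is a parametric
  bootstrap (each ratio redrawn from its normal), which is why a seed is
  part of the interface.
* **MR-PRESSO.** The observed statistic is the outcome-weighted residual
  sum of squares about leave-one-out IVW predictions; its null
  distribution is rebuilt by parametric simulation, giving an empirical
  global $p$ (with the $(r+1)/(n+1)$ correction) and per-variant
  Bonferroni-adjusted outlier $p$-values. Flagged variants are removed
  and IVW is re-fit as the corrected estimate. The distortion test is not
  computed: the motivating analysis reports no distortion results to
  compare against, so the field is explicitly `"not computed"`.

The screen runs every panel trait through selection, clumping,
harmonization, estimation and diagnostics, then applies Benjamini–Hochberg
step-up FDR control to the primary IVW $p$-values. The family size is the
*declared* panel size (41 in the motivating design), not the number of
traits that yielded instruments: traits with zero usable instruments
contribute $p = 1$. `bhAdjust()` therefore supports adjusting the $k$
smallest $p$-values of a family of $m > k$ tests — the arithmetic that
reproduces the published worked examples exactly
(`bhAdjust(c(0.013, 0.035), m = 41)` gives 0.533 and 0.718; the ten-value
reverse-screen block collapses to 0.082/0.131 under monotone step-up
enforcement). With both diseases, both directions are screened
(`runBidirectional()`), each direction-by-disease screen forming its own
family; the published adjusted values are numerically consistent with this
per-screen family of 41, which is why it is the default.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `pThreshold` | 1e-5 | instrument selection, strict `<` (genome-wide-suggestive) |
| `clumpR2` | 0.001 | LD pruning threshold, `>=` discards |
| `clumpKb` | 10,000 kb | clumping window; distance `<=` window discards |
| `fMin` | 10 | weak-instrument cutoff on per-SNP F |
| `qAlpha` | 0.05 | fixed/random IVW switch on Q's p-value |
| `outlierAlpha` | 0.05 | PRESSO outlier level after Bonferroni |
| `nBoot`, `nSim` | 1000 | bootstrap / PRESSO replicates |
| `ambiguityBand` | 0.08 | palindromic eaf band around 0.5 |

Instrument strength uses $R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\,b^2$ and
$F = R^2 (n - k - 1) / (k (1 - R^2))$; per-SNP mode takes $k = 1$, pooled
mode sums $R^2$ over the $k$ instruments and uses the smallest per-SNP
sample size. The two symbols sometimes written for the instrument count in
this formula are treated as the same quantity.

## Harmonization policy

Variants are matched by rsID. Outcome alleles matching in swapped order
have the outcome beta negated and eaf complemented; strand-complement
pairs of non-palindromic variants are resolved the same way (they are
unambiguous). Palindromic variants (A/T, C/G) are aligned by allele
frequency only when both frequencies are outside $0.5 \pm 0.08$ and are
dropped otherwise — frequency near one half cannot resolve the strand.
Pairs matching in no orientation are dropped. Every decision is logged
per variant (`kept` / `flipped` / `dropped` with a reason), the retained
set is invariant to relabelling either file's alleles, and harmonizing an
already-harmonized pair is a no-op.

## What the synthetic generator emulates — and what it does not

`simulatePair()` draws MAF uniform on [0.05, 0.5], instrument effects
$\gamma_j$ positive (effect alleles oriented exposure-increasing) from a
normal centred on the scale implied by a per-SNP F-statistic target (SD a
quarter of the centre), exposure/outcome SEs at the standard
unit-variance GWAS value $(2\,\mathrm{maf}(1-\mathrm{maf})\,n)^{-1/2}$,
and independent estimation noise in the two samples (the two-sample,
non-overlapping assumption holds by construction). Pleiotropy regimes:
`none` ($\alpha_j = 0$), `balanced` (zero-mean $\alpha$), `directional`
(mean $\mu_\alpha \ne 0$, InSIDE satisfied) and `inside_violating`
($\alpha_j$ correlated with $\gamma_j$ at $\rho$). Defaults mirror the
motivating study's shape: 8–30 instruments per trait, cytokine sample
sizes taken from the printed 41-trait panel (839–8,293;
`cytokinePanel()`), disease GWAS sizes 458,620 / 395,640, and F targets
uniform on [11.2, 789] — the instrument-strength range reported for the
real panel. Fifteen percent of variants are given palindromic alleles so
the harmonization path is exercised.

It does **not** emulate: LD between instruments (variants are placed
farther apart than the clumping window; an LD matrix is caller-supplied
when pruning is to be exercised), liability-scale case–control modelling
(binary-outcome betas are treated directly as log-ORs with their SEs),
sample overlap, population stratification, or genomic control — the last
two are upstream corrections in real GWAS. Passing calibration tests on
these data therefore shows the estimators and diagnostics are correct
under the stated model, not that real cytokine GWAS meet the model's
assumptions.

## Numerical choices and degenerate inputs

* 95% intervals use the multiplier 1.959964 throughout.
* P-values are clamped into $(0, 1]$ (never exactly zero); empirical
  p-values use $(r+1)/(n_{sim}+1)$.
* Clumping breaks p-value ties by lexicographic rsID, making the greedy
  scan deterministic under input permutation; selection is strict at the
  p-threshold and LD pruning inclusive at the r² threshold; the distance
  window is closed at `clumpKb`.
* Zero instruments yield a structured empty estimate (warning, not an
  error); a single instrument degenerates IVW to its Wald ratio with a
  warning; Egger and the weighted median require $J \ge 3$, PRESSO
  $J \ge 4$ (below which the leave-one-out predictions are too
  contaminated to define a useful null).
* A leave-one-out entry is flagged influential when its estimate moves by
  more than one full-sample SE — a conservative, scale-free screen for
  dominant variants.
* Per-trait seeds are derived from the master seed and the *trait name*,
  so screen output is invariant to panel ordering.

## Problem sizes used by the test suite

The calibration experiments run at sizes chosen to give stable Monte-Carlo
estimates while keeping the suite quick: interval coverage over 500
replicates of a 20-instrument trait at $n_{exp} = 8{,}293$ (the largest
panel size); directional-pleiotropy recovery over 300 replicates with
$\mu_\alpha = 0.05$; null-screen FDR over 40 replicate 41-trait panels;
outlier correction over 200 fixtures. Where a criterion sits exactly at
its theoretical boundary — BH's expected false-discovery proportion under
the global null *equals* the nominal level — the test allows the one-sided
Monte-Carlo error of the replicate count, since a point-boundary
comparison would fail half the time at any sample size by construction.

The outlier-correction fixture is built directly (six equal-strength
instruments, $\gamma = 0.3$, outcome SE 0.003, one variant offset by ten
outcome SEs, rotating across seeds) rather than drawn from the generator:
the displacement of the IVW estimate by one outlier is about $10/\sqrt{J}$
standard errors, and the removal-beats-retention property is only a
high-probability event when instrument weights are near-equal — with
heterogeneous weights the outlier can land on a low-weight variant and
its removal is not reliably distinguishable from noise. The fixture
isolates the property PRESSO claims.

## Known limitations

* Interval coverage under the default instrument-strength range measures
  ~0.93: moderately weak instruments attenuate two-sample
  ratio estimates toward the null and the first-order delta SE ignores
  exposure-side noise. This is inherent to the estimator, not an
  implementation artefact; the second-order ratio SE is available behind
  `waldRatios(..., secondOrder = TRUE)`.
* Cochran's Q is only calibrated for null or weak effects when the
  outcome GWAS is much larger than the exposure GWAS; with
  $\theta \ne 0$ the exposure noise that first-order weights ignore
  inflates Q (and the mode-auto switch then conservatively inflates the
  IVW SE).
* The simple (not penalized) weighted median is implemented.
* No Steiger filtering, radial MR, multivariable MR or mode-based
  estimators; no reference-panel strand inference or LD computation.

## A worked miniature

```{r, eval = FALSE}
panel <- simulatePanel(simConfig(nSnps = 12), nTraits = 5, nCausal = 1,
                       theta = 0.3, seed = 1)
screen <- runScreen(panel$exposures, panel$outcome,
                    config = screenConfig(seed = 1, familySize = 41))
screenSummary(screen)
renderReport(screen, "report/")
```
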