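---
title: "Two-step MR mediation with mrpath: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation with mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

# The problem

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate the causal effect of an exposure on an
outcome from two independent GWAS: per-SNP effects on the exposure
$(\hat\beta_{Xj}, \sigma_{Xj})$ and on the outcome
$(\hat\beta_{Yj}, \sigma_{Yj})$. The identifying assumptions are the usual
IV triplet: relevance (the SNP affects the exposure), independence (no
confounding of the SNP–outcome relation) and exclusion (no effect on the
outcome except through the exposure). mrpath implements the full two-step
workflow used to ask whether a molecular mediator (for instance a plasma
metabolite) carries part of the effect of an upstream trait (for instance
an immune cell phenotype) on a disease outcome: three MR legs — total
effect $\theta$ (exposure $\to$ outcome), direct effect A
($\alpha$, exposure $\to$ mediator) and direct effect B ($\beta$, mediator
$\to$ outcome) — composed by the product of coefficients,

$$ \mathrm{ME} = \alpha \cdot \beta, \qquad
   \mathrm{MP} = 100 \cdot \mathrm{ME} / \theta \ (\%). $$

All composition happens on the beta (log-odds for binary outcomes) scale;
published odds ratios are converted by natural log before composition.
This is not cosmetic: the worked-example mediation table shipped with the
package reproduces only on the log scale
(e.g. $\ln(1.042)\times 0.28 = 0.0115$).

# Instrument selection

`select_instruments()` applies, in order:

1. **p-value filter** (default $p < 10^{-5}$, strict inequality) — the
   suggestive threshold conventional for molecular-trait exposures, where
   genome-wide significant hits are too few.
2. **Greedy LD clumping** (default $r^2 < 0.001$ within 10,000 kb):
   candidates are ranked by ascending p-value with ties broken by variant
   id, so the result is independent of file order; each retained index SNP
   removes in-window correlated candidates. Pairs absent from the supplied
   LD table count as independent — the package consumes LD, it never
   computes it from a reference panel.
3. **Weak-instrument filter**: per-SNP $F = (\hat\beta/\sigma)^2 \ge 10$.
   One sometimes sees this statistic described in words as "beta divided by
   the square of the standard error"; read literally that quantity
   ($\beta/\sigma^2$) is not scale-invariant and is almost never what is
   computed. mrpath defaults to $(\beta/\sigma)^2$ and keeps the literal
   variant behind `instrument_config(f_literal = TRUE)` purely for audit.

# Harmonization

`harmonize()` aligns outcome to exposure effect alleles: swapped allele
pairs negate $\hat\beta_Y$ and mirror the allele frequency; opposite-strand
records are complemented before matching; irreconcilable allele sets are
dropped with a recorded reason. Palindromic (A/T, C/G) SNPs cannot be
strand-resolved from alleles alone: the default policy `infer_by_eaf`
resolves them by which side of 0.5 the two allele frequencies fall on and
drops them when either frequency is within 0.08 of 0.5 (or missing);
`drop_all` discards them outright. The 0.08 window is a declared
convention, standard in two-sample MR practice — the workflow this package
reproduces does not state its setting. Indels and multi-allelic records
are rejected at parse time in this version.

# Estimators

Given harmonized pairs, with weights $w_j = 1/\sigma^2_{Yj}$:

* **Wald ratio** (single SNP): $\hat\beta_Y/\hat\beta_X$, se
  $\sigma_Y/|\hat\beta_X|$ (first-order delta; SNP–exposure noise ignored,
  the usual strong-instrument approximation).
* **IVW**: weighted regression through the origin,
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$.
  Fixed-effect se is $(\sum w_j \hat\beta_{Xj}^2)^{-1/2}$; the default
  multiplicative random-effects model inflates it by
  $\sqrt{\max(1, Q/(k-1))}$, matching the de-facto default of widely used
  MR software, so heterogeneity widens but never narrows intervals.
* **MR-Egger**: the same regression with an intercept, after orienting all
  instruments to positive exposure effects. The intercept estimates the
  average directional pleiotropy; the slope is a pleiotropy-adjusted
  effect under the InSIDE assumption. Both standard errors carry the
  $\sqrt{\max(1, \mathrm{RSS}_w/(k-2))}$ underdispersion guard. P-values
  are two-sided normal by default (t with $k-2$ df behind a flag), because
  the reporting convention this package mirrors prints normal-style
  $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ intervals.
* **Weighted median**: the inverse-variance-weighted median of per-SNP
  Wald ratios (cumulative weights $(\sum_{i\le j} w_i - w_j/2)/\sum w_i$,
  linear interpolation at 0.5); consistent if valid instruments carry
  half the weight. Ratio variances use the second-order delta method.
* **Simple / weighted mode**: gaussian-kernel density over Wald ratios,
  bandwidth = `bandwidth_factor` (default 1) times the normal-consistent
  MAD of the ratios, argmax on a fixed 10,000-point grid spanning the
  ratios ± 3 bandwidths; the weighted variant weights kernels by
  normalized inverse variance. Zero spread returns the common ratio.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1000 replicates) that redraws every beta from its sampling
distribution; seeds are mandatory wherever randomness enters, so all
reported intervals are reproducible.

# Sensitivity diagnostics

* **Cochran's Q** against the IVW ($k-1$ df) or Egger ($k-2$ df) fit.
* **Egger intercept test** for directional pleiotropy.
* **MR-PRESSO**: observed weighted RSS of each SNP against the
  leave-that-SNP-out IVW prediction; a parametric null of `n_sim`
  (default 5000) simulated datasets analysed identically; global p via the
  add-one estimator $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$ (never exactly
  zero); per-SNP outlier p-values Bonferroni-adjusted by $k$, flagged at
  0.05; when outliers exist, a distortion test compares the estimate shift
  from removing them against removing 1000 random same-size subsets, and
  an outlier-corrected IVW estimate is reported. With no flagged outlier,
  distortion p and corrected estimate are absent by contract.
* **Leave-one-out** IVW refits, flagging SNPs whose removal flips the sign
  or moves the p-value across the configured threshold.

# The synthetic-data generator

`simulate_mediation_system()` emulates the summary-statistic structure of
large molecular-trait and disease GWAS without individual-level data. Per
SNP $j$ the latent linear system is

$$ x_j = \gamma_j + r\,\delta_j,\quad
   m_j = a\,x_j + \eta_j,\quad
   y_j = c\,x_j + b\,m_j + \delta_j + \alpha_j, $$

with $\gamma_j$ exposure-instrument effects, $\eta_j$ mediator-specific
effects, $\delta_j$ outcome-specific susceptibility effects (used by the
reverse screen), $r$ an optional true reverse effect and $\alpha_j$
horizontal pleiotropy on the outcome. Observed betas add
$N(0, \mathrm{se}^2)$ noise with the standardized-trait standard error
$\mathrm{se} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ for all traits
(for a binary outcome, pass an effective sample size). The truth ledger
records every draw plus $\theta = c + ab$ (exact by construction) and the
true mediated proportion.

Defaults are the stated desk-scale world: 50 exposure and 50
mediator-specific instruments, $n = 100{,}000$ per GWAS, MAF uniform on
[0.05, 0.5], per-SNP effect sd 0.05 (instrument F well above 30 for
selected SNPs), $a = 0.3$, $b = 0.4$, $c = 0.2$, no pleiotropy, LD,
outliers or reverse causation unless requested. Choices worth flagging:

* **Mediator-specific instruments exist by default.** Without them, every
  leg-B instrument would be an exposure SNP and the leg-B slope would
  estimate $(c+ab)/a$, not $b$. Real metabolite GWAS are dominated by
  strong trait-specific (often cis) loci; 50 such SNPs at effect sd 0.05
  is a deliberately conservative rendering of that.
* **Directional pleiotropy is oriented.** Its mean applies along
  $\mathrm{sign}(\gamma_j)$, i.e. relative to the exposure-increasing
  allele. A fixed per-allele mean would cancel under MR-Egger's
  positive-exposure orientation and no method could (or should) recover
  it.
* **Outliers are injected in residual units**: a flagged SNP receives
  pleiotropy of `outlier_scale` (default 10) times its own outcome
  standard error, so "an outlier with a 10-se residual" is true by
  construction rather than an emergent property.
* **LD blocks** only exercise the clumping code path: block members share
  a locus and a pairwise $r^2$, but effect correlation within blocks is
  not modeled.

What a green simulation test does **not** establish: robustness to
case-control ascertainment, sample overlap between the two GWAS,
population stratification, real LD structure, or winner's-curse bias from
discovery-and-use of the same GWAS — none of these are generated.

# Numerical and procedural choices

* **Egger diagnostics assume selected instruments.** Orienting a panel
  that still contains near-null SNPs flips a fraction of them incorrectly
  and dilutes the intercept toward zero (we measured ~20% downward bias at
  effect sd 0.05 before selection). The pipeline always runs selection
  first; the intercept-recovery tests do the same.
* **Reverse-MR contamination.** With a strong forward effect and a shared
  variant panel, exposure loci can pass the outcome's own instrument
  screen, and reverse MR then partially recovers the inverse forward
  effect — the textbook failure mode that Steiger filtering (out of scope
  here) addresses. The reverse screen is therefore validated in a world
  with a modest forward effect (total 0.15, matching the worked example),
  where outcome instruments are genuinely outcome-specific.
* **Significance thresholds are configuration, not constants.** The
  workflow this package mirrors states a $p < 0.001$ rule in its text yet
  reports associations up to $p = 0.046$; both the screening threshold
  (default 0.05) and the mediation-report threshold (default 0.05) are
  config presets, never hard-coded.
* **Mediated-effect uncertainty.** The default is the full Sobel delta
  method $\sqrt{\alpha^2\sigma_\beta^2 + \beta^2\sigma_\alpha^2}$; a
  `delta_b_only` variant ($|\beta|\sigma_\alpha$) is retained because
  published mediation p-values in this literature are often not exactly
  reproducible by Sobel from printed, rounded inputs, and auditing both
  conventions is useful.
* **Worked-example fixture.** `luad_mediation_fixture()` carries
  transcribed (never recomputed) estimates from a published two-step MR
  study of immune cell traits, plasma metabolites and lung
  adenocarcinoma. Its mediated effects reproduce from
  $\ln(\mathrm{OR}_a)\times\beta_b$ to within printed rounding
  (±0.0005); two of its printed mediated proportions deviate by up to
  ~1 percentage point from any recomputation because their total effects
  are small ($\ln 0.96$, $\ln 0.97$) and printed at two decimals — the
  replay table exposes both computed and printed columns rather than
  papering over the gap.
* **Determinism.** One seed in the run config drives every stochastic
  component through derived child seeds; rerunning a config byte-identically
  reproduces every output table, and the run manifest echoes every
  threshold and seed that influenced results.

# Known limitations

Biallelic SNPs only (indels rejected); no multivariable MR or
difference-method mediation; no Steiger directionality filtering; LD is
consumed, never computed; the simulator's standard-error model treats the
binary outcome as a standardized trait unless an effective n is supplied;
grid-scale screening of hundreds of traits is supported mechanically
(batch mode with failure collection) but the package ships no downloaded
GWAS data.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_mediation_system(sim_config(seed = 7))
med <- two_step_mediation(sim$exposure, sim$mediator, sim$outcome,
                          sim$ld, mr_config(seed = 7))
med           # mediated effect ~0.12, mediated proportion ~37.5%
sim$truth$mp_true

# the transcribed worked example
replay_mediation_fixture()
```
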