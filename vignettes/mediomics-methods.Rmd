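---
title: "Methods: screening and causal mediation for microbiome–metabolite–hormone studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and causal mediation for microbiome-metabolite-hormone studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediomics)
```

## The problem

Two groups of subjects (say, control and hypoxia-exposed animals) are
profiled on three layers: a genus-level 16S count table, untargeted LC–MS
metabolite intensity matrices (feces and serum), and a serum hormone panel.
The scientific question is not merely which features differ between groups,
but whether specific metabolites *mediate* the association between gut
microbes and host hormones — and in which direction. `mediomics` implements
that workflow as composable, seed-deterministic stages: differential
screening per layer, then bidirectional causal mediation over the
differential candidates.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic-data generator does and
does not emulate, and the known limitations.

## Differential screening

### Hormones

Per-hormone unpaired two-tailed t-tests. The default is the Student
(pooled-variance) form, matching the common GraphPad-style analysis of
small ELISA panels; Welch is available via `variant = "welch"`. With n = 6
per group neither dominates; the choice is recorded in the output. Features
with zero variance in both groups are resolved explicitly (equal means →
p = 1; unequal → p = 0, flagged degenerate) rather than erroring.

### Microbiome

* **Rarefaction** (`rarefy`): subsampling without replacement to the
  minimum sample depth (data-derived, not hard-coded), via `vegan::rrarefy`
  under a fixed seed. Rarefaction keeps diversity comparisons depth-fair at
  small n.
* **Alpha diversity** (`alpha_diversity`): Shannon entropy in log base 2
  (the QIIME-1 convention; natural log via `shannon_base`), observed
  richness, Simpson 1 − Σp², and Chao1 S + F1²/(2F2) with the
  bias-corrected fallback S + F1(F1−1)/(2(F2+1)) when no doubletons exist,
  avoiding division by zero. Group differences use the Mann–Whitney test,
  exact when the pooled sample is ≤ 20 and tie-free (at n = 6/group the
  exact null matters), normal-approximate with tie correction otherwise;
  the result records which path was taken.
* **Ordination**: CSS normalization → Bray–Curtis → PCoA. CSS divides each
  sample by the cumulative sum of its counts up to the median of its
  nonzero counts. The quantile is fixed at 0.5 rather than adaptively
  chosen: with 6 samples per group the adaptive criterion is unstable, and
  determinism is worth more here than the marginal fit gain. PCoA drops
  negative eigenvalues (no Cailliez/Lingoes correction) and reports
  proportions over the positive part — Bray–Curtis is not metric and the
  triangle inequality is deliberately not asserted anywhere.
* **LEfSe-style screen** (`lda_effect_screen`): per-sample total-sum
  scaling to 10⁶, Kruskal–Wallis per feature at `alpha = 0.05`, then a
  bootstrapped LDA effect size: `n_boot = 30` rounds each subsample
  `boot_fraction = 2/3` of every group, fit a two-class LDA direction
  w ∝ S⁻¹(μ₁−μ₀) with the pooled covariance shrunk halfway toward its
  diagonal (at n = 6/group the pooled covariance is singular; intensity
  0.5 is fixed, not tuned), normalize w, and score feature j as
  (|w_j(μ₁ⱼ−μ₀ⱼ)| + |μ₁ⱼ−μ₀ⱼ|)/2 per-million units. The LDA score is
  log10(1 + mean effect over rounds); a feature passes at KW p < 0.05 AND
  score > 3. The classic subclass/pairwise-Wilcoxon stage of LEfSe is a
  no-op in a plain two-group design with no subclass factor, and is
  documented rather than implemented. The screen runs on rarefied counts
  (TSS applied internally); this is configurable since toolchains differ on
  whether LEfSe sees rarefied or CSS-normalized tables.

### Metabolome

* **Missingness filter**: untargeted matrices code absent peaks as zero
  intensity; features whose zero fraction strictly exceeds 0.6 are dropped
  (7/12 zeros = 58.3 % survives, 8/12 = 66.7 % does not).
* **OPLS-DA** (`opls_fit`): NIPALS-based orthogonal projections to latent
  structures with one predictive component and `n_ortho = 1` orthogonal
  component by default — the minimal OPLS-DA; the orthogonal weight is the
  part of the loading orthogonal to the predictive weight,
  w_o = p − (wᵀp/wᵀw)w, and X is deflated by t_o p_oᵀ before the
  predictive component is extracted. Columns are mean-centered and
  unit-variance scaled by default (Pareto and none exposed; metabolomics
  practice varies and the choice is recorded in the model). Predictive
  scores are orthogonal to every orthogonal score column by construction
  and the package asserts |tᵀt_o| ≤ 1e-8.
* **Cross-validation**: "7-round CV with one seventh of samples excluded"
  is honored at small N as 7 seeded random partitions with hold-out size
  max(1, round(N/7)) — at N = 12 that is 2 samples per round, refitting the
  preprocessing inside each round. Q2 = 1 − PRESS/SS with held-out samples
  predicted including the training-fold intercept; omitting that intercept
  biases Q2 upward under the null, which the permutation guard (median Q2
  ≤ 0 over label permutations) exposed during development.
* **VIP**: over the predictive component only (orthogonal components carry
  no class information; a total-model VIP would dilute the ranking), so
  VIP_j = √J·|w_j| and Σ VIP² = J exactly — asserted numerically at 1e-8.
* **Selection**: strict VIP > 1 AND t-test p < 0.05 on the
  log10(x+1)-transformed filtered intensities (the transform is
  configurable; raw peak areas are equally defensible since upstream
  normalization conventions vary). Direction is the group-mean ratio on
  untransformed intensities, ties reported as "up".
* **Enrichment**: per-pathway right-tail hypergeometric test of the
  selected set against the tested background, from a user-supplied
  pathway → metabolite annotation (no live database queries).

Positive/negative ionization modes, when present, are merged by row
concatenation with mode-tagged feature ids before screening.

## Causal mediation

For a triad (X, M, Y) with binary treatment Z as adjustment covariate,
three OLS fits:

* Y ~ 1 + X + Z → β1 (total effect)
* M ~ 1 + X + Z → β2
* Y ~ 1 + M + X + Z → β3, β4

ACME = β2·β3, ADE = β4, total = β1. Because the three models share samples
and covariates, β1 = β2·β3 + β4 holds exactly (to numerical precision;
asserted at 1e-10), so ACME + ADE = total is an identity, not an estimate.

**Assumption gate.** Four flags, all required by default: p(β1) < α,
p(β2) < α, p(β3) < α, and |β4| < |β1| (the X–Y association weakens when M
is controlled; no magnitude margin is standard, so the strict inequality is
used). Gating happens *before* effect estimation, in the Baron–Kenny
screening tradition; `require_gate = FALSE` reports every triad on ACME
significance alone, since reasonable analysts differ on which rule defines
a "significant mediation".

**Inference.** Quasi-Bayesian Monte Carlo with `n_sims = 1000`: β2 is
drawn from N(β̂2, se²) and (β3, β4) jointly from their estimated bivariate
normal (the two models' coefficient blocks are independent), the draws are
propagated through the product, and 2.5/97.5 percentiles give the 95 % CI;
p = 2·min(frac ≤ 0, frac ≥ 0), floored at 2/n_sims. This is the standard
simulation engine for product-of-coefficients inference and is preferred
here over the nonparametric bootstrap for speed at equal calibration;
n_sims < 100 is rejected as numerically unstable.

**Screening both directions.** `screen_triples` enumerates
hormone → metabolite → genus and genus → metabolite → hormone over the
differential candidates. Transforms: genera enter as
log10(relative abundance + 1e-6) of rarefied counts, metabolites as
log10(intensity + 1), hormones raw — log transforms stabilize the variance
of skewed omics features; all are recorded in the output. Per-triad seeds
derive deterministically from the master seed and the triad labels, so
results are identical regardless of evaluation order. Exactly collinear
designs (e.g. an exposure constant within treatment groups) are flagged and
skipped with a reason rather than aborting the screen. No multiple-testing
correction is applied across triads by default — the workflow reports raw
p < 0.05, as is conventional in exploratory mediation screens — and a BH
adjustment can be applied downstream on the returned table.

## The synthetic-study generator

`generate_study` emulates the statistical structure the analysis assumes:

* two groups × 6 samples by default, the emulated study's size;
* 9 hormones, Gaussian with ~10 % CV; five carry group shifts of 3
  within-group SDs (three raised, two lowered — an HPA-activation /
  HPT-suppression pattern; shifts of this size reproduce the very small
  panel p-values such designs report);
* a compositional genus table: log-normal base composition, per-sample
  Dirichlet perturbation (concentration 200), multinomial counts at
  log-normal library sizes (mean 30,000, CV 0.2, the order of a typical
  16S run's minimum depth), with 13 differential genera at ±2 log2
  fold change;
* zero-inflated log-normal metabolites: log10 locations uniform on [4, 7],
  within-group SD 0.3, differential features at ±2 log2 fold change, and a
  two-component masking mechanism (baseline 15 % zero rate, 10 % of
  features at 75 %) so the missingness filter always has work to do;
* planted mediation triads from the structural equations M = aX + ε,
  Y = bM + c′X + δZ + ε′ on latent standardized scales, with the group
  shift carried by X so planted features are discoverable by the upstream
  screens. Latents map to observed scales affinely (hormone units, log10
  intensity, log10 relative abundance — the genus mapping is compressed by
  the latent's theoretical SD to keep planted abundances inside the
  library size), and the affine maps are recorded in the truth so tests
  can invert them and check coefficient recovery on the latent scale.
  After planting, non-planted genus rows are rescaled so every column
  still sums to its drawn library size.

Feature counts default to desk scale (60 genera, 300 fecal + 150 serum
metabolites) for test-suite speed; `full_scale = TRUE` switches to
254/2945/1457. All randomness flows from per-table child seeds of one
master seed, so identical configs give identical studies.

What the generator does **not** emulate: phylogenetic correlation among
genera, batch/injection-order effects, intensity-dependent missingness
(zeros are masked independently of abundance), correlated hormone axes,
and longitudinal structure. Passing tests therefore demonstrate that the
algorithms are implemented correctly and calibrated under clean
assumptions — not that any particular real dataset satisfies those
assumptions.

## Numerical and design notes

* Degenerate inputs are defined, not accidental: constant vectors in tests,
  all-zero sample pairs in Bray–Curtis (distance 0 with a warning),
  zero-variance features in scaling (centered only, flagged), empty
  candidate sets in the mediation screen (empty table with a message).
* The exact Mann–Whitney/approximation switch is total n ≤ 20 and
  tie-free; exact p-values are multiples of 1/C(n₁+n₂, n₁).
* `estimate_effects` reports the analytic point estimates (β̂2·β̂3, β̂4,
  β̂1), not simulation means, so the decomposition identity is exact; the
  simulation supplies intervals and p-values only.
* A type-I-error bound of 6 % is used for the ACME test at n = 12 (product
  tests are conservative under the complete null; the observed rate in the
  shipped checks is ≈ 3 %).
* In the end-to-end false-discovery check, the rate is computed over all
  evaluated candidate triples (the gate's input), and reverse-direction
  mirrors of planted triads count as false — conservative, since mediation
  analysis cannot orient a chain from observational data alone.
* Problem sizes in the shipped checks (e.g. 500–1000 replicate triads,
  desk-scale studies, n = 30/group for the recovery benchmark) were chosen
  as the smallest sizes at which the binomial noise of the measured rates
  is comfortably below the asserted bounds.

## Limitations

The mediation estimates are associations structured by a model, not
demonstrations of causality: sequential ignorability is untestable here and
no sensitivity (ρ) analysis is included. Outcomes are Gaussian-identity
GLMs only — binary or count outcomes and multi-mediator joint models are
out of scope. Phylogenetic diversity metrics (PD, UniFrac) are excluded
because the pipeline does not construct a tree. With 6 subjects per group,
screens are exploratory: the benchmark stage of the analysis workflow
quantifies exactly how much recovery improves from n = 6 to n = 30 under
identical planted effects.
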