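---
title: "Multi-level methylation analysis with methdrift: models, parameters and design choices"
author: "methdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level methylation analysis with methdrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`methdrift` analyses Illumina-style DNA methylation beta-value matrices
(probes x samples, values in [0,1]) in case/control designs at several
complementary levels: a per-probe epigenome-wide association analysis
(EWAS), cross-study meta-analysis, epigenetic-clock age acceleration,
stochastic epigenetic mutation (SEM) calling with a logistic drift-burden
model, a sliding-window scan for SEM-enriched regions (epivariations),
and a heuristic prioritization of the genes those regions hit. Every
stage can be exercised end to end on fully synthetic cohorts with
recorded ground truth.

This vignette is the package's account of the science: the models and
their assumptions, the tunable parameters with their defaults and units,
what the synthetic generator does and does not emulate, the numerical
choices, and known limitations. It states no empirical result that the
test suite does not itself compute.

# The models

## EWAS

Beta values are transformed to M-values, `M = log2(b / (1 - b))` after
clipping into `[1e-6, 1 - 1e-6]`; the logit scale stabilizes variance
across the methylation range and makes linear modelling reasonable. Each
probe is fitted by ordinary least squares against a design of intercept,
case/control indicator, and covariates (age, batch, PLS cell-composition
scores, or any sample-sheet columns). The group coefficient, its
standard error, the t statistic and a two-sided p-value from the t
distribution are reported, with both Benjamini-Hochberg and Bonferroni
adjustment (`stats::p.adjust`).

An optional variance moderation shrinks each probe's residual variance
toward the cross-probe harmonic-mean pooled value with a fixed prior
weight of 4 degrees of freedom. This is a deliberately simplified,
fixed-prior variant of empirical-Bayes moderation: the prior degrees of
freedom are not estimated from the data, the option is off by default,
and plain OLS output is exactly reproducible by textbook formulas —
which is what the oracle tests assert.

Gene-level ("region") statistics combine signed per-probe Z-scores by
unweighted Stouffer combination within each gene symbol of the
annotation. The choice of combination rule was genuinely open; Stouffer
on signed Z was chosen because it respects effect direction, reduces to
the site p-value for single-probe genes, and has a closed form the tests
can verify. Probes inside a sample-level deletion region can be excluded
before combining.

## Cross-study meta-analysis

Two complementary schemes, matching the two kinds of per-study output:

* **Sample-size weighted Z** for p-values: `z_i = sign_i *
  qnorm(1 - p_i/2)`, weights `w_i = sqrt(n_i)`, combined `Z = sum(w_i
  z_i) / sqrt(sum(w_i^2))`. This is the classic scheme for combining
  association p-values across cohorts when effect sizes are not on a
  common scale.
* **DerSimonian-Laird random effects** for effect sizes (drift log odds
  ratios, acceleration standardized mean differences): method-of-moments
  `tau2`, weights `1/(se^2 + tau2)`, normal-theory 95% CI, plus the
  heterogeneity statistics `Q` (fixed-effect weighted squared deviations)
  and `I2 = max(0, (Q - df)/Q) * 100`. REML and meta-regression are out
  of scope; DL is the transparent, closed-form choice, and the test
  suite cross-checks it against an independent implementation.

`forest_data()` emits exactly the numbers a forest plot renders:
per-study effect, 95% CI, normalized random-effects weight, and the
pooled row.

## Epigenetic clocks and age acceleration

A clock is an intercept plus a sparse linear combination of probe betas,
optionally followed by the log-linear age anti-transform used by
first-generation pan-tissue clocks (`x <= 0 -> 21*exp(x) - 1`, `x > 0 ->
21*x + 20`). Published coefficient sets are user-supplied inputs (CSV of
probe weights plus a JSON sidecar); none are shipped, because trained
clock weights are research artifacts of their authors and the machinery
here is generic. Missing clock probes are imputed with the cohort mean
of that probe — the behaviour of public calculators is not documented,
so the package declares its own rule and flags samples with fewer than
80% of clock probes observed rather than dropping them.

Age acceleration is the residual of DNAm age regressed on chronological
age (mean zero by construction). Group differences are expressed as
Cohen's d standardized mean differences with large-sample standard
errors, ready for random-effects pooling.

## Stochastic epigenetic mutations and the drift model

The core outlier definition: from the control samples only, each probe
gets a reference range

    lower = Q1 - k * IQR,   upper = Q3 + k * IQR,   k = 3

with Q1/Q3 the linear-interpolation (type-7) quartiles of the control
beta values. A sample's value above `upper` is a hyper-methylated SEM,
below `lower` a hypo-methylated SEM, directions relative to the control
median. Cases are never part of the reference: including them would let
a strong case signal widen its own reference range. Probes whose control
IQR is below `1e-6` are non-callable — a probe with no spread among
controls would otherwise be infinitely sensitive — as are probes with
fewer than 10 observed controls, and probes inside a sample's flagged
deletion regions are skipped for that sample.

The per-sample burden (SEM count) is modelled on the `log10(burden + 1)`
scale — the +1 keeps zero-burden samples in the model — by logistic
regression of case status on log burden plus the EWAS covariates. The
group difference is reported as an odds ratio with a Wald 95% CI. The
default fit is Firth's bias-reduced (Jeffreys-penalized) logistic
regression: when drift is strong, the two groups' burdens can separate
completely, plain maximum likelihood then diverges, and Firth's
penalization is the standard remedy that keeps estimates finite with
meaningful CIs. Plain ML (`firth = FALSE`) is available and flags
separation explicitly with an infinite CI instead of failing silently.

## Epivariations: the sliding-window scan

For each sample, a window of `n_window = 11` consecutive probes slides
by single sites along each chromosome (never spanning chromosomes). With
`N` the sample's callable probes genome-wide, `K` its total SEMs, and
`k` the SEMs inside the window, the window p-value is the inclusive
upper tail of the hypergeometric distribution, `P(X >= k)` for
`X ~ Hypergeometric(N, K, n_window)`. Genome-wide `N` and `K` are used
as background (rather than per-chromosome totals) because the rare-event
question is "is this window surprising given this sample's overall SEM
load".

Windows significant after a per-sample Bonferroni correction over all
scanned windows at `alpha = 0.05` are merged maximally: windows sharing
a probe or abutting in probe index form one region, whose coordinates
span its first to last probe. The significance rule was an open choice;
Bonferroni was selected as the conservative option matching the
rare-event framing, and merging is idempotent by construction. Mixed
hyper/hypo regions are allowed; the direction summary records both
counts. Regions are annotated with the gene symbols they span and
exported as both TSV and 0-based half-open BED.

Cross-study overlap reporting collects, per study, the genes hit in at
least one case and zero controls ("case unique"), the gene x study
membership matrix, genes shared by two or more studies, genes recurring
in more than 3 distinct case samples, and an upset-style intersection
table.

## Gene prioritization

The prioritization of epivariation-hit genes is heuristic by nature, so
the package declares a transparent additive score over case-unique
genes:

    score = n_case_samples + n_studies + 2*[phenotype hit]
          + 2*[brain expressed] + 1*[in any known list]

with user-tunable weights. "Brain expressed" means the gene's mean
expression across the regions of a user-supplied table exceeds the
table's cross-gene median; phenotype and known-gene inputs are plain
one-gene-per-line lists. The score is monotone in each component, which
is the property the tests assert. A generic hypergeometric
over-representation test (`ora_test`) stands in for web-based enrichment
services, sharing its tail kernel with the window scan.

# The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of array
methylation data with full ground truth:

* **Baseline**: probe means drawn from a bimodal mixture — 42.5% near
  beta 0.1, 42.5% near 0.9, 15% intermediate — mirroring the
  characteristic two-peaked array-wide beta distribution.
* **Noise**: per-sample noise on the M scale with SD 0.3, from a normal
  distribution truncated at ±2 SD. The truncation is deliberate: with
  unbounded normal noise, sampling error of control quartiles at
  realistic reference sizes (30–40 controls) produces an irreducible
  background of natural `k = 3` outliers of order 1e-4 per cell, and on
  the convex beta scale the stretched tail overshoots `Q3 + 3*IQR` at
  extreme-beta probes. Real cohorts do contain such natural extreme
  values — that is precisely why real SEM burdens are large — but a
  validation generator must make the injected outliers the *only*
  extreme outliers, so that caller tests measure the caller and not the
  generator's tail behaviour.
* **Group effects**: a configurable fraction of probes (default 2%)
  shifted by ±0.08 beta in cases; ids recorded.
* **SEMs**: independent per-probe events at `sem_rate_control = 5e-4`
  in controls, multiplied by `sem_rate_ratio = 2.5` in cases; injected
  values are placed at least 6 control IQRs from the control median
  (direction recorded), guaranteeing recoverability at `k = 3` by
  construction.
* **Epivariations**: per case, one run of 11 consecutive probes set to
  coherent outlier values on one chromosome, redrawn on boundary
  collisions.
* **Batch and cell composition**: per-batch probe shifts (SD 0.01 beta)
  and 5% of probes linearly linked to the first of five simulated cell
  fractions, whose mean differs mildly between groups; the standardized
  fraction is clamped at ±2 so this covariate, like the noise, cannot
  mimic an injected outlier.
* **Deletions**: runs of 8 probes with failed detection p-values
  (p > 0.01) in a random sample, emulating homozygous deletions.

What it does **not** emulate: probe-type chemistry differences (the SWAN
target), raw intensities, SNP-affected probes, sex chromosomes,
correlated residual structure along the genome, or heavy natural outlier
tails. Consequently, passing recovery tests demonstrates the
correctness of the calling/scanning machinery under clean conditions,
not the empirical burden levels or false-positive rates to expect on
real arrays.

Cohort sizes used by the validation suite were chosen to exercise the
methods at realistic scale while staying quick: the drift-model
replicates use 60 cases / 60 controls at 20,000 probes (50 seeds per
arm), the epivariation replicates use the generator defaults of 5,000
probes and 30/30 samples (50 seeds), and the full-pipeline determinism
check runs the default 3-study bundle. Burden-model replicates set
`dmp_fraction = 0` and `epivar_per_case = 0` so that the rate-ratio-1
null is a true null: injected epivariations add 11 SEMs to every case
and group-level methylation shifts produce systematic boundary
crossings in cases, either of which would make the null arm reject for
reasons unrelated to the drift rate being tested.

# Numerical choices and degenerate inputs

* Quartiles: type-7 linear interpolation throughout (the R default);
  the reference-range tests pin this convention to hand-computed values.
* M-value clipping at `eps = 1e-6`; generated betas are clipped into
  `[1e-6, 1 - 1e-6]`.
* Reference bounds are *not* clipped to [0,1]: beta values cannot leave
  the unit interval anyway, so clipping would only corrupt the recorded
  range.
* Detection failures: p > 0.01 (a common array QC convention); deletion
  regions require at least 3 consecutive failed probes — a balance
  between sensitivity and chance runs.
* `p = 0` entering the weighted-Z combination is clipped to the
  smallest positive double with a warning.
* Rank-deficient EWAS designs fail naming the collinear columns;
  constant log burden (collinear with the intercept) is an error;
  all-missing probes stay missing through every stage.
* Windows with zero SEMs (p = 1) are omitted from scan output but
  counted in the Bonferroni denominator.
* The quantile-normalization and batch-alignment helpers are generic
  stand-ins (cross-sample quantile mapping; per-probe location/scale
  alignment on the logit scale). They are not SWAN and not ComBat, they
  announce themselves when run, and they are off by default in the
  pipeline so that outlier-based stages see unmanipulated values.

# Known limitations

* Region-level EWAS uses gene symbols as regions; curated region sets
  (islands, shores) are not shipped.
* The drift model's Wald CI under Firth penalization is approximate in
  very small cohorts; profile-likelihood CIs are not implemented.
* The window scan assumes the annotation's probe order is the genome
  order and treats callable probes as exchangeable under the null;
  local correlation of methylation is not modelled.
* Prioritization weights are conventions, not learned quantities; the
  score is meant for ranking within a run, not comparison across runs.
* The generator's clean-tail design means empirical false-positive
  rates on real data will be higher than on synthetic cohorts.
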