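---
title: "Post-processing and covariate screening of label-free proteomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing and covariate screening of label-free proteomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqscreen)
```

## The problem

Label-free quantification (LFQ) assigns each protein one intensity per
sample, already normalised by the search engine. Downstream of that table,
a dose-response animal study — here the motivating design is six treatment
groups of three males and three females whose hepatic ascorbate
concentration (ng per mg tissue) varies with an ascorbate dosing regime —
needs four things:

1. a defensible treatment of the many **missing values**, which in LFQ are
   predominantly left-censored (low-abundance proteins drop out first);
2. a **quantifiability filter** that refuses to test proteins with too
   little evidence;
3. **pairwise differential-abundance calls** between treatment groups that
   remain stable at n = 3 per group; and
4. a **screen for proteins whose abundance tracks the continuous
   covariate** across all 18 animals of one sex, rather than differing
   between any two particular groups.

`lfqscreen` implements these four stages, a PCA front-end for sample-level
structure, and a synthetic-data generator that emulates the whole design so
that every stage can be validated against known ground truth.

## Imputation model

Missingness in LFQ is treated as missing-not-at-random: the probability
that a cell is unobserved increases as the true intensity decreases.
Under that premise a missing cell is evidence of *low* abundance, and the
package replaces it by a low-percentile "noise value" of its condition:

* a **condition** is by default a (group x sex) cell of the design, since
  females and males are analysed as two independent 18-sample studies;
  `condition_by = "group"` pools the sexes instead;
* the noise value is the **1st percentile** (linear-interpolation
  quantile, `type = 7`) of all *observed* intensities in that condition's
  columns, across all proteins — one scalar per condition;
* observed cells are never touched, so imputation is idempotent, and the
  pre-imputation missingness pattern is carried along (`raw_mask`) because
  two later rules must see it: the quantifiability filter and the
  missing-sample exclusion of the correlation screen.

Model-based alternatives (kNN, MinProb draws, maximum likelihood) are
deliberately out of scope: a single deterministic percentile keeps the
pipeline reproducible and auditable.

## Quantifiability

A protein enters a two-condition comparison only if

* it has observed intensities in **all three replicates of at least one**
  of the two conditions (with three replicates per group, "at least three
  values in the three replicates" can only mean complete observation), and
* **two or more** unique + razor peptides support it.

When both rules fail, `insufficient_replicates` is reported as the single
reason (the replicate rule is checked first). The filter is monotone:
adding an observed replicate or a peptide can never turn a quantifiable
protein unquantifiable.

## Differential abundance: the dual criterion

For each of the 15 unordered group pairs, within each sex, three
statistics are computed per quantifiable protein:

* the **ratio of LFQ intensity means** on the (imputed) linear scale —
  note this is a ratio of arithmetic means, not `2^log2fc`;
* a **robust Z-score** of the log2 fold change: the vector of per-protein
  log2 ratios of one comparison is standardised by its median and its
  MAD (scaled by 1.4826). Robust scaling keeps the ±1.96 threshold
  meaningful even when a large fraction of the proteome shifts; an
  ordinary mean/sd Z would be inflated by the very effects one wants to
  detect. The field does not pin down one Z definition; this one is pinned
  and documented here.
* a **moderated t q-value**: per-protein log2-scale pooled variances
  (df `d_g = n_a + n_b - 2 = 4`) are shrunk toward an empirical-Bayes
  prior. The hyperparameters `(d0, s0^2)` of the scaled
  inverse-chi-square prior are estimated by moment matching on the log
  variances: with `z_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`,
  `trigamma(d0/2) = var(z) - trigamma(d_g/2)` is solved by Newton
  iteration on the trigamma inverse, and `s0^2` follows from the mean
  relation. If the observed dispersion of log variances does not exceed
  its sampling expectation the prior df is infinite and every moderated
  variance equals the geometric-moment estimate `exp(mean(log s_g^2))`.
  The moderated statistic
  `t = log2fc / sqrt(s2_tilde (1/n_a + 1/n_b))` is referred to a t
  distribution with `d0 + d_g` df (normal when `d0` is infinite), and
  two-sided p-values are Benjamini–Hochberg adjusted within the
  comparison. With `d0 = 0` the machinery reduces exactly to the ordinary
  pooled two-sample t-test, which is how it is validated.

A protein is called **up** iff `q < 0.05` *and* `Z > 1.96`, **down** iff
`q < 0.05` *and* `Z < -1.96`; either criterion alone is insufficient.
Per-sex union lists (significant in at least one comparison) and their
cross-sex intersection summarise the comparisons.

Zero residual variances — possible when imputation makes both groups
constant — are excluded from the hyperparameter fit (their log is
undefined) but still receive a moderated variance through the prior.

## The covariate screen

Within one sex (N = 18 animals), each protein's imputed intensity —
log2-scaled by default — is correlated with the per-animal covariate.
Three gates must all pass:

* `|r|` must exceed the critical value
  `t*/sqrt(t*^2 + n - 2)`; at n = 18 and a two-sided 1% level this is
  **0.5897** (4 d.p.), the package's `critical_r(18, 0.01)`;
* the **fold gate**: the imputed-mean ratio between the extreme dose
  groups (default GL40 over GL00) must exceed 2 in absolute terms,
  i.e. `max(ratio, 1/ratio) > 2`, so down-regulated correlators pass the
  same gate as up-regulated ones;
* the **missingness gate**: proteins missing (pre-imputation) in more
  than 5 of the 18 samples are excluded outright.

Correlation is computed on imputed values with missingness handled solely
by the third gate — not by pairwise deletion — so `n_used` always equals
the sex's sample count and the critical value is the same for every
protein. Direction (positive/negative) is assigned only when all three
gates pass; the gates are mutually independent, so their order is
irrelevant. Per-sex positive/negative lists and the cross-sex common lists
are the screen's outputs. FDR over correlation p-values is intentionally
not applied: the screen gates on a fixed critical r.

## PCA

`lfq_pca()` runs classical PCA (via `prcomp`) on the imputed log2 matrix
with samples as observations: centering on by default, unit scaling of
proteins on by default (constant proteins are dropped with a warning when
scaling). The component sign is fixed by making each loading's
largest-magnitude entry positive so outputs are reproducible across
platforms. Explained-variance fractions are relative to the total variance
of all components.

## The synthetic generator

`simulate_study()` emulates the study design end to end:

* **design**: 6 groups x 3 replicates x 2 sexes = 36 animals; each
  animal's covariate is its group mean plus Gaussian noise (sd 10 ng/mg,
  truncated at zero). Default group means 0, 5, 15, 120, 150, 150 ng/mg
  for GL00, GL01, GL05, WT00, GL40, GLR40 are *illustrative* dose-ordered
  values, not measurements; the within-group animal dispersion is not
  documented anywhere authoritative, so it is configuration with no claim
  of fidelity.
* **abundance**: per protein,
  `log2 I = baseline + slope * covariate + sex_shift * [male] + N(0, residual_sd)`
  with baseline ~ N(25, 2) on the log2 scale (typical LFQ dynamic range),
  residual sd 0.5 by default. Four classes — dose-correlated up
  (slope +0.02 log2 per ng/mg), dose-correlated down (-0.02),
  sex-differential (±1 log2 shift in males), and null — are apportioned
  exactly by largest-remainder rounding, so realised counts match the
  requested proportions.
* **dropout**: each cell is set missing with probability
  `plogis(-steepness * (log2 I - midpoint))` (defaults: steepness 0.8,
  midpoint 21), i.e. a logistic left-censoring curve — the premise of the
  low-percentile imputation rule. Steepness 0 degenerates to a constant
  50% dropout, used as a self-check.
* **plumbing realism**: a configurable fraction of rows is flagged
  reverse/contaminant (5%), peptide counts follow 1 + Poisson(3) with 10%
  of proteins forced to a single peptide so the peptide filter is
  exercised, and fixtures round-trip through the MaxQuant-style
  tab-delimited dialect.

What the generator does **not** emulate: peptide-level structure,
retention-time or m/z effects, batch effects, or correlated proteins
(rows are independent given the design). Passing tests on synthetic data
therefore demonstrate the statistical machinery under the generative
model, not performance on any particular real dataset.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
brute-force percentile and BH step-up implementations, hand-computed
ratios and correlations, `t.test` at `d0 = 0`, limma's `squeezeVar` as an
external cross-check of the variance-moderation fit, and Monte-Carlo null
calibration of `critical_r`. Study-scale properties are checked at sizes
chosen to keep Monte-Carlo error well below the tolerances being asserted:
5000 proteins x 20 seeds for null calibration (type-I control of the dual
criterion; 1% r-gate exceedance), and 1000 proteins x 5 seeds for
recovery of spiked dose-correlated proteins (slope 0.014 log2 per ng/mg,
residual sd 0.3, extreme-group fold about 4.3, true |r| about 0.95).

Two deliberate choices in the recovery benchmark: spiked proteins all
carry at least two peptides (the peptide filter is a mechanical rule
tested separately; leaving 10% single-peptide spikes would cap measurable
sensitivity at 0.9 by construction), and the benchmark runs under mild
censoring (dropout midpoint 19, about 2.5% missing cells, imputation and
all gates still active). Under the generator's default censoring a
substantial fraction of low-baseline anticorrelated spikes is censored
into the >5-missing exclusion — the gate doing exactly its job — which
measures the detection floor rather than the screen's sensitivity; the
censoring behaviour itself is validated separately (null calibration at
default dropout, the monotone-MNAR property, and the toy missingness-gate
tests).

Note the benchmark's conditions are slightly over-determined: with the
default covariate spread (~68 ng/mg within a sex), requiring an
extreme-group fold of at least 4 forces a slope at which the true
correlation is ~0.95 rather than 0.9; the fold gate is the binding
constraint, and since every recovery quantity is a one-sided lower bound
the stronger signal is the conservative resolution.

## Numerical and degenerate-input conventions

* Percentile: linear interpolation between order statistics (`type = 7`);
  the method is pinned because different quantile definitions move the
  noise value.
* Zero intensities are converted to missing on ingest (the LFQ producer
  writes 0 for unquantified cells); an observed zero after that is an
  error, so linear-scale group means are always positive after imputation.
* A comparison whose log2 ratios have zero MAD (or fewer than 10
  quantifiable proteins) raises an error rather than emitting unstable
  Z-scores.
* Zero-variance rows in the correlation screen get `r = NA` with a
  `zero_variance` reason and never pass the r gate.
* The trigamma inverse is solved by damped Newton iteration to a relative
  tolerance of 1e-10, with asymptotic closed forms for extreme arguments.
* `critical_r` is compared at full precision internally; the 4-decimal
  0.5897 is a display convention.

## Known limitations

* The imputation constant is shared by all proteins of a condition; for
  proteins whose missingness is *not* left-censored this biases means
  toward the noise floor (mitigated, not removed, by the quantifiability
  and missingness gates).
* The moderated t assumes a common residual df across proteins (true
  here by design: complete 3 + 3 after imputation).
* Statistics are computed on imputed values; with very high missingness
  the effective sample size is overstated. The >5-missing exclusion
  bounds this for the screen but not for the pairwise comparisons, where
  the complete-condition rule plays the analogous role.
* The union/intersection summaries treat each comparison's calls as
  exchangeable evidence; no cross-comparison multiplicity adjustment is
  attempted beyond per-comparison BH.
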