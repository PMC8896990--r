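---
title: "Methods: multivariate connectivity-pattern analysis for longitudinal rs-fMRI cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate connectivity-pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connpattern)
```

## The scientific question

After a subcortical stroke that damages corticospinal projections, does the
*pattern* of resting-state functional connectivity between cortical
sensorimotor areas change — either on average, or in its between-subject
variability — over the first year of motor recovery? `connpattern`
implements the full statistical machinery needed to ask that question on
ROI-level BOLD time series: Fisher-Z connectivity patterns, a multivariate
permutation test on Euclidean pattern distance, a permutation-based
equivalence test that bounds undetected effects, within-group variability
tests, split-half reliability, and the voxel-level relative-connectivity
(RelCon) ratio. Because cohorts of this kind are rarely public, the package
also ships a first-class synthetic-cohort generator that emulates the
emulated design: 19 patients and 11 controls, five sessions at weeks
1/4/12/24/52, 210 volumes per scan at TR = 2 s, and roughly 11% of
follow-up sessions missing.

## The connectivity pattern

Ten ROIs (S1, M1, PMd, PMv, SMA in each hemisphere) give a 10 × 10
correlation matrix per scan. Pearson correlations of the ROI-averaged BOLD
series are Fisher-Z transformed (`atanh`, variance stabilizing) and the
upper triangle is vectorized in a fixed canonical order: 45 weights that
decompose into 10 intrahemispheric ipsilesional, 10 intrahemispheric
contralesional, and 25 interhemispheric pairs. Hemisphere block 1 is the
ipsilesional hemisphere for patients (the symptomatic side for a bilateral
lesion) and the left hemisphere for controls, so that pattern vectors and
their Euclidean distances are comparable across subjects.

Two conventions deserve note:

* **Control orientation.** Controls have no lesion, so their
  intrahemispheric weights are averaged across hemispheres
  (`average_pattern(control_hemisphere_average = TRUE)`). The source
  procedure specifies this averaging only for intrahemispheric weights; we
  extend it symmetrically to the two orientations of each heterologous
  interhemispheric pair (homologous pairs are orientation-free). This is a
  documented convention, not an empirical claim.
* **Degenerate correlations.** `|r| >= 1 - 1e-7` is clamped with a warning
  rather than made fatal, so synthetic edge cases degrade gracefully.

## Permutation inference

`delta_pattern_test()` measures the Euclidean distance between the two
groups' mean patterns and compares it to the distances obtained after
shuffling group labels (10,000 shuffles by default, size-preserving).
Distances are nonnegative and the group-distance estimate is positively
biased under the null; the permutation reference accounts for this. The
p-value counts null values **greater than or equal to** the observed
distance, so the degenerate all-identical case yields p = 1 and the test
is never anti-conservative.

`variability_test()` treats the mean member-to-group-mean distance as an
idiosyncrasy measure. Its null (from the same shuffling) is generally
asymmetric when group sizes differ, so the default p-value is one-sided in
the observed direction; a doubled-tail two-sided option exists.

`longitudinal_deltas()` compares a reference week against each later week
on the subjects observed at both (complete-case matching per comparison).
Since the same subjects appear at both weeks, the default null permutes
the week label *within* subject (a paired sign-flip design); free
relabeling is available via `paired = FALSE`. The source text does not
state its shuffling unit for these within-group comparisons; pairing is
the statistically conservative reading. Note a paired design with n
subjects cannot produce p below 2/2^n regardless of the shuffle count.

`week_variability_anova()` tests per-subject distance-to-reference values
across weeks. It is a plain one-way ANOVA with the week factor: for 10
subjects × 4 weeks the degrees of freedom are (3, 36), matching the
published table. (A repeated-measures formulation would give (3, 27); the
published df identify the one-way form, which we follow.)

## The equivalence test

When the distance test is non-significant, `equivalence_test()` asks which
effect sizes the data can actively *reject*. Per-subject deviations from
their own group mean are pooled; in each simulation the labels are
shuffled and a random Gaussian pattern scaled to Euclidean norm Δ\* is
added to every pseudo-patient, giving the sampling distribution of the
observed distance if the true difference had norm Δ\*. A candidate Δ\* is
rejected at level α when the observed distance falls at or below the
α-quantile of that distribution. The reported bound is the smallest grid
value (default grid 0.05 to 3.0 in steps of 0.05) from which every larger
value is rejected; identical shuffles and injected directions are reused
across the grid (common random numbers), which makes the rejection
boundary monotone. A fresh direction is drawn per simulation by default
(`redraw_direction = FALSE` fixes one), matching the per-simulation
wording of the source procedure.

**Effect-size conversion.** The source reports an "average univariate
Cohen's d" for Δ\* without defining the per-connection components of a
random pattern. We resolve this as the expectation over random unit
directions of `mean_i |δ_i| / s_i`, with `s_i` the pooled per-connection
SD (`cohens_d_from_delta(method = "expected")`). A single-draw variant and
the asymptotic heuristic `Δ* · sqrt(2/π)/sqrt(K) · mean(1/s_i)` are
exposed as options; for unit SDs the expectation reduces to
`Δ* · sqrt(2/π)/sqrt(45)`.

## The synthetic cohort: a stated world

Each subject owns a Fisher-Z pattern: ground truth, plus (for patients) a
fixed offset pattern of configurable norm in one cohort-level random
direction, plus Gaussian idiosyncratic noise; each session adds a smaller
session-level perturbation. The pattern is mapped to a correlation matrix
entrywise by `tanh`, repaired to positive definiteness if needed, and the
scan is a zero-mean multivariate AR(1) process with that stationary
correlation (common φ = 0.3; the source gives no temporal model, and
AR(1) is the simplest choice producing split-half reliabilities below 1).
Lesion side alternates across synthetic patients to exercise hemisphere
flipping; follow-up sessions are dropped independently at the configured
missingness; the enrollment session is never dropped.

Parameter defaults and where they come from:

| parameter | default | rationale |
|---|---|---|
| `ground_truth_z` anchors | 0.91, 0.58, 0.90, 0.59 | published control values for S1–M1, M1–PMv (within-hemisphere), S1–S1, M1–PMv (between); remaining pairs interpolate, homologous > heterologous |
| `subject_sd_patient` / `subject_sd_control` | 0.43 / 0.42 | calibrated so within-group pattern variabilities match the published week-1 values (~2.96 / ~2.81) given `session_sd` and 210-volume sampling noise |
| `session_sd` | 0.1 | modest session-to-session wobble, below subject level |
| `ar1_phi` | 0.3 | realistic temporal autocorrelation after preprocessing |
| `missing_rate` | 0.11 | published ~11% missing sessions |
| `roi_noise_sd` | 0 | additive observation noise (SNR knob); 0 keeps the generator unbiased |
| `injected_difference_norm` | 0 | the null world, mirroring the study's finding |

What the generator does **not** emulate: raw EPI volumes, head motion,
physiological noise, scanner drift, or hemodynamics. One visible
consequence: with `roi_noise_sd = 0` the default world is cleaner than
real BOLD, and split-half reliabilities come out near 0.9 rather than the
~0.66 of the real data. A green reliability test therefore establishes
the estimator's behavior, not the noise level of any scanner.

### The positive-definiteness constraint (a substantive caveat)

Implementation revealed a geometric fact worth knowing when interpreting
Δ\*: independent Fisher-Z perturbations of the magnitude needed to match
the published between-subject variability (per-weight SD ≈ 0.43), and
even a lone injected difference of norm 1 (per-weight ≈ 0.15), push the
entrywise `tanh` matrix far outside the cone of positive-definite
correlation matrices for essentially every draw. The repair projection
(eigenvalue clipping at 1e-6 with renormalization to unit diagonal — the
exact Higham nearest-correlation projection behaves the same) then
attenuates the realized group difference to roughly half the configured
norm. In other words, *no actual 10-ROI correlation structure exists* with
a true Fisher-Z difference of norm ~1 near these ground truths: real
pattern variability of that size must be structured along PD-compatible
directions, not isotropic. Accordingly, the equivalence-coverage
validation injects the true difference at the pattern level (exactly where
the equivalence simulation itself injects), while the end-to-end generator
injection path is validated through power monotonicity, where attenuation
does not break the property.

## Reliability

`split_half()` computes the pattern independently on the first and second
100 volumes (volumes beyond 200 of a 210-volume scan are ignored) and
Pearson-correlates the two half-patterns per subset. Group summaries use
a percentile bootstrap over subjects (10,000 resamples by default); the
source does not state its CI method, and the bootstrap is our documented
choice.

## RelCon

`relcon()` averages raw voxel-pair Pearson correlations across all
ipsilesional × contralesional SM1 pairs and divides by the average over
distinct within-ipsilesional pairs. Self-correlations are excluded from
the denominator (they are identically 1 and would inflate it); the source
description is ambiguous on this point, and a Fisher-Z-averaged variant is
provided. SM1 is operationalized as the union of the S1 and M1 voxel sets.
The ratio is refused when the within-hemisphere mean correlation is within
1e-6 of zero.

## Numerical and design choices

* Quantiles in the equivalence test use R's default type-7 definition.
* The equivalence Δ\* scan proceeds downward from the largest rejected
  grid value, so the reported bound is the smallest value from which the
  rejection region is contiguous.
* When a degenerate cohort has zero pooled SD on every connection, Δ\* is
  still reported but its Cohen's d equivalent is NA (the standalone
  converter keeps its documented error).
* All randomized routines take a seed, run under a local RNG state (the
  caller's `.Random.seed` is untouched), and are bit-reproducible.
* Results are reported unadjusted for multiplicity across subsets and
  weeks, matching the source analysis; the run log states this.

## Known limitations

* The off-anchor entries of the default ground-truth pattern are an
  interpolated convention; the source publishes only four anchor values.
* The generator's isotropic Fisher-Z noise model conflicts with the PD
  geometry at realistic magnitudes (see the caveat above); a structured
  (low-rank) variability model would be the natural refinement.
* `extract_roi_means()` operates on in-memory arrays; no NIfTI file
  reader is bundled.
* Mixed-effects model fits for M1–M1 and RelCon trajectories are out of
  scope; the pipeline emits the per-subject tables such fits would
  consume.

## A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1)          # the default null world
cohort <- generate_cohort(cfg)
report <- run_pipeline(run_config(B = 1000, seed = 1, verbose = FALSE),
                       cohort = cohort)
report$group_tests[report$group_tests$week == "W1", ]
```

Every number in the report tables is recomputable from the serialized
null distributions shipped alongside them; nothing in this vignette states
an empirical result that the test suite or the acceptance script does not
itself compute.
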