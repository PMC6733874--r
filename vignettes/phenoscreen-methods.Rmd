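---
title: "Behavioral phenoscore screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral phenoscore screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

## The problem

High-throughput behavioral screening in larval zebrafish measures group
motor activity in 96-well plates under a timed battery of stimuli
(low-volume acoustic taps and light pulses), and asks which library
compounds phenocopy an archetypal treatment. The archetype here is the
sedative state with an *enhanced acoustic startle response* (eASR):
animals that are immobile between stimuli, barely respond to light, yet
over-respond to a quiet tap — paradoxical excitation under a CNS
depressant. This package implements the full analysis chain for such a
screen, plus a seeded synthetic-data generator so every stage can be
exercised and validated without video data.

## Motion index and derived statistics

Activity per well is summarized by the motion index
`MI[t] = sum over pixels of |frame[t+1] - frame[t]|` at the video frame
rate (25 Hz by default). Conventions that the raw definition leaves open
are fixed as follows:

* `MI[t]` carries the timestamp of frame `t + 1`; stimulus windows are
  half-open `[onset, onset + duration)`.
* Event response windows add a post-stimulus tail (`tailS`, default 1 s)
  because startle responses outlast a 70 ms tap; the tail length is a
  parameter, not a constant of nature.
* The normalized series is `nMI = (MI - min MI) / max MI`, exactly as
  written: the divisor is the maximum, not the range, so the normalized
  maximum is `(max - min)/max < 1` whenever the minimum is positive. An
  all-zero MI (fully immobilized well) has no admissible divisor; pipeline
  code returns all zeros with a degenerate flag instead of erroring.
* Startle magnitudes integrate MI over the window with the trapezoidal
  rule; per-modality response magnitudes average the per-event window
  maxima (ties broken by the earliest time point, as `max()` returns the
  first maximum). A modality with no events is reported `NA`, never 0.
* Z-scores use the sample (n-1) SD; "normalized 0-1" is min-max rescaling
  across the well set, the only reading that actually yields the stated
  range.

## Phenoscore and the reference profile

The phenoscore of a well is the Pearson correlation between its MI series
and the reference profile. A "correlation distance" `d = 1 - r` carries
the same information; we report `r` itself because the stated range
(-1 to +1, positive = positive correlation) identifies that convention
uniquely. Zero-variance wells score 0 with a degenerate flag. Series
differing in length by one sample (trailing-frame bookkeeping) are
truncated to the shorter; anything larger is an error rather than a
silent re-alignment.

The reference is built from 36 replicate positive-control wells by
selecting the 12 whose responses are most mutually consistent and most
distant from vehicle behavior:

```
J(S) = mean pairwise cor within S  -  lambda * mean cor(S, DMSO wells)
```

maximized over size-12 subsets by simulated annealing with
swap-one-member proposals, Metropolis acceptance and geometric cooling
(default 20,000 iterations, cooling 0.995/iteration, `lambda = 1`). The
initial temperature defaults to the SD of `J` over 100 random subsets,
which makes the schedule scale-free in `J`'s units. The chain tracks the
best subset ever visited, so the returned objective never falls below the
best of its own proposals; on instances small enough to enumerate
(`exhaustiveReference()`), the annealer reproduces the exact optimum, and
at the default size it beats the best of 1,000 random subsets.

Significance cutoffs are not taken from theory: `simulateCutoffs()`
scores a large sample of simulated vehicle-class wells against the frozen
reference and returns upper quantiles (1% and 5% by default) of that null
distribution. Plate quality is summarized by the standard screening
Z-factor `1 - 3(sd_pos + sd_neg)/|mu_pos - mu_neg|` and a two-sample
Kolmogorov–Smirnov comparison. Note the Z-factor is validated against its
closed form only; published per-screen Z-factors computed by unstated
variants are not reproduction targets.

## The synthetic generator

No public raw data accompany screens of this kind at the scale needed for
testing, so the generator is a first-class module. One well is

```
MI(t) = m_w * [ gB * b(t) + gA * sum_taps K_ac(t) + gV * sum_pulses K_vi(t) ] + eps(t)
```

truncated at zero, with `b(t)` smoothed positive baseline noise, `K_ac`
an alpha-function startle kernel (0.12 s rise, ~0.5 s decay), `K_vi` a
10 s boxcar with an onset transient, `m_w` a lognormal well effect, and
`eps` additive measurement noise. Class gains (`gB`, `gA`, `gV`)
interpolate from the vehicle value 1 to the class value along the
compound's Hill dose law; the optional descending Hill arm produces
bell-shaped responses and bounded efficacy windows. Vehicle wells sit at
the dose-law origin, and the toxic class is modelled as
concentration-independent immobilization (all gains ~0): a "toxic at any
dose" compound, which is what the toxic call is meant to capture.

Per-well lognormal jitters on the gains and on the noise level create the
well-to-well phenoscore spread seen on real control plates; per-event
amplitude jitter decorrelates individual startles. All constants live in
`generatorDefaults()`. The calibration was set once, at large simulated
n, so that the full default pipeline (36+36 wells, annealed reference,
fresh control wells) reproduces the control statistics of a
well-separated production screen — positive wells 0.71 with SD 0.11,
vehicle wells 0.2 with SD 0.05 — and the constants were then frozen.
Sampling: 25 Hz over the default 120 s battery (6 taps, 3 violet
pulses), i.e. 3,000 samples per well, which keeps a 944-well control
experiment under a few seconds while preserving the time-scale separation
between kernels and baseline.

Randomness follows a one-root-seed contract: each well draws from a
deterministic substream indexed by its position (positives and negatives
in disjoint index ranges), so adding wells never perturbs existing ones.
`nFish` enters only as a noise-variance divisor (`8/n_fish`);
fish-to-fish interaction is not modelled.

What the generator does *not* emulate: habituation across repeated taps,
plate-position effects, circadian drift, video artifacts, or compounds
with mixed phenotypes. Passing tests therefore demonstrate correctness of
the analysis pipeline under a plausible data-generating process, not
robustness to every failure mode of real plates.

## Screening calls

The screen table records, per well, the phenoscore and an
*immobilization index*: `1 - clip(violet_mag / median violet_mag of DMSO
wells, 0, 1)`. This index is an artifact definition — the light assay is
the screen's motor-activity readout, so suppression of the light-evoked
response relative to vehicle is the natural operationalization of
immobilization. Compounds are scored by the mean phenoscore over
replicate wells (mean rather than max, for robustness), ranked
descending with lexicographic compound-id tie-breaks (making the top-k
rule fully deterministic), and the top `kHits` (default 125) are hits.
Non-hits with immobilization index >= 0.9 whose phenoscore falls below
the hit floor (the lowest phenoscore among called hits) are toxic; the
rest are inactive. Vehicle wells pass through as controls, so calls
partition the plate.

Dose-response curves are 4-parameter logistic fits on log10
concentration via Levenberg–Marquardt least squares with multi-start
initialization (EC50 started across the tested span, Hill slopes
0.5/1/2/4 and negative variants); EC50 is constrained to within a factor
of 10 of the tested span, and non-convergence — including flat responses
— is reported as a flag with diagnostics, never an exception. Efficacy
windows mark each tested concentration strong when its mean phenoscore
reaches a cutoff (typically the simulated 5% cutoff) and report the
longest contiguous strong run, taking the first run on ties.

## Cheminformatics

Hit structure is analyzed on binary fingerprints. Tanimoto similarity
`|A∩B|/|A∪B|` defines the distance `1 - T` for average-linkage
hierarchical clustering (average linkage is the common choice for
Tanimoto dendrograms; the cut count is a parameter). Two all-zero
fingerprints are treated as identically empty (similarity 1, with a
warning; configurable to 0). Guilt-by-association target enrichment uses
the enrichment factor `EF = (k/topN)/(K/N)` with a hypergeometric tail
p-value, optional permutation p-values, and Benjamini–Hochberg adjustment
across targets. For discrete statistics the plain permutation p-value is
conservative; `ties = "midp"` and `ties = "random"` (fuzzy p-values,
exactly uniform under the null) are provided, the latter being the right
tool for calibration studies. The published similarity-ensemble machinery
(raw-score sums with an extreme-value background model) is deliberately
out of scope; the EF statistic is the generic formulation. Binding
panels are normalized as `npKi = 4 - log10(Ki)` with the Ki unit recorded
as metadata (default uM) rather than guessed.

## Numerical choices and limitations

* Quantiles use R's default type-7 definition; the 1% cutoff is
  therefore always at least the 5% cutoff.
* The annealing objective is evaluated from precomputed correlation
  matrices, so a 20,000-iteration chain on 36 candidates runs in about a
  second.
* `fitDoseResponse` can confuse very shallow true slopes with flat
  responses at high noise; the `converged` flag plus `rmse` should be
  inspected before trusting an EC50 near the span boundary.
* Printed significance cutoffs from any particular published screen
  depend on that screen's (unavailable) simulation recipe; this package's
  cutoffs are defined by its own documented null procedure and are not
  expected to match any specific printed pair.
* Problem sizes used in the shipped tests (e.g. 944-well control
  experiments, 200-compound screens, 126-compound libraries) were chosen
  as the smallest sizes at which the statistical claims are stable; all
  scale linearly if enlarged.

## A worked example

```{r, eval = FALSE}
candidates <- generateControlPlates(36, 0, seed = 1)
vehicle <- generateControlPlates(0, 36, seed = 2)
ref <- selectReference(candidates, vehicle, annealConfig(seed = 3))

controls <- generateControlPlates(472, 472, seed = 4)
scores <- phenoscore(controls, ref)
cls <- wellData(controls)$class
qualityStats(scores$phenoscore[cls == "etomidate_like"],
             scores$phenoscore[cls == "dmso"])

cut <- simulateCutoffs(function(n, s) generateControlPlates(0, n, seed = s),
                       ref, nSim = 1000, seed = 5)

scr <- generateScreen(200, 0.1, 0.05, seed = 6)
tab <- screenTable(scr$profiles, ref)
calls <- rankAndCall(tab, kHits = 20)
head(attr(calls, "compounds"))
```
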