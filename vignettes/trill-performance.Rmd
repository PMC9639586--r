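---
title: "Measuring and comparing trill performance between the sexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing trill performance between the sexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trillr)
```

## The problem

Blue tit (*Cyanistes caeruleus*) song is a short vocalization: a few
high-pitched introductory notes followed by a *trill*, the terminal
section in which one note shape is repeated in rapid succession. Both
sexes sing, and quantitative sex comparisons rest on a chain of
measurements made on the trill: spectral descriptors of each note,
performance scores of the whole trill, and a statistical stage that
separates sex, age and seasonal effects from individual and pair-level
variation. `trillr` implements that chain end to end and ships a seeded
synthetic song generator so every stage can be exercised and validated
without any field recording.

## The measurements

All acoustic measures operate on the trill only; introductory notes are
more variable, sometimes absent, and are excluded by design.

* **Mean power spectrum** (`mean_power_spectrum()`): Welch-averaged
  1024-sample Hann windows (50% overlap, final window snapped to the
  note end), in dB relative to the spectral peak. The frequency grid
  step is `sample_rate/1024` (46.9 Hz at 48 kHz).
* **Peak frequency**: the bin with maximum amplitude; ties break to the
  lowest frequency for determinism.
* **Maximum/minimum frequency and bandwidth** (`freq_extent()`): the
  extreme frequencies reaching −20 dB relative to the peak; bandwidth is
  their difference. Because the reference is the peak, these are
  scale-free, which is why notes are peak-normalized when cut from a
  recording.
* **Trill length**: start of the first usable trill note to the end of
  the last, in seconds.
* **Trill rate** (`trill_rate()`): `(N − 1) / onset span`. Each counted
  note carries its following gap except the last, so the estimator does
  not depend on the number of renditions; it requires at least three
  consecutive notes. Masked notes break the onset spacing, so the rate
  is computed on the longest unmasked run of consecutive notes.
* **Vocal consistency** (`vocal_consistency()`): mean over consecutive
  note pairs of the maximum spectrogram cross-correlation
  (`spcc_pair()`), with 512-sample Hann windows, 90% overlap, dB floored
  at −80, and temporal offsets searched up to ±20 ms. Offsets step on
  the spectrogram frame grid (the hop is 51 samples ≈ 1.06 ms at
  48 kHz, the closest realizable step to a 1 ms search resolution);
  the shorter spectrogram slides over the longer one and the Pearson
  correlation is taken over the overlapping cells.
* **Vocal deviation** (`fit_upper_bound()`, `vocal_deviation()`): songs
  of both sexes are pooled, bandwidth is cut into 100 Hz bins, the
  maximum trill rate per non-empty bin is regressed on the bin-centre
  bandwidth (OLS), and each song's deviation is its orthogonal distance
  to that upper-bound line, signed positive below the bound. We bin the
  *bandwidth* axis: 100 Hz is not a meaningful bin width for a trill
  rate of ~8 notes/s, and a few kHz of bandwidth range divided into
  100 Hz bins yields a bound fit with a few dozen degrees of freedom,
  consistent with published fits. Distances are computed in (Hz,
  notes/s) axes; since the frontier slope is much smaller than 1 in
  those units, the orthogonal distance is dominated by the rate
  shortfall.

Per song, note-level measures are averaged into one row, with at most
10 songs per individual, song type and recording date (earliest songs
kept, mirroring counting from the first recorded song).

## The statistical stage

* Weekly singing probabilities (proportion of box visits with a singing
  bird, per sex) are compared with a paired Wilcoxon signed-rank test;
  songs per observation with a Mann–Whitney U test (exact null
  distributions for small untied samples, normal approximation with
  continuity correction otherwise).
* Context use is modelled with a binomial GLM with a **log** link:
  each individual contributes one proportion per context (solo, alarm,
  agonistic; zeroes included), weighted by its number of observations,
  with sex, context, and their interaction as predictors and female /
  solo as reference levels. Exponentiated coefficients are rate ratios;
  the package reports both scales, the back-transform being exactly
  `exp()` of the log-scale column. Confidence intervals are
  profile-likelihood intervals (better calibrated than Wald intervals
  when some context counts are small), with a Wald fallback. The GLM
  pseudo-R² is McFadden's (the likelihood-ratio flavour; configurable
  choices would all be reported alongside the same fit).
* Acoustic traits are modelled with Gaussian linear mixed models
  (`lme4`, maximum likelihood so AICc is comparable across fixed
  structures) with random intercepts for individual and pair. All
  admissible fixed-effect subsets (interactions only together with
  their main effects) are ranked by AICc; models within ΔAICc < 2 of
  the best form the selected set. The package reports the
  **full-average** estimate (zero substituted where a model lacks the
  term — a shrinkage estimate), the **conditional** average over models
  containing the term, the unconditional standard error, and a 95% CI
  centred on the conditional average. The CI is attached to the
  conditional average deliberately: the zero-substituted full average
  is biased towards zero by construction, and pairing it with a
  symmetric interval produces intervals that demonstrably under-cover
  the generative truth in this package's own recovery suite. Relative
  importance is the summed (renormalized) Akaike weight of selected
  models containing the term — the only definition consistent with
  non-integer importance values. R²m/R²c follow the variance
  decomposition for mixed models (fixed / fixed-plus-random share of
  total variance) on the full model.
* Continuous covariates (weeks to first egg, tarsus) are scaled and
  centred. The age class enters the averaged models as a **centred
  dummy**: in models containing a sex × age interaction, a
  treatment-coded main effect of sex would be the conditional effect at
  the reference age, and averaging coefficients with different meanings
  across models inflates their spread. Centring the interaction partner
  keeps the sex coefficient an average sex effect in every candidate.
* Variance-inflation factors are computed from auxiliary regressions on
  the non-interaction design columns (`1/(1 − R²)`), flagged above 3.
* Random-effect SD intervals use profile likelihood
  (`varcomp_ci = "profile"`), which is deterministic and avoids the
  runtime cost of a parametric bootstrap.

## The synthetic population

`population_config()` fixes the generative truth; `synth_population()`
draws a complete dataset (individuals, song-level traits, focal
observations, weekly box visits) bit-for-bit reproducibly from its
seed. Defaults emulate the published field estimates for this species:

* trill length: intercept 0.483 s, male effect +0.196 s, variance
  components 0.06 (individual), 0 (pair), 0.04 (residual);
* vocal consistency: female intercept 0.867, male effect +0.024, a
  seasonal increase, variances 0.002 / 0 / 0.004;
* peak frequency: intercept 5.02 kHz, age and seasonal declines with
  sex interactions, variances 0.15 / 0.02 / 0.09 (kHz²);
* trill rate: intercept 8.582 notes/s, variances 2.9 / 0.48 / 1.2;
* song output: negative-binomial songs per observation with mean ± SD
  10.2 ± 10.6 (females) and 24.3 ± 23.5 (males), truncated at 1;
  weekly singing probabilities 8.2% vs 28.2% of boxes visited;
* observation intensity: ~2.8 context observations per female and ~3.7
  per male (the field ratio of 101 observations over 36 females to 106
  over 29 males);
* repertoires: females drawn mostly with one song type, males with
  two to four, from a shared population pool.

The published random-effect column is printed under a caption calling
it a standard deviation, but the printed R²m/R²c values are arithmetic
consequences of reading those numbers as *variances* (e.g. for trill
length, R²c − R²m = 0.504 equals 0.06/(0.0125 + 0.06 + 0.04) exactly),
and the printed Z value for the trill-length sex effect (3.284)
matches the variance reading too; the generator therefore treats them
as variances.

Seasonal slopes are expressed per week in natural units (e.g.
−0.064 kHz/week for peak frequency), calibrated so the standardized
per-SD effects match the published standardized estimates for a typical
seasonal spread (SD ≈ 4 weeks). Trill rate and bandwidth are negatively
coupled (≈ −300 Hz per note/s plus noise) so pooled songs show the
rate–bandwidth performance frontier with a strongly negative bound
slope. Context probabilities per sex must sum to one; the published
rate ratios are mutually incompatible with that constraint (a male:
female solo ratio of 2.4 on a female solo share of 0.435 would exceed
1), so the defaults keep the two headline ratios — solo ratio 2.4 and
sex × alarm ratio 0.12 — on a feasible simplex: female
(0.30, 0.30, 0.40), male (0.72, 0.0864, 0.1936).

Audio rendering (optional, `render_audio = TRUE`) synthesizes each song
as cosine-tapered (10% Tukey) linear frequency sweeps: the flat-top
envelope keeps nearly the whole synthesized sweep above the −20 dB
bandwidth threshold, whereas a full-length cosine envelope would
suppress the sweep ends and shrink measured bandwidth well below the
nominal one. Notes are placed with exact onset spacing `1/trill rate`
and >10 ms silent gaps; the label track records ground-truth
boundaries. Consistency jitter multiplies frequency endpoints and
duration by `1 + N(0, jitter)`, which degrades SPCC monotonically.
Rendering clamps physically impossible values (negative durations,
consistency above 1); the statistical trait table keeps the raw
Gaussian truth, because the mixed models assume it.

## What the generator does not emulate

Real recordings carry background noise, reverberation, amplitude
modulation within notes, non-tonal calls, and masking by other
species; song types differ in introduction structure, not only in
trill parameters; and real sampling is opportunistic rather than
multinomial. Passing recovery suites on this generator therefore
validates the *measurement and inference chain*, not robustness to
field recording conditions.

## Problem sizes and numerical choices

The recovery suites use 30 pairs (60 individuals) and ≈ 760–900 songs
per replicate with 100 seeded replicates, matching the scale of the
acoustic dataset they emulate; the context analyses use 65 individuals.
Degenerate inputs are explicit errors: silent notes (undefined dB
reference), fewer than three non-empty bandwidth bins (degenerate
bound), constant variables in `scale_center()`, all-zero paired
differences in the signed-rank test, and diverging log-link GLM fits
(complete separation). Peak-frequency ties take the lowest bin;
nearest-date ties in repertoire matching take the earlier male date;
notes shorter than one FFT window are zero-padded with a warning.

## Known limitations

The log-link binomial GLM can step outside the unit interval during
iteration; fits start from log weighted cell means with a damped
retry. The upper-bound regression is sensitive to bin occupancy at the
bandwidth extremes. SPCC offsets are limited to the spectrogram frame
grid. The per-week singing comparison treats weeks as independent.
Model-averaged intervals are approximate by nature; their empirical
calibration under the generator's conditions is part of the test
suite.
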