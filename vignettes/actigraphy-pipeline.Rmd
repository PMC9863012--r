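---
title: "From wrist acceleration to direction-annotated feature importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist acceleration to direction-annotated feature importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

actiphen implements an end-to-end actigraphy analysis for digital
phenotyping of psychiatric risk: raw wrist-accelerometer signals are
reduced to zero-crossing-method (ZCM) activity series, a 96-feature
registry of circadian, sleep and wavelet-structure descriptors is
extracted per subject, low-correlation feature subsets are selected by a
lenient Welch screen and maximal-clique enumeration, three classifier
families are evaluated under stratified 10-fold cross-validation against
a 3-feature baseline, and Shapley attributions of the retained
(above-baseline) models are summed row-wise into direction-annotated
importance rankings. A synthetic-cohort generator with injectable group
effects makes every stage testable without clinical data.

This vignette is the package's methods account: the model at each stage,
its assumptions, the tunable parameters and their defaults, the design
choices made where the design was genuinely open, and what the synthetic
tests do and do not demonstrate.

## Signal preparation

Recordings are triaxial acceleration in g (canonically 10 Hz, ±8 g,
delimited text `t,x,y,z`). Only recordings with at least 2 continuous
days are analyzed (inclusive bound; `min_valid_days`).

Each axis is band-passed with an order-4 Butterworth design,
0.25–2.5 Hz, applied forward and backward (zero phase, so epoch
boundaries are not shifted; the magnitude response is applied twice).
The pass band removes gravity and drift below 0.25 Hz and vibration
noise above 2.5 Hz while retaining the human voluntary-movement band.

Activity is the Zero Crossing Method count: per axis, upward crossings
of the +0.05 g threshold (a sample below the threshold followed by one
at or above it — one count per oscillation cycle; the threshold sits
slightly above the sensor noise floor), summed over the three axes
within 60 s epochs. Epochs are anchored to the first whole minute at or
after the recording start, because all diurnal windows (day thirds,
night windows) are defined in clock time. The epoch series is smoothed
with an 11-epoch sliding mean (5 before, 5 after, truncated at the
series edges); all ZCM-derived features operate on this smoothed series
except the fragmentation index (below).

Two details are worth noting. The crossing definition ("upward crossings
of +τ on the signed filtered signal") is pinned against a brute-force
per-sample counter in the test suite, as are the window searches and
family statistics downstream. And at 10 Hz an in-band oscillation
crosses the threshold at most once per cycle, so per-axis counts are
bounded by the band's cycle count (≈105/min near the 1.75 Hz band
centre); the threshold-crossing rate of Gaussian movement noise responds
steeply to its amplitude near τ, which is what makes ZCM a usable
intensity meter.

## The 96-feature registry

`feature_registry()` fixes names and order:

* **Circadian (6)** — M10 and L5 (mean activity of the most active 10 h
  and least active 5 h windows; contiguous, wrapping within each
  calendar day, 1-epoch stride, averaged over days), relative amplitude
  RA = (M10−L5)/(M10+L5), ADAT (mean daily summed activity), and the
  nonparametric IS and IV. IS and IV use the standard hourly-binned
  definitions (24 clock-hour bins): IS = (n·Σ_h(x̄_h−x̄)²)/(p·Σ(x−x̄)²)
  ∈ [0,1], IV = (n·Σ(x_i−x_{i−1})²)/((n−1)·Σ(x−x̄)²), ≈2 for white
  noise. Their closed-form limits (IS = 1 for a repeated pattern,
  E[IS] ≈ 1/days and E[IV] ≈ 2 for i.i.d. noise,
  IV = 2(1−cos(2π/24)) for an hourly 24-h cosine) are asserted in the
  suite.
* **Boundary envelope (7)** — the epoch series is Savitzky–Golay
  smoothed (window 61 epochs ≈ 1 h, cubic; both config keys) and its
  strict local maxima/minima over a ±15-epoch neighborhood form ceiling
  and floor curves; the features are sums, means, the ceiling–floor
  difference and population standard deviations of these boundary
  values. The envelope reading of "upper/lower boundary" is a documented
  design choice; window, order and neighborhood are configurable, and
  points without a full two-sided neighborhood are never extrema (so
  monotone series correctly have none).
* **Diurnal windows (5)** — mean activity in the clock thirds 00–08,
  08–16, 16–24 (averaged over days) and the mean/population-SD of all
  epochs.
* **Sleep and nocturnal structure (76)** — see below.
* **Wavelet structure (2)** — see below.

Population (divide-by-N) standard deviations are used throughout for
consistency; the SD of a singleton is 0.

## Sleep, humps and fragmentation

Within each night window (18:00 to noon the next day, clock time), the
longest contiguous run of smoothed ZCM ≤ 5 that lasts at least 120 min
is that night's sleep period. The window bounds and the minimum run
keep daytime rest from masquerading as sleep; both are config keys. A
"hump" (peak) inside sleep is a maximal run of smoothed ZCM > 0; its
width is the run length, its height the run maximum, and the distance
between consecutive peaks is the number of zero epochs between them.

Peaks pooled over all nights are split into lower/upper groups two ways:
by the median height (lower ≤ median, upper > median — ties go down, so
an all-equal peak set is entirely "lower") and by quartiles (lower ≤ Q1,
upper ≥ Q3, interquartile middle excluded; `_qrt` names). For each
group and for all peaks, min/max/mean/median of distances, widths and
heights are computed (3 × 4 × 2 per split = 48 grouped features, 12
ungrouped), along with the four hump counts, `number_of_peaks`, and the
"bigger" family — gap lengths between consecutive upper-median peaks and
their heights. Within-group distances are measured between consecutive
group members inside one sleep period, never across nights. Statistics
whose preconditions fail (fewer than two group members, no peaks) are
missing values, imputed with the column median at table assembly.

The fragmentation index is the ratio of mobile time during sleep to
total sleep time, averaged over nights. Mobility is judged on the
**raw** epoch series: sleep periods are delimited on the smoothed
series, inside which individual raw minutes can still spike above the
ZCM-5 ceiling; those are the mobile minutes. (Judging mobility on the
smoothed series would be degenerate — a smoothed-run sleep period
contains no smoothed value above its own defining ceiling.) The
"immobile runs shorter than one minute count as mobile" clause is
vacuous at 60 s epochs and implemented only for sub-minute epoch
configurations. The whole-recording zero-activity fraction
(`zero_ratio`) and mean nightly sleep duration complete the set.

## Morlet wavelet structure

The smoothed sleep activity of up to 5 consecutive nights is
concatenated (fewer nights are used with a warning, minimum 2) and
analyzed with a continuous wavelet transform using the Morlet mother
wavelet, ω₀ = 6, L2-normalized, computed in the Fourier domain with
zero padding. The linear 1–200 min scale axis is interpreted as Fourier
periods and converted through the standard Morlet relation
λ = 4πs/(ω₀+√(2+ω₀²)); the real part of the coefficients is kept. The
structure curve is the per-scale sum of squared coefficients over time
(no cone-of-influence masking by default — the full map is summed);
`structure_pm` is its trapezoidal integral over 20–100 min and
`structure_pm_stdev` the population SD of the 51–67 min values. A
direct-convolution oracle pins the transform for periods ≥ 4 min;
periods within a factor ~2 of the Nyquist period differ between time-
and frequency-domain discretizations and are excluded from that
comparison (the 1-min grid still emits them; they contribute little to
the 20–100 min band).

## Selection funnel

Features are z-scored per column (population SD; zero-variance columns
are left centered and flagged). Per case–control task (control vs one
propensity group; the control subjects are shared), a two-sided Welch
unequal-variance t-test screens each feature at the lenient α = 0.3
(strict `p < α`). The retained features form a graph whose edges connect
pairs with |Pearson r| ≤ 0.3 (deletion is strict — an edge exactly at
the threshold stays), so cliques are sets of mutually weakly-correlated
features. All maximal cliques with ≥ 8 members are enumerated
(Bron–Kerbosch via igraph, order pinned lexicographically) and 1600 are
sampled uniformly without replacement. When the clique space is too
large to hold in memory (beyond ~2×10⁵ maximal cliques, which happens
for some synthetic cohorts), random maximal cliques are drawn directly
by greedy extension of seeded vertex permutations — every draw is still
a genuine maximal clique, at the cost of exact uniformity; the
enumeration path is used whenever it is tractable.

## Models, baseline and metrics

Three families: ridge-regularized logistic regression (glmnet, α = 0,
λ = 0.05), random forest (200 trees), and depth-limited gradient-boosted
trees (60 rounds, depth 3, learning rate 0.15, exact greedy splits).
Hyperparameters are fixed, chosen once for cohorts of a few dozen
subjects, and never tuned per feature combination (no selection
leakage). Folds are stratified with seed-controlled shuffling;
out-of-fold predictions are pooled into one confusion matrix (rather
than averaging per-fold metrics — pooled accuracies are fractions of the
cohort size, matching how many-decimal accuracies arise), with accuracy
(TP+TN)/total, precision TP/(TP+FP) and recall TP/(TP+FN), the
propensity class positive. The baseline uses three descriptors of the
smoothed ZCM series — mean, population SD and zero fraction — and a
candidate model is retained only if its pooled accuracy strictly
exceeds the baseline of the same algorithm and task.

## Shapley attribution and aggregation

Attributions explain the positive-class probability of the full-data
model under the marginal-replacement value function: for a coalition S,
v(S) is the mean prediction over background rows with the features in S
replaced by the subject's values. The background is a subsample of the
training rows (8 by default) — the standard summarized-background
practice, which keeps exact enumeration affordable. With ≤ 8 features
(config `shap_exact_max`) all 2^k coalitions are enumerated and the
Shapley weights applied exactly; otherwise an antithetic
permutation-sampling estimator is used (16 permutations by default).
Both satisfy local accuracy — per subject, attributions plus the base
value equal the model output — exactly, because each permutation's
contributions telescope; the suite asserts this and the closed-form
linear-model values.

Per task, the attribution matrices of all retained models are summed
element-wise aligned by (subject, feature) — a feature absent from a
model contributes zero, and opposite attributions cancel. Features are
ranked by mean absolute aggregated attribution; the direction sign is
the sign of the Pearson correlation between feature values and
aggregated attributions ('+': high values push toward the propensity
class), with '?' when |r| < 0.3. The correlation-based sign makes the
visual beeswarm reading algorithmic and reproducible.

## The synthetic cohort

`simulate_cohort()` emulates the deposited data's envelope — 10 Hz, ±8 g,
gravity on +z, wide-band sensor noise (SD 0.01 g) — and the structure
the features measure: a daytime intensity template mixed with
day-specific 3-hour-block noise at weight `interdaily_jitter` (the IS
dial), lognormal minute-scale variation, a nightly sleep window with
night-to-night onset/duration jitter, Poisson-clustered movement bouts
and brief high-count "twitches" inside sleep, and daytime sedentary
quiet spells. Movement is band-limited (0.5–3 Hz) Gaussian burst noise
whose amplitude envelope these processes set, so simulated activity
survives the analysis band-pass; bout and hump amplitudes are kept near
the crossing threshold so nocturnal humps stay below the sleep ceiling,
as they must for the sleep detector to see the night as one period.

A dozen independent per-subject trait axes (bout rate, duration and
amplitude; twitch rate and amplitude; jitter; circadian phase;
modulation depth; overall intensity and its variability; quiet-spell
rate; chronotype shift) emulate the between-subject independence of
real cohorts — without them, all nocturnal features collapse onto a
couple of latent factors and the low-correlation graph loses its
cliques. The default group contrasts encode the recovery targets: the
cyclothymia-like profile has stronger nocturnal twitches, a less
repeatable day-to-day profile and lower daytime intensity (higher L5
and fragmentation, lower IS); the schizotypy-like profile has fewer and
weaker nocturnal events, longer sleep, more regular days and a higher
evening share (higher zero ratio and IS, lower L5). Effect sizes are
the package's own choice — the study reports attribution directions,
not generative effect sizes — set to moderate standardized differences
(d ≈ 1): large enough to pass the lenient Welch screen reliably,
small enough that mixture-induced correlations between discriminative
features stay mostly below the 0.3 edge threshold. They were calibrated
once against the study's printed funnel shape (about half the features
surviving the screen and an ample clique space) and then frozen.

What the synthetic tests show: every pipeline stage computes what its
definition says (oracle equivalences), the closed-form circadian limits
hold, the generator's injected contrasts appear in the extracted
features with the intended signs, and the full chain runs end-to-end
deterministically. What they do not show: performance on real wrist
data, where non-wear, posture changes, device artifacts and far richer
behavioral variation are present; and the synthetic correlation
structure — however many trait axes — remains simpler than a real
cohort's. One honest consequence, visible in the acceptance suite: the
composite features (`frg_index`, and L5 in the cyclothymia task)
correlate strongly with their constituent nocturnal families through
the shared realization of the night's events, so under the exact funnel
settings (|r| ≤ 0.3, cliques ≥ 8, 47 subjects) they enter few or no
maximal cliques in many simulated cohorts and their aggregated
attribution sign is then undefined for that seed. The study's own
feature lists imply its real-data correlation structure did not have
this degeneracy; reproducing that aspect synthetically was not
achieved, and the corresponding recovery check reports it rather than
papering over it.

## Problem sizes and determinism

Defaults follow the study design: 25/22/22 subjects, 10-day recordings,
1600 combinations, 10 folds, ≈9600 models. The test and analysis runs
use scaled sizes chosen by the package: 48-hour recordings (the minimum
satisfying the 2-day validity rule, with two full calendar days for IS
and at least one full night), 24–40 sampled combinations per task, 10
cohort seeds for the recovery suite, and a 160-combination run for the
search-size arithmetic (extrapolated linearly to the full 1600). All
randomness flows from explicit integer seeds through one guarded RNG
scope; bulk per-sample noise uses a compiled xoshiro256++/Box–Muller
generator whose stream is itself seeded from the R stream, so a fixed
cohort seed reproduces recordings byte-identically.

## Limitations

No non-wear or posture modeling; no nap detection outside the night
window; no cosinor/parametric rhythm fitting; public raw-data deposits'
container formats are not parsed (delimited text is the interchange
format); and the recovery of attribution directions through the full
funnel is demonstrated for the regularity/zero-ratio axes but is
structurally unreliable for composite intensity features at this cohort
size, as discussed above.
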