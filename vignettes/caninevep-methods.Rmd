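---
title: "Models and methods behind caninevep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind caninevep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`caninevep` implements a complete analysis chain for non-invasive canine
visual event-related potentials (ERPs): dogs viewing pictures of dog and
human faces (aggressive, neutral, happy), household objects and
phase-scrambled images, recorded with a 7-electrode montage (F3, F4, T3,
T4, Cz, P3, P4) at 512 Hz. The chain covers a synthetic-data generator, a
conventional sensor-level ERP analysis, time-resolved single-trial
decoding with permutation inference, cross-subject aggregation, and
equivalent-current-dipole (ECD) source modelling. This vignette documents
the models, the tunable parameters, and the design choices that were
genuinely open.

## The synthetic-data generator

Every downstream stage is exercised on simulated recordings, so the
generator is first-class, tested code. It emulates the recording
conditions of the study design it mirrors: 8 subjects, 8 stimulus
categories (`AD, ND, HD, AH, NH, HH, OB, S`), 128–155 trials per category
and subject (drawn uniformly per cell), 7 channels, 512 Hz, epochs from
−150 to 710 ms around stimulus onset.

A trial is

$$x_{c}(t) = s_{\mathrm{cat}, c}(t) + n_{c}(t) + w_{c}(t)
  \; [+\; a_c(t) \;+\; \ell(t)]$$

* **Evoked template** $s_{\mathrm{cat},c}$: a sum of Gaussian-shaped
  components, each with a peak latency, temporal width (Gaussian SD), a
  per-channel amplitude vector, and the set of categories it applies to.
  The default set plants the response structure seen in canine visual
  ERPs: a dominant posterior component at 105 ms (attenuated by half for
  scrambled images), a face-sensitive component at 140 ms, an early
  threat component at 35 ms for aggressive dog faces, a dog-face
  component at 75 ms, a happy-face component at 150 ms, and a late social
  component at 260 ms. Component amplitudes (0.3–3 µV) and the noise
  level below were chosen once to give single-trial signal-to-noise in
  the range where face-vs-scrambled decoding lands at 60–70% — the
  realistic regime for this kind of recording — and were not tuned
  afterwards.
* **Background noise** $n_c$: per-channel, per-trial $1/f^{\alpha}$
  Gaussian noise (default $\alpha = 1$, SD 4 µV), synthesized in the
  frequency domain and normalized per trace. Independent white noise
  $w_c$ (default SD 2 µV) models sensor noise. Channels are independent;
  real EEG has correlated channels, so passing tests here says nothing
  about spatial leakage in real data.
* **Artifacts**: with probability 0.06 a trial receives a 15-ms-wide
  Gaussian transient of 1.5 × 150 µV peak on one random channel, so
  artifact trials deterministically exceed the 100 µV rejection
  threshold used by the ERP stream. The generator records the artifact
  ground truth per trial.
* **Trigger leak** $\ell$: optional exponentially decaying transient
  (30 ms time constant) added identically to all channels, matching the
  regressor used by `remove_trigger_leak()`.

Trial-level amplitude variability of real evoked responses is unknown, so
the template is deterministic and all variability lives in the noise
terms; the component amplitudes are user parameters, not fixed claims.

Seeding: a master seed spawns per-subject and per-stage substreams
(`derive_seed`), so any subject or permutation stream can be reproduced in
isolation; a fixed master seed gives bit-identical output.
`make_null_config()` makes every component apply to all 8 categories, so
labels carry no information — the global-null condition behind the
calibration tests.

## Preprocessing: two analysis streams

* **ERP stream**: band-pass 2–40 Hz, rejection of trials whose absolute
  deviation from their own within-window mean exceeds 100 µV anywhere in
  −150…350 ms, baseline correction by the −150…0 ms mean. Rejected
  trials stay in the container with `kept = FALSE`.
* **Decoding stream**: band-pass 2–25 Hz, *all* trials kept (single-trial
  decoding needs the data, and the permutation null absorbs artifacts
  symmetrically), 20-ms binning, vectorization.

Design choices worth stating:

* **Filter**: the nominal design is a zero-phase 4th-order Butterworth.
  A single 4th-order band-pass recursion at 2–25 Hz / 512 Hz has poles at
  $|z| \approx 0.992$ and measurably leaks; the implementation therefore
  cascades a 4th-order high-pass and a 4th-order low-pass, each run
  forward–backward (`filtfilt`). Epochs are padded by even (mirror)
  reflection of at least three time constants of the high-pass corner:
  odd (point) reflection would add a step of $2x(T)$ to the local mean at
  the junction, which the 2 Hz corner smears into the epoch. The response
  is verified against sinusoid oracles (passband within 5%, stopband
  ≥ 20 dB down, DC removed, symmetric pulses keep their peak).
* **Rejection statistic**: "amplitude deviation" is implemented as the
  absolute deviation from the trial's own within-window mean — robust to
  DC offsets and well-defined after filtering. Peak-to-peak would be an
  alternative reading; it differs by at most a factor 2 and is not
  exposed.
* **Binning**: 20 ms at 512 Hz is 10.24 samples, so bins are half-open
  intervals on the *time axis* (alternating 10 and 11 samples), and a
  trailing bin extending past the sampled coverage is dropped. A
  −150…710 ms epoch (441 samples) yields 43 bins and hence 7 × 43 = 301
  whole-epoch features; a single interval has 7 features (one per
  channel).
* **Decoding span**: 301 = 7 × 43 features fixes the decoding epoch at
  860 ms. The generator therefore spans −150…710 ms by default; the span
  is configurable.
* **Trigger-leak removal**: per trial and channel, ordinary least squares
  on (intercept, leak template); the residual is orthogonal to the
  regressor by construction.

## Sensor-level ERP statistics

Per-subject, per-condition evoked averages (kept trials only) enter a
sliding-window analysis: 16-ms windows stepping by 4 ms over 0–250 ms
(59 windows). For each channel and window, the window-mean amplitudes of
the six face conditions form a two-way *fully within-subject* ANOVA with
factors species (dog, human) and expression (aggressive, neutral, happy),
fitted with `stats::aov` and `Error(subject/(species*expression))`
strata. With 8 subjects each contributing all six cells, the
repeated-measures model is the only defensible flavor. No sphericity
correction is applied by default (mirroring the original analysis); a
Greenhouse–Geisser correction for the 3-level factor and the interaction
is available behind `gg = TRUE`, with $\varepsilon$ computed from the
double-centered covariance of the repeated measures.

Per-window p-values are deliberately uncorrected for the number of
windows; instead, only effects significant ($p < 0.05$) in **at least two
step-adjacent windows** are reported, merged into
$[\text{first start}, \text{last end})$ intervals with the p-range of the
run (`contiguity_filter()`). Face-vs-object comparisons are planned
paired-samples t tests on the same window grid.

The type-I behaviour of the whole construction is checked by simulation:
on white-noise evokeds the per-window p-values are uniform (KS test on a
decorrelated subset) and the raw rejection rate sits at the nominal 5%.

## Time-resolved decoding

For each unordered category pair (28 per subject; the 7
scrambled-vs-other pairs in the time-resolved analysis) a linear-kernel
support-vector classifier (`e1071::svm`, C = 1 by default) is trained on
single-trial feature vectors — whole-epoch (301-dim) or one 20-ms
interval (7-dim) — with stratified 10-fold cross-validation. Folds are
seeded and shared across the intervals of a task, so interval accuracies
are comparable. Standardization statistics (mean/SD per feature) come
from the training folds only; the original analysis is silent on
stratification and scaling, so both choices are recorded in the result
objects and switchable. Slight class imbalance is kept as-is (all trials
retained); inference never relies on a nominal 50% chance level but on
the permutation null. A lasso-regularized logistic regression
(`glmnet`) is available behind `classifier = "lasso"` as the alternative
classifier.

## Permutation inference

For each classifier, category labels are permuted 200 times and the full
cross-validation is repeated, giving a null distribution of accuracies.
Two readings of "permuting the training data" exist; the default permutes
labels once per permutation on the **whole dataset** before the CV loop,
which preserves exchangeability and matches common MVPA practice;
`scope = "train"` permutes training folds only.

Family-wise error over all intervals × task pairs of one subject is
controlled by **maximum statistics**: permutation $r$ applies the *same*
label shuffle stream to every classifier (shared permutation seeds —
`maxstat_threshold()` refuses misaligned nulls), $M(r)$ is the maximum
accuracy over the family, and the threshold is the empirical
$1 - \alpha/N_{\mathrm{subjects}}$ quantile of $\{M(r)\}$ (Bonferroni
across the 8 dogs). The quantile is the inclusive order statistic
(ceiling rule), so ties break toward the *larger* threshold, and cells
are significant only on strict exceedance — both choices conservative.
The `empirical_chance_interval()` is the central 95% interval of the
pooled null accuracies; pooling across classifiers is one defensible
reading of the "empirical chance level" and is documented as such.

Calibration is tested, not assumed: `fwer_simulation()` measures the
family-wise error on global-null replicates, and `chance_calibration()`
checks the pooled null mean against the binomial oracle
$0.5 \pm 3 \cdot 0.5/\sqrt{n}$.

## Aggregation

`significant_fraction_timecourse()` reports, per interval,
$100 \cdot \#\text{significant}/(N_{\text{subjects}} \cdot
N_{\text{tasks}})$ — with 8 subjects and 7 scrambled-vs-other tasks the
denominator is 56. `division_fractions()` reports the same fraction per
task group for three standard divisions (species, expression, combined),
always with object-vs-scrambled as the reference group, computed by the
identical rule. Groups are descriptive; no between-group test is offered.

## Source modelling

The forward model is a **three-shell concentric sphere** (brain/skull/
scalp, conductivities 0.3 / 0.006 / 0.3 S/m) rather than an MRI-derived
boundary-element model: it is fully testable on a desk and is the
standard EEG approximation when no individual anatomy is available.
Default radii are 40/45/50 mm, a beagle-sized head. The dipole potential
is expanded in spherical harmonics; for each order $n \le 60$ the radial
coefficients in the three shells are obtained by solving the 5 × 5
interface system (continuity of potential and radial current, insulating
exterior) with column equilibration — no closed-form shell formula is
assumed. Truncation at order 60 gives sub-0.1% error for sources below
0.9 of the brain radius (the series term scales as $(b/R)^{n-1}$), and
the homogeneous special case is verified against an independent
closed-form solution obtained by summing the Legendre series with
generating-function identities. Potentials are average-referenced — the
natural reference of the sphere solution; a physical right-ear reference
is a linear transform of it and does not change dipole fits.

Electrode positions for the 7-channel canine montage are not published;
`canine_layout()` ships an idealized, documented placement on the scalp
sphere (Cz vertex, frontal/parietal pairs at 50°, temporal pairs at 75°)
and is user-replaceable.

`fit_ecd()` scans a regular volumetric grid (2-mm default spacing,
sources restricted to 0.9 of the brain radius), solves the moment
linearly at each candidate, refines the best 5 grid points by
Nelder–Mead on the residual (locations leaving the shell are projected
back with a warning), and reports location, moment (nAm) and goodness of
fit $\mathrm{GOF} = 100\,(1 - \|v - \hat v\|^2/\|v\|^2)$.
`fit_ecd_window()` repeats the fit at every time point of the 90–110 ms
window with the grid scan amortized; `moment_timecourse()` fixes the
location and solves the moment over −50…300 ms. With 7 electrodes the
average-referenced topography has 6 degrees of freedom against 6 dipole
parameters, so the model can interpolate *any* topography: noiseless
recovery is exact (sub-millimetre, GOF ≥ 99.9%), but under sensor noise
the fit still reaches GOF ≈ 100% and the noise moves the location —
median errors grow from ~1.5 mm at 0.5% noise to ~10 mm at 5% noise in
the recovery tests. Fits are therefore layout-limited location
estimates, best read at cluster level; clustering of fitted dipoles
across time points is left to the user.

## Degenerate inputs and tie-breaks

All-zero topographies, empty conditions, empty amplitude windows,
all-zero leak regressors, misaligned permutation counts and
out-of-Nyquist bands raise explicit errors (or a warning plus no-op where
the spec calls for one). Quantile ties break conservatively; equality
with a threshold is *not* significant; zero-variance features get unit
scale during standardization.

## Problem sizes used by the test suite

The suite runs everything at sizes chosen to keep the full check fast
while leaving the statistics meaningful: family-wise error is estimated
from 50 global-null replicates (3 tasks × 5 intervals, 60 trials/class,
100 permutations, 5-fold CV); ANOVA type-I from 25 null experiments over
all channels and windows; the planted-effect power check from 20
simulations; chance calibration from one 200-permutation null at 100
trials/class; dipole recovery from 12 noisy dipoles plus the noiseless
and closed-form oracles. These sizes are the package's own trade-off
between Monte-Carlo error and turnaround.

## Known limitations

* The generator's spatial model is white across channels and its evoked
  templates are deterministic; it validates the *pipeline*, not claims
  about real canine EEG.
* Independent-component analysis (a manual, inspection-driven step in
  the original workflow) is out of scope; amplitude rejection is the
  only artifact control.
* The sphere model ignores the thick canine head musculature that a
  boundary-element model with an individual MRI would capture.
* With 7 electrodes, single-dipole fits are at the edge of
  identifiability; treat locations as cluster-level summaries, not
  millimetre claims.
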