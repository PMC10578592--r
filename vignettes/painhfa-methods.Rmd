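---
title: "Methods: sliding-window mixed models of intracranial HFA and tonic pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window mixed models of intracranial HFA and tonic pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

During a tonic thermal pain task, a participant holds a hand on a
thermoelectric surface for 10 s, removes it, answers the binary question
"was that painful?", and rates the perceived intensity on a 0-10 visual
analog scale (VAS). Stimulus temperatures are chosen trial by trial by an
adaptive Bayesian staircase so that they straddle the participant's pain
threshold. In patients implanted with stereo-EEG depth electrodes, every
trial is time-locked to the intracranial recording, and the question is
whether broadband high-frequency activity (HFA, the 70-150 Hz envelope of
the local field potential, a proxy for local population firing) around the
hand-on and hand-off events predicts the psychophysical reports.

`painhfa` implements the full analysis chain — preprocessing, HFA
extraction, region-level feature construction, sliding-window generalized
linear mixed-effects models (GLMEs), and permutation-based significance —
together with a synthetic-data generator that emulates the task and the
recordings with known ground truth, so that every stage can be exercised
and calibrated without patient data.

# The models

For each brain region, event (hand-on / hand-off), and 500 ms window
(sliding by 250 ms), the per-trial feature $A$ is the mean baseline
z-scored HFA over the window, averaged over the patient's retained contacts
in the region. Two models are fit, in Wilkinson notation

$$ y \sim A + (A \mid B) + (A \mid C), $$

with $B$ the trial temperature (rounded to 0.1 °C to form levels) and $C$
the patient: random intercepts and slopes for both grouping factors. The
binary report uses a binomial family with logit link; the VAS rating uses an
identity-link gaussian. The fixed-effect estimate $\beta$ and its
$t = \beta / \mathrm{SE}$ are the quantities of interest. Estimation is
delegated to `lme4`; binomial fits use the fast PIRLS-profiled criterion
(`nAGQ = 0`) so that the real fit and the thousands of permutation refits
optimise the same objective.

Because temperature is a *random* effect, any association between $A$ and
$y$ that runs purely through temperature is largely absorbed by the
temperature intercepts; what the fixed effect detects is trial-level
covariation between neural amplitude and the report *beyond* the stimulus.

## Permutation significance

Model significance is assessed non-parametrically: the responses are
randomly permuted and the model refit `n_perm` times (1000 in full-scale
use), giving a null distribution of pseudo-$t$ statistics. The real model is
significant when its $t$ falls outside the 2.5th-97.5th percentile band of
the pseudo-$t$; the p-value doubles the count of pseudo-$t$ values more
extreme than the real $t$ in the tail matching its sign, floors the count at
one, and divides by the number of converged permutations, so the smallest
attainable p with 1000 permutations is 0.002. Counting in the tail matching
$\mathrm{sign}(t)$ keeps the formula meaningful for negative coefficients
(a literal "greater than" count degenerates there).

A permutation test of an association is exact when the margin being
shuffled is exchangeable under the null. The two margins here are not
symmetric in that respect. The *reports* carry the staircase's temperature
structure: shuffling them within patient breaks the response-temperature
association that the temperature random effects otherwise absorb, permuted
refits see inflated residual variance, the pseudo-$t$ spread shrinks, and
the null rejection rate inflates measurably (about 6% instead of 5% in
feature-level simulation, more after the full pipeline). Restricting
response shuffles to patient-by-temperature cells restores exactness but
cripples power for the binary report, whose extreme cells are constant and
shuffle to themselves, so the pseudo-$t$ distribution degenerates toward
the real $t$. The *HFA feature*, by contrast, is baseline-normalised noise
under the null — exchangeable within patient by construction. The default
scheme therefore shuffles the feature $A$ within patient and refits,
breaking the neural-report pairing while leaving the response vector and
its temperature structure intact: exact under the null and fully powered.
The response-shuffling schemes remain available through the `scheme`
argument for comparison.

The permutation engine rebuilds the `lme4` deviance function per permutation
from a cached parsed model and optimises it with the same settings as a
fresh fit; this reproduces `lmer`/`glmer` results exactly (verified to
machine precision in the test suite) at roughly a third of the cost of
`refit()`. Two non-obvious details are handled explicitly: the relative
covariance factor inside the cached parse is mutated in place by each
optimisation and must be restored from forced copies, and the deviance
closure resolves `lme4`-internal functions through its environment chain,
so it is re-anchored in the `lme4` namespace.

# Preprocessing chain

The pipeline follows a fixed order: common-median reference, epoch
extraction, threshold artifact rejection, MAD outlier flagging,
downsampling, filter-Hilbert, smoothing, baseline z-scoring.

* **Referencing.** The per-sample median across channels is subtracted from
  every channel (robust to large transients, unlike the common average).
  The subtracted trace is stored with the recording.
* **Epochs.** Each trial is sliced from −3000 to +1000 ms around the event
  (half-open windows, 0-based sample indices). The wide span carries both
  the −3 to −2 s baseline and the −1000..1000 ms analysis window; trials
  whose span exceeds the recording are dropped and logged.
* **Threshold rejection.** A trial-by-channel epoch is rejected when its
  60 Hz Welch power density exceeds 100 μV²/Hz, its maximum one-sample
  slope exceeds 300 μV/ms, its variance falls below 1 μV², or any sample
  reaches the ±6553 μV amplifier saturation voltage. These rules are
  stated in amplifier units, so when the epochs carry a reference trace the
  subtracted median is added back before testing — otherwise a dead-flat
  channel or an exactly-saturated sample would be masked by the reference.
  Welch segments are 1 s Hann windows with 50% overlap (about 1 Hz
  resolution at both 1 kHz and 500 Hz).
* **MAD outliers.** For each channel, the median and the scaled MAD
  (consistent for the normal distribution, `stats::mad`'s default) are
  computed over all of that channel's retained epoch samples; an epoch
  containing any value more than 3 MADs from the median is flagged. The
  scaled convention is deliberate: with the raw MAD the threshold sits
  near 2 standard deviations and flags essentially every epoch of any
  realistic noise process. The statistics are likewise computed in
  amplifier units: with few channels the common-median trace coincides
  with each channel a sizeable fraction of the time, which puts an atom at
  zero in the referenced marginal and artificially halves the MAD.
* **Downsampling.** Thresholds are applied at the native 1 kHz (the slope
  rule needs native resolution); signals are then low-passed (Butterworth,
  cutoff 200 Hz, zero-phase) and decimated to 500 Hz.
* **HFA.** Each epoch is band-passed at 70-150 Hz with a 4th-order
  zero-phase Butterworth response and the analytic-signal magnitude is
  taken. The zero-phase response is applied spectrally (the squared
  magnitude of the designed filter on the DFT grid), which is the same
  linear operator as forward-backward filtering up to boundary handling;
  epochs are long, the analysis window sits 2 s from the left edge, and the
  outer 100 ms is excluded from every statistic, so the periodic boundary
  is immaterial and one response vector serves every epoch. The envelope is
  smoothed with a 300 ms centered moving average (edges shrink), then
  z-scored per trial and channel against the mean and SD of its own
  −3 to −2 s baseline (trimmed 100 ms where it touches the epoch edge); a
  zero baseline SD flags the entry instead of dividing by zero. Smoothing
  precedes z-scoring.

# The synthetic-data generator

`simulate_study()` generates the full study: per-patient observers,
staircase-adapted temperatures, behavioural reports, and continuous
multichannel recordings.

* **Observer.** Each trial draws a percept drive
  $d = (T - \theta)\,s + \varepsilon$ with $\varepsilon$ standard logistic.
  The binary report is $d > 0$ — marginally exactly the logistic
  psychometric $\mathrm{logistic}((T-\theta)s)$ — with a small lapse rate
  (coin flip); the VAS is $\mathrm{gain}\cdot\max(0, d/s)$ plus report
  noise, clamped to [0, 10] and rounded to integers, which concentrates
  ratings in the 0-4 range. The realized drive
  $\mathrm{logistic}(d)$ is the latent pain that also scales the neural
  response, so the binary report, the VAS, and the neural signal are
  correlated at the single-trial level — the property the mixed models are
  designed to detect (a percept shared only through temperature would be
  absorbed by the temperature random effects).
* **Staircase.** Threshold estimation is grid-based Bayesian updating with
  a logistic likelihood; the proposal is the posterior-mean threshold
  quantised to the grid. Defaults: grid 40-48 °C in 1 °C steps, slope
  1.2 /°C, lapse 0.02. With a deterministic observer the estimate converges
  to within one grid step in well under 40 trials.
* **Trial timing.** 10 s hand-on, 5 s inter-trial interval (so the
  −3..−2 s baseline never overlaps the previous stimulation), 4 s lead-in,
  2 s tail, 20 trials per patient, 1 kHz sampling.
* **Background LFP.** Band-limited (0.3-250 Hz) approximately $1/f^{1.5}$
  Gaussian noise (25 μV RMS; white noise shaped by a first-order pole-zero
  shelving cascade, average power slope within a few percent of the target
  with about ±1.5 dB ripple), soft-compressed with a tanh at 2.2 SD, plus an
  amplitude-modulated 10 Hz rhythm (15 μV) and a 60 Hz line component
  (4 μV, well under the rejection threshold). The soft compression gives
  artifact-free epochs the bounded excursions that the value-level 3-MAD
  screening rule presumes; heavy-tailed excursions are modelled explicitly
  as injected artifacts rather than as background. This is the main
  idealisation relative to real sEEG, whose kept epochs pass the same
  screening but whose rejected fraction and tail structure are richer;
  passing tests therefore validate the pipeline's logic and calibration,
  not the rejection yield on any particular clinical recording.
* **Evoked response.** Around each event, every channel receives a
  narrowband (90-130 Hz carrier) burst over 0-500 ms whose mean envelope
  increment is $(b_0 + \mathrm{effect} \cdot \mathrm{latent})\,\sigma_b$,
  with $b_0 = 0.5$ a constant evoked component, `effect` the region's
  entry in the ground-truth effect map (z units per unit latent pain), and
  $\sigma_b$ the channel population's baseline smoothed-envelope SD
  (estimated once per study from a reference background realisation). The
  carrier amplitude corrects for incoherent addition
  ($a = \sqrt{(\mu+\delta)^2 - \mu^2}$) and the raised-cosine taper is
  normalised to unit window mean so the injected number is the
  window-averaged envelope increment. Per-trial baseline z-scoring still
  attenuates the realized regression slope (noisy per-trial SD
  denominators), which is why recovery tests define their target as the
  population slope of the generative process rather than the raw injected
  value.
* **Artifacts.** Five labelled classes sized to exceed their rejection
  thresholds with comfortable margins: 30 μV line noise (PSD ≈ 300
  μV²/Hz), 450 μV single-sample transients, flat (constant) spans,
  ±6553 μV saturation plateaus entered by slow ramps (so only the
  saturation rule trips), and smooth 250 μV spikes that are large against
  the MAD rule but too slow for the slope rule. Every injection is logged
  with its location, enabling exact recall measurement.
* **Regions.** The default layout reproduces the sixteen-region cohort
  table (3-20 patients per region); two contacts per carried region is the
  default, matching typical per-patient contact counts, and features
  average a patient's contacts. White-matter contacts are generated and
  excluded by the inclusion filter (white matter, and regions with fewer
  than three unique patients, are dropped).

# Numerical and design choices

* Sample indices are 0-based; all windows are half-open `[start, end)` in
  ms relative to the event, which tiles the 250 ms-overlap grid without
  ambiguity. Onset windows span (−250, 1000); offset windows span
  (−1000, 1000).
* Temperature levels for the random effect are temperatures rounded to
  0.1 °C.
* Binomial and gaussian permutation streams are seeded once per scan;
  non-converged refits are dropped (never imputed) and a result is marked
  unreliable when more than 10% fail.
* Ties in the staircase proposal resolve to the lower temperature.
* The linear reading of a binomial coefficient as "percent change in the
  proportion of yes-responses per unit HFA" (`coefficient_to_percent`) is
  a linearisation of the logit slope around the operating point, provided
  because it is how such coefficients are conventionally quoted.
* The binary accuracy metric is 0.5-threshold misclassification of the
  fitted conditional response, in percent; VAS accuracy is reported as the
  mean absolute conditional error plus the fitted-versus-real scatter and
  its rank correlation.

# Problem sizes used in the shipped checks

The package's calibration and recovery checks run at deliberately scaled
sizes, chosen as the smallest designs that still measure what they claim:

* Type-I calibration: a 5-patient, 18-region null study, 209 region-window
  tests (gaussian across all regions, binomial on one), 200 permutations
  each; the rejection rate is compared with 5% under a binomial 95%
  interval. Stratified permutation makes each test exact under the null
  irrespective of sample size, so the small design tests the harness, not
  the asymptotics. Overlapping windows make the tests positively
  correlated, so the interval is, if anything, slightly narrow; it is used
  as stated.
* Parameter recovery: 100 independent studies at the full 20-patient,
  20-trial design with a 1 z-unit effect in one region; per-seed Wald CIs
  are checked for sign and for coverage of the inverse-variance-weighted
  mean across seeds (the population slope of the generative process).
  Detection is a rate, not a one-shot event: staircase realisations vary
  enough that the per-study permutation power at these conditions is about
  70%, so the checks require the effect window to be flagged at a rate
  irreconcilable with the 5% null rate (at least four of eight studies;
  one-sided binomial p below 1e-3) while the pre-stimulus baseline window
  is essentially never flagged.
* Full-scale analyses of real recordings would use `n_perm = 1000` and the
  complete region set; nothing in the code is specific to the scaled sizes.

# Known limitations

* The generator's background is stationary within a session; drifts,
  state changes (drowsiness), and epileptiform activity beyond the modelled
  artifact classes are absent.
* The VAS model is an identity-link gaussian on a bounded 0-10 integer
  scale, chosen to match the analysis being emulated; a proper ordinal or
  beta model would respect the support better.
* The conversion of binomial coefficients to percent change is a
  linearisation, quoted for comparability, not a marginal effect.
* Region inclusion is evaluated before trial-level rejection; patients who
  lose all trials of a region are dropped from that region's model, and the
  three-patient rule is not re-checked afterwards.
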