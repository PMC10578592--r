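# painhfa

Sliding-window mixed-effects analysis of intracranial high-frequency
activity (HFA) during tonic thermal pain.

## What this package is for

In stereo-EEG patients performing a tonic pain task — hand on a
thermoelectric surface for 10 s, hand off, a binary "was that painful?"
report, then a 0–10 visual analog scale (VAS) rating, with stimulus
temperatures adapted trial-by-trial by a Bayesian (QUEST-style) staircase —
the question is whether the broadband 70–150 Hz envelope of the local field
potential around the hand-on and hand-off events predicts the
psychophysical reports. `painhfa` provides the complete analysis chain for
researchers working with such recordings:

- **Preprocessing**: common-median referencing, −3000..1000 ms epoching,
  threshold artifact rejection (60 Hz power > 100 μV²/Hz, slope
  > 300 μV/ms, variance < 1 μV², saturation at ±6553 μV), 3-MAD outlier
  flagging, downsampling to 500 Hz.
- **HFA extraction**: 70–150 Hz zero-phase Butterworth filter-Hilbert
  envelope, 300 ms smoothing, per-trial baseline (−3..−2 s) z-scoring.
- **Modeling**: for each region, event, and 500 ms window (250 ms step),
  the mixed model `y ~ A + (A | temperature) + (A | patient)` where `A` is
  the mean z-scored HFA — binomial-logit for the binary report,
  identity-gaussian for the VAS — with significance from a permutation
  pseudo-*t* procedure (the neural-report pairing randomly broken, model
  refit, real *t* compared with the 95% band of the pseudo-*t*; p-value
  `2 * max(count, 1) / n_perm`; several permutation schemes available, the
  default shuffling the exchangeable HFA feature within patient).
- **Reporting**: *t*-statistic heatmaps over regions × windows,
  misclassification percent, fitted-versus-real VAS scatter, coefficient
  interpretation as percent change.
- **Synthetic data**: `simulate_study()` emulates the whole paradigm —
  adaptive staircases, logistic observers sharing one latent pain drive
  between both reports and the neural response, region-resolved 1 kHz
  recordings with injected effect sizes in baseline z units, and five
  labelled artifact classes — so every stage runs, and is calibrated,
  without patient data.

## Worked example

Simulate a small study with a 1 z-unit HFA effect in the amygdala at
stimulus onset, run the pipeline, and test the effect window:

```r
library(painhfa)

study <- simulate_study(
  n_patients = 6,
  regions = data.frame(region = c("Amyg", "Hipp", "OFC"),
                       n_patients = c(6, 6, 5)),
  n_trials = 20, seed = 11,
  effects = data.frame(region = "Amyg", event = "hand_on", effect = 1.0))

proc  <- process_study(study, events = "hand_on")
feats <- build_features(proc, "Amyg", "hand_on", c(0, 500))
fit   <- fit_glme(feats, "binomial")
fit
#> <pain_glme binomial> [Amyg hand_on 0..500 ms]
#>   HFA fixed effect: beta = 0.3299 (SE 0.1909), t = 1.729
#>   120 trials, 6 patients

permutation_test(fit, n_perm = 200, seed = 3)
#> <pain_perm binomial> [Amyg hand_on 0..500 ms] t = 1.729, null 95% bounds [-1.812, 1.566]
#>   p = 0.03 (significant), 200/200 permutations converged
```

The positive fixed effect says trials with higher onset-window HFA in the
amygdala were more often reported painful; the real *t* falls outside the
95% band of 200 permutation refits (the HFA feature shuffled within
patient), with the permutation p-value at 0.03. The same features fit the
VAS model with `fit_glme(feats, "gaussian")`, and a full region-by-window
significance map comes from `scan_windows(proc)` with `tstat_heatmap()` for
the standard heatmap view. A pre-stimulus window on the same data stays
non-significant:

```r
permutation_test(fit_glme(build_features(proc, "Amyg", "hand_on",
                                         c(-1000, -500)), "binomial"),
                 n_perm = 200, seed = 4)
#> <pain_perm binomial> [Amyg hand_on -1000..-500 ms] t = 1.640, null 95% bounds [-1.790, 2.301]
#>   p = 0.14 (not significant), 200/200 permutations converged
```

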