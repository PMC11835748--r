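# statesync

Brain-state synchrony and facial affect dynamics for discriminating
depression subtypes.

## The scientific problem

Melancholic depression — marked by psychomotor slowing, loss of mood
reactivity and profound anhedonia — is hypothesised to blunt both the neural
and the facial response to positive naturalistic stimuli, relative to
non-melancholic depression. `statesync` implements the analysis pipeline for
testing that hypothesis from two recording streams:

1. **fMRI ROI time series** recorded while participants watch an emotionally
   evocative movie. A K-state Gaussian-observation hidden Markov model (HMM)
   is fitted to the concatenated multi-subject series, decomposing activity
   in a set of positive-valence regions into recurring brain states with a
   transition probability matrix. The core statistic is **windowed
   inter-subject state consistency**: for each state *k* and volume *v*, the
   percentage of a group's participants whose Viterbi path visits *k* within
   a ±3-TR window of *v* (0% = no overlap, 100% = state present in all
   participants). Consistency during positively valenced scenes is tested
   against two bespoke nulls:
   - a **between-group null** — 1000 random pseudo-groups of the original
     group sizes drawn from the whole cohort, thresholded at the 95th
     percentile per state and volume; and
   - a **within-group null** — surrogate state paths simulated from the
     group's transition matrix with random initial states, destroying
     cross-subject temporal alignment; the 95th percentile of the
     volume-averaged surrogate consistency gives a per-state level.

   Periods exceeding **both** nulls inside the positive-scene mask are
   flagged as synchrony events. Conventional state dynamics (fractional
   occupancy, dwell time, subject-level transition matrices) are compared
   between groups with max-statistic permutation FWE and a network-based
   statistic (NBS) on the transition graph.

2. **Facial action-unit (AU) recordings** (OpenFace format, 10 frames/s)
   while participants watch a stand-up comedy clip. Per-AU mean intensities
   are compared between groups with two-sample t-tests under
   Benjamini–Hochberg FDR across the 16 emotion-relevant AUs (AU45/blink is
   parsed but excluded), alongside the pooled first principal component and
   bootstrap confidence bands of the group-mean curves.

The two streams are linked by regressing each subject's ROI signal on the
positive-epoch boxcar (no haemodynamic convolution; the coefficient equals
the epoch-minus-baseline mean difference) and testing the group × facial
expressivity interaction with an analysis of covariance
(`beta ~ group * facial`, extra-sum-of-squares F on 1 and n − 4 df).

Because the underlying clinical recordings are not publicly deposited, the
package ships a first-class synthetic-cohort module (`make_truth`,
`simulate_cohort`, `simulate_au_cohort`, `simulate_epoch_behaviour`) that
generates data with the statistical structure the analyses assume — planted
synchrony episodes, blunted smile-AU amplitudes, group-specific
brain–behaviour slopes — so every stage is testable end to end.

## Worked example

A synthetic cohort at a reduced scale (35 subjects, 6 states, 10 regions,
1400 volumes at TR 0.81 s) with a synchrony episode planted in the
melancholic-like group A during the first positive scene:

```r
library(statesync)

scenes <- read_scene_table(system.file("extdata",
  "synthetic_positive_scenes.csv", package = "statesync"))
truth   <- make_truth(K = 6, R = 10, separation = 5, seed = 1)
episode <- planted_sync("A", state = 2, windows = list(c(40, 65)),
                        adherence = 0.9)
sim  <- simulate_cohort(truth, n_per_group = c(15, 20), T = 1400,
                        planted = list(episode), seed = 2)
mask <- scenes_to_mask(scenes, tr_seconds = 0.81, n_volumes = 1400,
                       trim_start = 10)

fit <- fit_hmm(sim$cohort, K = 6, n_restarts = 2, seed = 3)
#> HmmFit: K = 6 states, 10 regions, full covariance
#>   log-likelihood -727555.84 after 3 EM iterations (converged)

paths <- decode_cohort(fit, sim$cohort)
round(colMeans(fractional_occupancy(paths, mask)), 3)
#> state1 state2 state3 state4 state5 state6
#>  0.171  0.165  0.153  0.155  0.185  0.170

syn <- synchrony_analysis(paths, sim$cohort$group_labels, mask,
                          n_iter = 200, seed = 4, min_run = 5)
head(syn$events$A, 3)
#>   state start  end duration      peak
#> 1     5    38   66       29 100.00000
#> 2     6  1339 1349       11  66.66667
#> 3     5   802  809        8  53.33333
```

The top-ranked event recovers the planted episode: a 29-volume run at
volumes 38–66 in which every group-A subject expresses the same state
(peak consistency 100%), exceeding both nulls. The fitted label differs
from the generating one (state 5 vs 2) — HMM state labels are arbitrary;
`align_states()` resolves the permutation against a reference model.

The facial arm, on a synthetic cohort whose smile-AU response amplitude is
blunted in group A, flags exactly the six smile-related action units:

```r
au <- simulate_au_cohort(c(15, 20), n_frames = 3000,
                         event_times = seq(150, 2850, by = 150),
                         amp = c(0.4, 1), seed = 5)
st <- compare_au_groups(au_mean_intensity(au), au$group_labels)
subset(st, q < 0.05)
#>      au mean_A mean_B     t        p        q
#> 5  AU06  0.541  0.612 -19.8 6.93e-20 3.68e-19
#> 6  AU07  0.543  0.607 -16.4 1.83e-17 5.86e-17
#> 7  AU09  0.549  0.609 -19.6 9.20e-20 3.68e-19
#> 9  AU12  0.545  0.610 -23.2 5.46e-22 4.37e-21
#> 10 AU14  0.547  0.606 -14.8 3.68e-16 9.80e-16
#> 15 AU25  0.542  0.610 -24.0 1.83e-22 2.92e-21
```

And the brain–behaviour interaction detects a blunted group-A slope:

```r
d <- simulate_epoch_behaviour(c(15, 20), slopes = c(-0.1, -1),
                              noise_sd = 0.2, seed = 6)
ancova_interaction(d$roi_beta, d$facial_mean, d$group)
#> ANCOVA interaction: F(1, 31) = 42.911, p = 2.587e-07
#>   slopes: A = -0.085, B = -1.056 (n = 15, 20)
```

Published clinical contrasts can be recomputed directly from group
summaries with the same pooled-variance t routine:

```r
mad <- t_from_summary(22.0, 8.9, 40, 29.6, 10.1, 30)
#> MADRS contrast: t(68) = -3.3, p = 0.001
```

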