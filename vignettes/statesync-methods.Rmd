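---
title: "Methods: brain-state synchrony and facial affect dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-state synchrony and facial affect dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statesync)
```

`statesync` analyses two streams recorded during naturalistic stimulation —
multi-region fMRI time series and facial action-unit (AU) intensity series —
to compare a melancholic group (label `A`) with a non-melancholic group
(label `B`). This vignette documents the models, the parameters that matter,
the synthetic-data generator, and the numerical choices, in enough detail
that a reader could re-derive every statistic the package computes.

## ROI preprocessing

`preprocess_series()` applies the final preprocessing stage expected of ROI
traces extracted upstream (spatial preprocessing, band-pass filtering and
confound regression are assumed already done and are out of scope):

* drop the first `trim_start = 10` and last `trim_end = 35` volumes, the
  periods when the movie is not playing;
* standardise each subject-by-region trace to mean 0, SD 1 over the retained
  volumes.

Standardisation is **per subject per region** by default — the convention of
multi-subject HMM toolboxes, which prevents between-subject amplitude
differences from dominating the state space. Whether to standardise per
subject or on the concatenated cohort is genuinely open; the pooled
alternative is exposed as `scale = "pooled"`. A constant trace is a hard
error (its SD is zero and it carries no dynamic information), reported with
subject and region ids.

Scene annotations (onset and duration in seconds, valence tag) are converted
to a per-volume mask by `scenes_to_mask()`. Volume `v` of the post-trim
series is inside an epoch when its acquisition onset
`(v + trim_start) * TR` falls in the half-open interval
`[onset, onset + duration)`. Half-open intervals make adjacent scenes
partition volumes without double counting; a volume on a shared boundary
belongs to the later scene. Scene times are absolute movie time: the movie
starts at volume `trim_start`, so the trim offset is the time origin. The
annotation rounding rule is not fixed by any convention we know of; onset
containment is the natural reading of "a volume acquired during a scene".

## The hidden Markov model

`fit_hmm()` fits a K-state HMM with Gaussian observations to the
concatenation of all subjects' (volumes × regions) matrices, the standard
device for obtaining one shared state space whose expression can then be
compared across subjects. Three structural choices matter:

* **Inference is EM (Baum–Welch), not variational Bayes.** EM is
  deterministic given an initialisation, has a monotone log-likelihood
  (asserted on every fit from `loglik_trace`), and needs no extra
  dependency. Model order is selected by AIC on the EM log-likelihood,
  playing the same role a free-energy criterion plays in a variational
  treatment.
* **Subject boundaries reset the recursions.** The forward–backward and
  Viterbi passes restart at each subject with the shared initial
  distribution, so concatenation cannot manufacture a transition from the
  last volume of one subject to the first of the next.
* **Observation model.** Full covariance per state by default; `"diagonal"`
  and `"shared"` (tied) options. Parameter count, used by AIC, is
  `(K-1) + K(K-1) + KR + cov dof`.

### Initialisation and restarts

Each of `n_restarts = 5` restarts seeds R's RNG with `seed + r - 1` and
initialises from k-means. The k-means step runs on a random subsample of at
most 20 000 volumes with `nstart = 10`; a single full-data k-means start
proved unreliable at locating all centroids of well-separated state
configurations (it merges one pair and splits another, and EM then settles
in the corresponding local optimum), while ten subsampled starts locate
them consistently and more cheaply. All volumes are then assigned to the
nearest centroid to initialise covariances; the transition matrix starts
sticky (0.9 on the diagonal). The restart with the best final
log-likelihood wins, ties broken by restart order.

### Numerical details

* Emission log-densities are computed per state via Cholesky factors; the
  forward–backward pass runs in compiled code with per-volume scaling (the
  classical rescaling that is exact in the log-likelihood and immune to
  underflow). The per-subject log-likelihood is validated against
  exhaustive path enumeration on small instances in the test suite.
* Convergence is declared when the per-volume log-likelihood improvement
  falls below `tol = 1e-4` (500 iteration cap, mirroring the study's
  training-cycle budget).
* A covariance update that loses positive-definiteness receives a ridge of
  `1e-6` times its mean variance, escalating tenfold until the Cholesky
  succeeds; persistent failure is a degenerate-fit error.
* Viterbi ties are broken toward the lowest state index (strict-inequality
  argmax), making decoded paths reproducible.
* HMM state labels are arbitrary. `align_states()` resolves label switching
  against a reference model by optimal assignment (a compact Hungarian
  solver, tested against brute force) on the decoded-vs-true confusion
  matrix, or on the between-means distance matrix when paths are not
  supplied.

## State dynamics over positive scenes

Given decoded paths and the positive-scene mask:

* `fractional_occupancy()` — the masked state histogram per subject; rows
  sum to one.
* `dwell_times()` — mean uninterrupted visit duration in seconds. Visits are
  maximal runs within **contiguous masked segments**: a masked gap truncates
  a run rather than bridging it, since the intervening volumes are simply
  unobserved by the analysis. Never-visited states are `NA`, not zero.
* `transition_matrices()` — per-subject transition counts over consecutive
  masked pairs, row-normalised. Rows with no observed exits are left
  absorbing and flagged; downstream tests can exclude or keep them.

Group inference uses two permutation schemes:

* `group_compare_fwe()` — two-tailed pooled-variance t per feature, with
  family-wise error from the permutation distribution of the maximum |t|
  under group-label shuffling. When the label space is small
  (`choose(n, n_A) <= n_perm`) it is enumerated exactly, making p-values
  deterministic.
* `nbs_transitions()` — the network-based statistic adapted to the directed
  transition graph: edge-wise t-tests, a supra-threshold graph at
  `t_thresh`, weakly connected components scored by edge count, and the
  maximal-component-size permutation null. Weak connectivity and the extent
  statistic are the standard NBS choices; the edge-forming threshold is a
  required user parameter because no principled default exists — its value
  trades sensitivity to broad weak effects against focal strong ones.

## The synchrony statistic and its nulls

`windowed_consistency()` computes, for each state and volume, the percentage
of a group's subjects whose path visits that state anywhere in the window
`[v - w, v + w]`, with `w = 3` volumes (a 7-TR window, ~5.7 s at TR 0.81 s)
and truncation at the series edges. "Visited" means presence at one or more
window volumes — the natural reading of counting participants who visit a
state, and the only one consistent with anchoring the score at 100% when a
state is present in all participants. Consistency is monotone
non-decreasing in `w`; `w = 0` degenerates to the instantaneous state
share.

Two nulls, answering different questions, gate event flagging:

* **Between-group null** (`between_group_null()`): is group structure
  relevant? Each of `n_iter = 1000` iterations splits the whole cohort
  without replacement into pseudo-groups of the original sizes and computes
  their consistency curves; the per-state, per-volume 95th percentile forms
  the threshold surface, separately per group size. Under exchangeability
  the observed curve exceeds the surface at roughly 5% of volumes.
* **Within-group null** (`within_group_null()`): is the alignment more than
  the group's own switching statistics produce by chance? Surrogate paths
  are simulated for every member from the group's empirical transition
  matrix (pooled masked transition counts of its decoded paths) with a
  uniformly random initial state, then the surrogate set's consistency is
  averaged over volumes per state; the 95th percentile across iterations
  gives one scalar threshold per state. Volume-averaging to a scalar
  matches the horizontal-line presentation this null takes in the source
  analyses; a pooled-across-states scalar is available via `pooled = TRUE`.
  Whether "the group's transition matrix" should instead be the joint fit's
  matrix is ambiguous when the HMM is fitted jointly; both are supported
  (`transmat =`), with the group-empirical estimate as default since it is
  the only group-specific object available. The initial state is uniform
  ("a random initial state"); a stationary-distribution option exists.

`flag_sync_events()` flags masked volumes whose consistency strictly
exceeds **both** thresholds, and emits contiguous runs of at least
`min_run` volumes as events ranked by duration. Degenerate rows in a
surrogate transition matrix fall back to self-transition and are flagged.

Two properties of the statistic are worth knowing when interpreting events:
the ±3-volume window smears a genuine episode's flags by up to 3 volumes
outward, and a Markov chain leaving a strongly synchronised period decays
back to baseline over roughly its dwell time, extending flags past the
true end of an episode unless a scene boundary cuts the mask there.

## Facial action units

Sixteen emotion-relevant AUs are analysed
(01, 02, 04, 05, 06, 07, 09, 10, 12, 14, 15, 17, 20, 23, 25, 26); AU45
(blink) is parsed from OpenFace files but excluded before any statistic, as
blinking is not an emotional display. Frames with `success = 0` are
missing, never zero, and are dropped from means. No per-subject
normalisation is applied anywhere — the static-AU semantics that preserve
individual differences in expressivity, which are exactly the signal of
interest.

* `compare_au_groups()` — two-tailed t per AU (pooled variance by default:
  it reproduces printed summary-statistic t values exactly; Welch is an
  option), Benjamini–Hochberg across the 16-AU family.
* `first_pc()` — the principal axis of the pooled frames × 16 matrix,
  centred per AU over the pool. Pooling is group-blind so that group
  comparisons of scores are not circular. The sign is fixed by requiring a
  positive mean loading on the six smile-related AUs
  (06, 07, 09, 12, 14, 25); the axis is otherwise sign-ambiguous. Both the
  per-subject score series and per-subject mean scores are returned —
  which of the two a downstream group test should use is left to the
  analyst.
* `bootstrap_band()` — subject-level bootstrap (1000 samples) of the
  per-frame group mean, 5th/95th percentile envelope.
* `correlate_with_covariate()` — per-AU Pearson correlation with a clinical
  covariate, BH-adjusted, pairwise-complete with the retained n reported.
* `t_from_summary()` — the pooled-variance t from printed (mean, SD, n)
  summaries, for recomputing published clinical contrasts.

## Linking brain to behaviour

`epoch_boxcar_beta()` regresses each subject-by-region trace on an
intercept plus the positive-epoch boxcar, without haemodynamic convolution.
The coefficient algebraically equals the mean signal difference between
epoch and non-epoch volumes, an identity asserted exactly in the tests.
ROI-level traces replace voxelwise mapping throughout: discovering clusters
in voxel space requires voxel data the package deliberately does not
handle, but the interaction machinery is identical in form.

`ancova_interaction()` fits `beta ~ group + facial + group:facial` and
tests the interaction with the extra-sum-of-squares F against the
parallel-slopes model on (1, n − 4) df — the classical separate-lines
ANCOVA. Points beyond 2.5 SD of their group mean are reported, never
removed. No covariate adjustment (medication, motion) is applied; nothing
in the analysis contract specifies one.

## The synthetic-cohort generator

The generator exists so that every downstream stage is testable without any
clinical recording, at the study's stated conditions: two groups of 30 and
40 subjects, T = 1400 retained volumes at TR 0.81 s, 25 regions, a
12-state model, AU series at 10 frames/s.

* `make_truth()` draws K state centroids with a guaranteed minimum pairwise
  separation (random directions rescaled once so the closest pair meets the
  margin), unit spherical covariances, and a sticky transition matrix
  (`p_stay = 0.85`, giving mean dwells of ~6.7 volumes ≈ 5.4 s, in the
  range reported for fMRI state models).
* `simulate_cohort()` draws latent Markov paths and Gaussian emissions.
  Planted synchrony episodes (`planted_sync()`) force subjects of one group
  into a given state with a per-volume adherence probability — acting on
  the **latent path, not the emissions**, so a fitting-plus-flagging
  pipeline genuinely has to recover the episode. The chain continues from
  the forced state, which realistically prolongs the episode's influence
  past its end.
* `simulate_au_cohort()` builds each AU as baseline AR(1) noise plus
  event-locked gamma-shaped responses (peak ~1 s, ~4 s support). The six
  smile AUs take amplitude `amp[1]` in group A and `amp[2]` in group B;
  the others share `amp[2]`. Setting `amp[1] < amp[2]` emulates melancholic
  blunting confined to positive-affect units. Intensities are floored at 0.
* `simulate_epoch_behaviour()` pairs a common facial-expressivity
  distribution with group-specific linear responses
  `beta = intercept + slope_g * facial + noise`.

All generators snapshot and restore the caller's RNG state and are
bit-reproducible given a seed.

What the generator does **not** emulate — and what passing tests therefore
do not establish about clinical data: haemodynamic response dynamics and
autocorrelated fMRI noise (emissions are conditionally white), non-Gaussian
state geometry, ragged or motion-corrupted recordings, inter-site scanner
effects, and any coupling between the fMRI and facial streams beyond the
constructed slopes. Tests on this generator validate the statistical
machinery, not the clinical findings.

## Test and verification scales

The suite validates exact components at toy scale (path enumeration for
likelihood and Viterbi on T ≤ 8, K ≤ 3; brute-force assignment; literal
BH step-up; enumerated permutation FWE) and statistical behaviour at
reduced scale chosen for desk-time turnaround: state/transition recovery on
70-subject cohorts with K = 12/R = 25 and K = 6/R = 10 (transition error ≤
0.05, path agreement ≥ 0.9); synchrony null calibration on 100 cohorts of
8 + 10 subjects, T = 200, K = 6 (conjunction flag rate ≤ 7.5% per state);
planted-episode recovery (adherence 0.9, 30 volumes ending at a scene
boundary, 15 + 20 subjects) with Jaccard ≥ 0.8 in ≥ 90% of seeds; and
ANCOVA null calibration against F(1, n − 4) with power under the blunted
fixture. The planted window is placed flush against a scene boundary
because of the post-episode persistence noted above — mid-scene placements
systematically over-extend flagged runs, which is a property of the
statistic worth knowing, not a defect of the test.

## Known limitations

* AIC with full covariances overselects K on small samples (it is not a
  consistent order-selection criterion); the diagonal observation model is
  better behaved when states are near-spherical. The per-K AIC table is
  always returned so the elbow can be inspected directly.
* The consistency statistic's time resolution is limited by the 7-TR
  window; event boundaries are accurate to about ±3 volumes at best.
* The between-group null can saturate at 100% for very small groups with a
  strong shared episode, making flags impossible at those volumes;
  group sizes of 10+ avoid this in practice.
* The within-group null conditions on the estimated transition matrix;
  with very short masked segments that estimate is noisy and the null
  correspondingly unstable.
* Dwell times within a fragmented mask are biased short by design
  (truncation at mask boundaries), which is the behaviour wanted for
  scene-restricted analysis but not an estimate of free-running dwell.
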