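---
title: "Extracting muscle synergies from walking EMG"
author: "gaitsynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting muscle synergies from walking EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Muscle synergy analysis treats the envelopes of several muscles recorded
during a repetitive movement as the output of a small number of shared
neural drives. For a gait-cycle matrix $M$ ($n$ time points $\times$ $m$
muscles, nonnegative), the model is the factorization

$$M \approx H\,W,$$

where $H$ ($n \times k$) holds the *synergy activation coefficients* — one
nonnegative time course per synergy over the normalized gait cycle — and $W$
($k \times m$) holds the *muscle synergy weights* — how strongly each muscle
participates in each synergy. Both factors are constrained nonnegative, which
is what makes the decomposition interpretable as additive muscle drives:
nonnegative matrix factorization (NMF).

The factorization is inherently ambiguous up to per-synergy rescaling and
permutation. `gaitsynergy` fixes the scale by rescaling each row of $W$ to
maximum 1 (the compensating factor absorbed into the columns of $H$), so
entries of $W$ are *relative muscle weights* comparable across subjects, and
fixes the order downstream by sorting synergies by the gait-cycle position of
their activation peak.

## From raw EMG to the matrix $M$

`preprocess()` implements the standard linear-envelope chain, each stage
exposed as its own function:

1. **Band-pass 10–500 Hz** (`bandpass_filter`): Butterworth, order 4,
   zero-phase. At a 1000 Hz sampling rate the nominal 500 Hz upper edge sits
   on the Nyquist frequency; the edge is clipped to 0.99 × Nyquist and a
   warning is emitted rather than failing, since the band is then effectively
   a 10 Hz high-pass, which is what the stage scientifically does.
2. **Full-wave rectification** (`full_wave_rectify`).
3. **Low-pass 6 Hz** (`lowpass_envelope`): Butterworth, order 4, zero-phase;
   small negative ringing is clipped at 0.
4. **Segmentation** into gait cycles (`segment_cycles`) from externally
   supplied events (0-based, half-open `[start, end)` sample intervals). The
   package deliberately does not detect gait events from the EMG itself.
5. **Submaximal amplitude normalization** (`normalize_amplitude_per_cycle`):
   each channel divided by its own within-cycle maximum.
6. **Time normalization** (`time_normalize`): natural cubic-spline resampling
   onto 101 points spanning 0–100 % of the cycle, endpoints included.
7. **Averaging across cycles** (`build_subject_matrix`), then re-dividing
   each column by its maximum, because averaging per-cycle-normalized
   envelopes can leave column maxima below 1 while the matrix contract is
   values in $[0,1]$ with per-muscle maximum 1.

Zero-phase (forward–backward) filtering is used everywhere because burst
*timing* is an analysis target; causal filtering would lag every burst by a
phase that differs across the band. The implementation pads each channel
with an odd-symmetric reflection and starts the filter in its constant-input
steady state, so edge transients do not contaminate the first and last
cycles of a recording.

Two consequences of this preprocessing are worth keeping in mind when
interpreting results. First, submaximal normalization removes each muscle's
absolute scale: a uniform change of one muscle's gain across the whole cycle
is unobservable, and only changes that alter the muscle's *profile* across
synergies survive. Second, averaging as few as three cycles leaves residual
within-subject noise in $M$; the factorization sees that noise.

## Fitting and choosing the number of synergies

`nnmf_decompose(M, k)` minimizes the Frobenius reconstruction error with the
classical multiplicative update rules, which preserve nonnegativity and
never increase the loss. Numerical choices:

* initialization: uniform random factors scaled so the initial product
  matches the mean of $M$; `n_restarts = 20` seeded restarts by default, the
  lowest-loss restart wins and ties go to the earliest seed;
* convergence: stop when the relative loss decrease drops below
  `tol = 1e-6`, or after `max_iter = 2000` updates;
* a small `1e-12` is added to update denominators to avoid division by zero;
* the result is canonicalized (rows of $W$ to max 1).

Reconstruction quality is summarized by the variance accounted for,

$$\mathrm{VAF}_m = 1 - \frac{\sum_t (\hat M_{tm} - M_{tm})^2}
                            {\sum_t M_{tm}^2},$$

computed per muscle and pooled globally (`vaf_per_muscle`, `vaf_global`).
This is the standard uncentered squared-residual form; a sign-sensitive
unsquared variant occasionally seen in print is exposed via
`form = "unsquared"` for comparison but is unbounded above and not used
anywhere in the pipeline.

`select_num_synergies()` fits $k = 1, 2, \dots$ and stops at the first $k$
whose per-muscle VAFs all exceed the threshold (default 0.9). Each fit at
$k+1$ includes a warm-start candidate built from the best $k$ solution
padded with a tiny random extra component, alongside fresh restarts; since
updates are monotone, the best achievable loss — and hence the global VAF
curve — is non-decreasing in $k$, which keeps the stopping rule well
defined. If the rule is never met by `k_max` (default: the number of
muscles) the curve is flagged and `k_max` returned with a warning rather
than silently picking something.

## Comparing groups

Per-subject decompositions are compared across two cohorts as follows:

* **Ordering and alignment.** Within a subject, synergies are ordered by
  activation-peak position (ties: larger energy first). Across subjects,
  `align_subject_to_reference()` finds the permutation maximizing the summed
  Pearson correlation of matched activation columns, by exhaustive search —
  exact for the $k \le 8$ of any realistic synergy analysis.
* **Group sets.** `group_mean_synergies()` averages aligned $H$ and $W$
  across subjects (`mean_H`, `mean_W`, `sd_W`). Averaging per-subject fits
  was chosen over factorizing concatenated group data because the analysis
  is defined per subject and group dispersion (SD of weights) is itself
  reported. The reference subject is the first by input order; with the
  burst-like activations this package targets, matching is insensitive to
  that choice.
* **Similarity.** `crossgroup_correlation()` correlates the two groups' mean
  activation coefficients (all $k \times k$ pairs; the matched diagonal is
  the headline). `classify_similarity()` maps $|r|$ onto the conventional
  bands small $[0, 0.3)$, moderate $[0.3, 0.7)$, high $[0.7, 1]$ —
  left-closed so the nominal band gaps at 0.29–0.3 and 0.69–0.7 are covered
  — and warns for values within 0.05 of a band edge, because published
  readings of near-boundary correlations are inconsistent (values just above
  0.3 are sometimes called weak). The warning surfaces the ambiguity instead
  of resolving it.
* **Tests.** `compare_weights()` runs an independent-samples pooled-variance
  t-test per (synergy, muscle) cell on the aligned relative weights, with
  Shapiro–Wilk normality p-values attached per sample. No multiple-testing
  correction is applied by default, mirroring common practice in this
  literature; Holm correction and a Mann–Whitney variant are available
  behind flags. `compare_vaf()` t-tests per-subject global VAF at each k.
  When the two groups' modal selected $k$ differ, `run_pipeline()` refits at
  the overall modal $k$ (ties to the smaller) and flags this in the run
  warnings, since the cross-group report needs a common $k$.

## The synthetic cohort generator

Real walking-EMG cohorts are rarely shareable, so the package ships a
generator (`synergy_model`, `cohort_spec`, `generate_cohort`) whose ground
truth is known exactly, making every downstream stage testable by parameter
recovery.

* **Activation profiles** are Gaussian bursts, one per synergy, on a
  circular 0–100 % cycle domain (bursts near the cycle boundary wrap). The
  default four-synergy model places bursts at 12, 45, 70 and 92 % of the
  cycle with widths 9, 8, 8 and 7 % — weight acceptance, plantarflexor
  push-off, early-swing dorsiflexion, late-swing deceleration — over the
  five muscles GA, TA, VL, GM, BF.
* **Default weights** were designed for identifiability: each synergy has a
  distinctive dominant muscle, so the noiseless three-synergy fit leaves at
  least one muscle's VAF near 0.82, well below the 0.9 selection threshold,
  while four synergies reconstruct exactly. VL deliberately carries its
  largest weight in the late-swing synergy (0.75) and a sub-maximal weight
  (0.45) in the first: under submaximal normalization a perturbation of a
  muscle's *maximal* weight entry would be largely absorbed by the
  normalization itself — an observability constraint of the normalization
  scheme, not of the generator.
* **Raw EMG** is band-limited (20–450 Hz) unit-variance Gaussian carrier
  noise amplitude-modulated by the envelope, sampled at 1000 Hz — the
  standard surrogate for interference-pattern surface EMG. Gait cycles have
  seeded random durations (1.1 ± 0.08 s) and exact cycle boundaries are
  emitted as the event sidecar.
* **Noise and variability.** Envelope noise is multiplicative log-normal
  (amplitude-proportional, as for rectified EMG), scale 0.2 by default
  ("moderate"); between-subject variability is i.i.d. multiplicative jitter
  on weight entries (SD 0.1, truncated at 0). Group B optionally applies
  multiplicative perturbations to named (synergy, muscle) weight entries.
* **Not emulated:** electrode placement and cross-talk, motion artifact,
  inter-muscle carrier correlation, within-cycle duration structure
  (stance/swing asymmetry), kinematics. Passing recovery tests on this
  generator therefore demonstrates the pipeline's correctness on data that
  satisfy the synergy model, not robustness to every artifact of real
  recordings.

`generate_cohort(level = "envelope")` skips the carrier synthesis and
returns noisy 101-point envelopes directly; Monte-Carlo studies of the
statistics use this fast path, while the raw path exercises the full
preprocessing chain.

## Degenerate inputs and tie-breaks

* All-zero channels fail amplitude normalization (and VAF) with an error
  naming the channel — silently propagating 0/0 would corrupt group means.
* Overlapping, inverted or out-of-bounds gait events fail with the cycle
  index named.
* Cycles shorter than 4 samples cannot be cubic-resampled and error.
* Constant activation columns yield `NA` correlations with a warning.
* Equal activation peaks are ordered by energy; equal restart losses by
  seed order; modal-k ties by the smaller k.

## Problem sizes used by the test-suite experiments

The packaged experiments run at sizes chosen to make their statistical
claims meaningful while staying quick on a laptop: the cohort-level
recovery run uses 10 subjects per group with 3 cycles each; factor-recovery
uses 20 seeded noiseless subjects; null calibration of the weight tests
uses 30 replicate cohorts (600 test cells) and the power check 100
replicate cohorts at the 1.5× perturbation. Larger replicate counts shrink
the Monte-Carlo error of the estimated rates but do not change the
qualitative conclusions.

## Known limitations

* Multiplicative-update NMF converges to local optima; restarts mitigate
  but do not guarantee the global optimum. The test suite cross-checks
  achieved losses against an independent alternating nonnegative
  least-squares solver on small problems.
* The per-muscle VAF rule inherits the threshold's arbitrariness; near-0.9
  fits make the selected k sensitive to noise realizations.
* Submaximal normalization makes absolute activation levels unobservable by
  design; only relative weight structure is compared across groups.
* Exhaustive permutation matching is exact but factorial in k; k > 8 would
  need a proper assignment algorithm.
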