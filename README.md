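# gaitsynergy

Muscle synergy analysis of walking EMG in R: linear-envelope preprocessing,
nonnegative matrix factorization (NMF) into synergy weights and activation
coefficients, variance-accounted-for (VAF) selection of the number of
synergies, and two-group comparison of synergy patterns and relative muscle
weights. It is written for movement scientists who record multi-channel
surface EMG during gait and want the standard synergy pipeline as tested,
scriptable functions rather than ad-hoc MATLAB scripts — plus a synthetic
cohort generator with known ground truth so the whole pipeline can be
validated by parameter recovery.

## The model

A per-subject gait-cycle matrix *M* (101 time points × *m* muscles,
nonnegative, each muscle normalized to its per-cycle maximum) is factorized
as

    M ≈ H W,   H ≥ 0 (101 × k),   W ≥ 0 (k × m)

where each column of *H* is a synergy's activation coefficient over the
normalized gait cycle and each row of *W* its relative muscle weights
(canonicalized to row-max 1). Reconstruction quality per muscle is

    VAF_m = 1 − Σ_t (Ĥ W − M)²_tm / Σ_t M²_tm

and the number of synergies is the smallest *k* with VAF_m > 0.9 for every
muscle. Groups are compared by Pearson correlation of mean activation
coefficients (banded small/moderate/high at 0.3 and 0.7) and by
independent-samples t-tests on the aligned relative weights and VAF values.

## Worked example

Simulate one subject's raw EMG (five muscles at 1000 Hz, three gait cycles,
four-synergy ground truth, moderate envelope noise), preprocess it to the
101 × 5 matrix, and select the number of synergies:

```r
library(gaitsynergy)

mod  <- default_synergy_model(noise_sigma = 0.2, seed = 42)
spec <- cohort_spec(n_subjects = 10, n_cycles_per_subject = 3)
sim  <- synthesize_raw_emg(mod, spec, subject_seed = 1)

M <- preprocess(sim$recording, sim$events)   # warns: 500 Hz edge Nyquist-clipped
curve <- select_num_synergies(M, threshold = 0.9, seed = 1)
curve
#> Synergy selection curve (threshold 0.9): k_selected = 4
#>  k vaf_global min_vaf_muscle vaf_GA vaf_TA vaf_VL vaf_GM vaf_BF
#>  1     0.6314         0.1034 0.1034 0.2435 0.9714 0.7807 0.8226
#>  2     0.7958         0.5311 0.7041 0.5311 0.9846 0.8233 0.8323
#>  3     0.9307         0.8347 0.9990 0.9868 0.9838 0.8523 0.8347
#>  4     0.9983         0.9964 1.0000 1.0000 0.9964 0.9993 0.9964
```

One synergy explains 63 % of the pooled signal energy but leaves GA at
VAF 0.10; four synergies are the first count at which every muscle exceeds
0.9, so `k_selected = 4`. The fit at the selected k:

```r
summary(selected_decomposition(curve))
#> Synergy decomposition with k = 4
#> Activation peaks (% of cycle): 69, 45, 12, 92
#> Relative muscle weights W (rows max-1):
#>       GA    TA    VL    GM    BF
#> S1 0.002 1.000 0.094 0.010 0.086
#> S2 1.000 0.043 0.065 0.002 0.019
#> S3 0.045 0.043 0.500 1.000 0.084
#> S4 0.035 0.097 0.983 0.374 1.000
#> Global VAF: 0.9983  (loss 0.3789)
```

Each synergy is a burst at a distinct phase of the cycle with a dominant
muscle (TA in early swing, GA at push-off, GM/VL at weight acceptance, BF in
late swing), recovering the generating structure.

A full two-group study — here with group B's VL weight in the first synergy
scaled by 1.5× — runs end to end from one config:

```r
cfg <- default_run_config(seed = 42)
cfg$simulate$weight_perturbations <-
  data.frame(group = "B", synergy = 1, muscle = "VL", factor = 1.5)
run <- run_pipeline(cfg)

run$modal_k
#> A B
#> 4 4
run$report
#> Matched synergy pairs (diagonal):
#>  synergy     r similarity
#>        1 0.997       high
#>        2 1.000       high
#>        3 0.999       high
#>        4 0.999       high
#>
#> Weight tests: 2 of 20 (synergy, muscle) cells significant
#>  synergy muscle mean_A  sd_A mean_B  sd_B statistic        p ...
#>        1     VL  0.590 0.075  0.806 0.137     -4.38 0.000361
#>        2     VL  0.115 0.022  0.093 0.023      2.28 0.034900
```

Both groups select four synergies; the activation patterns stay highly
correlated while the perturbed (synergy 1, VL) weight is the clearest
significant difference — exactly the dissociation (same synergy count and
timing, shifted relative weights) this kind of analysis is designed to
detect. `run_pipeline(cfg, out_dir = "run1/")` additionally writes all
per-subject matrices, factors, VAF curves, report tables and a checksummed
manifest.

## Package layout

* `R/simulate.R` — ground-truth models, cohort specs, raw-EMG synthesis
* `R/preprocess.R` — filtering, rectification, envelope, segmentation,
  normalization (`preprocess()` chains them)
* `R/nmf.R`, `R/select.R` — the `synergy_nmf` fit (print/summary/coef/
  fitted/residuals/plot methods), VAF, `select_num_synergies()`
* `R/compare.R` — ordering, permutation alignment, group means,
  correlation bands, weight/VAF tests
* `R/pipeline.R`, `R/io.R` — YAML-configured `run_pipeline()`, CSV/JSON I/O

See `vignettes/muscle-synergy-pipeline.Rmd` for the methods account:
assumptions, parameter defaults and units, generator design, numerical
choices and limitations.
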