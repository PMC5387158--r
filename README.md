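# metavbq

Simulation and analysis tools for studying how **perceptual metacognitive
ability** relates to **quantitative brain-map measures**, with every stage
validatable against known ground truth.

People differ in how well their trial-by-trial confidence tracks their
actual accuracy. The standard measure of this insight is the **type-II
AROC**: the area under the ROC built from confidence criteria
discriminating correct from incorrect trials,

> H_k = P(confidence ≥ k | correct), F_k = P(confidence ≥ k | incorrect),
> k = 2..4, anchored at (0,0) and (1,1), area by the trapezoid rule,

with 0.5 = no insight and 1 = perfect insight. Relating AROC to voxelwise
quantitative MRI parameters (MT saturation, R1, R2\* — markers of myelin
and iron) requires a long chain: an adaptive motion-discrimination task,
confidence binning and signal-detection analysis, per-subject 3D maps, and
mass-univariate regression with familywise-error (FWE) control. `metavbq`
implements the whole chain and, because its observers and maps are
simulated with known generating parameters, every link can be tested:
planted effects must be recovered, absent effects must be rejected at the
nominal rate.

The package provides, as composable tibble-first functions:

* **Behaviour simulation** — `run_session()`, `simulate_cohort()`: dual
  2-up-1-down staircases (adaptive mean angle at fixed 30° direction SD,
  and adaptive SD at fixed 15° mean) converging on ~71% correct; 0–100
  confidence ratings from a noisy, variance-biased evidence readout.
* **Behavioural analysis** — `filter_trials()`,
  `bin_confidence_quartiles()`, `compute_sdt()`, `compute_aroc()`,
  `confidence_bias_betas()`, `staircase_stability_anova()`,
  `summarise_cohort()`.
* **Synthetic maps** — `generate_cohort_maps()`: MT/R1/R2\* grey-matter
  volumes on an MNI-like grid with planted AROC effects at published
  coordinates, covariate confounds and 4 mm-smooth noise; NIfTI round-trip
  via `write_cohort()` / `read_cohort()`.
* **Voxelwise inference** — `build_design()`, `fit_voxelwise()`,
  `make_voi_mask()`, `permutation_fwe()`: Freedman–Lane permutation maxT
  (small-volume peak-level) and max-cluster-extent (whole-brain
  cluster-level, p < 0.001 cluster-forming) FWE correction.
* **One-call pipeline** — `run_pipeline()`: all stages with derived
  per-stage seeds and a checksum manifest.

## Worked example

Simulate one observer's session and analyse it:

```r
library(metavbq)

trials <- run_session(seed = 1)
f <- filter_trials(trials)
f$report
#> # A tibble: 1 × 6
#>   n_input n_dropped_first_block n_dropped_no_response n_dropped_rt_fast ...
#> 1     320                    40                     0                 0

binned <- bin_confidence_quartiles(f$trials)
compute_aroc(binned[binned$condition == "mu", ])
#> <type2_roc> AROC = 0.5970 (100 correct, 37 incorrect trials)

summarise_subject(binned, already_filtered = TRUE)[
  , c("accuracy", "d_prime", "criterion", "aroc", "mean_rt_ms")]
#>   accuracy  d_prime  criterion     aroc mean_rt_ms
#> 1  0.73187 1.243396 0.02229277 0.616876   410.6164
```

The observer sits near the staircase's 70.7% fixed point (accuracy 0.73,
d′ ≈ 1.24 against the ~1.09 implied by exactly 70.7%), responds without
side bias (criterion ≈ 0), and shows moderate metacognitive insight
(average AROC 0.62: confidence separates correct from incorrect trials
well above the 0.5 chance level). The negative `variance_bias_beta`
(−6.4 confidence points per SD-unit of stimulus variability) recovers the
generative observer's built-in variance-induced confidence bias.

A full cohort analysis — 48 subjects, synthetic maps with planted effects,
and permutation-corrected voxelwise regression:

```r
cfg <- pipeline_config(seed = 1, n_subjects = 48, n_perm = 500,
                       output_dir = "metavbq-output")
manifest <- run_pipeline(cfg)
read_report(file.path(cfg$output_dir, "report_significant.csv"))
```

The significant-cluster table recovers the planted ground truth: MT+ and
R1+ clusters peaking within a few mm of the right-aPFC site (37, 41, 22),
an MT− cluster at the left-hippocampus site (−31, −25, −14), and the three
R2\* effects, each with its planted sign.

See the vignette (`vignettes/metacognition-vbq-methods.Rmd`) for the
observer model, the generator's assumptions, and every numerical choice.

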