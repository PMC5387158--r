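---
title: "Simulating metacognition experiments and voxelwise quantitative-map regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metacognition experiments and voxelwise quantitative-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metavbq)
```

# The problem

Metacognitive ability — how well trial-by-trial confidence tracks objective
accuracy — varies substantially across people, and individual differences in
it have been related to the structure of anterior prefrontal cortex,
precuneus and medial temporal regions. Testing such brain–behaviour
relationships voxel by voxel requires a long computational chain: an
adaptive psychophysical task, type-II signal-detection analysis of
confidence, per-subject quantitative brain maps, and mass-univariate
regression with familywise-error control. Every link of that chain can hide
bugs that bias the scientific conclusion.

`metavbq` re-implements the full chain with *simulated* observers and
*synthetic* quantitative maps, so that each stage can be validated against
known ground truth: planted effects must be recovered, and absent effects
must be rejected at the nominal error rate. Real trial tables (CSV) and
real quantitative maps (NIfTI) with the same layout can be run through the
identical code path.

# The behavioural task and observer model

## Task

The simulated task is a two-alternative global-motion discrimination with
retrospective confidence ratings. Each trial presents 1100 dots whose
directions (in degrees from vertical; negative = leftward) are drawn as

$$\textrm{direction}_i = \pm\mu + \varepsilon_i,\qquad
  \varepsilon_i \sim \mathcal N(0,\sigma^2),$$

with the sign set by the true side. Two interleaved conditions control
difficulty through different parameters:

* **mu staircase**: the mean angle $\mu$ adapts; $\sigma$ is fixed at 30°;
* **sigma staircase**: $\sigma$ adapts; $\mu$ is fixed at 15°.

Both tracks follow the rule that two consecutive correct responses make the
task harder and any error makes it easier, whose fixed point is
$p^2 = 1/2$, i.e. $\approx 70.7\%$ correct. A session comprises a 56-trial
practice block with accuracy feedback (a session-level flag records whether
practice accuracy exceeded 70%) followed by 320 main trials split evenly
between conditions and interleaved randomly within blocks with equal
per-block counts. The default is 8 blocks of 40 trials; the trial count and
block count are configurable, and the 8 × 40 layout is the one consistent
with a 320-trial session.

Staircase start levels, steps and bounds are design choices (they are not
fixed by the task description): the mean-angle track starts at 15° (step 1°,
bounds 0.5–45°) and the SD track at 30° (step 2°, bounds 5–90°), i.e. each
adaptive parameter starts at the fixed value of the opposite condition and
moves away from it as the observer settles at threshold.

## Observer

The observer estimates the mean direction by averaging a random subsample of
`n_effective_dots` dots (default 4) and adding Gaussian sensory noise
(default SD 10°); the choice is the sign of the estimate $e$. Limited-sample
averaging is essential: an ideal averager of all 1100 dots would see a
standard error under 1° even at $\sigma = 90°$, and the SD staircase could
never pull performance down to 71%. With defaults, the two tracks
equilibrate near $\mu \approx 10°$ and $\sigma \approx 50°$ — the right
order of magnitude for the adaptive thresholds this task produces
(reported medians are ~6.5° and ~53°); a single-channel Gaussian observer
cannot match both medians simultaneously, and we did not add a second
parameter to force it.

Confidence is modelled as a noisy readout of decision evidence. The raw
evidence $|e|$ is first standardised against its trial-conditional
folded-normal distribution (mean and SD of $|e|$ given the trial's $\mu$,
$\sigma$ and the observer's noise), then corrupted with Gaussian
*metacognitive noise*, shifted by `variance_bias_weight` × (stimulus SD),
and affinely mapped and clamped to a 0–100 scale. The standardisation is a
deliberate modelling choice with one purpose: it guarantees that stimulus
parameters influence confidence **only** through the explicit bias weight,
so the within-subject bias regression has a clean generative target — a
planted weight of zero really means a zero partial association. Without it,
the spread of $|e|$ grows with stimulus SD and a spurious "variance bias"
appears that no regression on observable covariates can fully remove.

Metacognitive noise controls insight: at 0 the confidence ordering matches
the evidence ordering (AROC near its ceiling); as it grows, AROC falls
toward 0.5. Cohorts draw it per subject from a log-normal (median 0.4,
log-SD 0.8), which yields cohort AROC of roughly 0.65 ± 0.04 — close to the
0.68 ± 0.06 such tasks produce (the residual gap is the ceiling imposed by
a Gaussian observer held at 71% accuracy with quartile-binned ratings).
Reaction times are `rt_base_ms` plus gamma noise (mean ≈ 410 ms); the
simulator never times out, but imported data may contain non-responses,
which the filter stage drops.

# Behavioural analysis

* **Filtering** (`filter_trials()`): drop the first block (staircase
  stabilisation), non-responses, trials with RT < 100 ms, then trials more
  than 3 SD from the mean RT, with mean and SD computed once on the
  already-cleaned set (single pass — re-applying the filter can drop more
  trials, and this non-idempotence is documented and tested). The RT
  moments are pooled over conditions.
* **Confidence binning** (`bin_confidence_quartiles()`): per-subject
  rank-based assignment into 4 near-equal bins, ties broken by trial index;
  bin sizes differ by at most one. Rank binning makes AROC invariant to any
  strictly monotone transform of raw confidence.
* **Type-I SDT** (`compute_sdt()`): with rightward stimuli as "signal",
  $d' = z(H) - z(F)$ and $c = -(z(H)+z(F))/2$; extreme rates are adjusted
  by the 1/(2N) rule so both stay finite.
* **Type-II AROC** (`compute_aroc()`): cumulative type-II ROC over the
  three interior confidence criteria — $H_k = P(\mathrm{conf} \ge k \mid
  \mathrm{correct})$, $F_k = P(\mathrm{conf} \ge k \mid \mathrm{incorrect})$
  for $k = 2,3,4$ — anchored at (0,0) and (1,1), with the area computed by
  the trapezoid rule. 0.5 is chance insight, 1 perfect insight. The printed
  rendering of this formula in the source literature is typographically
  corrupted; the cumulative-trapezoid construction is the standard reading
  of the cited metric, and the implementation is verified against an
  independent brute-force oracle on random count tables. AROC is computed
  separately per condition and averaged.
* **Confidence-bias regression** (`confidence_bias_betas()`): within each
  subject, OLS of raw confidence on standardised trial-wise mean angle,
  stimulus SD, accuracy and RT. The SD weight is the variance-induced
  confidence bias carried into the group design.
* **Stability ANOVA** (`staircase_stability_anova()`): each subject's
  retained trials are re-binned into 8 equal-count bins per condition
  (sessions may be truncated, so time bins rather than raw blocks), and
  per-bin accuracy enters a two-way fully within-subject ANOVA (bin ×
  condition). "8 equal-count bins" is the coherent reading of the
  re-binning description, which as printed (8 bins of 20%) is
  self-contradictory. Because sphericity is not guaranteed, uncorrected and
  Greenhouse–Geisser-adjusted p-values are reported side by side.

# Synthetic quantitative maps

`generate_cohort_maps()` builds per-subject MT (percent units), R1 (1/s)
and R2* (1/s) grey-matter maps on a reduced MNI-like grid: 2 mm isotropic
voxels spanning x ∈ [−59, 59], y ∈ [−75, 71], z ∈ [−24, 40] mm (configurable
down to 0.8 mm), with a superellipsoid pseudo grey-matter mask that keeps
every default coordinate in-mask. Each map is

$$\textrm{baseline} \;+\; \sum_{\textrm{sites}} \beta_s\,
  (x_{\textrm{pred}} - \bar x)\, k_s(\mathbf v) \;+\;
  \textrm{confounds} \;+\; \textrm{smooth noise},$$

where $k_s$ is a Gaussian spatial kernel (SD = extent/2) around the site's
coordinate. Defaults: baselines 0.9 pu / 0.62 s⁻¹ / 16 s⁻¹ (plausible
grey-matter values; absolute levels do not matter for the regression),
noise SDs 0.04 / 0.025 / 1.2 rescaled after smoothing to the exact in-mask
SD, noise smoothness 4 mm FWHM, and uniform age, gender and TIV confound
fields (age effects on by default — age is a strong determinant of brain
microstructure). The default effect sites place AROC effects at the
published coordinates (right aPFC MT+/R1+, left hippocampus MT−, precuneus
R2*+, V1 R2*−, left MTG R2*+) with slopes scaled so planted peak t-values
land in the 4–6 range reported for such effects, and a 12 mm spatial extent
mirroring the several-hundred-voxel cluster sizes reported at those peaks.

What the generator does *not* emulate: MRI physics (FLASH signal equations,
B1 correction, R2* fitting), segmentation and nonlinear registration,
non-stationary smoothness, non-Gaussian noise, and spatially structured
confounds. Passing tests therefore demonstrate the correctness of the
*analysis chain*, not robustness to acquisition artefacts in real maps.

# Voxelwise inference

`build_design()` assembles the group design: intercept, average AROC (the
effect of interest, kept on its native scale — t statistics are
scale-invariant), average d′, average confidence, criterion, the
variance-bias beta, the staircase mean-signal difference (median adaptive
mean angle minus the 15° fixed mean), and age, gender, TIV. Continuous
covariates are z-scored, gender is centred; constant columns are dropped
with a warning and residual rank deficiency is an error.

`fit_voxelwise()` runs OLS per in-mask voxel (vectorised linear algebra;
verified to 1e-10 against per-voxel `lm()`), giving the AROC t-map with
n − p degrees of freedom; the negative contrast is the sign-flipped map.

`permutation_fwe()` replaces analytic random-field corrections with
permutation inference, which is exact under exchangeability and testable by
calibration:

* **Nuisance handling**: Freedman–Lane — maps are residualised against all
  covariates except AROC, residual rows are permuted, and the full model is
  refit. The implementation collapses each permutation to a single
  (p+1) × n × V cross-product via the Frisch–Waugh identities, which makes
  hundreds of permutations on a 10⁵-voxel grid cheap.
* **Peak level / small-volume correction**: max-t null over the mask —
  typically the union of 5 mm spheres at the eight published a-priori
  coordinates (`make_voi_mask()`), α = 0.05.
* **Cluster level**: suprathreshold clusters of the one-tailed t-map at the
  cluster-forming threshold (p < 0.001; 0.005 for exploratory analyses),
  26-neighbour connectivity, scored against the max-cluster-extent null.
* **Conventions**: the identity permutation is always the first of
  `n_perm`, so p-values are bounded below by 1/`n_perm` and the observed
  statistic is included in its own null (the standard tie-safe choice);
  one-tailed tests per signed contrast mirror the separate
  positive/negative analyses.

Note that 5 mm spheres on this 2 mm grid give a VOI mask of a few hundred
voxels; published mask sizes generated by other tooling on finer grids are
not comparable and are not a target.

# Numerical and degenerate-input choices

* AROC is undefined without both correct and incorrect trials; the error
  names the missing class.
* d′/c use the 1/(2N) adjustment for 0 or 1 rates.
* Total-tie confidence vectors are split deterministically by trial index.
* Constant within-subject predictors are dropped from the bias regression
  and flagged rather than producing a singular solve.
* All-equal ANOVA cells return F = 0 (not 0/0).
* Smoothing kernels are renormalised at volume edges, so a constant field
  is preserved exactly; noise fields are rescaled to the target SD after
  smoothing (exact marginal SD rather than the analytic kernel norm, which
  edge effects would bias).
* Cluster labelling uses union-find over the 13 forward neighbour offsets;
  verified against a brute-force flood fill.
* Every stage accepts an explicit seed; `run_pipeline()` derives per-stage
  seeds by hashing the master seed with the stage name, so single stages
  can be reproduced in isolation and the whole pipeline is
  checksum-deterministic.

# Problem sizes used in the test-suite experiments

The calibration and recovery experiments in the test suite run at reduced
scale, chosen as the smallest sizes at which the binomial confidence
intervals of the checks are meaningful: FWE calibration uses 200 null
cohorts of 24 subjects on a 6 mm grid with 300 permutations; planted-effect
recovery uses 20 cohorts of 48 subjects on the default 2 mm grid with 49
permutations; reported analyses should use ≥ 500 permutations (the
default).

# Known limitations

* The observer is a single-channel Gaussian averager: it reproduces the
  staircase equilibria and type-II structure qualitatively, not the exact
  printed medians of both adaptive parameters at once.
* Cohort AROC sits slightly below 0.68 because quartile binning and the
  71%-accuracy operating point cap attainable AROC for this observer class.
* Uniform confound fields make nuisance regression non-trivial but are a
  best-case for it; spatially varying confounds in real data are harder.
* Permutation inference assumes exchangeable subjects under the null;
  heavy-tailed or heteroscedastic between-subject noise would call for
  sign-flipping or robust variants not implemented here.
* No atlas labelling: report tables carry coordinates, with an optional
  user-supplied labeller.

# A minimal worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1, n_subjects = 48, n_perm = 500,
                       output_dir = "metavbq-output")
manifest <- run_pipeline(cfg)
report <- read_report(file.path(cfg$output_dir, "report_significant.csv"))
```

The significant-cluster report recovers the planted sites: positive MT and
R1 clusters at the right-aPFC coordinate, a negative MT cluster in the left
hippocampus, and the three R2* effects, each with its planted sign and a
peak within the planted spatial extent.
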