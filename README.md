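# laminar

Cortical-depth-resolved ("laminar") fMRI analysis of multisensory and
attentional effects, with a ground-truthed synthetic cortical-patch
simulator so that every stage of the pipeline is verifiable at desk scale.

## The scientific problem

Submillimetre 7T fMRI can sample the BOLD response at several depths
between the white-matter and pial surfaces of cortex, asking *where in the
cortical microcircuit* an effect arises: feedforward input arrives in
middle layers, while feedback and neuromodulation weigh on superficial and
deep laminae. This package implements the analysis stack used to ask such
questions about audiovisual interactions: do visual stimuli deactivate
auditory cortex uniformly across depth? Does attention scale the response
multiplicatively, preserving its spatial pattern? Does the laminar profile
of a vertex in one contrast predict its profile in another?

The package targets people building or validating laminar analysis
pipelines: because raw submillimetre datasets are rarely public, every
downstream stage here runs on synthetic vertex × depth × block datasets
with planted, recoverable ground truth.

## What it implements

* **Experiment construction** — looming stimuli (expanding annuli; rising
  tone complexes with amplitude `A(t) = A0·e^(0.68 t) − 1`), the 33 s
  block / 16 s fixation timeline (18 blocks per run, 50 stimuli per block
  at 660 ms SOA, 4 runs over 2 days), target scheduling (16 per modality
  per condition, biased to block ends) and behavioural scoring with 2.5 s
  response windows truncated at the next target.
* **Synthetic data** — flat 2D cortical patches (A1, PT, V1, V2/3) with
  curvature-coupled area proxies; vertex × 6-depth × 72-beta datasets with
  a superficial-bias depth gain, planted crossmodal deactivation shapes,
  patchy modulation fields correlated with the deactivation field,
  multiplicative pattern-preserving attentional gain, and block-level
  noise; voxel time series at the acquisition geometry (TR 3 s, 302
  volumes/run).
* **First-level GLM** — mixed block-event design matrix (canonical
  double-gamma HRF + temporal derivative, target and extra-response
  events, DCT drift with 128 s cutoff) fitted by AR(1) generalized least
  squares with a pooled lag-1 estimate.
* **Laminar profiles** — closed-form equivolume depth fractions, trilinear
  sampling along surface normals, median-over-vertices ROI profiles, the
  six block-wise contrasts (e.g. `[V−Fix] = [V_AttA + V_AttV]/2`,
  `[AV−A] = [(AV_AttA − A_AttA) + (AV_AttV − A_AttV)]/2`), and the laminar
  shape GLM `y(d) = C + L·x(d)` with centred depth regressor
  `x = −2.5 … 2.5`, so `C` is the profile mean and `L` the per-depth-step
  slope (positive = increase toward the surface).
* **Group inference** — 2 (shape: C, L) × 2 (ROI: primary, non-primary)
  step-down testing: a joint stage-1 test, per-shape stage-2 tests, and
  per-ROI stage-3 t-tests, gated at α = 0.05, with a-priori one-sided
  (negative) tests for crossmodal-deactivation constants.
* **MVPA** — per-depth linear SVC decoding (cost 1, features mean-centred
  within training and test sets separately) with leave-one-run-out
  cross-validation; accuracy-profile shape fits; Spearman pattern
  similarity with Fisher transform and a two-sided **exact sign
  permutation test** (all 2^n sign flips enumerated).
* **Raster regression** — vertices sorted and binned by a shape parameter
  of a predicting contrast, the predicted contrast's shape regressed on it
  in a leave-one-day-out cross-validation (runs 1–2 vs 3–4) that removes
  selection bias, one-sample t-tests on subject slopes, and 1%-FWHM
  display smoothing.

## Worked example

```r
library(laminar)

design   <- build_run_design(rng_seed = 1)
patch    <- make_cortical_patch(list(A1 = 150, PT = 120, V1 = 150, V23 = 120),
                                rng_seed = 1)
subjects <- simulate_vertex_betas(patch, ground_truth(), design,
                                  n_subjects = 8, rng_seed = 1)

# Is the visual-induced deactivation of auditory cortex constant across depth?
tab <- group_shape_table(subjects, c(primary = "A1", nonprimary = "PT"), "V-Fix")
stepdown_test(tab, sidedness = c(C = "less", L = "two.sided"))
#> <stepdown_result> n=8 method=exact
#>   stage 1: F(2, 6) = 78.998, p = 4.897e-05
#>   stage 2 [C]: stat = -11.011, p = 5.651e-06 (less)
#>   stage 2 [L]: stat = 0.087, p = 0.7766 (two.sided)
#>   stage 3 [C_primary]: t(7) = -12.944, p = 1.91e-06 (less)
#>   stage 3 [C_nonprimary]: t(7) = -8.040, p = 4.415e-05 (less)

# Audiovisual vs auditory blocks decode perfectly at every depth here
round(decode_per_depth(subjects[[1]], "A1", "AV_vs_A")$accuracy, 2)
#> [1] 1 1 1 1 1 1

# Attention scales patterns; visual input reshapes them: the similarity
# contrast is positive in every subject, so the exact two-sided sign
# permutation p is the smallest attainable for n = 8
z <- vapply(subjects, function(s) pattern_similarity(s, "A1")$contrast, numeric(1))
exact_sign_permutation(z)
#> [1] 0.0078125
```

The planted ground truth behind these numbers: a deactivation of constant
−1 across depth in auditory ROIs (recovered by the negative stage-2/3
constants with a flat linear term), a +0.3 crossmodal modulation field
(supporting the perfect AV-vs-A decoding), and a multiplicative attention
gain (driving attention-pair pattern similarity above stimulus-pair
similarity).

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
on synthetic data and write their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R          # design, targets, behaviour, datasets
Rscript analysis/02_first_level.R       # AR(1)-GLS beta recovery at TR 3 s
Rscript analysis/03_laminar_profiles.R  # contrast profiles + shape parameters
Rscript analysis/04_group_inference.R   # step-down tables per cortex family
Rscript analysis/05_mvpa.R              # decoding profiles + similarity test
Rscript analysis/06_raster.R            # cross-validated raster slopes
```

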