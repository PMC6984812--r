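---
title: "Methods: laminar profile analysis on synthetic cortical patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar profile analysis on synthetic cortical patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminar)
```

This vignette is the package's own account of the models it implements,
the assumptions behind them, and the design choices made where the
procedure was genuinely open.

## The experimental design being modelled

The design is a 3 (stimulus: auditory, visual, audiovisual looming) × 2
(attended modality) block design. Stimuli loom for 500 ms: visually, up to
four white annuli start in the centre (one every 125 ms), each expanding
from 0.25° at 15.52°/s until it reaches 3.88° and is removed; acoustically,
a 14-tone complex rises in amplitude as $A(t) = A_0 e^{0.68t} - 1$ ($t$ in
seconds) while each tone's frequency ramps linearly by two thirds of its
base value. The printed form of the amplitude law is typographically
ambiguous between $A_0e^{0.68t}-1$ and $A_0e^{0.68t-1}$; the package adopts
the first (the most literal reading), and the alternative grouping is noted
in the function documentation. Whether an annulus persists after reaching
the maximal radius is similarly unstated; here it is removed, so each
trajectory is defined on $[0, t_{\max}]$.

Each run consists of 18 pseudo-randomized 33 s blocks (3 per condition),
each preceded by 16 s of fixation with a 3 s attention cue, and holds 50
stimuli at a fixed 660 ms onset asynchrony; 4 runs are split over 2 days.
"Pseudo-randomized" is implemented as a seeded permutation constrained only
to 3 occurrences per condition per run, since no further constraint is
stated. Targets (16 per modality per condition) follow a 2:1 rule — two
thirds of a condition's 12 blocks carry one target per modality, one third
two — and are drawn uniformly from the *final half* of the block with at
least 1 s separation; the generating distribution is unstated beyond
"toward the end of blocks", and the uniform-final-half choice keeps
response windows non-degenerate. Behavioural scoring uses windows from
target onset to 2.5 s or the next target, whichever is earlier; presses
outside every window are extra-responses (they become a nuisance regressor,
not an error).

## The synthetic data generator

The generator is the package's substitute for non-public raw data, and its
defaults *are* the study conditions of the test suite. Each ROI (bilateral
A1, PT, V1, V2/3) is a flat 2D vertex grid — all downstream statistics
operate on per-vertex scalars, so no mesh topology is needed — carrying a
smoothed-Gaussian curvature field and curvature-coupled inner/outer area
proxies. "Patchy" fields are smoothed Gaussian random fields with a
configurable correlation length (default 3 grid units); the qualitative
term has no stated generative model, and thresholding is left to the
consumer.

Per vertex $v$, depth $d$ (1 = white-matter boundary, 6 = most
superficial) and block, the signal model is:

* stimulus-driven response $g(d)\,a(v)\,(1 + \gamma w(d))$ when the ROI's
  preferred modality is present, where $g(d)$ rises linearly from 1 to 2
  toward the surface (the gradient-echo superficial bias, "roughly linear
  toward the surface"), $a(v)$ is a patchy activation field (mean 2, sd
  0.4), and the attentional gain $\gamma = 0.2$ applies only when the
  preferred modality is attended, weighted by $w(d)$ rising from 0.5 to
  1.5 — multiplicative and hence pattern-preserving;
* crossmodal deactivation added for the non-preferred unisensory
  condition with planted shape $C^* + L^* x(d)$: $(-1, 0)$ in auditory
  ROIs (constant-shaped) and $(-1, -0.2)$ in visual ROIs (deactivation
  growing toward the surface);
* a crossmodal modulation field (mean $+0.3$, sd 0.5) added to
  audiovisual blocks, constructed so its correlation with the deactivation
  field is $\rho^* = 0.5$ in expectation — this planted coupling is what
  the raster regression recovers;
* i.i.d. block-level Gaussian noise (sd 0.5) and Gaussian subject random
  effects on $(C^*, L^*)$ (sd 0.2 and 0.05), the latter needed to exercise
  the group model.

One deliberate choice: the depth gain multiplies the *stimulus-driven*
response only, while planted contrast effects are injected additively in
post-gain units. Multiplying the effects too would make zero-noise
recovery of the planted $(C^*, L^*)$ impossible by construction; with this
convention the full pipeline returns them to machine precision on
noiseless data, which is the property the test suite leans on. Exact
recovery additionally requires vertex-constant effect fields, because the
ROI summary is a median: the sample median of a patchy field is not
exactly its centre, so the noiseless-recovery tests disable patchiness
while the statistical tests keep it.

What the generator does *not* emulate: draining-vein biophysics beyond the
linear gain, 3D volume geometry and resampling chains, k-space/EPI
artifacts, or spatial noise correlations across vertices (noise is
independent per vertex; patchiness lives in the effect fields, not the
noise). Passing tests therefore validate the *estimators*, not the
physiological realism of the simulations.

Voxel time series are simulated at the acquisition geometry — TR 3 s, 302
volumes per run (the nominal 902 s timeline plus 4 s of trailing
acquisition) — as design prediction + slow cosine drift + AR(1) noise
parameterized by its marginal sd.

## First-level model

The design matrix convolves each of the 18 block regressors and every
event (4 target types, extra-responses) with a canonical double-gamma HRF
(peak 6 s, undershoot 16 s, ratio 1/6 — the usual parameters; the source
names only "canonical") and its temporal derivative, at 0.1 s microtime
resolution. Drift uses a DCT basis with periods above 128 s; the order is
$K = \lfloor 2T/128 \rfloor$, i.e. 14 columns for a 906 s run. Events with
no instances yield all-zero columns that are flagged degenerate and
dropped before fitting rather than breaking the rank check.

AR(1) generalized least squares is the standard two-pass scheme: OLS
residuals give per-voxel lag-1 coefficients, pooled by the median across
voxels ("global approximate" autocorrelation; whether pooling was per run
or per session is unstated — per-run pooling is documented here as this
package's choice, not an inference about intent), then both sides are
prewhitened and refitted. Two caveats the tests make explicit: with a rich
drift basis the residual-based $\hat\rho$ is biased toward zero (the drift
absorbs low frequencies), so the calibration test uses a compact design;
and on noiseless data the residuals are numerically zero, where
$\hat\rho$ is defined as 0. Only the 18 activation-block HRF betas per run
are retained downstream (72 per subject), mirroring the retention rule of
the original analysis.

## Laminar profiles and shape parameters

Equivolume depth fractions have a per-vertex closed form: with
cross-sectional area interpolating linearly from the inner area $A_i$ to
the outer $A_o$, the depth containing volume fraction $\alpha$ is
$\rho = (\sqrt{(1-\alpha)A_i^2 + \alpha A_o^2} - A_i)/(A_o - A_i)$,
reducing to the equidistant grid for $A_i = A_o$. The full 3D level-set
construction is out of scope; the closed form captures the curvature
compensation that matters at this scale. Sampling along surface normals is
plain trilinear interpolation; points leaving the grid flag the vertex as
missing, and a vertex must have all 6 depths to enter any analysis
(exclusion, not imputation).

ROI profiles are medians over vertices (the vertex distribution is skewed,
especially superficially). The six contrasts are formed block-wise — same
block index, same run — giving 12 estimates per subject, ROI and contrast.
The shape GLM regresses the 6-depth profile on a constant and a centred
linear term $x = -2.5,\dots,2.5$. The regressors are exactly orthogonal,
so $C$ is the profile mean and $L = \sum x y / \sum x^2$; the linear
regressor's scale is a unit per depth step, a choice the source never
fixes, so absolute $L$ values are comparable only within this convention.
No quadratic term is included (U-shaped profiles are not modelled).

## Group inference: the step-down procedure

For each contrast and cortex family, subject-level $(C, L)$ values for the
primary and non-primary ROI (block-wise values averaged per subject by
default; block-wise entry is an option flag) enter a 2 × 2 step-down:
stage 1 jointly tests the ROI-averaged $C$ and $L$; stage 2 tests each
shape separately (only if stage 1 is significant); stage 3 tests each ROI
separately (only for shapes surviving stage 2). Deactivation constants use
one-sided (negative) alternatives throughout stages 2–3, reflecting the
a-priori direction; everything else is two-sided. α = 0.05 at every stage.

The default implementation uses exact subject-level reductions: Hotelling's
$T^2$ (an $F(2, n-2)$ statistic) at stage 1 and one-sample t-tests at
stages 2–3. For a balanced one-value-per-cell design these are exactly
calibrated at any $n$, which the 2000-simulation type-I test verifies. A
mixed-model Wald path (`method = "wald"`: random intercept per subject,
Satterthwaite denominator df via lmerTest) is retained for users who want
the LMM formulation; with residual rather than Satterthwaite df that
formulation is anticonservative at $n = 11$ (empirically ~0.09 type-I at
nominal 0.05), which is why it is not the default and why printed
denominator df from the original data are not expected to be reproduced.

## Decoding and pattern similarity

Decoding is a linear SVC (cost 1) per depth with leave-one-run-out folds;
features are mean-centred within the training set and, separately, within
the test set — test statistics never reach the training side, a property
asserted directly by a test that tampers with held-out data and checks the
training weights bit-for-bit. Pooled comparisons stack block-wise samples
(24 vs 24) rather than averaging attention conditions. Decision ties at
exactly zero margin break toward the lower label index, deterministically.
Accuracy profiles are shape-fitted after subtracting chance (0.5) with the
same laminar GLM machinery.

Pattern similarity uses Spearman correlations over vertices between
condition-mean patterns, Fisher-transformed, averaged within the
attention-pair and stimulus-pair families, and contrasted per subject.
Whether the original analysis pooled depths is unstated; patterns here are
averaged across blocks, runs and depths by default, with per-depth
similarity exposed as an option. $\rho = \pm 1$ maps to
$\mathrm{atanh}(1 - 10^{-12})$ — clipping keeps arithmetic finite while
preserving order. The group test enumerates all $2^n$ sign assignments of
the subject values ($n \le 20$) and reports the proportion whose absolute
mean reaches the observed one; p-values have granularity $2^{1-n}$ with
minimum $2^{-n}$, and ties are compared with a $10^{-12}$ relative slack
so the test is invariant to positive rescaling.

## Raster regression

To ask whether one contrast's laminar shape in a vertex predicts
another's, vertices are ranked by the sorting contrast's shape parameter
(ties broken by vertex index for reproducibility) and partitioned into $B$
near-equal contiguous bins, earlier bins taking the remainder vertices. At
the group level $B$ defaults to the smallest ROI vertex count across
subjects. Crucially the sorting values and the predicted values come from
*different days* (runs 1–2 vs 3–4): sorting noisy data on itself produces
a large spurious slope (the package exposes `day_split = FALSE` precisely
to demonstrate this — on pure noise it returns slopes near 1 where the
day-split estimator stays at 0). How the two fold slopes combine is
unstated in the source; they are averaged per subject before the
one-sample group t-test. Binning exists for display only: with $B$ equal
to the vertex count the slope equals the unbinned regression exactly, and
display smoothing (Gaussian along the bin axis, FWHM = 1% of $B$,
edge-renormalized so constants are preserved) never feeds statistics.

The default ground truth plants the constant-shape coupling (deactivation
field correlated with modulation field at $\rho^* = 0.5$) but no
linear-shape coupling, so the A1 linear–linear regression in the analysis
scripts is a planted-null illustration.

## Problem sizes and numerical tolerances

The test suite validates the estimators at sizes chosen to keep the full
run in a few minutes on one CPU while leaving Monte-Carlo error well below
the asserted tolerances: $10^4$ random profiles against the shape-GLM
oracle; 200 AR(1) fits at 1200 samples (tolerance ±0.05 on $\hat\rho$);
2000 null step-down simulations at $n = 11$ (stage-1 rejection within
0.05 ± 0.01); 200 permuted-label decodings at 40 features (mean accuracy
within 0.5 ± 0.02); 100 planted-slope raster recoveries (±0.05 around the
planted 0.5) and 1000 null raster simulations with 5 subjects and 60
vertices (group-test rejection within 0.05 ± 0.01); exact sign-permutation
equality against brute-force enumeration for $n \le 10$. ROI sizes in the
analysis scripts (300/240 vertices) are an order of magnitude below real
surface meshes; all statistics used are either size-free or scale as
$\sqrt{n}$, so conclusions about calibration and unbiasedness transfer,
while absolute decoding accuracies do not (they rise with feature count
and are near ceiling here).

## Known limitations

* The flat-grid patch has no realistic folding geometry; equivolume depths
  are exercised through their 1D closed form only.
* Noise is spatially white across vertices; spatially correlated noise
  would widen the null distribution of raster slopes at small ROI sizes.
* The simulator's effect injection (additive, post-gain) is a convention;
  real crossmodal effects presumably also pass through the vascular gain,
  in which case measured shape parameters are gain-weighted versions of
  the neural ones.
* Absolute linear-term values depend on the unit-per-depth-step regressor
  scale; compare shapes only within this convention.
* The behavioural repeated-measures ANOVA and surface-based group
  registration of the original workflow are out of scope; scoring tables
  are produced, inference on them is delegated.
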