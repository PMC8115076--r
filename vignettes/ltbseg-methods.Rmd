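---
title: "Models and methods for luminance texture boundary segmentation"
author: "ltbseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for luminance texture boundary segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltbseg)
```

## The problem

Two adjacent surfaces can differ in mean luminance without any luminance step
at their border: one region simply contains more light texture elements and
the other more dark ones. We call such a border a *luminance texture boundary*
(LTB), as opposed to a *luminance step boundary* (LSB), where the luminance
changes abruptly at the border — the kind of edge a cast shadow produces.
Psychophysically, human observers classify the orientation of an LTB robustly
even when an LSB of conflicting orientation is superimposed, which a model
computing a single regional luminance difference cannot do. `ltbseg`
implements the full simulation-and-modelling pipeline for this problem:
parametric stimulus synthesis, image-computable observer models with one or
two stages of filtering, maximum-likelihood fitting with BIC model
comparison, and simulators for the adaptive-staircase and masking
experiments, with model-based simulated observers standing in for human
participants throughout.

## Stimuli

**Texture boundaries.** An LTB disc (`ltb_spec()`, `make_ltb()`) holds `n_p`
non-overlapping Gaussian micropatterns on each side of an oblique boundary
(default `n_p = 32`; 16 and 64 are the other densities studied). Each
micropattern is a Gaussian blob of SD `sigma_mp = 2` px truncated to a
circular footprint of radius `2 * sigma_mp = 4` px (an 8-pixel dot), with
peak amplitude `±A` about the mid-gray background 0.5. The proportion `pi_u`
of micropatterns on each side that lack a same-polarity partner on the other
side is the segmentation cue: `pi_u = 0` gives no boundary, `pi_u = 1` fully
segregated polarities. Because micropattern counts must be whole numbers and
are split over quadrants, `pi_u * n_p` must be a multiple of 4; requests are
snapped to the nearest feasible value and the snapped value recorded.

Three identities follow from the construction and are enforced by tests:

* the Michelson contrast is exactly `2 * A` (the extrema are `0.5 ± A`);
* the luminance difference across the *anti-diagonal* is exactly zero,
  because each polarity class is split equally between the two quadrants of
  each side, so the only luminance cue is the one across the boundary;
* the RMS contrast (SD/mean over the disc interior) is proportional to
  `A * sqrt(n_p)` and entirely independent of `pi_u` — with non-overlapping
  identical stamps the pixel-value multiset does not depend on the layout at
  all, so the invariance is exact rather than statistical.

**Placement.** Candidate centres are drawn uniformly within the eligible
region of each quadrant and rejected against an occupancy map marking a
radius-4 disc around every placed centre (10,000 attempts per pattern before
the density is declared infeasible). Centres keep a margin from both
diagonals large enough that no stamp pixel touches either diagonal, and stay
clear of the edge taper, so the balance identities above hold exactly for
every seed. Placement is driven by the spec's seed: the same spec and seed
give a bit-identical image.

**Disc geometry.** The original stimuli are 256×256 px discs subtending 4
degrees of visual angle; the disc radius and taper width are not part of the
published parameterization, so the package fixes them as defaults: radius
`image_size/2 - 4` (124 px at the default frame) with a raised-cosine taper
over the outer `image_size/16` (16) px. Pixels are the native unit
throughout; the degree mapping is metadata only. All geometry scales with
`image_size`, which lets simulations run on smaller frames (see *Problem
sizes* below).

**Step boundaries.** `make_lsb()` multiplies an oblique step edge of
Michelson contrast `c_m` about mid-gray by the cosine-tapered disc:
luminance `0.5 * (1 ± c_m * taper(r))` on the two halves. The 180-degree
phase stimulus is the 180-degree rotation of the 0-degree one.

**Composites.** `compose_stimulus()` adds the deviations from mid-gray of a
texture target and a step masker and clips to [0, 1], recording how many
pixels clipped (none at the contrast levels used here). The four masking
relations are `neu` (no masker), `con_0`/`con_180` (same orientation, equal
or opposite phase) and `inc` (orthogonal orientations).

## Features

`measure_features()` returns the three scalars the one-stage models consume:
`L_R` and `L_L`, the absolute differences between the mean luminances of the
two half-discs separated by the right- and left-oblique diagonal, and `C`,
the RMS contrast. Half-means (not sums) are used so the scale does not depend
on the frame size; any scale choice is absorbed by the model gain. `C` is
computed over the disc interior only — the constant background would dilute
it by an arbitrary factor. Pixels exactly on a diagonal belong to neither
half (the frame sizes used make the diagonal coordinates integer, so "on the
diagonal" is exact); this keeps the split symmetric and deterministic.

## Observer models

**Psychometric function.** For a stimulus level `x` (the cue magnitude:
`pi_u` for textures, `c_m` for steps), proportion correct follows a
signal-detection model with a power-law transducer,
`P_C = lambda/2 + (1 - lambda) * Phi((g x)^tau / 2)`,
with gain `g` (> 0, reciprocal level units), transducer exponent `tau` (> 0)
and lapse rate `lambda` in [0, 0.1]. The 75%-correct level defines the JND.
Thresholds are reported from the with-lapse fit by default, because
lapse-free fits can understate the slope when an observer occasionally
guesses at easy levels.

**One-stage model.** The image-computable one-stage model transduces the two
diagonal luminance differences and compares them:
`u = (g1 L_R)^p1 - (g1 L_L)^p1`, `P(R) = Phi(u)`. With divisive contrast
normalization both terms are divided by `1 + (g2 C)^tau2`. On stimuli whose
anti-diagonal difference is zero this coincides with the SDT model up to the
gain rescaling `g -> g / 2^(1/tau)`, a nesting the tests verify numerically.
On contrast-constant data the divisive term is absorbed into the gain, so
additive and divisive fits predict identically — which is why the divisive
variant is only fit where `C` varies.

**Two-stage model.** The filter–rectify–filter model first convolves the
image's deviations from mid-gray with ON and OFF difference-of-Gaussians
kernels, `h = c - rho_ie * s`, unit-peak isotropic Gaussians with
`sigma_c = 4` px (matched to the micropattern radius) and `sigma_s = 2
sigma_c`; the OFF kernel is the negated ON kernel. `rho_ie`, the
surround-to-centre amplitude ratio, is the single first-stage free parameter:
the kernel's DC response (its output to uniform light) decreases strictly in
`rho_ie` and crosses zero near 0.27 for the default support (the discrete
truncation sets the exact crossing; `dog_balanced_rho()` computes it). Each
channel is half-wave rectified and raised pointwise to the exponent `p1`,
then pooled uniformly over the two half-discs on each diagonal; the pooled
channel response is the absolute difference between the halves. The decision
variable applies the second-stage gain and exponent,
`u = (g2 L_R_ON)^p2 + (g2 L_R_OFF)^p2 - (g2 L_L_ON)^p2 - (g2 L_L_OFF)^p2`,
and `P(R) = Phi(u)`. Four free parameters: `rho_ie, p1, p2, g2`.

Two readings of "rectified, with exponent `p1`" are defensible: rectify each
pixel and exponentiate before pooling (the default, `rectify_pool`), or pool
the linear output first and rectify the signed half-disc difference
(`pool_rectify`). Both are implemented and switchable; the default makes the
first-stage nonlinearity act locally, which is what a cascade of neural
filters would do, and reduces to intuitive behaviour at `p1 = 1`.

Convolution uses zero padding, and pooling is restricted to the disc interior
eroded by the kernel half-width (default 16 px), so padding artifacts and the
edge taper never enter the pools. A DC-balanced first stage makes the model
provably invariant to uniform luminance offsets, which the tests check at
machine precision.

## Fitting

All models are fit by maximum likelihood: binomial per level for the
psychometric function, Bernoulli per trial for the image-computable models
(the two differ only by a parameter-free constant). Probabilities are clamped
to `[1e-9, 1 - 1e-9]` to keep log-likelihoods finite. Optimization is
bounded quasi-Newton (L-BFGS-B) in log-parameter space from a grid of start
points — gains scaled to the data, exponents {0.5, 1, 2}, and for the
two-stage model `g2` in five log steps from 1e-3 to 10 — keeping the best
optimum; bounds are `g in [1e-6, 1e4]` (wider for `g1`, whose natural scale
is the reciprocal of a small luminance difference), exponents in `[0.1, 10]`,
`lambda in [0, 0.1]`.

For the two-stage model the stimuli are pre-filtered once per candidate
`rho_ie` on the grid 0.10–0.40 in steps of 0.05; the per-trial half-disc
convolution values are cached so the pooled responses for any `p1` come from
one vectorized pass. `(p2, g2)` are optimized from their start grid inside a
profile over `p1` (grid values then golden-section refinement), and the best
`rho_ie` is chosen by profiled likelihood. If the optimum lands on an end of
the grid, the grid is extended one step at a time (down to 0, up to a
configurable maximum) until the optimum is interior — the same rule the
original analysis needed for its least-surround observers.

Model comparison uses `BIC = logL - (K/2) ln n` (larger is better;
exponentiating a difference gives the posterior odds). `bootstrap_pf()`
implements the parametric bootstrap: each resample redraws every level's
correct count from a binomial at the observed proportion, refits, and
percentile 95% intervals are formed for the parameters and the JND; B = 200
resamples by default, matching the original figure legends. Degenerate
resamples (all correct or all incorrect) are counted and skipped rather than
silently fit.

## Experiment simulators

`run_staircase()` implements the standard 1-up-2-down rule on a discrete
level ladder: start at the top, move up one ladder index after any error,
down one index after two consecutive correct responses, clip at the ends;
true orientation and luminance phase are randomized each trial. The rule
concentrates trials at the level with true proportion correct `2^(-1/2)`
(70.71%). Thresholds from staircase data are obtained by fitting the
psychometric function to all trials (`jnd_from_trials()`); averaging
reversal levels (`reversal_level()`) is used for the convergence check only,
averaging an even number of post-burn-in reversals so peaks and valleys
balance. The level ladders are the experimental ones: nine even `pi_u` steps
from 0 to 1, and eleven log-spaced contrasts from `10^-2.7` to `10^-1.7`.
One ladder index per move is assumed; the original step size in level units
is not stated.

`masking_design()` + `build_masking_stimuli()` + `simulate_responses()`
implement the constant-stimuli masking experiment: per block, 200 neutral
trials, 100 phase-aligned plus 100 opposite-phase congruent trials, and 200
incongruent trials, orientations balanced within condition to within one
trial, texture at its 75% JND level and masker at a matched contrast. The
variant in which the masker JND is measured in the presence of an
uninformative (`pi_u = 0`) texture is available as a flag on `lsb_jnd()`.
`calibrate_gain()` rescales an observer's gain so its deterministic mean
accuracy over the neutral stimuli hits the 75% design target — the
simulation analogue of presenting each cue at the observer's JND.

Condition-level statistics use the Pearson chi-squared homogeneity test on
correct/incorrect counts without continuity correction — the variant that
reproduces the published pooled statistics exactly from the published
proportions — and Wilson score intervals for binomial proportions
(Clopper–Pearson available by flag; the published analysis does not name its
method).

## What the simulations do and do not show

The synthetic generator reproduces the *parametric* structure of the original
stimuli: micropattern counts, amplitudes, proportions, the step taper, and
the masking relations. Simulated observers are the package's models
themselves, so experiments on them demonstrate self-consistency (parameter
recovery, model identifiability, the qualitative masking signatures), not
facts about human vision: no human data are redistributed with the package,
and published human thresholds are not reproduction targets. What the
simulations *do* establish is that the analysis pipeline distinguishes the
models where the original study says they differ — a one-stage observer
collapses to chance under incongruent maskers while a two-stage observer
does not, an effect large enough that BIC model comparison recovers the
generating architecture from a few hundred trials.

## Problem sizes and numerical choices

Tests and example analyses run the image-heavy simulations on 128-px frames
(same micropattern size and kernel, half the linear frame size), where the
per-stimulus cue magnitudes are larger but all qualitative relations are
unchanged; stimulus-identity checks run at the full 256-px default.
Staircase convergence is measured with a 30,000-trial run on a 100-step
ladder. Two-stage fits in the test-suite recovery study use 600 trials (the
full masking design) and the full `rho_ie` grid; the model-selection
replicates use ~200 trials and a three-point grid, which is already enough
for decisive BIC differences. The fit convergence tolerance is the L-BFGS-B
default (~1e-8 on the objective); ties in the `rho_ie` profile resolve to
the first maximum. Degenerate inputs — single-level data, all-correct data,
empty masks, infeasible densities, unreachable calibration targets — raise
informative errors rather than returning silently wrong numbers.

## Limitations

The models are deliberately minimal: isotropic center-surround first-stage
filters at a single scale (no oriented or multi-scale banks), uniform
half-disc second-stage pooling, and no temporal dynamics, eccentricity
dependence or attention effects. The disc radius, taper width and the exact
DC-balance point depend on discretization choices the original publication
does not pin down; they are configurable, and the defaults are documented
above. Simulated observers respond independently across trials — no learning,
fatigue or sequential dependencies — so staircase dynamics are cleaner than a
human session would be.
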