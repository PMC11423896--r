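---
title: "Methods: planted selectivity, localization, lesioning, and encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planted selectivity, localization, lesioning, and encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the choices
behind them: what the synthetic worlds state, what the statistical
procedures assume, which knobs matter, and what a green test suite does and
does not establish.

## The scientific question

In high-level visual cortex, small populations respond selectively to
faces, bodies, scenes, or written words. The same organization emerges in
deep feature hierarchies, which makes three analyses possible *in silico*
that are hard or impossible in a brain: exhaustive localization of
selective units, clean causal lesions with downstream recomputation, and
encoding models linking unit populations to measured voxel responses.
`selunit` implements all three against simulated systems whose ground
truth is stored, so that recovery — not plausibility — is the test.

## The stimulus world

`generate_stimulus_set()` draws, for each template category k, a unit-norm
template t_k from a random orthonormal frame in `input_dim` = 64
dimensions, and builds each stimulus as

x = c · t_k + σ_w · z,  z ~ N(0, I/d),

so `sigma_w` (default 0.2) is approximately the norm of the
within-category jitter and `category_signal` c (default 0.075) the
template coefficient. A "scrambled" category is pure jitter with no
template and enters only the localizer and probe splits. The probe split
re-draws jitter at its own width (default 0.3), standing in for a
distribution-shifted probe image set.

The default c was calibrated a priori from two opposing constraints, and
then frozen:

* per-category mean features must correlate strongly (> 0.8) with their
  template for 20 localizer stimuli per category — the correlation is
  approximately c / sqrt(c² + σ_w²/n), pushing c up;
* units with *random* weights must behave nearly as null under the
  localizer's t contrast, so that planted selectivity is recoverable
  against ground truth — a random unit's between-category t has spread
  ≈ c·√n/σ_w (≈ 1.7 at the defaults), pushing c down.

Eight template categories are the default (face, body, scene, word,
object, tool, animal, vehicle): a desk-scale category set large enough for
per-category recognition analyses with k = 1, and more contrast categories
also make the localizer's all-contrast intersection harder to pass by
chance.

At `sigma_w = 0` every stimulus of a category equals c·t_k exactly — the
zero-jitter limit collapses each category onto its (scaled) template.

## The planted model

`build_planted_model()` constructs a rectified linear hierarchy (default
3 layers × 200 units) in which a fraction ρ (default 0.05) of each layer's
units per domain is *planted*: its weight row is a background-distributed
random row plus g times a calibrated direction, with a bias that cancels
the projection of the mean non-preferred calibration response, so the unit
rests near zero for non-preferred input. g (default 4) is the single
selectivity-strength dial; at g = 0 the construction reduces exactly to
the background distribution, which is what makes the null-calibration
experiment meaningful.

Three construction details matter and were chosen deliberately:

* **Centered calibration direction.** The planted direction is the
  domain's mean previous-layer response minus the grand mean, normalized.
  The uncentered mean points mostly along the layer's shared baseline at
  depth; using it starves deep planted units of contrast and makes
  whole-domain recovery collapse stochastically.
* **Modular random fabric.** Every unit's random weight component is zero
  on the previous layer's planted units (remaining entries rescaled to
  preserve variance). Without this, randomly wired downstream units
  genuinely inherit category preference from the strong planted channels,
  and "precision against the planted mask" stops being a meaningful
  quantity — the masks would no longer exhaust the truly selective units.
  Selectivity still propagates in depth, but only through the calibrated
  component of deeper planted units.
* **Within-domain tuning diversity.** Each planted unit's direction is
  `normalize(dir + κ·ξ_i)` with its own random ξ_i (κ = `tuning_jitter`,
  default 1). Real selective units share a category preference but differ
  in sub-tuning; with κ = 0 a domain's planted units are clones, every
  voxel built from them is indistinguishable from every other, and sparse
  source recovery is mathematically ill-posed.

Planted rows and biases are rescaled by 1/sqrt(1+g²) so planted output
*magnitudes* match background units; t statistics are invariant to this,
but downstream mixing is not.

## Localization

`contrast_tmap()` is the classic pooled-variance (Student) two-sample t
per unit; `bh_fdr_mask()` the Benjamini–Hochberg step-up at q = 0.05
applied per (layer, contrast); `localize_selective_units()` intersects:
selective means passing FDR with t > 0 against *every* non-preferred
contrast category. Pre- and post-rectification stages are treated as
distinct computational stages and localized separately (post is the
default and the stage all downstream analyses use). The 2:1 ratio variant
(`ratio_localize()`) is defined on post-rectification stages only, with
the denominator floored at 1e-8 and units with zero preferred mean never
selected.

Two aggregation choices are deliberately simple and configurable in
principle: the per-domain "mean unit t" averages a selected unit's
pairwise-contrast t values, and FDR is scoped per (layer, contrast) rather
than pooled — matching the per-contrast thresholding-then-intersection
reading of the procedure.

**What FDR calibration means here.** The calibration experiment (100
seeds, 2000 units) runs at g = 0 *and* `category_signal = 0`. Both are
necessary: with structured stimuli every randomly weighted unit has a
real, if weak, category preference, so flagged units are true — not
false — discoveries, and no FDR bound applies. Only when category labels
carry no signal is the per-unit null true and the ≤ q bound testable.

## Readout and lesioning

The readout is a multinomial linear head on frozen features trained by
plain minibatch SGD with a proximal (soft-threshold) L1 step — reference
hyperparameters λ = 1e-5, 10 epochs, batch 512, one-cycle schedule with
max_lr = 0.05, initial_lr = 0.001, pct_start = 0.3. The one-cycle anneal
shape is not fully specified by those three numbers; the implementation
ramps initial→max with a cosine over the first pct_start of steps and
anneals max→initial/100 with a cosine thereafter. The desk-scale defaults
in `default_pipeline_config()` (150 epochs, batch 64, max_lr = 10) differ
because learning rates tuned for large networks' feature scales underfit
badly on features two orders of magnitude smaller; the schedule's shape is
unchanged.

Lesions zero a chosen unit set's post-rectification outputs during the
forward pass, with all downstream activations recomputed and no
retraining. Cost profiles store (baseline − lesioned) top-k accuracy in
percentage points, so deficits are positive; the activation–cost
correlation is computed against (lesioned − baseline), preserving the
convention that a *negative* correlation means the categories a unit
group responds to most are the ones its loss hurts most. Top-k score ties
break by ascending category index; cross-validation halves are stratified
by category and seeded, with the larger half used for identification when
counts are odd.

**Random-lesion nulls at desk scale.** Size-matched random unit draws are
the control for the activation–cost relation. In this planted world 20% of
every layer is planted (4 domains × ρ = 0.05), so a random draw usually
contains a few genuinely selective units, and its activation–cost
correlation is attenuated toward zero rather than exactly zero (typically
≈ −0.3 against ≈ −0.9 for domain lesions). The meaningful statement — and
the one the tests assert — is the paired comparison: random draws sit far
closer to zero than domain-targeted lesions. An exact zero would only be
expected in a regime with many categories and a small selective fraction.

## Voxel simulation and encoding

A simulated voxel of ROI domain d mixes s = 5 of that domain's true
selective units in one layer with Exp(1)-distributed non-negative weights;
the noiseless signal is standardized to unit variance across stimuli so
the trial noise SD is interpretable on the signal scale (default
`noise_sd = 1`, i.e. single-trial NCSNR ≈ 1; recovery experiments use
0.2). Each stimulus is presented 3 times; trials are shuffled (so repeats
cross sessions) and cut into contiguous sessions, each applying a
multiplicative lognormal(0, 0.2) gain and additive N(0, 0.5) offset —
the minimal session structure that makes per-session z-scoring
non-trivial. These noise parameters are chosen for testability; the
within-category response variance of real ROI data is not characterized
by the source material.

Preparation mirrors the standard large-scale pipeline: per-voxel
per-session z-scoring (exact zero mean, unit sample SD; zero-variance
cells flagged and left at 0), repeat averaging, and NCSNR filtering.
NCSNR decomposes the single-trial variance into noise (mean across-repeat
unbiased variance) and signal (total minus noise, floored at 0) and keeps
voxels with signal-SD/noise-SD strictly above 0.3.

The encoding model is the package's own cyclic coordinate descent for

min (1/2n)·‖y − Xw − c‖² + α·Σ wⱼ  subject to w ≥ 0,

with an unpenalized, unconstrained intercept (an explicit decision; the
intercept's treatment is otherwise unspecified) and KKT-based convergence
at tolerance 1e-6. Tests verify it against a dense grid-search oracle on
small problems and against `glmnet` (lower.limits = 0) on larger ones.
The reference α is 0.1; the desk-scale pipeline default is 1e-3 because α
trades off against the design's activation scale, and ground-truth
recovery selects α on a small grid {1e-4, 3e-4, 1e-3} by validation MSE.

Evaluation computes the ROI-mean univariate correlation (the ROI mean of
per-voxel predictions is correlated with the measured ROI mean — the
alternative ordering is a documented switch-in-principle) and veRSA (RDM
lower-triangle correlation on the same voxel set for both sides).
Best-layer selection is an argmax on validation metrics per metric, ties
to the shallower layer, with final numbers from the held-out test split.
A constant prediction — e.g. when positivity drives all weights to zero
for a mismatched unit subset — is scored 0 and flagged, not NA: no
predictive power, not an undefined experiment.

Noise ceilings are Monte-Carlo: draw a noiseless profile (or pattern set)
from the signal spec, add noise averaged over n_rep repeats, correlate,
and average over ≥ 100 simulations. In the synthetic regime the signal
and noise SDs are the generator's true parameters; otherwise the
per-voxel moment estimates from repeats stand in. This is a deliberately
simple substitute for generative noise-ceiling modeling, preserving the
simulation logic without re-implementing a separate method.

The Gabor baseline pools quadrature-pair energy (one-sided Gaussian
frequency-domain bumps; modulus of the inverse FFT) over a 16 × 16 grid
at four scales with 12/8/6/4 orientations — 7680 features at the published
configuration. Wavelengths descend in octave steps (4, 8, 16, 32 px) and
the bandwidth is half the center frequency; these parameters are
unspecified upstream and exposed as arguments. Gist-PC features are the
first 50 centered principal components of that matrix.

## Geometry

`meta_rdm_trajectories()` reduces each layer's probe activations to 10
principal components (sign-fixed: the largest-magnitude loading of each
component is forced positive, so embeddings are bitwise reproducible),
stacks layers, computes the Pearson-dissimilarity meta-RDM, and embeds it
with *classical* (Torgerson) MDS — chosen over stress majorization for
determinism; only determinism, not exact reproduction of any published
figure, is claimed. `pc_projection_map()` projects probe stimuli into a
2-component PCA of reference activations and draws each domain's 25 most
selective units (by mean contrast t) as arrows: the unit's one-hot vector
through the component matrix, times a constant 2.5e4 that changes lengths
but never angles.

Emergent separation — the deepest layer separating categories more than
the first — requires the selective fraction to grow with depth (ρ =
0.02/0.05/0.10 in the emergence world), which is also the depth trend the
motivating systems show. In the uniform-ρ default world the effect is
present but weak and not monotone in every seed.

## What a green suite establishes — and what it does not

The tests establish that *on these stated worlds* the localizer is
FDR-calibrated under the null and recovers planted selectivity at g = 4;
that lesions dissociate causally with activation-predictable costs; that
non-negative sparse encoding recovers true sources, prefers
matched-selectivity subsets, and finds the generating layer; and that the
geometry pipeline detects emergent separation. They do not establish
anything about trained networks or real fMRI data: the synthetic worlds
have near-orthogonal category templates, Gaussian jitter, affine session
artifacts, and planted units whose selectivity is constructed rather than
learned. Known further limitations: convolutional weight sharing is not
modeled (units are fully connected; "different spatial positions as
different units" is honored trivially), recognition readout at desk scale
uses k = 1 over 8 categories rather than top-5 over 1000, and the
random-lesion null is attenuated rather than exactly zero for the reason
given above.
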