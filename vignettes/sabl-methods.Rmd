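---
title: "Quantifying specific amyloid load by nonspecific-uptake subtraction: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying specific amyloid load by nonspecific-uptake subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantification problem

Amyloid-PET tracers bind specifically to cortical amyloid-beta plaques and
nonspecifically to myelin, which makes white matter (WM) the brightest
structure in an amyloid scan of an amyloid-negative brain. The conventional
biomarker, the standardized uptake value ratio (SUVr; tracer uptake divided
by the mean uptake of an amyloid-free reference region, here a cerebellar
grey-matter analogue), therefore mixes two signals inside cortical grey
matter (GM): true plaque binding and a nonspecific (NS) myelin component
aggravated by point-spread spill-over from adjacent WM. The NS component
varies between subjects -- globally with myelin content and diffuse
cerebrovascular disease (CeVD), and locally inside WM hyperintensities
(WMH), lacunes and cortical infarcts, which all reduce it. SUVr
consequently inherits a CeVD-driven variance component that has nothing to
do with amyloid.

`sabl` implements a subtraction-based alternative: estimate each subject's
NS uptake map from structural MRI (T1-weighted and T2-FLAIR carry the
myelin and lesion information), subtract it voxel-wise from the SUVr image
in native space, and average the difference over cortical GM. The scalar
result is the specific amyloid load, SAbL. Two comparison biomarkers are
included: the global SUVr (GM mean of the SUVr image) and the two-template
amyloid load AbL, obtained by ordinary least squares of the SUVr image on
an NS template and an amyloid-deposition template derived from a
cross-sectional pool by principal component analysis.

## Pipeline overview

```{r}
library(sabl)

cohort <- generate_cohort(40, phantom_config(p_high = 0, burden_low_sd = 0), seed = 1)
sg     <- vapply(cohort$subjects, function(s) roi_mean(s$volumes$pet, s$volumes$masks$gm), numeric(1))
pool   <- select_training_set(sg, 40)            # lowest-SUVr subjects: mostly NS
split  <- split_train_eval(pool, 6, seed = 2)    # 34 train / 6 held out
pairs  <- lapply(split$train, function(i)
  list(volumes = cohort$subjects[[i]]$volumes,
       target  = cohort$subjects[[i]]$volumes$pet))
model  <- train_translator(pairs, translator_config())
ns     <- predict_ns(model, cohort$subjects[[split$eval[1]]]$volumes)
```

The training pool is assembled by the lowest-SUVr rule: scans with the
smallest global SUVr carry little specific binding, so their SUVr images
are usable as NS targets. The evaluation subjects are never seen during
training.

## The synthetic phantom cohort

No imaging data ship with the package; every stage is exercised on
simulated cohorts whose ground truth is known exactly.

**Anatomy.** Nested, smoothly perturbed ellipsoidal shells on a 48^3 grid
at 2 mm isotropic voxels (the default; 32^3 is used for fast unit tests):
a CSF rind, a cortical GM shell, a WM core with ventricles and two deep-GM
nuclei, and a spatially separate cerebellar compartment whose GM shell
serves as the amyloid-free reference region. The atrophy grade thins the
cortical shell monotonically, reproducing the geometry-driven aggravation
of WM-to-GM spill-over.

**Nonspecific uptake.** A WM-dominant tissue profile (WM 1.35, cortical GM
0.55, deep GM 0.70, CSF 0.12 in SUVr-like units, cerebellar GM/WM
0.55/1.30). A per-subject myelin scale multiplies the supratentorial
parenchyma only; the cerebellar reference keeps unit scale. This asymmetry
is deliberate: a factor applied to *all* tissues, reference included, would
cancel exactly under SUVr normalization, and inter-subject NS variability
-- the phenomenon the method exists to remove -- could not exist in SUVr
space. The scale is drawn as N(1, 0.06), truncated to [0.8, 1.2], minus a
diffuse CeVD term 0.15 x severity with severity ~ U(0, 1). The resulting
spread of low-burden GM SUVr (roughly 0.85-1.25) matches the spread a
lowest-SUVr training pool exhibits in practice. Spherical lesions (WMH in
WM, lacunes in WM/deep GM, cortical infarcts in cortical GM, microbleeds
anywhere in parenchyma; Poisson counts proportional to severity) reduce NS
locally by a configurable factor, 0.5 by default -- the magnitude of the
intra-lesion NS reduction is a free parameter of the generator, exposed in
the configuration, since it is direction, not size, that is established.

**Specific uptake.** Burden x a smooth positive cortical deposition
pattern (mean 1 over cortical GM), zero outside cortical GM and therefore
zero in the reference region. Burden follows a 70/30 low/high mixture:
half-normal(0, 0.05) versus N(0.8, 0.25) truncated at 0.2, emulating a
mixed amyloid-negative/positive memory-clinic cohort.

**Observation model.** PET: Gaussian point-spread blur (FWHM 6 mm,
typical clinical amyloid-PET resolution) of NS + specific uptake, additive
Gaussian noise (SD 0.04 pre-normalization), then division by the
reference-region mean of that blurred noisy image -- so the reference mean
of the simulated SUVr image is exactly 1. MRI: tissue-mean images with
lesion-specific contrast (WMH: T1-dark, strongly FLAIR-bright; lacunes and
infarcts: dark in both; microbleeds: small dark foci), light resolution
smoothing, a smooth multiplicative bias field (amplitude 0.05) and
Gaussian noise (SD 0.02).

**MRI-myelin coupling.** Cerebral-WM MRI intensity is tied to the same
myelin scale that drives NS binding: T1 rises with myelin (factor
1 + 0.7(s - 1)) and FLAIR falls steeply (factor 1 - 1.2(s - 1)). The
strong FLAIR response mirrors the clinical appearance of severe diffuse
myelin injury (FLAIR hyperintense, as in confluent WMH) and serves an
identifiability requirement: at every myelin level the joint (T1, FLAIR)
WM signature remains distinguishable from cortical GM. A weaker coupling
can place WM on top of GM in both channels at once, at which point no
method could recover the WM condition from MRI -- a degenerate phantom,
not a realistic difficulty. The premise under test is precisely that
structural MRI carries the myelin and lesion information.

**Covariates.** Cognition = 28 - 5 x burden - 0.25 x total lesion count +
N(0, 1.2); atrophy = 0.12 + 0.25 x burden + 0.15 x severity + N(0, 0.06)
(clamped to [0, 1], and fed back into the anatomy); hippocampal volume =
4.0 - 1.0 x burden + N(0, 0.3) mL. Burden and CeVD severity are drawn
independently, so any association between SAbL and lesion counts would be
spurious by construction, while SUVr acquires a genuine lesion-count
association through the diffuse CeVD -> NS -> SUVr path. This reproduces,
qualitatively, the reported association structure of the biomarkers
(SUVr confounded by CeVD, the subtraction-based marker not).

**What the phantom does not emulate.** MR sequence physics, skull and
scalp, registration error, motion, Poisson projection-space PET noise,
and realistic cortical folding are all absent; cortical thickness (about
8 mm here) is exaggerated relative to real cortex. Passing tests
demonstrate that the pipeline recovers what the generator planted under a
known forward model -- they do not certify performance on real scans.

All randomness derives from one seed via a documented splitting scheme
(`derive_seed`); identical (configuration, seed) reproduce cohorts
bit-identically.

## The MRI-to-NS translation model

A small multi-scale 3D convolutional regression network stands in for the
full-scale published image-translation architectures (explicitly out of
scope): `n_levels` parallel branches at dyadically downsampled resolutions
(default 2), each a stack of `n_hidden + 2` 3x3x3 convolutions (default 3:
in -> 8 -> 8 -> 1) with ReLU activations and a linear single-channel
output, fused by summation after nearest-neighbour upsampling. Input
channels are the configured modalities (multimodal T1 + FLAIR by default),
each divided by its brain-mask mean, plus one Gaussian-smoothed context
channel per modality (sigma 3 voxels, mask-normalized convolution).

Two design choices deserve their rationale:

* **Mean normalization rather than z-scoring.** Per-volume z-scoring
  divides by the brain SD, which itself grows with tissue contrast -- it
  removes most of the very signal (contrast magnitude) that encodes the
  subject's myelin level. Dividing by the brain mean preserves contrast
  ratios. Z-scoring remains available as an option.
* **A global contrast gate.** The mean GM uptake to be predicted is, to
  first order, a per-subject global scale times an anatomy-driven pattern.
  Plain additive convolutions approximate such product structure very
  slowly. Each branch therefore carries a squeeze-and-excitation style
  gate: per-channel means and SDs of the full-volume input (after mean
  normalization the SDs measure tissue contrast), standardized across the
  training cohort so the between-subject variation is unit-scale, feed a
  small tanh layer whose scalar output multiplies the branch prediction.
  The gate initializes to the identity.
* **A global calibration head.** Even with the gate, a small network
  trained for a few hundred desk-scale epochs recovers the global uptake
  level only partially, leaving a subject-level offset. Analyses of such
  translation models have noted exactly this failure mode -- a global
  offset on the estimates that can in principle be deduced and removed.
  Here the offset is predicted from MRI rather than assumed constant: a
  ridge regression (lambda 0.1, fit on the training pairs only) maps
  tissue-resolved global statistics of the normalized inputs (WM / GM /
  reference means, whole-brain moments and quantiles, eroded-WM mean,
  log contrast ratios) plus gross shape features (GM and WM volume
  fractions, a WM FLAIR-hyperintensity fraction as lesion-load proxy) to
  the log mean target uptake over cortical GM. At inference the
  translated map is rescaled so its GM mean matches the predicted level.
  The head uses MRI-derived features only -- the subject's PET is never
  touched -- and all of its inputs come through the same parcellation
  masks the surrounding pipeline already requires.

Training minimizes voxel-wise MSE inside the brain mask with Adam
(learning rate 3e-3 by default, step decay 0.3 at 60% and 85% of the
schedule) on random cubic patches (24^3 by default) with the loss
restricted to the patch interior, the standard regime for fully
convolutional 3D networks; inference runs on the full grid. Targets stay
in SUVr units. Negative predictions are clamped to zero at inference.
Training is single-threaded and bit-deterministic given (data, seed);
divergence (non-finite loss) aborts with the offending epoch. The
convolution kernels (im2col plus BLAS products, in compiled code) are
validated against a brute-force direct convolution and by central finite
differences through the full network including the gate.

## Biomarkers

* `compute_suvr`: division by the reference-region mean; the reference
  mean of the result is 1 by construction (tested to 1e-6).
* `compute_sabl`: voxel-wise subtraction of the NS estimate from the SUVr
  image in native space; SAbL is the mean of the difference over cortical
  GM. Locally negative voxels are retained -- SAbL is a mean, and clipping
  would bias it upward; no partial-volume correction is attempted.
* `build_templates` / `fit_abl`: the NS template is the voxel-wise mean of
  the lowest-global-SUVr half of the pool; the deposition template is the
  first principal axis of the mean-centered pool within the fit mask,
  sign-oriented to a positive cortical-GM mean. The exact PCA pipeline of
  the prior template-based method is not restated in the underlying
  description, so this deterministic, testable construction is a
  documented stand-in. The fit is ordinary least squares without
  intercept, on the common phantom grid standing in for a standardized
  template space (inputs share a grid by construction; no spatial
  normalization is implemented). AbL is invariant to adding any multiple
  of the NS template to the input (only the ns coefficient shifts).

## Evaluation metrics

Four mask-restricted scalar metrics compare an estimate X with a ground
truth Y: MSE; a single global SSIM statistic
(2 mx my + c1)(2 cov + c2) / ((mx^2 + my^2 + c1)(vx + vy + c2)) with
c1 = (0.01 L)^2, c2 = (0.03 L)^2 -- computed over the whole masked region
with no sliding window, the literal reading of the defining equation, with
L defaulting to the pooled dynamic range; the signed mean relative error
MRE = 100 (mean Y - mean X) / mean Y, whose cohort summary is the mean of
absolute values; and the histogram intersection over 64 shared bins
spanning the pooled range (the bin count is not prescribed anywhere; 64 is
stable for the 10^4-10^5 voxel masks used here, and configurable).
Identical inputs give exactly (0, 1, 0, 1); two all-identical inputs have
histogram intersection 1 by convention. Region-wise reports cover whole
brain, cortical GM, WM and the reference region, with the WM mask eroded
(6-connectivity, 2 iterations by default) to avoid contamination by
specific GM uptake at the boundary.

## Association analysis

Spearman correlations (mid-ranks, two-sided t-approximation p values --
adequate at the 10^2 cohort sizes targeted here; an exact permutation
option exists for n <= 12) between the biomarkers (SUVr, SAbL, AbL, the
GM-mean NS estimate) and covariates (cognition, atrophy, hippocampal
volume, lesion counts, WMH volume), with significance markers at p < 0.1
(.), 0.05 (*), 0.01 (**), 0.001 (***). Association improvements are
reported as percent change of |rho|, since improvements occur on
positive and negative associations alike. Missing covariates are handled
by pairwise deletion.

## Problem sizes and determinism

The bundled analyses use desk-scale sizes chosen as package defaults: the
NS-accuracy evaluation trains the default translator on 34 of 40
zero-burden 48^3 phantoms and evaluates on the 6 held out; the biomarker
association analysis uses a 200-subject cohort with the oracle (generator)
NS map, which validates the analysis design independently of model
training; the demonstration pipeline (`demo_config()`) runs 40 phantoms on
a 32^3 grid with a tiny translator in about a minute. Re-running any stage
with the same configuration and seed reproduces its CSV outputs
byte-for-byte.

## Known limitations

* The translator is a deliberately small analogue of the published
  networks; its absolute accuracy figures are meaningful only under the
  phantom's forward model.
* Global SUVr pools voxels over one cortical GM mask (whether the original
  analysis averaged region means over AD-specific regions or pooled voxels
  is not stated; pooling is the documented choice here).
* The two-template model shares the phantom grid instead of a nonlinear
  standardized space; template-space misregistration effects are therefore
  outside the phantom's reach.
* CeVD severity enters NS through a single diffuse slope plus local
  lesions; real CeVD is heterogeneous in both.
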