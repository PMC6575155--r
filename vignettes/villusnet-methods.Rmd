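---
title: "villusnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{villusnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package does

`villusnet` implements a small, fully specified image-analysis pipeline for
three-class duodenal biopsy classification — healthy control, celiac disease
(CD) and environmental enteropathy (EE) — together with the downstream
analyses that make the classifier interpretable: tracing the strongest
feature-map activations back to source-pixel segments, testing which filters
fire class-specifically, and correlating noninvasive biomarkers with the
network's activation patterns through sparse linear models.

Real slide cohorts for this problem are not publicly deposited, so the
package ships a seeded synthetic-cohort generator with the statistical
structure the pipeline assumes. Everything downstream is exercised and
tested against those synthetic cohorts; the package makes no claim of
reproducing any clinical accuracy figure.

## The classifier

The network is a compact AlexNet-style stack chosen for small cohorts:

* four convolution layers with 16, 32, 32 and 32 feature maps and square
  kernels of side 5, 5, 5 and 3; stride 1; zero padding preserves the
  spatial size ("same" convolution);
* each convolution is followed by a rectified linear unit and a max-pooling
  layer with windows 2, 4, 5 and 5;
* one fully connected layer of 1024 units with dropout 0.5, then a softmax
  over the three classes.

**Pooling stride.** The pools use stride equal to their window. This is the
only convention under which the architecture's documented shapes hold
(1000 → 500 → 125 → 25 → 5 through the four pools; a 25×25×32 grid after the
fourth convolution; a flattened fan-in of 5·5·32 = 800), so the package
fixes it and `layerShapes()` exposes the arithmetic. The input side must be
divisible by the product of the pool windows (200); tests and the synthetic
study use 200×200 inputs, for which the fourth convolution grid is 5×5 and
the fan-in is 32.

**Training.** The loss is softmax cross-entropy, implied by the probability
read-out. Optimizer settings are not dictated by the architecture, so the
package defaults are explicit choices: adaptive-moment gradient descent
(Adam) with learning rate 1e-3, minibatch 32, 20 epochs — a deliberately
short schedule that limits overfitting on cohorts of tens of cases. Weights
use scaled-normal initialisation with variance 2/fan-in, appropriate for
rectified layers. The engine (Rcpp/RcppArmadillo, im2col + GEMM) trains in
single precision for speed and exposes a double-precision path used by the
gradient-check tests, which require numerical-vs-analytic agreement to
1e-4 relative error on a reduced four-layer configuration. Runs are
deterministic for a fixed seed on fixed hardware and thread settings; the
shuffle and dropout streams use a self-contained generator so results do
not depend on the C++ library's distribution implementations.

**Aggregation.** Patch probabilities live on the 3-simplex; image-level
probabilities are the arithmetic mean of the fixed 15-patch test layout
(centre + four corners, each with horizontal and vertical reflections), and
case-level probabilities the mean over the case's images. Means of simplex
points stay on the simplex, so no renormalisation is applied. Argmax ties
break towards the earlier class in the fixed order (control, CD, EE) —
deliberately conservative for disease screening. When an image equals the
patch size the 15 patches collapse to 3 distinct pixel grids; the
implementation forwards unique grids once and weights by multiplicity,
which is exact.

## Image preparation

Slides are tiled into non-overlapping 1360×1024 frames, row-major; partial
border strips are discarded because the network needs fixed-size inputs.
Training patches are sampled uniformly at random (ten 1000×1000 patches per
image by default) and emitted with their horizontal and vertical
reflections — a factor-30 augmentation per image. Test patches are the
deterministic 15-patch layout above; the centre offset uses floor division
(the convention is unobservable one pixel either way). Gamma correction
`out = round(255·(in/255)^γ)` with γ drawn uniformly from [0.5, 2.0] is the
recommended colour augmentation; contrast-limited adaptive histogram
equalization (via EBImage, applied to the luminance channel) is available
but off by default, as gamma alone performed best in the source protocol.
Gamma is drawn per patch rather than per image to maximise augmentation
diversity; no colour augmentation is applied at test time.

## Evaluation

Cross-validation is case-preserving: folds partition *cases*, stratified by
class (round-robin after a seeded shuffle, so per-class fold sizes differ by
at most one), and all of a case's images share its fold. Accuracy is
reported per image (each image judged individually from its 15-patch mean)
and per case (after probability averaging). The false-negative rate is
defined for screening: diseased cases (CD or EE) predicted as control,
divided by diseased cases; an all-cases denominator is available via
`fnDenominator = "all"`.

The intercountry transfer protocol trains, for `n` cases of the class of
interest at site A, `n` leave-one-case-out models (each with a seeded random
allocation of control/CD cases) and evaluates each on all site-B cases,
yielding a 2×`n` table of per-image and per-case accuracies. A named subset
of site-A cases can additionally be trained as one extra model (for probing
which cases carry the transferable signal). The random allocations are
recorded on the result.

## Activation traceback

The "deconvolution" here is deliberately minimal: only the highest
activation of each final-layer feature map is traced back, not a full
transposed-convolution reconstruction. `receptiveFieldBox()` implements the
standard recurrence — field size grows by `(kernel−1)·jump` per convolution
and `(window−1)·jump` per pool, and the jump multiplies by each pool window
— giving a 164-pixel field with a 40-pixel jump at the fourth convolution
of the default architecture. The exported segment crops default to side
142, the segment size conventionally reported for this architecture; the
two numbers cannot be reconciled under any standard stride convention, so
the package reproduces the 142-pixel artifact while exposing the analytic
field size on every record. Peak ties break to the smallest row-major grid
index. Crops are clipped at image borders; interior crops are exactly
142×142.

The traceback is validated constructively: `blobDetectorModel()` hand-sets
the first feature map to a local-darkness detector (negative mean filter,
positive bias) and the deeper layers to identity centre-taps, so the
final-layer peak provably sits on the darkest structure. Implanting a dark
blob at a random location and checking that the traced field box covers the
blob's bounding box gives a ground-truth localization test, run over 50
seeded trials in the acceptance suite.

## Per-filter class statistics

For each feature map the per-image maxima are compared between a target
class and the pooled other classes with a one-sided Welch (unequal
variance) test — group sizes and variances differ across classes, so the
pooled-variance form would be anti-conservative. The sampling unit is the
image, not the patch, to limit pseudo-replication (patch-level sampling
would treat 30 correlated crops as independent); a pairwise mode tests each
other class separately. Raw p values are reported with a Holm step-down
adjustment across the 32 filters. Filters that are identically zero in
both groups (dead filters) are reported as t = 0, p = 0.5 rather than as
errors.

## Biomarker correlation framework

Case-level targets are built with a maximum operator: per feature map, the
maximum over all the case's images of the per-image grid maxima, with the
argmax segment stored. One lasso model per map regresses the targets on
biomarkers standardized with training-case statistics only (leakage
control). The penalty is selected per map by inner 5-fold cross-validation.
Because rectified activations are nonnegative, negative predicted
activations are clamped to zero; clamping (rather than dropping the
estimate) keeps the 32-vector aligned for MSE and segment matching, and
never increases the MSE against nonnegative ground truth — a property the
test suite checks on random draws. Reconstruction matches each estimate to
the training segment with the nearest stored activation (earliest wins
exact ties) and reports segments sorted by absolute difference.

Feature selection follows importance-guided backward elimination: one
random forest per feature map (500 trees, permutation importance, seeded),
importances averaged across maps into a single ranking computed once; then
the least important marker is removed step by step, the lasso set refit,
and the cross-validated MSE recorded per subset size. The reported optimum
is the arg-min subset.

## The synthetic cohort generator

Synthetic images are minimal texture analogues, not renderings: a pinkish
noisy background (H-E-like), dark elliptical blobs standing in for
secretory cells, and sinusoidal intensity ridges standing in for villus
structure. Three latent parameters per case — blob density (per megapixel),
blob eccentricity and ridge amplitude — are realized log-normally (10%
jitter) around class means and persisted in a manifest sidecar. Inter-site
staining differences are modelled as a constant per-channel RGB offset in
[−30, 30], clipped to the 8-bit range — the simplest model of a global hue
shift. Biomarkers are linear in the latents plus independent Gaussian
noise, making link recovery exactly checkable at zero noise.

The synthetic study conditions used by the tests and the acceptance script
are fixed once: 30 cases (10 per class), 5 images per case, 200×200 pixels,
blob densities (125, 750, 2000) per megapixel, eccentricities (1.2, 1.8,
2.5) and ridge amplitudes (30, 15, 5) — widely separated classes, as the
protocol's sanity floor requires (a trivial blob-count classifier reaches
at least 95% on these settings). Default image size for standalone use is
one slide frame (1360×1024) with densities (20, 60, 120) per megapixel.

What passing these tests shows — and does not show: the pipeline's
statistics, shape arithmetic, leakage control and determinism are correct,
and the classifier can learn strongly separated textures within 20 epochs.
Synthetic blobs and ridges do not emulate real histology's within-class
heterogeneity, staining physics, focus artifacts or annotation noise, so
synthetic accuracy says nothing about clinical accuracy.

## Numerical and degenerate-input policies

* Images are 8-bit RGB arrays (0..255); the engine scales to [0, 1].
* Images smaller than one tile yield an empty tiling with a warning, not an
  error; images smaller than one patch are an error naming both shapes.
* `γ ≤ 0` is a validation error; drawn gammas are bounded by construction.
* Probability triples must sum to 1 within 1e-6 (softmax guarantees this).
* Single-marker lasso sets fall back to ordinary least squares (the L1
  path requires at least two predictors).
* Empty segment libraries, missing markers, duplicate case ids and
  malformed manifest rows raise errors naming the offending entity.

## Problem sizes

Unit tests run on reduced architectures (12×12 and 40×40 inputs with 2-4
maps per layer) chosen so exhaustive loops — gradient checks against
numerical differentiation, brute-force metric oracles — stay fast. The
acceptance computations use the fixed synthetic study above; the 10-fold
cross-validation trains ten networks of the full default architecture at
input 200 and is the dominant cost of a full run.

## Known limitations

* No stain normalisation or deconvolution; the hue-shift model is global
  and linear, unlike real reagent variation.
* No transfer learning, gradient-weighted class-activation mapping, or
  deeper architectures.
* The biomarker framework reports associations on synthetic links only;
  no biological interpretation is implied or possible from it.
* Determinism is guaranteed per platform/BLAS build, not bit-identical
  across different linear-algebra libraries.
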