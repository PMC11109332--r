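---
title: "Classifying segmented objects with minimalist CNNs: methods and design"
author: "segpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying segmented objects with minimalist CNNs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Modern segmentation tools (CellPose, StarDist, Ilastik, ...) delineate
thousands of cells or nuclei with little effort, but a segmentation mask by
itself rarely answers a biological question. The scientific payload is
usually a *classification* of the segmented objects — activated versus
resting cells, one tissue compartment versus another, one phenotype versus
another — followed by counting and statistics. `segpatch` implements the
annotate → train → predict loop for exactly this setting: given an
intensity image (2D or 3D, any number of channels) and an integer label
mask from any upstream segmenter, a user labels a handful of connected
components (classes are numbers from 1 to 9), a small convolutional
classifier is trained on patches around those objects, and the trained
model classifies every object of one image or a whole folder.

## The model

For each object we extract a fixed-size patch centered on the floor of the
object's mean voxel coordinate; windows extending beyond the image are
zero-filled, so border objects produce full-size patches without inventing
texture. An optional extra channel carries the binary silhouette of the
*target* object (other objects in the window are zeroed). Patches may
contain several objects, and this channel disambiguates which one the
network is being asked about; whether the original tool feeds the mask to
its network is not documented, so both behaviors are available behind
`includeMaskChannel` (default `TRUE`).

The classifier family is deliberately minimalist and has exactly two
architectural degrees of freedom, its **depth** $d$ (number of blocks) and
**width** $w$ (filters per convolution):

$$\underbrace{\mathrm{conv}_{k^{\dim}} \to \mathrm{ReLU} \to
\mathrm{maxpool}_2}_{d \text{ blocks, } w \text{ filters each}}
\to \mathrm{GAP} \to \mathrm{affine} \to K \text{ logits}$$

Convolutions use stride 1 and same zero padding with kernel extent $k = 3$
per axis; the pooling halves every spatial axis (floor); the global
average pool (GAP) head makes one spec serve any patch size (137×137 and
45×45×45 are the 2D/3D config defaults, matching common practice for
nucleus-scale objects at ordinary magnifications). The trainable parameter
count has the closed form

$$ C w k^{\dim} + w \;+\; (d-1)(w^2 k^{\dim} + w) \;+\; wK + K $$

which the test suite checks against introspection of the built model. The
block structure itself (constant width, conv–ReLU–pool, GAP head) is this
package's concretization: width and depth are the family's only declared
degrees of freedom, and this is the smallest standard design with those
two knobs. A depth of 3 and width of 32 is a good default compromise; the
classification quality depends only mildly on the choice.

There is no deep-learning framework dependency: the forward and backward
passes are written in R as im2col gathers plus BLAS matrix products, with
the backward-to-input pass evaluated as the transposed-kernel convolution
(an equivalent im2col product, avoiding scatter-adds). Gradients are
verified against central finite differences in the tests. Weights use
fan-in-scaled uniform initialization ($U(\pm 1/\sqrt{\text{fanin}})$, zero
biases) so an untrained model predicts close to the uniform distribution —
the epoch-1 cross-entropy is within a few percent of $\ln K$, which the
suite asserts as a wiring sanity check.

## Training

Training minimizes the mean cross-entropy over shuffled mini-batches with
Adam (defaults: learning rate $10^{-3}$, $\beta = (0.9, 0.999)$, batch
size 16, 600 epochs) and a step decay that multiplies the learning rate by
0.5 every $\lceil \text{epochs}/3 \rceil$ epochs, which stabilizes the end
of optimization. These optimizer values are common stable settings; they
are all exposed in the JSON configuration, which round-trips losslessly so
a run is reproducible from its config + seed alone (the run manifest
records the config, seed and output hashes). Everything random —
initialization, shuffling, augmentation draws, label sampling — derives
from one seeded stream, and two runs with the same config and seed produce
bit-identical checkpoints.

Augmentation is an ordered pipeline of named transforms, each firing
independently with its own probability, applied online (per sample per
epoch, never as a pre-expanded dataset). Built-ins: `hflip`, `vflip`,
`rot90`, `rotate(angle_range)` (nearest-neighbor resampling, zero fill);
`registerAugmentation()` is the extension point for richer libraries. The
mask channel is always transformed identically to the intensity channels.
Two caveats the package takes seriously:

* orientation-sensitive tasks must not use rotation/flip augmentation —
  for the oriented-texture benchmark the class *is* the orientation, so
  rotations alias the labels by construction; its protocol uses none.
* per-patch min-max normalization (the default, rescaling each patch to
  [0,1] by its own extrema; a constant patch maps to zero) erases the
  absolute intensity. When the absolute gray level is the discriminant —
  as in the gray-level cell benchmark — normalization must be `none`
  (patches are then kept on a global [0,1] scale by the white point).

Prediction normalizes patches exactly as at training time: the checkpoint
sidecar records the architecture spec, patch size, mask-channel flag and
normalization mode, so a checkpoint is self-describing and reusable on new
images of the same kind without retraining. Argmax ties break toward the
smallest class index, deterministically. Unreviewed predictions are never
promoted to training labels during the correction loop — only explicit
corrections and confirmations enter the next training round, which avoids
a confirmation-bias feedback in the human-in-the-loop cycle.

## Synthetic benchmarks: what they emulate

No external data is needed anywhere: three seeded generators reproduce the
statistical structure of the classic object-classification test cases, and
every generator is a pure function of its parameters + seed.

**Gray-level cells** (`genCells`): 120 non-overlapping disks (radii 5–9 px
on a 256² canvas), class interiors at mean 80 versus 180 gray levels with
Gaussian noise of SD 5 — a 20× mean gap, so the task is trivially
separable *by a feature that sees absolute intensity*. The benchmark
protocol (`benchmarkCells`) samples 5 labels per class, trains the
depth-3/width-32 network on 16×16 patches (a window at the scale of the
largest object, dominated by the target's interior) for 200 epochs with
`normalization = "none"`, and evaluates on the remaining 110 objects.

**Oriented textures** (`genOrientedTextures`): 156 tiles of 32×32 px; each
tile is white Gaussian noise smoothed by an elongated oriented Gaussian
kernel at its class angle (0° or 90°), then *affinely standardized per
tile to a common mean and variance*. First and second moments therefore
carry no class information at all — only the orientation does — which is
the construction that defeats any classifier restricted to predefined
radiometric/morphometric features. The texture synthesis method is this
package's choice; only the moment matching and the orientation contrast
are constrained. The protocol (`benchmarkTextures`) labels 45 random
tiles, trains the same network on 32×32 min-max patches for 100 epochs
with no augmentation, and evaluates the rest. A `layout = "segregated"`
option places the two classes in opposite canvas halves, making *position*
a perfect confound for studying spatially aware classifiers.

**3D blobs** (`genBlobs3d`): ellipsoids in a 48×64×64 volume whose classes
differ by interior intensity or by elongation; this is a fixture for the
full 3D code path (multi-page volumes, 3D convolutions), not an attempt to
imitate any particular real volume.

What these scenes deliberately do **not** model: point-spread functions,
shading, staining variability, touching objects, segmentation errors, or
class imbalance. Passing the benchmarks shows that the pipeline learns the
intended feature (intensity, orientation) from a handful of labels under
clean conditions; it does not certify performance on real microscopy.

The problem sizes (canvas, tile and patch extents, epoch counts) were
chosen so a full annotate–train–predict cycle runs in seconds to tens of
seconds on a single CPU core, which keeps the benchmarks convenient to run
routinely.

## The random-forest baseline and the confounding demonstration

`rfBaselineFeatures` computes the classic predefined feature families for
one object: area/volume, equivalent diameter, interior mean/variance and
quantiles (10/25/50/75/90), the mean of a 2-voxel exterior background
ring, and optionally the centroid coordinates. `rfBaselineTrainPredict`
fits a seeded 100-tree random forest (majority vote). Two results follow
by construction and are asserted as acceptance checks:

* on the texture task the forest is near chance (no predefined feature
  encodes orientation) while the CNN is essentially perfect;
* with spatial features on a segregated scene the forest scores highly by
  *position* alone and collapses on a 90°-rotated copy, whereas the CNN
  trained on cells with rotation augmentation loses at most a couple of
  points under the same rotation — the textbook confounding-variable
  picture.

## Evaluation metrics

`confusionCounts` produces one-vs-rest counts per class ($n_i$, TP, FP,
FN, TN). `metricsAsPrinted` then computes the aggregate forms exactly as
they are conventionally displayed for this kind of study:

$$\mathrm{Precision} = \frac{1}{N}\sum_{i=1}^{N}
\frac{n_i\,TP_i}{n_i\,TP_i + FP_i},\qquad
\mathrm{Recall} = \frac{1}{N}\sum_{i=1}^{N}
\frac{n_i\,TP_i}{n_i\,TP_i + FN_i},$$
$$F_1 = \frac{2PR}{P+R},\qquad
\mathrm{Accuracy} = \frac{1}{N}\sum_{i=1}^{N}
\frac{TP_i + TN_i}{TP_i + FP_i + TN_i + FN_i}$$

with $N$ the number of classes. Note that the $n_i$ weighting sits
*inside* the per-class fractions, which is not the conventional
support-weighted mean; both are reported (`asPrinted` and `weighted`
slots) and they agree at 1.0 for a perfect classifier but differ
measurably otherwise — the suite pins a hand-computed two-class example.
$N$ is taken as the class count (consistent with the per-class
summation); a zero-denominator term contributes 0 with a warning.
`countConcordance` is the coefficient of determination of predicted
against manual per-image counts about the identity line (it can be
negative; constant manual counts are an error, not a NaN).

## Grad-CAM

For interpretation, `gradCAM` computes the gradient-weighted class
activation map at the last convolution block: channel weights are the
spatial average of $\partial y_c / \partial A$ (computed analytically
through the GAP head and the pooling argmaxes), the map is the rectified
weighted activation sum, upsampled to the patch size (nearest-neighbor by
default to avoid interpolation artifacts in tests; linear available).
Maps are non-negative and invariant to adding a constant to all logits;
a single-filter toy network is checked against the closed form
$\mathrm{ReLU}((v/S)A)$.

## Numerical and design notes

* Axis convention: channel-first, spatial axes (Z,)Y,X; masks carry no
  channel axis. One convention for the 2D and 3D code paths.
* On disk: TIFF for images (16-bit samples scaled by a white point,
  default 255; multi-page = Z; samples = channels, at most 4), masks and
  class masks 16-bit integers (bit-exact round trip); annotations as a
  JSON array of `{image_id, object_id, class}`; predictions as CSV
  `image_id,object_id,class,confidence`. Batch mode pairs images and
  masks by identical filename stem and aborts (with a listing) unless the
  pairing is a bijection.
* An object larger than the patch is simply truncated by the crop — there
  is no rescaling, matching the fixed-receptive-field design.
* Pooling on odd extents drops the trailing row/column (floor semantics);
  a patch must be at least $2^d$ per axis, enforced with a clear error.
* Stratified validation splits use `floor(fraction * n_k)` per class, so
  a singleton class always stays in training.
* Class weighting is off by default; inverse-frequency weights are
  available for imbalanced annotation sets.

## Limitations

The engine is CPU-bound R: ideal for the few-label regime it targets
(tens to hundreds of annotations, seconds to minutes of training), not
for training on tens of thousands of patches. Only TIFF is read natively;
classes are capped at 9 by the annotation convention; there is no
uncertainty-driven annotation sampling (selection is manual or uniform),
no test-time augmentation, and no probability calibration.
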