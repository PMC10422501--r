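---
title: "Pooled convolutional features for egocentric activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled convolutional features for egocentric activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable (chest- or head-mounted) cameras record activities of daily
living -- eating, washing, dressing -- from the first-person perspective.
Classifying a pre-segmented clip into one of a fixed set of activities
supports functional-health monitoring, but egocentric footage is hard:
the camera moves constantly, the same activity looks different across
people and homes, and different activities share similar scenes. egopool
implements a classical transfer-learning pipeline for this setting: a
pre-trained image CNN supplies per-frame features, fixed spatial and
temporal pooling turn them into one clip vector, and a linear one-vs-all
SVM classifies it. No training of the feature extractor is involved, which
matters when labelled egocentric video is scarce.

## Frame descriptor: regional mean/max spatial pooling (MMSP)

The last convolutional block of VGG16 (pool5) represents a frame as a
7 x 7 grid of cells, each holding a 512-channel activation vector
$x(i, j) \in \mathbb{R}^{512}$. Object-like patterns activate specific
channels at specific cells, so the *spatial arrangement* carries signal
that a fully connected layer discards. MMSP summarises the grid over six
fixed regions -- the whole grid, a 3 x 3 centre, and four 4 x 4 corner
quadrants that overlap on row/column 4 -- with both a per-channel mean and
a per-channel max:

$$
f_{\mathrm{mean}}^{(R)}[c] = \frac{1}{|R|}\sum_{(i,j)\in R} x_c(i,j),
\qquad
f_{\mathrm{max}}^{(R)}[c] = \max_{(i,j)\in R} x_c(i,j).
$$

Means aggregate all objects present in a region; maxima pick out the
single strongest activation. The twelve pooled vectors (six means, six
maxima, each of length 512) are concatenated in a fixed order -- means for
whole, center, top_left, top_right, bottom_left, bottom_right, then the
maxima in the same region order -- giving a 6144-dimensional frame
descriptor, a 4x reduction against flattening all 49 cells (25,088,
available as `stackPool5()` for comparison).

### The two mean conventions

Published formulations of this pooling differ on the coefficient used for
the 16-cell corner quadrants: the region-size reciprocal (1/16) versus a
constant 1/9 carried over from the 9-cell centre region. `regionMean()`
and `mmsp()` expose both: `mode = "true_mean"` (the default; each region
divides by its own cell count) and `mode = "ninth"` (1/49 for the whole
grid, 1/9 for every sub-region). The default is `true_mean` on the
judgment that the constant coefficient is a transcription artefact: it is
not a mean, and it breaks the interpretation of the block as an average.
`ninth` is retained, and tested, for exact reproduction of the printed
arithmetic. For a linear SVM on L2-normalised descriptors the choice is
nearly immaterial -- it rescales 4 of the 12 blocks by 16/9 -- but both
modes are contract-checked against a brute-force oracle.

Region indices are quoted 1-based inclusive everywhere user-facing; the
0-based half-open conversion happens once, inside the region resolver.
Non-7x7 grids are accepted only through an explicit region override; the
printed regions are not rescaled silently.

## Motion stream

Activity is as much motion as appearance. Dense optical flow between
consecutive *sampled* frames is rendered as a colour image -- hue encodes
flow direction (mapped linearly around the full hue circle), saturation
encodes magnitude, value is held at maximum -- and that image is fed
through the same backbone and MMSP pooling as an ordinary frame, giving
the motion stream its own 6144-dimensional descriptors.

Because no optical-flow library is available to R, the estimator is
implemented in the package: coarse-to-fine pyramidal Lucas--Kanade.
Numerical choices, all exposed as arguments of `estimateFlow()`:

* pyramid depth `levels`: `floor(log2(min(h, w)/16)) + 1`, so the coarsest
  level is at least 16 px across;
* `iterations = 5` warp/solve passes per level;
* Gaussian window `windowSigma = 3` px for the local least-squares solve;
* Tikhonov regulariser `lambda = 1e-3` on the structure-tensor diagonal,
  which pins textureless pixels to zero flow instead of amplifying noise;
* a light Gaussian smoothing (sigma 1) of the incremental field between
  iterations as the regularising prior.

Two properties are guaranteed and tested: identical frames produce an
*exactly* zero field (the temporal gradient is identically zero, so every
increment is zero), and a synthetic integer translation of a textured
square is recovered within one pixel median error. Magnitude
normalisation of the rendered image defaults to per-frame min--max
(`per_frame`), making the image invariant to a global rescaling of the
field; a `fixed` cap mode exists when cross-clip comparability of
saturation matters. Whether flow should be computed at the native or the
sampled frame rate is genuinely open; the package computes it between
sampled frames, which keeps the two streams aligned frame-for-frame and
avoids a second sampling parameter.

The motion sequence is padded by duplicating its last image so both
streams have exactly one descriptor per sampled frame; a one-frame clip
gets a single zero-flow image.

## Clip descriptor: two-level temporal pyramid (TPMM)

Per-frame descriptors $f_1, \dots, f_N$ are aggregated with a two-level
temporal pyramid: an element-wise max over the whole clip, then
element-wise means of the first and second halves,

$$
g = \big[\, \max_{t \le N} f_t,\;
\operatorname{mean}_{t \le \lfloor N/2 \rfloor} f_t,\;
\operatorname{mean}_{t > \lfloor N/2 \rfloor} f_t \,\big],
$$

tripling the frame dimension (3 x 6144 = 18,432 per modality). The max
block captures the most salient frame anywhere in the clip; the half-wise
means capture coarse temporal ordering ("first X happened, then Y").
Edge cases are fixed deliberately: for odd $N$ the first half takes
$\lfloor N/2 \rfloor$ frames and each mean divides by its *own* half's
count (a printed $1/(N/2)$ assumes even $N$); a single-frame clip reuses
its frame for both halves rather than erroring, so very short clips stay
processable. Plain `max` and `mean` pooling over the whole clip are
retained as baselines. The pyramid is invariant to frame reordering
within each half but not to swapping the halves -- a property the tests
demonstrate with an explicit counterexample.

## Normalisation and fusion

Each modality's clip vector is L2-normalised; with both streams enabled
the two unit vectors are concatenated ([appearance, motion], 36,864
dimensions) and renormalised. Normalising per stream before concatenation
equalises the energy contribution of the two modalities; the alternative
-- a single normalisation of the raw concatenation -- is available as
`normalization = "after_fuse"` since the convention is not fixed by the
method itself. A frame-level fusion path (`fusion = "frame"`) instead
concatenates the two 6144-dim frame descriptors (12,288 per frame) before
temporal pooling. A zero vector cannot be normalised and is passed
through with a warning rather than producing NaNs.

## Classification and evaluation

A linear SVM is deliberately paired with the high-dimensional pooled
features: the representation is meant to do the work, the classifier to
stay simple. One binary C-classification SVM (linear kernel, C = 1,
libsvm tolerance 1e-4, no feature rescaling) is trained per class;
each fit is reduced to an explicit weight vector and bias, oriented so
larger values favour the class; prediction is the argmax, with exact ties
broken by class order for determinism. C = 1 is the conventional default
for L2-normalised inputs and the decision function is insensitive to it
here; linear-kernel SVM training is deterministic, so no solver seed is
needed.

Evaluation is leave-one-person-out (LOPO): each subject's clips form one
test fold and all other subjects train. This measures what matters for
deployment -- generalisation to an unseen person -- and every fold
asserts that the held-out subject contributed no training rows. The
confusion matrix (rows = ground truth, columns = prediction) is pooled
across folds; from it, accuracy is $100 \sum_i C_{ii} / N$, per-class
precision is $100\, C_{jj} / \sum_i C_{ij}$, and AP is the unweighted mean
of the per-class precisions. A class never predicted has an undefined
0/0 precision and contributes 0 by convention, penalising degenerate
classifiers. AP is computed from the pooled matrix (per-fold accuracies
are logged separately): pooling matches the single-confusion-matrix
definition of the metrics and is stable when per-subject folds are tiny.

Frame sampling: clips are sub-sampled to a target rate (1 fps by default,
10 fps the studied alternative) with stride `round(native_fps/target_fps)`
starting at the first frame. The anchor is the simplest deterministic
choice; an offset argument exists but nothing in the method depends on it.
The native rate is taken from the manifest rather than probed from
containers so that runs are reproducible across decoders.

## What the synthetic generator emulates -- and what it does not

`genFeatureStack()` emulates the one structural assumption the method
rests on: class-discriminative, spatially localised activations. Each
class places an additive bump (default +3 activation units, against
N(1, 0.5) background noise) in one of the six MMSP pooling regions,
across a fixed seeded 64-channel subset. Because the signal lives in a
*pooling region*, the MMSP stage specifically is what renders classes
linearly separable -- a targeted integration test of the spatial-pooling
equations, not just of the classifier. `genVideo()` emulates the motion
assumption: a textured square translated in integer-pixel steps over a
static textured background, with the applied shift recorded as flow
ground truth, and the square anchored in the class's region so the
content-preserving mock backbone sees the same localisation.

The default study conditions are 3 subjects x 2 classes x 2 clips each,
9 frames per clip at 64 px and a nominal 3 fps manifest rate; the
chance-level control uses 5 subjects x 4 clips per class (N = 40) so a
binomial interval is informative. These sizes keep the full suite in the
low minutes on one CPU while still exercising every stage end to end.

What passing these tests shows: the pipeline's algebra (pooling, fusion,
protocol) is correct and recovers signals *of the assumed form*. What it
does not show: performance on real egocentric video -- no camera shake,
motion blur, background clutter, class imbalance, or intra-class
variation is simulated, and the mock backbone (7 x 7 block means expanded
through a seeded non-negative channel-mixing matrix) preserves spatial
layout but has none of a trained CNN's invariances.

The label-shuffled control permutes labels *within* subject. A stratified
permutation is the appropriate null under LOPO: it preserves every fold's
class balance, so chance accuracy follows the binomial reference. An
unstratified shuffle leaves complementary train/test imbalances that a
majority-leaning classifier systematically anti-predicts, biasing
measured accuracy below chance -- a property of balanced cross-validation
designs, not of this pipeline.

## Backbone providers

The `vgg16` provider is a full VGG16 forward pass written in R (im2col
convolutions on BLAS, 2 x 2 max pooling, fc6/fc7), instantiated
architecture-only with seeded He-initialised weights; a user-supplied
weight list is accepted, and the provider identifier (recorded in every
result file) states the weight provenance. Numeric equality across weight
sets is never promised. Untrained weights still pin down everything the
package's checks rely on: output shapes (7 x 7 x 512 pool5; 4096 fc7),
determinism, and post-ReLU non-negativity. Preprocessing is a direct
bilinear resize to 224 x 224 (no centre crop -- the simplest convention,
and configurable) followed by the standard ImageNet per-channel
standardisation in RGB order. The `mock` provider is the test/offline
workhorse: deterministic, content-preserving, and a pure function of
(seed, image content).

## Known limitations

* Frame input is PNG directories; video containers must be pre-extracted.
* The pyramidal Lucas--Kanade estimator is a classical local method: it
  underestimates large displacements relative to image texture scale and
  has no occlusion handling.
* The pooling regions are fixed; no learned or attention-based pooling.
* The pyramid depth is fixed at two levels; deeper pyramids are out of
  scope.
* No class re-weighting for imbalanced datasets; metrics are reported
  per class so imbalance is visible rather than corrected.
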