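---
title: "Methods: tooth detection and caries severity assessment on bitewing phantoms"
author: "BitewingCaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tooth detection and caries severity assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BitewingCaries)
```

## The problem

Approximal caries — lesions on the contact surfaces between adjacent teeth —
are hidden from direct clinical view and are read from bitewing radiographs,
where demineralized tissue absorbs fewer X-rays and appears as a dark patch
on the bright tooth crown. BitewingCaries implements a complete screening
pipeline for such images: it locates individual teeth, crops them, balances
the training classes by flip/rotation augmentation, classifies each tooth
into three severity stages (`normal`, `incipient`, `advanced`), and
evaluates the classifier with one-vs-rest diagnostic metrics, per-exam
lesion counts, paired Wilcoxon signed-rank tests against a reference rater,
and a paired-design power analysis.

Because clinical radiographs cannot be redistributed, the package ships a
phantom generator that renders bitewing-like images with exact ground
truth. Every stage of the pipeline is exercised and tested on these
phantoms.

## The phantom generator

`generateBitewing()` renders one or two arch rows of bright, rounded
(superellipse, exponent 4) teeth on a darker background, separated by
narrow gaps. Default geometry is 800 x 600 px — the 3200 x 2400 acquisition
format scaled by 1/4, with all pixel-unit parameters scaled by the same
factor — and 3–4 teeth per row, giving the 6–8 teeth per image typical of
bitewing views. Each tooth draws a severity label from the class mix
`c(normal, incipient, advanced) = (305, 113, 62)/480`, the stage frequency
of a screening population of 480 teeth. Lesions are elliptical patches of
intermediate intensity placed on a lateral (approximal) tooth edge; their
size is determined by the class (absent / small / large), so the classes
are separable by construction. Pre-noise intensities default to background
40, lesion 90, tooth 200 (8-bit), and additive Gaussian noise (sd 6,
clipped to [0, 255]) models detector noise; radiographic noise physics is
deliberately out of scope.

What the phantom does *not* emulate: anatomical tooth shapes, enamel/dentin
layering, overlapping contacts, cervical burnout, restorations and scatter.
Passing tests on phantoms therefore demonstrates that the implementation is
correct and self-consistent, not that the trained classifier would transfer
to clinical images.

`generateLabeledCrops()` renders single-tooth crops directly (one tooth per
crop with the same lesion model) and records the exact tooth and lesion
pixel fractions in the crop metadata, which the test suite uses as ground
truth.

## Tooth detection

`detectTeeth()` composes four deterministic stages:

1. **Contrast-limited adaptive histogram equalization** (`adaptiveEqualize`),
   8 x 8 tile grid. The clip limit is not fixed by common practice, so it
   is a parameter (`eqClipLimit`, normalized; default 0.01) — contrast
   limiting prevents noise amplification in flat regions. Images whose
   size is not a multiple of the grid are border-replicated and cropped
   back. Equalization increases tooth/background separation locally (the
   tests measure it across a band edge); it is not guaranteed to increase
   global contrast.
2. **Otsu thresholding** (`otsuThreshold`): the threshold maximizes
   between-class variance over a 256-bin histogram; the mask is
   `image > threshold`, storing teeth as foreground `TRUE`. A constant
   image has a degenerate histogram and raises an error.
3. **Morphological refinement** (`morphologicalRefine`): erosion by a wide
   flat rectangle (default 130 x 20 px, width x height, at the 3200-px
   reference width) severs bridges between adjacent teeth; an opening by a
   radius-20 disk removes small spurious regions; a dilation by a
   radius-15 disk restores the eroded tooth borders. All sizes scale
   linearly by `imageWidth / 3200` (minimum 1 px). The middle step is
   exposed as `morphOp = "opening"` (default) or `"closing"`, because
   either ordering of the two primitive operations is defensible for this
   cleanup; opening is the variant that removes bright speckle, which is
   what the thresholded phantoms actually contain.
4. **Component extraction** (`extractToothRegions`): 8-connected components
   with area at least `minAreaFraction` (default 0.1%) of the image become
   `ToothRegion`s, ordered left-to-right by `(c0, r0)`; crops are taken
   from the original (unequalized) image, since equalization is a
   detection aid, not a photometric correction. Bounding boxes are 0-based
   half-open, the convention also used in the JSON interchange format.

EBImage provides the equalization, threshold and morphology primitives; the
8-connected labeling is compiled code in the package (the available
labeling routine is 4-connected, which splits teeth touching diagonally).

## Split and augmentation

`splitDataset()` holds out `testPerClass` crops per class (default 15, i.e.
45 test teeth), seeded and without replacement. The pipeline's
`runPipeline()` additionally enforces *exam-level* disjointness: whole
exams are assigned to the test pool until every class is covered, test
crops are drawn only from those exams, and their remaining crops are
discarded rather than trained on. Training therefore never sees any crop
from a test exam (a guard in `trainModel()` raises on violation).

`augmentTrainingSet()` multiplies each class by a fixed factor using the
ordered transform pool {no flip, flip} x {0°, −10°, −5°, 5°, 10°}. The
default multiplicities 4/12/24 are chosen so the three classes end up
nearly balanced: 290/98/47 training crops become 1160/1176/1128 images.
The pool has only 10 distinct members, so multiplicities above 10 reuse
pool entries with Gaussian angle jitter (sd 1°, seeded) — reused variants
are thus distinct but visually equivalent. Rotation uses bilinear
interpolation with border-replicate fill, so rotated corners resemble
surrounding tissue rather than black padding; vertical flips are excluded
as anatomically implausible for arch symmetry. The original crop counts
toward its multiplicity as the identity transform.

## The severity classifier

`trainModel()` optimizes categorical cross-entropy with momentum SGD
(momentum coefficient 0.9, a standard choice where only the optimizer
family is fixed), batch size 16, and learning rates conventionally in
{0.1, 0.01, 0.001}. A stratified, seeded 20% validation holdout is used
only for accuracy logging. Class imbalance is handled by the augmentation
stage, not by loss weighting. Crops are padded to square with border
replication and bilinearly resized to `inputSize` (default 64 px — small
enough for CPU-scale training while lesions of a few pixels radius remain
resolvable; configurable). Convolution and pooling passes are compiled
(im2col + GEMM); training is single-threaded and bit-reproducible given
the seed.

Three architectures are provided:

* `tiny` (default, desk scale): three convolution blocks, global average
  pooling, softmax head. The first block is a 3 x 3 smoothing kernel
  replicated at 16 intensity thresholds; the second is a 1 x 1 layer
  initialized to second differences of adjacent threshold channels, which
  yields tent-shaped *radiodensity band* detectors — the feature family
  that distinguishes lesion, background and enamel pixels; the third block
  passes the band maps through (plus four freely initialized mixing
  channels). Pooling in this architecture is *average* pooling: with
  global average pooling downstream, pooled features remain exact
  area-fraction measurements, whereas max pooling would erase small dark
  lesion regions. Training follows a fine-tuning regime: the
  structured-initialized blocks are frozen (`lrMult = 0`) and the frozen
  feature standardization plus softmax head are trained. The
  standardization (`featnorm`) centers and scales each pooled feature with
  statistics estimated once from the training data at the start of
  training (then serialized with the model); without it the all-positive,
  small-variance area fractions make the head's optimization so
  ill-conditioned that no learning rate in the configured range converges
  within the configured iteration budgets.
* `resnet_like`: three residual units after a small stem; each unit is two
  3 x 3 convolutions and two ReLU activations with an identity shortcut,
  `y = relu(x + conv2(relu(conv1(x))))`.
* `inception_like`: two modules of parallel 1 x 1, 3 x 3 and 5 x 5
  convolutions plus a 3 x 3 stride-1 max-pool branch, concatenated along
  channels.

The deeper variants honor the quoted module structure at reduced
depth/width — they are desk-scale stand-ins, not 50-layer reproductions —
and use a batch-normalized feature head. If the loss becomes non-finite
(plausible at learning rate 0.1 and above), training stops early with a
classed `divergenceWarning`, keeps the last finite weights, and the model
remains evaluable; such runs typically degenerate to single-class
predictors, and the evaluation suite is required to handle them.

An optional warm-up hook (`pretrainSteps`, default 0) runs extra optimizer
steps on freshly generated phantom crops before the main run, standing in
for large-scale pretraining without any download dependency.

## Evaluation metrics

`perClassMetrics()` decomposes the 3 x 3 confusion matrix one-vs-rest:
per class, precision = TP/(TP+FP), recall = TP/(TP+FN), specificity =
TN/(TN+FP), NPV = TN/(TN+FN), plus overall accuracy = trace/total. Ratios
with an empty denominator (0/0) are reported as **0**, the convention that
matches how degenerate single-class predictors appear in published metric
tables (a NaN convention would be defensible but would not reproduce those
entries). The comparison tolerance used in the tests is ±0.001 because
published tables mix truncation (13/15 → 0.866) and rounding (25/27 →
0.926), so no single rounding rule achieves exact 3-decimal equality.

`rocAucOneVsRest()` computes AUC as the Mann–Whitney probability that a
random positive outranks a random negative, ties counted 1/2 (average
ranks); this equals the trapezoidal area under the empirical ROC curve,
which the tests verify, and the curve points are returned for plotting.
AUC values from other studies are not reproduction targets here, because
per-item scores are generally unpublished and the binarization scheme for
a 3-class softmax is ambiguous.

## Agreement analysis and power

`lesionsPerExam()` counts incipient and advanced calls per exam (normal
teeth are not lesions). `wilcoxonSignedRank()` compares two raters'
per-exam counts: zero differences are dropped by default (the mainstream
default; a Pratt-style `zeroMethod = "pratt"` retains them), absolute
differences are ranked with average ranks for ties, and the statistic is
the smaller of the signed-rank sums. The two-sided p-value is exact (the
signed-rank null distribution) when the effective n is at most 25 and no
ties are present; otherwise a normal approximation with tie correction and
continuity correction is used. If all differences are zero the result is
p = 1 with a `degenerate` flag. The exact branch is verified against a
full 2^n sign-enumeration oracle in the tests.

`minSampleSizePaired()` solves the noncentral-t power equation for a
two-sided paired t-test, `power(n) = P(|T_{n-1}(d sqrt(n))| >
t_{1-alpha/2, n-1})`, for continuous n and truncates to an integer — the
convention consistent with the published minimum of 22 exams at d = 0.8,
alpha = 0.05, power = 0.95 (the continuous solution is ~22.6; a strict
`rounding = "ceiling"` mode returning the smallest n meeting the target is
also provided and gives 23).

## Reproducibility and problem sizes

Every stochastic step takes a seed, and all stage seeds in `runPipeline()`
derive from one global seed; identical configurations produce
byte-identical reports. The test suite runs the detection property checks
on 24 phantoms of 6–8 teeth at 800 x 600, the classifier checks on 300
phantom crops (100 per class, 64 px) for 500 optimizer steps, and the
default pipeline on 40 exams — sizes chosen so a complete run stays
comfortably CPU-scale while the class counts remain large enough for
stable stage behavior at realistic lesion prevalence.

## Known limitations

* Phantoms are geometric surrogates; no claim is made about clinical
  transfer of trained weights.
* The `tiny` architecture's frozen band blocks are tailored to
  intensity-coded severity; data whose classes differ by texture rather
  than radiodensity occupancy would require unfreezing (`lrMult`) or the
  deeper architectures.
* The exact Wilcoxon branch requires untied differences; counts data often
  tie, in which case the approximate branch is used even at small n.
* Detection assumes teeth are bright, roughly convex regions separated by
  darker gaps; crowding, implants and malocclusion are out of scope.
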