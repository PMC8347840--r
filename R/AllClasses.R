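#' Canonical caries severity stages
#'
#' The fixed class order used throughout the package: teeth without a lesion
#' (\code{normal}), enamel-confined lesions (\code{incipient}) and lesions
#' reaching dentin/pulp (\code{advanced}). All confusion matrices, score
#' matrices and serialized models use this order.
#'
#' @return Character vector of the three stage names, in canonical order.
#' @export
#' @examples
#' cariesStages()
cariesStages <- function() c("normal", "incipient", "advanced")

#' @title Phantom bitewing specification
#'
#' @description Geometry and intensity parameters of the synthetic bitewing
#' generator: bright rounded-rectangle teeth arranged in one or two arches on
#' a darker background, separated by narrow gaps, with optional darker lesion
#' patches at approximal (lateral) tooth surfaces. Intensities are 8-bit
#' (0--255); all geometric fields are pixels.
#'
#' @slot width,height image size in pixels.
#' @slot nTeethPerRow number of teeth rendered per arch row.
#' @slot rows number of arch rows (1 or 2).
#' @slot toothWidthRange,toothHeightRange sampling ranges for tooth size.
#' @slot gapWidth minimum horizontal gap between neighbouring teeth.
#' @slot backgroundLevel,toothLevel,lesionLevel pre-noise intensities; must
#'   satisfy background < lesion < tooth (lesions absorb fewer X-rays than
#'   sound enamel, so they render darker than the tooth body).
#' @slot classProbs named sampling probabilities over \code{cariesStages()}
#'   used to draw each rendered tooth's severity label.
#' @slot noiseSd standard deviation of additive Gaussian noise (intensity
#'   units), clipped to [0, 255].
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(width = "numeric", height = "numeric",
                 nTeethPerRow = "numeric", rows = "numeric",
                 toothWidthRange = "numeric", toothHeightRange = "numeric",
                 gapWidth = "numeric", backgroundLevel = "numeric",
                 toothLevel = "numeric", lesionLevel = "numeric",
                 classProbs = "numeric", noiseSd = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  geom <- c(object@width, object@height, object@nTeethPerRow, object@rows,
            object@toothWidthRange, object@toothHeightRange)
  if (any(geom <= 0)) msg <- c(msg, "all geometric fields must be positive")
  if (object@gapWidth < 1) msg <- c(msg, "gapWidth must be >= 1")
  if (!object@rows %in% c(1, 2)) msg <- c(msg, "rows must be 1 or 2")
  if (!(object@backgroundLevel < object@lesionLevel &&
        object@lesionLevel < object@toothLevel))
    msg <- c(msg, "need backgroundLevel < lesionLevel < toothLevel")
  lv <- c(object@backgroundLevel, object@toothLevel, object@lesionLevel)
  if (any(lv < 0 | lv > 255)) msg <- c(msg, "intensity levels must be in [0, 255]")
  if (length(object@classProbs) != 3 ||
      !setequal(names(object@classProbs), cariesStages()) ||
      any(object@classProbs < 0) || sum(object@classProbs) <= 0)
    msg <- c(msg, "classProbs must be named over cariesStages() and non-negative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  need <- object@nTeethPerRow * max(object@toothWidthRange) +
    (object@nTeethPerRow + 1) * object@gapWidth
  if (need > object@width)
    msg <- c(msg, "teeth do not fit horizontally at requested geometry")
  if (object@rows * max(object@toothHeightRange) * 1.1 > object@height)
    msg <- c(msg, "teeth do not fit vertically at requested geometry")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults render 800 x 600 phantoms: the study-scale 3200 x 2400 bitewings
#' scaled by 1/4, with 6--8 teeth per image (two arches of 3--4 teeth) and
#' stage frequencies matching a typical screening population where roughly
#' two thirds of teeth are sound.
#'
#' @param width,height image size in pixels.
#' @param nTeethPerRow teeth per arch row.
#' @param rows arch rows (1 or 2).
#' @param toothWidthRange,toothHeightRange tooth size sampling ranges (pixels).
#' @param gapWidth horizontal gap between teeth (pixels).
#' @param backgroundLevel,toothLevel,lesionLevel pre-noise 8-bit intensities.
#' @param classProbs named severity sampling probabilities.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' phantomSpec(nTeethPerRow = 3)
phantomSpec <- function(width = 800, height = 600, nTeethPerRow = 4, rows = 2,
                        toothWidthRange = c(110, 150),
                        toothHeightRange = c(170, 230),
                        gapWidth = 24, backgroundLevel = 40, toothLevel = 200,
                        lesionLevel = 90,
                        classProbs = c(normal = 305, incipient = 113,
                                       advanced = 62) / 480,
                        noiseSd = 6) {
  new("PhantomSpec", width = width, height = height,
      nTeethPerRow = nTeethPerRow, rows = rows,
      toothWidthRange = sort(toothWidthRange),
      toothHeightRange = sort(toothHeightRange), gapWidth = gapWidth,
      backgroundLevel = backgroundLevel, toothLevel = toothLevel,
      lesionLevel = lesionLevel,
      classProbs = classProbs[cariesStages()] / sum(classProbs),
      noiseSd = noiseSd)
}

#' @title Tooth-detection parameters
#'
#' @description Parameters of the detection stage: CLAHE tile grid and clip
#' limit, the morphological structuring elements, and the minimum component
#' area. Structuring-element sizes are given at the reference acquisition
#' resolution and rescaled linearly by \code{imageWidth / referenceWidth}
#' (minimum 1 px) when images of other sizes are processed, so reduced-scale
#' phantoms behave like full-resolution radiographs.
#'
#' @slot eqTile CLAHE tile grid as (rows, cols).
#' @slot eqClipLimit normalized CLAHE clip limit (fraction of tile pixels).
#' @slot erosionSe erosion rectangle as (width, height) in pixels at the
#'   reference resolution; the wide flat shape severs bridges between
#'   neighbouring teeth without merging them.
#' @slot openingRadius,dilationRadius disk radii (pixels at reference
#'   resolution) for the opening that removes small spurious regions and the
#'   final dilation that restores eroded tooth borders.
#' @slot minAreaFraction connected components smaller than this fraction of
#'   the image area are discarded.
#' @slot referenceResolution (width, height) the pixel-unit defaults refer to.
#' @slot morphOp \code{"opening"} or \code{"closing"} for the middle
#'   morphological step.
#' @exportClass DetectionParams
setClass("DetectionParams",
  representation(eqTile = "numeric", eqClipLimit = "numeric",
                 erosionSe = "numeric", openingRadius = "numeric",
                 dilationRadius = "numeric", minAreaFraction = "numeric",
                 referenceResolution = "numeric", morphOp = "character"))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (length(object@eqTile) != 2 || any(object@eqTile < 1))
    msg <- c(msg, "eqTile must be two values >= 1")
  if (object@eqClipLimit <= 0) msg <- c(msg, "eqClipLimit must be > 0")
  if (length(object@erosionSe) != 2 || any(object@erosionSe < 1))
    msg <- c(msg, "erosionSe must be two values >= 1")
  if (object@openingRadius < 1 || object@dilationRadius < 1)
    msg <- c(msg, "radii must be >= 1")
  if (object@minAreaFraction < 0 || object@minAreaFraction >= 1)
    msg <- c(msg, "minAreaFraction must be in [0, 1)")
  if (!object@morphOp %in% c("opening", "closing"))
    msg <- c(msg, "morphOp must be 'opening' or 'closing'")
  if (length(msg)) msg else TRUE
})

#' Construct DetectionParams
#'
#' @param eqTile CLAHE tile grid (rows, cols).
#' @param eqClipLimit normalized clip limit.
#' @param erosionSe erosion rectangle (width, height) at reference resolution.
#' @param openingRadius,dilationRadius disk radii at reference resolution.
#' @param minAreaFraction minimum component area as a fraction of image area.
#' @param referenceResolution (width, height) pixel parameters refer to.
#' @param morphOp middle morphological step, \code{"opening"} (default) or
#'   \code{"closing"}.
#' @return A validated \linkS4class{DetectionParams}.
#' @export
#' @examples
#' detectionParams()
detectionParams <- function(eqTile = c(8, 8), eqClipLimit = 0.01,
                            erosionSe = c(130, 20), openingRadius = 20,
                            dilationRadius = 15, minAreaFraction = 0.001,
                            referenceResolution = c(3200, 2400),
                            morphOp = "opening") {
  new("DetectionParams", eqTile = eqTile, eqClipLimit = eqClipLimit,
      erosionSe = erosionSe, openingRadius = openingRadius,
      dilationRadius = dilationRadius, minAreaFraction = minAreaFraction,
      referenceResolution = referenceResolution, morphOp = morphOp)
}

#' @title Train/test split specification
#' @slot testPerClass held-out teeth per severity class.
#' @slot seed RNG seed for the without-replacement draw.
#' @exportClass SplitSpec
setClass("SplitSpec", representation(testPerClass = "numeric",
                                     seed = "numeric"))

setValidity("SplitSpec", function(object) {
  if (object@testPerClass < 0) "testPerClass must be >= 0" else TRUE
})

#' Construct a SplitSpec
#' @param testPerClass held-out teeth per class (default 15, i.e. 45 test
#'   teeth over the three classes).
#' @param seed RNG seed.
#' @return A \linkS4class{SplitSpec}.
#' @export
splitSpec <- function(testPerClass = 15, seed = 1L) {
  new("SplitSpec", testPerClass = testPerClass, seed = seed)
}

#' @title Class-balancing augmentation policy
#'
#' @description Flip/rotation augmentation with per-class multiplicities.
#' The transform pool is the ordered set
#' \{no flip, flip\} x \{0, rotation angles\}; a crop of class \code{c}
#' yields exactly \code{multiplicity[c]} outputs (the untransformed original
#' is the first pool entry and counts toward its multiplicity). When a
#' multiplicity exceeds the pool size, pool entries are reused with Gaussian
#' angle jitter so no two outputs are identical.
#'
#' @slot rotationAngles rotation angles in degrees.
#' @slot flip whether horizontal mirroring is in the pool.
#' @slot multiplicity named per-class output multiplicities.
#' @slot angleJitterSd jitter standard deviation (degrees) for reused entries.
#' @slot seed RNG seed for the jitter draws.
#' @exportClass AugmentPolicy
setClass("AugmentPolicy",
  representation(rotationAngles = "numeric", flip = "logical",
                 multiplicity = "numeric", angleJitterSd = "numeric",
                 seed = "numeric"))

setValidity("AugmentPolicy", function(object) {
  msg <- character()
  if (any(abs(object@rotationAngles) >= 90))
    msg <- c(msg, "rotation angles must lie in (-90, 90)")
  if (any(object@rotationAngles == 0))
    msg <- c(msg, "0 degrees is implicit; do not list it")
  if (length(object@multiplicity) != 3 ||
      !setequal(names(object@multiplicity), cariesStages()) ||
      any(object@multiplicity < 1))
    msg <- c(msg, "multiplicity must be named over cariesStages(), all >= 1")
  if (object@angleJitterSd < 0) msg <- c(msg, "angleJitterSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AugmentPolicy
#'
#' The default multiplicities 4/12/24 balance training sets with the class
#' imbalance of a caries screening cohort: 290/98/47 crops per class become
#' 1160/1176/1128 augmented images.
#'
#' @param rotationAngles rotation angles in degrees (0 is implicit).
#' @param flip include horizontal mirroring.
#' @param multiplicity named per-class multiplicities.
#' @param angleJitterSd Gaussian jitter sd (degrees) for reused pool entries.
#' @param seed RNG seed for jitter.
#' @return A validated \linkS4class{AugmentPolicy}.
#' @export
#' @examples
#' augmentPolicy()
augmentPolicy <- function(rotationAngles = c(-10, -5, 5, 10), flip = TRUE,
                          multiplicity = c(normal = 4, incipient = 12,
                                           advanced = 24),
                          angleJitterSd = 1.0, seed = 1L) {
  new("AugmentPolicy", rotationAngles = rotationAngles, flip = flip,
      multiplicity = multiplicity[cariesStages()],
      angleJitterSd = angleJitterSd, seed = seed)
}

#' @title Classifier training configuration
#'
#' @description Architecture and optimizer settings for the severity
#' classifier: momentum SGD (coefficient 0.9), batch size 16, and a learning
#' rate conventionally taken from \{0.1, 0.01, 0.001\}. \code{iterations}
#' counts optimizer steps. Crops are pad-to-square (border replicate) and
#' resized to \code{inputSize} x \code{inputSize} before entering the
#' network.
#'
#' @slot architecture one of \code{"tiny"}, \code{"inception_like"},
#'   \code{"resnet_like"}.
#' @slot learningRate,batchSize,momentum,iterations optimizer settings.
#' @slot validationFraction stratified fraction of the training data held out
#'   for validation-accuracy logging.
#' @slot inputSize network input side length in pixels.
#' @slot nClasses number of output classes (3).
#' @slot seed RNG seed (weight init, batch order, validation split).
#' @slot pretrainSteps optional warm-up steps on freshly generated phantom
#'   crops before the main run (0 disables).
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(architecture = "character", learningRate = "numeric",
                 batchSize = "numeric", momentum = "numeric",
                 iterations = "numeric", validationFraction = "numeric",
                 inputSize = "numeric", nClasses = "numeric",
                 seed = "numeric", pretrainSteps = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@architecture %in% c("tiny", "inception_like", "resnet_like"))
    msg <- c(msg, "unknown architecture")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@validationFraction <= 0 || object@validationFraction >= 1)
    msg <- c(msg, "validationFraction must be in (0, 1)")
  if (object@iterations < 1) msg <- c(msg, "iterations must be >= 1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@inputSize < 8) msg <- c(msg, "inputSize must be >= 8")
  if (object@nClasses != 3) msg <- c(msg, "nClasses must be 3")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' @param architecture \code{"tiny"} (default), \code{"inception_like"} or
#'   \code{"resnet_like"}.
#' @param learningRate SGD learning rate.
#' @param batchSize minibatch size.
#' @param momentum momentum coefficient.
#' @param iterations optimizer steps.
#' @param validationFraction stratified validation holdout fraction.
#' @param inputSize network input side length (pixels).
#' @param seed RNG seed.
#' @param pretrainSteps optional phantom warm-up steps (0 = off).
#' @return A validated \linkS4class{TrainConfig}.
#' @export
#' @examples
#' trainConfig(iterations = 500)
trainConfig <- function(architecture = "tiny", learningRate = 0.001,
                        batchSize = 16, momentum = 0.9, iterations = 2000,
                        validationFraction = 0.2, inputSize = 64,
                        seed = 1L, pretrainSteps = 0) {
  new("TrainConfig", architecture = architecture, learningRate = learningRate,
      batchSize = batchSize, momentum = momentum, iterations = iterations,
      validationFraction = validationFraction, inputSize = inputSize,
      nClasses = 3, seed = seed, pretrainSteps = pretrainSteps)
}

#' @title A set of labeled tooth crops
#'
#' @description Grayscale tooth crops (matrices of 8-bit intensities, rows =
#' image rows) with severity labels and source exam identifiers. Behaves like
#' a vector: \code{length()}, \code{[} and \code{c()} are supported.
#'
#' @slot crops list of numeric matrices.
#' @slot labels factor with levels \code{cariesStages()}.
#' @slot examIds character vector of source exam identifiers.
#' @slot meta data.frame of optional per-crop generator metadata (e.g.
#'   ground-truth lesion pixel fractions for phantom crops).
#' @exportClass ToothCropSet
setClass("ToothCropSet",
  representation(crops = "list", labels = "factor", examIds = "character",
                 meta = "data.frame"))

setValidity("ToothCropSet", function(object) {
  n <- length(object@crops)
  msg <- character()
  if (length(object@labels) != n || length(object@examIds) != n)
    msg <- c(msg, "crops, labels and examIds must have equal length")
  if (!identical(levels(object@labels), cariesStages()))
    msg <- c(msg, "labels must use levels cariesStages()")
  if (nrow(object@meta) > 0 && nrow(object@meta) != n)
    msg <- c(msg, "meta must be empty or have one row per crop")
  if (length(msg)) msg else TRUE
})

#' Construct a ToothCropSet
#' @param crops list of grayscale matrices (0--255).
#' @param labels severity labels (coerced to factor over
#'   \code{cariesStages()}).
#' @param examIds source exam identifiers.
#' @param meta optional per-crop metadata data.frame.
#' @return A \linkS4class{ToothCropSet}.
#' @export
toothCropSet <- function(crops, labels, examIds, meta = NULL) {
  if (is.null(meta)) meta <- data.frame()
  new("ToothCropSet", crops = crops,
      labels = factor(as.character(labels), levels = cariesStages()),
      examIds = as.character(examIds), meta = meta)
}

#' @title Detected tooth regions of one bitewing
#'
#' @description Connected foreground components accepted as teeth. Bounding
#' boxes are 0-based half-open \code{(r0, c0, r1, c1)}: pixel rows
#' \code{r0..r1-1} and columns \code{c0..c1-1} belong to the box. Crops are
#' cut from the original (unequalized) image.
#'
#' @slot bbox integer matrix (n x 4), columns \code{r0, c0, r1, c1}.
#' @slot area component pixel counts.
#' @slot masks list of logical matrices (component mask within its box).
#' @slot crops list of grayscale matrices cut from the original image.
#' @exportClass ToothRegionSet
setClass("ToothRegionSet",
  representation(bbox = "matrix", area = "numeric", masks = "list",
                 crops = "list"))

setValidity("ToothRegionSet", function(object) {
  n <- nrow(object@bbox)
  msg <- character()
  if (ncol(object@bbox) != 4) msg <- c(msg, "bbox must have 4 columns")
  if (length(object@area) != n || length(object@masks) != n ||
      length(object@crops) != n)
    msg <- c(msg, "slot lengths must agree")
  if (n > 0) {
    if (any(object@bbox[, 3] <= object@bbox[, 1]) ||
        any(object@bbox[, 4] <= object@bbox[, 2]))
      msg <- c(msg, "bboxes must be non-degenerate half-open intervals")
    if (any(object@area <= 0)) msg <- c(msg, "areas must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @title A rendered phantom bitewing
#'
#' @description The generator's output: the noisy image, per-tooth ground
#' truth (bounding boxes and severity labels), and the exact pre-noise tooth
#' and lesion masks used to render it.
#'
#' @slot image numeric matrix of 8-bit intensities.
#' @slot regions data.frame with columns \code{examId, r0, c0, r1, c1,
#'   label} (0-based half-open boxes).
#' @slot toothMask integer matrix; 0 = background, k = tooth number k.
#' @slot lesionMask logical matrix of lesion pixels.
#' @slot spec the \linkS4class{PhantomSpec} used.
#' @exportClass BitewingPhantom
setClass("BitewingPhantom",
  representation(image = "matrix", regions = "data.frame",
                 toothMask = "matrix", lesionMask = "matrix",
                 spec = "PhantomSpec"))

#' @title A trained (or untrained) severity classifier
#'
#' @description Compact convolutional network with a fixed, serialized class
#' order. \code{layers} holds the weight arrays; \code{log} the per-step
#' training loss and periodic validation accuracy.
#'
#' @slot architecture architecture identifier.
#' @slot config the \linkS4class{TrainConfig} used to build/train it.
#' @slot layers list of layer descriptors with weight arrays.
#' @slot classOrder character, always \code{cariesStages()}.
#' @slot trained logical.
#' @slot diverged logical; \code{TRUE} if training hit a non-finite loss and
#'   stopped early (the last finite weights are kept).
#' @slot log data.frame training log.
#' @exportClass CariesModel
setClass("CariesModel",
  representation(architecture = "character", config = "TrainConfig",
                 layers = "list", classOrder = "character",
                 trained = "logical", diverged = "logical",
                 log = "data.frame"))
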