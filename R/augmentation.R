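#' @title Split and class-balancing augmentation
#' @name augmentation
#' @description Stratified train/test splitting of labeled tooth crops, and
#' a flip/rotation augmentation that multiplies each class by a fixed factor
#' to balance the training set. Only training crops are ever transformed;
#' the test set is held out before augmentation.
NULL

#' Split labeled crops into training and test sets
#'
#' Draws exactly \code{testPerClass} crops per severity class (without
#' replacement, seeded) for the test set; the remainder is the training set.
#'
#' @param crops a \linkS4class{ToothCropSet}.
#' @param spec a \linkS4class{SplitSpec}.
#' @return List with elements \code{train} and \code{test}
#'   (\linkS4class{ToothCropSet}s with disjoint crops).
#' @export
#' @examples
#' crops <- generateLabeledCrops(c(normal = 8, incipient = 6, advanced = 6),
#'                               cropSize = 32, seed = 1)
#' sp <- splitDataset(crops, splitSpec(testPerClass = 2, seed = 1))
#' length(sp$test)
splitDataset <- function(crops, spec = splitSpec()) {
  validObject(spec)
  labs <- cropLabels(crops)
  sizes <- table(labs)
  if (spec@testPerClass > 0 && any(sizes < spec@testPerClass))
    stop("split error: a class has fewer members than testPerClass",
         call. = FALSE)
  testIdx <- withSeed(spec@seed, {
    unlist(lapply(cariesStages(), function(cls) {
      pool <- which(labs == cls)
      if (spec@testPerClass == 0) integer() else
        sort(sample(pool, spec@testPerClass))
    }))
  })
  trainIdx <- setdiff(seq_along(labs), testIdx)
  list(train = crops[trainIdx], test = crops[sort(testIdx)])
}

#' Apply a flip/rotation transform to a crop
#'
#' Horizontal mirroring (applied first) followed by rotation about the crop
#' centre with bilinear interpolation and border-replicate fill, so rotated
#' corners look like surrounding tissue rather than black padding.
#'
#' @param crop grayscale matrix.
#' @param flip mirror left-right?
#' @param angle rotation angle in degrees, within (-90, 90).
#' @return Transformed crop, same shape.
#' @export
#' @examples
#' m <- matrix(runif(64, 0, 255), 8, 8)
#' identical(applyTransform(m, FALSE, 0), m)
applyTransform <- function(crop, flip = FALSE, angle = 0) {
  checkImage(crop)
  if (abs(angle) >= 90) stop("angle must be in (-90, 90)", call. = FALSE)
  out <- if (flip) crop[, rev(seq_len(ncol(crop))), drop = FALSE] else crop
  if (angle != 0) out <- rotate_replicate(out, angle)
  pmin(pmax(out, 0), 255)
}

# Ordered transform pool: flip varies slowest, angle fastest; entry 1 is the
# identity so the original counts toward its class multiplicity.
transformPool <- function(policy) {
  angles <- c(0, policy@rotationAngles)
  flips <- if (policy@flip) c(FALSE, TRUE) else FALSE
  data.frame(flip = rep(flips, each = length(angles)),
             angle = rep(angles, times = length(flips)))
}

#' Class-balancing augmentation of a training set
#'
#' Each crop of class \code{c} yields exactly \code{multiplicity[c]} output
#' crops. Transforms are drawn deterministically from the ordered pool
#' \{no flip, flip\} x \{0, rotation angles\}; when a multiplicity exceeds
#' the pool size, pool entries are reused with Gaussian angle jitter
#' (seeded) so the extra variants are distinct. Labels and exam identifiers
#' are preserved.
#'
#' @param train a \linkS4class{ToothCropSet}.
#' @param policy an \linkS4class{AugmentPolicy}.
#' @return The augmented \linkS4class{ToothCropSet}.
#' @export
#' @examples
#' crops <- generateLabeledCrops(c(normal = 2, incipient = 1, advanced = 1),
#'                               cropSize = 32, seed = 1)
#' length(augmentTrainingSet(crops, augmentPolicy()))  # 2*4 + 12 + 24
augmentTrainingSet <- function(train, policy = augmentPolicy()) {
  validObject(policy)
  if (length(train) == 0) stop("training set is empty", call. = FALSE)
  pool <- transformPool(policy)
  np <- nrow(pool)
  labs <- as.character(cropLabels(train))
  exams <- cropExams(train)
  imgs <- cropImages(train)
  withSeed(policy@seed, {
    outCrops <- vector("list", sum(policy@multiplicity[labs]))
    outLabs <- character(length(outCrops))
    outExams <- character(length(outCrops))
    o <- 0L
    for (i in seq_along(imgs)) {
      m <- policy@multiplicity[[labs[i]]]
      for (k in seq_len(m)) {
        o <- o + 1L
        if (k <= np) {
          fl <- pool$flip[k]; ang <- pool$angle[k]
        } else {
          base <- pool[((k - np - 1L) %% np) + 1L, ]
          fl <- base$flip
          ang <- base$angle + rnorm(1, 0, policy@angleJitterSd)
        }
        outCrops[[o]] <- if (!fl && ang == 0) imgs[[i]] else
          applyTransform(imgs[[i]], fl, ang)
        outLabs[o] <- labs[i]
        outExams[o] <- exams[i]
      }
    }
    toothCropSet(outCrops, outLabs, outExams)
  })
}
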