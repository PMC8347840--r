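#' @title Synthetic bitewing phantoms
#' @name phantom
#' @description Renders bitewing-like test images with exact ground truth:
#' bright tooth-shaped regions (rounded rectangles, i.e. superellipse masks)
#' in one or two arch rows on a dark background, separated by narrow gaps,
#' with optional darker lesion patches on approximal (lateral) tooth edges.
#' Lesion size is determined by the severity class: absent for
#' \code{normal}, small for \code{incipient}, large for \code{advanced},
#' which makes the classes separable by construction and every downstream
#' stage testable without patient data.
NULL

# Superellipse (exponent 4) foreground mask of size h x w.
superellipseMask <- function(h, w, exponent = 4) {
  y <- abs(seq(-1, 1, length.out = h))^exponent
  x <- abs(seq(-1, 1, length.out = w))^exponent
  outer(y, x, `+`) <= 1
}

# Draw one lesion on a lateral edge of a local tooth mask. Returns a logical
# matrix (same shape) of lesion pixels; empty for class "normal".
# Radius fractions (of tooth height) separate incipient from advanced.
drawLesion <- function(mask, label) {
  h <- nrow(mask); w <- ncol(mask)
  les <- matrix(FALSE, h, w)
  if (label == "normal") return(les)
  fr <- if (label == "incipient") runif(1, 0.09, 0.13) else runif(1, 0.20, 0.28)
  side <- sample(c("left", "right"), 1)
  cy <- round(runif(1, 0.30, 0.70) * h)
  cy <- min(max(cy, 2), h - 1)
  rowpix <- which(mask[cy, ])
  if (!length(rowpix)) rowpix <- which(mask[round(h / 2), ])
  cx <- if (side == "left") min(rowpix) else max(rowpix)
  a <- max(2, fr * h / 2)        # vertical semi-axis
  b <- max(2, 0.8 * a)           # horizontal semi-axis
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ell <- ((rr - cy) / a)^2 + ((cc - cx) / b)^2 <= 1
  les[ell & mask] <- TRUE
  les
}

# Render one tooth into the scene at (y0, x0) (1-based top-left).
paintTooth <- function(scene, y0, x0, h, w, label, k) {
  m <- superellipseMask(h, w)
  les <- drawLesion(m, label)
  ys <- y0:(y0 + h - 1); xs <- x0:(x0 + w - 1)
  sub <- scene$image[ys, xs]
  sub[m] <- scene$toothLevel
  sub[les] <- scene$lesionLevel
  scene$image[ys, xs] <- sub
  tm <- scene$toothMask[ys, xs]; tm[m] <- k
  scene$toothMask[ys, xs] <- tm
  lm <- scene$lesionMask[ys, xs]; lm[les] <- TRUE
  scene$lesionMask[ys, xs] <- lm
  scene
}

#' Generate a phantom bitewing with ground truth
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed integer seed; identical \code{(spec, seed)} give bit-identical
#'   output.
#' @param examId exam identifier recorded in the ground truth.
#' @return A \linkS4class{BitewingPhantom}.
#' @export
#' @examples
#' ph <- generateBitewing(phantomSpec(), seed = 1)
#' groundTruth(ph)
generateBitewing <- function(spec, seed, examId = sprintf("exam%04d", seed)) {
  validObject(spec)
  stages <- cariesStages()
  withSeed(seed, {
    H <- spec@height; W <- spec@width
    scene <- list(image = matrix(spec@backgroundLevel, H, W),
                  toothMask = matrix(0L, H, W),
                  lesionMask = matrix(FALSE, H, W),
                  toothLevel = spec@toothLevel,
                  lesionLevel = spec@lesionLevel)
    regions <- NULL
    k <- 0L
    bandH <- H / spec@rows
    for (r in seq_len(spec@rows)) {
      n <- spec@nTeethPerRow
      ws <- round(runif(n, spec@toothWidthRange[1], spec@toothWidthRange[2]))
      hs <- round(runif(n, spec@toothHeightRange[1],
                        min(spec@toothHeightRange[2], 0.92 * bandH)))
      margin <- floor((W - sum(ws) - (n - 1) * spec@gapWidth) / 2)
      if (margin < 1)
        stop("teeth cannot fit at requested geometry", call. = FALSE)
      bandTop <- floor((r - 1) * bandH)
      x0 <- margin + c(0, cumsum(ws[-n] + spec@gapWidth)) + 1
      for (t in seq_len(n)) {
        k <- k + 1L
        yc <- bandTop + bandH / 2 + runif(1, -0.04, 0.04) * bandH
        y0 <- round(yc - hs[t] / 2)
        y0 <- min(max(y0, bandTop + 2), bandTop + floor(bandH) - hs[t] - 1)
        label <- sample(stages, 1, prob = spec@classProbs)
        scene <- paintTooth(scene, y0, x0[t], hs[t], ws[t], label, k)
        regions <- rbind(regions,
          data.frame(examId = examId, r0 = y0 - 1L, c0 = x0[t] - 1L,
                     r1 = y0 - 1L + hs[t], c1 = x0[t] - 1L + ws[t],
                     label = label, stringsAsFactors = FALSE))
      }
    }
    img <- scene$image
    if (spec@noiseSd > 0)
      img <- pmin(pmax(img + rnorm(length(img), 0, spec@noiseSd), 0), 255)
    new("BitewingPhantom", image = img, regions = regions,
        toothMask = scene$toothMask, lesionMask = scene$lesionMask,
        spec = spec)
  })
}

#' Generate labeled single-tooth phantom crops
#'
#' Renders the requested number of tooth crops per severity class, each a
#' centred tooth on background with a class-determined lesion (absent /
#' small / large). Ground-truth lesion and tooth pixel fractions are
#' recorded in the crop metadata.
#'
#' @param nPerClass named counts per class, e.g. \code{c(normal = 290,
#'   incipient = 98, advanced = 47)}; missing names count as 0.
#' @param cropSize crop side length in pixels (minimum 24).
#' @param seed integer seed.
#' @param levels background / lesion / tooth pre-noise intensities.
#' @param noiseSd additive Gaussian noise sd.
#' @return A \linkS4class{ToothCropSet} with \code{meta} columns
#'   \code{toothFrac} and \code{lesionFrac}.
#' @export
#' @examples
#' crops <- generateLabeledCrops(c(normal = 4, incipient = 2, advanced = 2),
#'                               cropSize = 48, seed = 1)
#' table(cropLabels(crops))
generateLabeledCrops <- function(nPerClass, cropSize = 64, seed = 1L,
                                 levels = c(background = 40, lesion = 90,
                                            tooth = 200),
                                 noiseSd = 6) {
  stages <- cariesStages()
  counts <- stats::setNames(rep(0, 3), stages)
  if (is.null(names(nPerClass)) && length(nPerClass) == 3)
    names(nPerClass) <- stages
  if (!all(names(nPerClass) %in% stages))
    stop("nPerClass names must be caries stages", call. = FALSE)
  counts[names(nPerClass)] <- nPerClass
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (cropSize < 24)
    stop("cropSize too small to render a tooth (minimum 24 px)",
         call. = FALSE)
  withSeed(seed, {
    crops <- list(); labels <- character(); meta <- NULL
    i <- 0L
    for (cls in stages) {
      for (repI in seq_len(counts[[cls]])) {
        i <- i + 1L
        w <- round(runif(1, 0.50, 0.68) * cropSize)
        h <- round(runif(1, 0.68, 0.88) * cropSize)
        m <- superellipseMask(h, w)
        les <- drawLesion(m, cls)
        img <- matrix(levels[["background"]], cropSize, cropSize)
        y0 <- max(1, round((cropSize - h) / 2) + sample(-2:2, 1))
        x0 <- max(1, round((cropSize - w) / 2) + sample(-2:2, 1))
        y0 <- min(y0, cropSize - h + 1); x0 <- min(x0, cropSize - w + 1)
        ys <- y0:(y0 + h - 1); xs <- x0:(x0 + w - 1)
        sub <- img[ys, xs]
        sub[m] <- levels[["tooth"]]
        sub[les] <- levels[["lesion"]]
        img[ys, xs] <- sub
        if (noiseSd > 0)
          img <- pmin(pmax(img + rnorm(length(img), 0, noiseSd), 0), 255)
        crops[[i]] <- img
        labels[i] <- cls
        meta <- rbind(meta, data.frame(toothFrac = sum(m) / cropSize^2,
                                       lesionFrac = sum(les) / sum(m)))
      }
    }
    if (i == 0L)
      return(toothCropSet(list(), factor(character(),
                                         levels = stages), character()))
    toothCropSet(crops, labels, sprintf("syn%05d", seq_len(i)), meta)
  })
}

#' Write phantom ground truth as JSON
#'
#' One record per tooth: \code{exam_id}, \code{bbox} as
#' \code{[r0, c0, r1, c1]} (0-based half-open) and \code{label}.
#'
#' @param phantom a \linkS4class{BitewingPhantom}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeGroundTruth <- function(phantom, path) {
  recs <- lapply(seq_len(nrow(phantom@regions)), function(i) {
    r <- phantom@regions[i, ]
    list(exam_id = r$examId, bbox = c(r$r0, r$c0, r$r1, r$c1),
         label = r$label)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
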