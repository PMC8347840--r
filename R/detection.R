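#' @title Tooth detection on bitewing images
#' @name detection
#' @description The region-of-interest stage: contrast-limited adaptive
#' histogram equalization separates tooth from background tonalities, Otsu
#' thresholding binarizes the equalized image, morphology (erosion by a wide
#' flat rectangle, an opening, then a dilation) removes small spurious
#' regions while keeping neighbouring teeth disconnected, and connected
#' components above an area floor become per-tooth bounding boxes whose
#' crops are cut from the original (unequalized) image.
NULL

# Scale a pixel-unit parameter from the reference resolution to this image.
scalePx <- function(v, imageWidth, params) {
  pmax(1, round(v * imageWidth / params@referenceResolution[1]))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-local histogram equalization (CLAHE) with bilinear interpolation of
#' the tile mappings. Images whose size is not a multiple of the tile grid
#' are border-replicated to the next multiple and cropped back.
#'
#' @param image grayscale matrix in [0, 255].
#' @param params a \linkS4class{DetectionParams}; uses \code{eqTile}
#'   (rows, cols) and \code{eqClipLimit}.
#' @return Equalized image, same shape, intensities in [0, 255].
#' @export
adaptiveEqualize <- function(image, params = detectionParams()) {
  checkImage(image)
  nty <- params@eqTile[1]; ntx <- params@eqTile[2]
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 2 * nty || nc < 2 * ntx)
    stop("image too small for the equalization tile grid", call. = FALSE)
  padR <- (nty - nr %% nty) %% nty
  padC <- (ntx - nc %% ntx) %% ntx
  ri <- c(seq_len(nr), rep(nr, padR))
  ci <- c(seq_len(nc), rep(nc, padC))
  padded <- image[ri, ci, drop = FALSE] / 255
  eq <- EBImage::clahe(asEB(padded), nx = ntx, ny = nty, bins = 256,
                       limit = max(1, params@eqClipLimit * 256))
  out <- fromEB(eq)[seq_len(nr), seq_len(nc), drop = FALSE] * 255
  pmin(pmax(out, 0), 255)
}

#' Otsu thresholding
#'
#' Picks the threshold maximizing between-class variance over a 256-bin
#' histogram; the binary mask is \code{image > threshold}, so the bright
#' teeth are foreground (\code{TRUE}).
#'
#' @param image grayscale matrix in [0, 255] with at least two distinct
#'   values.
#' @return List with \code{threshold} (intensity) and \code{mask} (logical
#'   matrix).
#' @export
otsuThreshold <- function(image) {
  checkImage(image)
  if (length(unique(as.vector(image))) < 2)
    stop("degenerate histogram: image is constant", call. = FALSE)
  th <- EBImage::otsu(asEB(image / 255), range = c(0, 1), levels = 256) * 255
  list(threshold = th, mask = image > th)
}

ebErode <- function(m, kern) fromEB(EBImage::erode(asEB(m), t(kern))) > 0.5
ebDilate <- function(m, kern) fromEB(EBImage::dilate(asEB(m), t(kern))) > 0.5

diskKernel <- function(r) EBImage::makeBrush(2 * r + 1, shape = "disc")

#' Morphological refinement of the tooth mask
#'
#' Applies, in order: erosion by a wide flat rectangle (severs bridges
#' between adjacent teeth and removes elongated spurious regions), an
#' opening by a disk (eliminates remaining small regions; a closing variant
#' is selectable via \code{morphOp}), and a dilation by a smaller disk
#' (restores tooth borders removed by the erosion). All structuring-element
#' sizes are rescaled from the reference resolution to this image's width.
#'
#' @param mask logical matrix, \code{TRUE} = tooth foreground.
#' @param params a \linkS4class{DetectionParams}.
#' @return Refined logical mask, same shape.
#' @export
morphologicalRefine <- function(mask, params = detectionParams()) {
  if (!is.matrix(mask) || length(mask) == 0)
    stop("mask must be a non-empty matrix", call. = FALSE)
  mode(mask) <- "logical"
  w <- ncol(mask)
  seW <- scalePx(params@erosionSe[1], w, params)
  seH <- scalePx(params@erosionSe[2], w, params)
  rOpen <- scalePx(params@openingRadius, w, params)
  rDil <- scalePx(params@dilationRadius, w, params)
  if (seH > nrow(mask) || seW > ncol(mask) ||
      2 * rOpen + 1 > min(dim(mask)) || 2 * rDil + 1 > min(dim(mask)))
    stop("structuring element larger than image after scaling",
         call. = FALSE)
  num <- mask + 0
  rect <- matrix(1, seH, seW)
  out <- ebErode(num, rect)
  disk <- diskKernel(rOpen)
  out <- if (params@morphOp == "opening")
    ebDilate(ebErode(out + 0, disk) + 0, disk)
  else
    ebErode(ebDilate(out + 0, disk) + 0, disk)
  ebDilate(out + 0, diskKernel(rDil))
}

#' Extract tooth regions from a refined mask
#'
#' Labels 8-connected foreground components, drops those below the minimum
#' area fraction, and returns per-component bounding boxes, masks and crops
#' from the original (unequalized) image. Regions are ordered left-to-right
#' by \code{(c0, r0)}.
#'
#' @param mask refined logical mask.
#' @param original the original grayscale image (same shape).
#' @param params a \linkS4class{DetectionParams}.
#' @return A \linkS4class{ToothRegionSet} (possibly empty).
#' @export
extractToothRegions <- function(mask, original, params = detectionParams()) {
  if (!all(dim(mask) == dim(original)))
    stop("mask and original image must have the same shape", call. = FALSE)
  mode(mask) <- "logical"
  lab <- cc_label8(mask)
  nlab <- max(lab)
  if (nlab == 0)
    return(new("ToothRegionSet", bbox = matrix(0L, 0, 4), area = numeric(),
               masks = list(), crops = list()))
  floorArea <- params@minAreaFraction * length(mask)
  bb <- NULL; areas <- numeric(); masks <- list(); crops <- list()
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < floorArea) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    bb <- rbind(bb, c(r0 - 1L, c0 - 1L, r1, c1))
    areas <- c(areas, nrow(idx))
    masks <- c(masks, list(lab[r0:r1, c0:c1, drop = FALSE] == k))
    crops <- c(crops, list(original[r0:r1, c0:c1, drop = FALSE]))
  }
  if (is.null(bb))
    return(new("ToothRegionSet", bbox = matrix(0L, 0, 4), area = numeric(),
               masks = list(), crops = list()))
  colnames(bb) <- c("r0", "c0", "r1", "c1")
  ord <- order(bb[, "c0"], bb[, "r0"])
  new("ToothRegionSet", bbox = bb[ord, , drop = FALSE], area = areas[ord],
      masks = masks[ord], crops = crops[ord])
}

#' Detect teeth on a bitewing image
#'
#' Full detection pipeline: \code{\link{adaptiveEqualize}} then
#' \code{\link{otsuThreshold}} then \code{\link{morphologicalRefine}} then
#' \code{\link{extractToothRegions}}. Fully deterministic.
#'
#' @param image grayscale matrix in [0, 255].
#' @param params a \linkS4class{DetectionParams}.
#' @return A \linkS4class{ToothRegionSet}.
#' @export
#' @examples
#' ph <- generateBitewing(phantomSpec(nTeethPerRow = 3), seed = 7)
#' regs <- detectTeeth(phantomImage(ph))
#' length(regs)
detectTeeth <- function(image, params = detectionParams()) {
  eq <- adaptiveEqualize(image, params)
  th <- otsuThreshold(eq)
  refined <- morphologicalRefine(th$mask, params)
  extractToothRegions(refined, image, params)
}

#' Write detected regions to JSON and CSV
#'
#' @param regions a \linkS4class{ToothRegionSet}.
#' @param jsonPath,csvPath output paths (either may be \code{NULL}).
#' @return Invisibly, a data.frame of boxes and areas.
#' @export
writeToothRegions <- function(regions, jsonPath = NULL, csvPath = NULL) {
  df <- as.data.frame(bboxes(regions))
  df$area <- regionAreas(regions)
  if (!is.null(jsonPath)) {
    recs <- lapply(seq_len(nrow(df)), function(i)
      list(bbox = as.integer(df[i, 1:4]), area = df$area[i]))
    jsonlite::write_json(recs, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath)) write.csv(df, csvPath, row.names = FALSE)
  invisible(df)
}
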