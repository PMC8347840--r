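#' @useDynLib BitewingCaries, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif pnorm psignrank pt qt uniroot rbinom
#' @importFrom utils head write.csv
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# EBImage stores images as (x, y) = (col, row); the package uses R's
# (row, col). These two helpers convert at the boundary.
asEB <- function(m) EBImage::Image(t(m))
fromEB <- function(img) t(EBImage::imageData(img))

checkImage <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop("image must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(image)) || min(image) < 0 || max(image) > 255)
    stop("image intensities must be finite and within [0, 255]",
         call. = FALSE)
  invisible(TRUE)
}

#' Read a grayscale image
#'
#' Reads PNG/JPEG/TIFF via EBImage; color images are averaged to gray.
#'
#' @param path file path.
#' @return Numeric matrix of intensities in [0, 255], rows = image rows.
#' @export
readGrayImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3) d <- apply(d, c(1, 2), mean)
  t(d) * 255
}

#' Write a grayscale image
#'
#' @param image numeric matrix in [0, 255].
#' @param path output path (format from extension, e.g. \code{.png}).
#' @return Invisibly, \code{path}.
#' @export
writeGrayImage <- function(image, path) {
  checkImage(image)
  EBImage::writeImage(asEB(image / 255), path)
  invisible(path)
}

# Pad to a square by replicating border rows/cols (split evenly).
padToSquare <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr == nc) return(m)
  if (nr < nc) {
    extra <- nc - nr
    top <- extra %/% 2
    ri <- c(rep(1L, top), seq_len(nr), rep(nr, extra - top))
    m[ri, , drop = FALSE]
  } else {
    extra <- nr - nc
    left <- extra %/% 2
    ci <- c(rep(1L, left), seq_len(nc), rep(nc, extra - left))
    m[, ci, drop = FALSE]
  }
}

# Pad-to-square then bilinear-resize a crop to S x S, mapped to [-0.5, 0.5].
prepNetInput <- function(crop, size) {
  sq <- padToSquare(crop) / 255
  if (nrow(sq) != size) {
    r <- EBImage::resize(asEB(sq), w = size, h = size)
    sq <- fromEB(r)
  }
  sq - 0.5
}

#' Intersection-over-union of two bounding boxes
#'
#' Boxes are 0-based half-open \code{(r0, c0, r1, c1)}.
#'
#' @param a,b numeric vectors of length 4.
#' @return IoU in [0, 1].
#' @export
#' @examples
#' bboxIoU(c(0, 0, 10, 10), c(5, 5, 15, 15))
bboxIoU <- function(a, b) {
  ih <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iw <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ih * iw
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
    inter
  if (union <= 0) return(0)
  inter / union
}

#' Match detected regions to ground-truth boxes by IoU
#'
#' Greedy one-to-one matching in decreasing IoU order.
#'
#' @param regions a \linkS4class{ToothRegionSet} or an n x 4 bbox matrix.
#' @param truth ground-truth bbox matrix (m x 4) or a
#'   \linkS4class{BitewingPhantom}.
#' @param minIoU matches below this IoU are discarded.
#' @return data.frame with columns \code{truthIdx, regionIdx, iou}.
#' @export
matchRegionsToTruth <- function(regions, truth, minIoU = 0.0) {
  rb <- if (is(regions, "ToothRegionSet")) bboxes(regions) else regions
  tb <- if (is(truth, "BitewingPhantom")) bboxes(truth) else truth
  nr <- nrow(rb); nt <- nrow(tb)
  if (nr == 0 || nt == 0)
    return(data.frame(truthIdx = integer(), regionIdx = integer(),
                      iou = numeric()))
  iou <- matrix(0, nt, nr)
  for (i in seq_len(nt)) for (j in seq_len(nr))
    iou[i, j] <- bboxIoU(tb[i, ], rb[j, ])
  out <- data.frame(truthIdx = integer(), regionIdx = integer(),
                    iou = numeric())
  repeat {
    m <- which(iou == max(iou), arr.ind = TRUE)[1, , drop = TRUE]
    if (iou[m[1], m[2]] <= minIoU && nrow(out) > 0) break
    if (iou[m[1], m[2]] <= minIoU) break
    out <- rbind(out, data.frame(truthIdx = m[1], regionIdx = m[2],
                                 iou = iou[m[1], m[2]]))
    iou[m[1], ] <- -1
    iou[, m[2]] <- -1
    if (all(iou < 0) || nrow(out) == min(nt, nr)) break
  }
  out[order(out$truthIdx), , drop = FALSE]
}
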