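#' @title Accessors and methods for package classes
#' @name accessors
#' @rdname accessors
#' @description \code{cropImages}, \code{cropLabels} and \code{cropExams}
#' extract the crop matrices, severity labels and exam identifiers of a
#' \linkS4class{ToothCropSet}; \code{bboxes} and \code{regionAreas} extract
#' the bounding boxes and areas of a \linkS4class{ToothRegionSet};
#' \code{groundTruth} returns the ground-truth region table of a
#' \linkS4class{BitewingPhantom}; \code{phantomImage} its pixel matrix;
#' \code{trainingLog} a model's training log.
#' @param x the object.
#' @param i index vector.
#' @param j,drop,... ignored (vector-style subsetting).
#' @return The extracted component; \code{[} returns an object of the same
#'   class.
NULL

#' @rdname accessors
#' @export
setGeneric("cropImages", function(x) standardGeneric("cropImages"))
#' @rdname accessors
#' @export
setGeneric("cropLabels", function(x) standardGeneric("cropLabels"))
#' @rdname accessors
#' @export
setGeneric("cropExams", function(x) standardGeneric("cropExams"))
#' @rdname accessors
#' @export
setGeneric("bboxes", function(x) standardGeneric("bboxes"))
#' @rdname accessors
#' @export
setGeneric("regionAreas", function(x) standardGeneric("regionAreas"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setMethod("cropImages", "ToothCropSet", function(x) x@crops)
#' @rdname accessors
#' @export
setMethod("cropLabels", "ToothCropSet", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("cropExams", "ToothCropSet", function(x) x@examIds)
#' @rdname accessors
#' @export
setMethod("bboxes", "ToothRegionSet", function(x) x@bbox)
#' @rdname accessors
#' @export
setMethod("regionAreas", "ToothRegionSet", function(x) x@area)
#' @rdname accessors
#' @export
setMethod("bboxes", "BitewingPhantom",
          function(x) as.matrix(x@regions[, c("r0", "c0", "r1", "c1")]))
#' @rdname accessors
#' @export
setMethod("groundTruth", "BitewingPhantom", function(x) x@regions)
#' @rdname accessors
#' @export
setMethod("phantomImage", "BitewingPhantom", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("trainingLog", "CariesModel", function(x) x@log)

#' @rdname accessors
#' @export
setMethod("length", "ToothCropSet", function(x) length(x@crops))
#' @rdname accessors
#' @export
setMethod("length", "ToothRegionSet", function(x) nrow(x@bbox))

#' @rdname accessors
#' @export
setMethod("[", "ToothCropSet", function(x, i, j, ..., drop = TRUE) {
  meta <- if (nrow(x@meta)) x@meta[i, , drop = FALSE] else x@meta
  toothCropSet(x@crops[i], x@labels[i], x@examIds[i], meta)
})

#' Concatenate ToothCropSets
#' @param x,... \linkS4class{ToothCropSet} objects.
#' @return The combined \linkS4class{ToothCropSet} (metadata is kept only
#'   when present for all parts).
#' @export
setMethod("c", "ToothCropSet", function(x, ...) {
  parts <- c(list(x), list(...))
  metas <- lapply(parts, function(p) p@meta)
  meta <- if (all(vapply(metas, nrow, 1L) > 0)) do.call(rbind, metas)
          else data.frame()
  toothCropSet(do.call(c, lapply(parts, function(p) p@crops)),
               unlist(lapply(parts, function(p) as.character(p@labels))),
               unlist(lapply(parts, function(p) p@examIds)), meta)
})

setMethod("show", "ToothCropSet", function(object) {
  cat("ToothCropSet with", length(object), "crops\n")
  if (length(object)) {
    print(table(object@labels))
    cat("exams:", length(unique(object@examIds)), "\n")
  }
})

setMethod("show", "ToothRegionSet", function(object) {
  cat("ToothRegionSet with", length(object), "regions\n")
  if (length(object)) {
    df <- as.data.frame(object@bbox)
    df$area <- object@area
    print(utils::head(df, 8))
    if (length(object) > 8) cat("...\n")
  }
})

setMethod("show", "BitewingPhantom", function(object) {
  cat(sprintf("BitewingPhantom %dx%d px, %d teeth (%s)\n",
              nrow(object@image), ncol(object@image), nrow(object@regions),
              paste(names(table(object@regions$label)),
                    table(object@regions$label), sep = ":", collapse = " ")))
})

setMethod("show", "CariesModel", function(object) {
  cat(sprintf("CariesModel <%s>, %s%s\n", object@architecture,
              if (object@trained) "trained" else "untrained",
              if (object@diverged) " (diverged)" else ""))
  if (object@trained && nrow(object@log)) {
    va <- object@log$valAccuracy
    va <- va[!is.na(va)]
    if (length(va)) cat(sprintf("final validation accuracy: %.3f\n",
                                va[length(va)]))
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %gx%g px, %g row(s) x %g teeth\n", object@width,
              object@height, object@rows, object@nTeethPerRow))
})
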