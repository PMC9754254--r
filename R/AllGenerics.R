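#' Read a rectangular pixel region from a slide
#'
#' Returns an \code{h x w x 3} array. Coordinates are 0-based from the
#' top-left corner; parts of the requested window that fall outside the slide
#' are padded with white (1.0), so the result never has fewer pixels than
#' requested.
#'
#' @param x a \linkS4class{SlideRaster}.
#' @param x0,y0 0-based pixel origin of the window.
#' @param w,h window width and height in pixels.
#' @return numeric array \code{h x w x 3}.
#' @export
setGeneric("readRegion", function(x, x0, y0, w, h) standardGeneric("readRegion"))

#' @rdname readRegion
setMethod("readRegion", "SlideRaster", function(x, x0, y0, w, h) {
  stopifnot(w >= 1, h >= 1, x0 >= 0, y0 >= 0)
  out <- array(1, dim = c(h, w, 3))
  d <- dim(x@pixels)
  ys <- seq.int(y0 + 1, length.out = h)
  xs <- seq.int(x0 + 1, length.out = w)
  yok <- ys <= d[1]
  xok <- xs <= d[2]
  if (any(yok) && any(xok))
    out[which(yok), which(xok), ] <- x@pixels[ys[yok], xs[xok], , drop = FALSE]
  out
})

#' Slide identifier accessor
#' @param x a SlideRaster, PatchDB, ReconstructedSlide or SlidePrediction.
#' @return character scalar.
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))

#' @rdname slideId
setMethod("slideId", "SlideRaster", function(x) x@slideId)
#' @rdname slideId
setMethod("slideId", "PatchDB", function(x) x@slideId)
#' @rdname slideId
setMethod("slideId", "ReconstructedSlide", function(x) x@slideId)
#' @rdname slideId
setMethod("slideId", "SlidePrediction", function(x) x@slideId)

#' Slide dimensions in pixels
#' @param x a \linkS4class{SlideRaster}.
#' @return integer width (\code{slideWidth}) or height (\code{slideHeight}).
#' @export
setGeneric("slideWidth", function(x) standardGeneric("slideWidth"))
#' @rdname slideWidth
setMethod("slideWidth", "SlideRaster", function(x) dim(x@pixels)[2])
#' @rdname slideWidth
#' @export
setGeneric("slideHeight", function(x) standardGeneric("slideHeight"))
#' @rdname slideWidth
setMethod("slideHeight", "SlideRaster", function(x) dim(x@pixels)[1])

#' Patch record table accessor
#' @param x a \linkS4class{PatchDB}.
#' @return data.frame of patch records (one row per tile, sorted by
#'   patch_index).
#' @export
setGeneric("patchRecords", function(x) standardGeneric("patchRecords"))
#' @rdname patchRecords
setMethod("patchRecords", "PatchDB", function(x) x@records)

#' Patch prediction table accessor
#' @param x a \linkS4class{PatchDB}.
#' @return data.frame with columns patch_index, p_M, p_D, p_N, argmax_class.
#' @export
setGeneric("patchPredictions", function(x) standardGeneric("patchPredictions"))
#' @rdname patchPredictions
setMethod("patchPredictions", "PatchDB", function(x) x@predictions)

#' Confidence grid accessor
#' @param x a \linkS4class{ReconstructedSlide}.
#' @return numeric array nRows x nCols x 3.
#' @export
setGeneric("confidenceGrid", function(x) standardGeneric("confidenceGrid"))
#' @rdname confidenceGrid
setMethod("confidenceGrid", "ReconstructedSlide", function(x) x@grid)

#' Final class accessor
#' @param x a \linkS4class{SlidePrediction}.
#' @return character scalar in \{M, D, N\}.
#' @export
setGeneric("finalClass", function(x) standardGeneric("finalClass"))
#' @rdname finalClass
setMethod("finalClass", "SlidePrediction", function(x) x@finalClass)

#' Confusion matrix accessor
#' @param x a \linkS4class{QCMetrics}.
#' @return 3x3 matrix, dx rows by AI columns (M, D, N).
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
#' @rdname confusionMatrix
setMethod("confusionMatrix", "QCMetrics", function(x) x@confusion)

setMethod("show", "SlideRaster", function(object) {
  cat(sprintf("SlideRaster '%s' %dx%d px (%s)\n", object@slideId,
              slideWidth(object), slideHeight(object), object@source))
})

setMethod("show", "PatchDB", function(object) {
  cat(sprintf("PatchDB '%s': %dx%d grid of %d px tiles (%d tissue), %s\n",
              object@slideId, object@nCols, object@nRows, object@patchSize,
              sum(object@records$tissue_flag),
              if (nrow(object@predictions)) sprintf(
                "%d patch predictions", nrow(object@predictions))
              else "unpredicted"))
})

setMethod("show", "ReconstructedSlide", function(object) {
  d <- dim(object@grid)
  s <- apply(object@grid, c(1, 2), sum)
  cat(sprintf("ReconstructedSlide '%s': %dx%d grid, %d tissue cells\n",
              object@slideId, d[2], d[1], sum(s > 0.5)))
})

setMethod("show", "SlidePrediction", function(object) {
  cat(sprintf("SlidePrediction '%s': %s (M=%.3f D=%.3f N=%.3f) [%s]%s\n",
              object@slideId, object@finalClass, object@confidence[1],
              object@confidence[2], object@confidence[3], object@modelId,
              if (length(object@flags))
                paste0(" flags: ", paste(object@flags, collapse = ","))
              else ""))
})

setMethod("show", "QCMetrics", function(object) {
  cat(sprintf(paste0(
    "QCMetrics on %d slides: ternary accuracy %.2f%%, NPV %.2f%%, ",
    "binary (M vs non-M) accuracy %.2f%%\n"),
    object@nIncluded, 100 * object@ternaryAccuracy, 100 * object@npv,
    100 * object@binaryAccuracy))
  if (sum(object@excluded))
    cat("  excluded:", paste(names(object@excluded), object@excluded,
                             sep = "=", collapse = ", "), "\n")
  print(object@confusion)
})
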