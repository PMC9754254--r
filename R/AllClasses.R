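#' SlideRaster: an in-memory RGB slide image
#'
#' Desk-scale stand-in for a whole-slide image: a dense H x W x 3 array of
#' values in [0, 1] with a slide identifier. Coordinates are 0-based with the
#' origin at the top-left corner; \code{\link{readRegion}} pads reads beyond
#' the slide edge with white, mirroring how edge tiles are handled downstream.
#'
#' @slot slideId character slide identifier.
#' @slot pixels numeric array, height x width x 3, values in [0, 1].
#' @slot source character tag for the pixel source ("memory", "png", "tiff").
#' @export
setClass("SlideRaster",
  representation(slideId = "character", pixels = "array", source = "character"),
  prototype(source = "memory"))

setValidity("SlideRaster", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3)
    return("pixels must be a height x width x 3 array")
  if (length(object@slideId) != 1 || !nzchar(object@slideId))
    return("slideId must be a non-empty string")
  rng <- range(object@pixels)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("pixel values must lie in [0, 1]")
  TRUE
})

#' PatchDB: index/location database for the tiles of one slide
#'
#' Per-slide table of patch records (index, grid position, pixel origin,
#' tissue flag) plus, after prediction, per-patch class-confidence rows and
#' the slide-level class. The patch index is row-major:
#' \code{patch_index = grid_row * nCols + grid_col}, tiles are half-open
#' \code{[x0, x0 + size)} and jointly cover the slide without overlap.
#'
#' @slot slideId character.
#' @slot patchSize integer tile edge in pixels.
#' @slot nCols,nRows integer grid dimensions.
#' @slot records data.frame with columns patch_index, grid_col, grid_row,
#'   x0, y0, size, tissue_flag.
#' @slot predictions data.frame with columns patch_index, p_M, p_D, p_N,
#'   argmax_class (zero rows until \code{\link{predictPatches}} is run).
#' @slot slideClass character, NA until slide-level prediction is stored.
#' @export
setClass("PatchDB",
  representation(slideId = "character", patchSize = "integer",
                 nCols = "integer", nRows = "integer",
                 records = "data.frame", predictions = "data.frame",
                 slideClass = "character"),
  prototype(predictions = data.frame(patch_index = integer(),
                                     p_M = numeric(), p_D = numeric(),
                                     p_N = numeric(),
                                     argmax_class = character()),
            slideClass = NA_character_))

setValidity("PatchDB", function(object) {
  r <- object@records
  need <- c("patch_index", "grid_col", "grid_row", "x0", "y0", "size",
            "tissue_flag")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) != object@nCols * object@nRows)
    return("records must hold one row per grid cell")
  if (!identical(r$patch_index, r$grid_row * object@nCols + r$grid_col))
    return("patch_index must equal grid_row * nCols + grid_col")
  if (!identical(r$x0, r$grid_col * object@patchSize) ||
      !identical(r$y0, r$grid_row * object@patchSize))
    return("pixel origins must equal grid position times patch size")
  if (nrow(object@predictions) &&
      !all(object@predictions$patch_index %in% r$patch_index))
    return("predictions reference unknown patch_index")
  TRUE
})

#' ReconstructedSlide: patch confidences arranged on the tile grid
#'
#' A compact representation of one slide: an nRows x nCols x 3 array holding
#' the patch classifier's (M, D, N) confidence vector at each tissue cell.
#' Background / unclassified cells are exact zero vectors, which no softmax
#' output can produce, so tissue and background remain distinguishable.
#'
#' @slot slideId character.
#' @slot grid numeric array nRows x nCols x 3; tissue cells sum to 1 (within
#'   1e-6), background cells sum to 0.
#' @export
setClass("ReconstructedSlide",
  representation(slideId = "character", grid = "array"))

setValidity("ReconstructedSlide", function(object) {
  d <- dim(object@grid)
  if (length(d) != 3 || d[3] != 3)
    return("grid must be nRows x nCols x 3")
  s <- apply(object@grid, c(1, 2), sum)
  ok <- abs(s - 1) < 1e-6 | abs(s) < 1e-12
  if (!all(ok))
    return("every cell must sum to 1 (tissue) or exactly 0 (background)")
  TRUE
})

#' SlidePrediction: final slide-level classification
#'
#' @slot slideId character.
#' @slot finalClass "M", "D" or "N".
#' @slot confidence named numeric triple (p_M, p_D, p_N) at slide level.
#' @slot modelId organ route of the model used ("gastric"/"colorectal"), or
#'   "oracle"/"none" for ground-truth and degenerate paths.
#' @slot flags character vector, e.g. "no_tissue" for an empty slide.
#' @export
setClass("SlidePrediction",
  representation(slideId = "character", finalClass = "character",
                 confidence = "numeric", modelId = "character",
                 flags = "character"),
  prototype(flags = character()))

setValidity("SlidePrediction", function(object) {
  if (!object@finalClass %in% QC_CLASSES)
    return("finalClass must be one of M, D, N")
  if (length(object@confidence) != 3 ||
      abs(sum(object@confidence) - 1) > 1e-6)
    return("confidence must be a probability triple summing to 1")
  TRUE
})

#' QCMetrics: aggregate concordance metrics for a QC batch
#'
#' @slot confusion 3x3 matrix; rows are the diagnosis class, columns the AI
#'   class, both ordered M, D, N; counts only records included after
#'   exclusions.
#' @slot ternaryAccuracy trace / total.
#' @slot npv fraction of AI-N slides whose diagnosis class is also N.
#' @slot binaryAccuracy,binarySensitivity,binarySpecificity metrics after
#'   collapsing \{D, N\} to non-M, with M as the positive class.
#' @slot excluded named integer counts by exclusion reason.
#' @slot nIncluded integer, confusion-matrix total.
#' @export
setClass("QCMetrics",
  representation(confusion = "matrix", ternaryAccuracy = "numeric",
                 npv = "numeric", binaryAccuracy = "numeric",
                 binarySensitivity = "numeric", binarySpecificity = "numeric",
                 excluded = "integer", nIncluded = "integer"))

setValidity("QCMetrics", function(object) {
  if (!all(dim(object@confusion) == c(3, 3)))
    return("confusion must be 3x3 (dx rows, AI columns; M, D, N)")
  if (sum(object@confusion) != object@nIncluded)
    return("nIncluded must equal the confusion-matrix total")
  rates <- c(object@ternaryAccuracy, object@npv, object@binaryAccuracy,
             object@binarySensitivity, object@binarySpecificity)
  if (any(!is.na(rates) & (rates < 0 | rates > 1)))
    return("all rates must lie in [0, 1]")
  TRUE
})
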