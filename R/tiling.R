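# Patch maker: converts a slide into indexed 256x256 tiles with a persistent
# index/location database (the PatchDB). Tiles are 0-based, half-open
# [x0, x0 + size) x [y0, y0 + size), non-overlapping, and jointly cover the
# slide; edge tiles are padded with white rather than dropped, so lesions at
# the slide border stay visible to the classifier.

#' Pixel origin of a grid cell, and its inverse
#'
#' \code{patchOrigin} maps a (column, row) grid position to the 0-based pixel
#' origin of its tile; \code{patchIndexAt} maps a pixel coordinate back to
#' the row-major patch index. For all cells,
#' \code{patchIndexAt(patchOrigin(c, r))} is the identity.
#'
#' @param gridCol,gridRow 0-based grid position.
#' @param size tile edge in pixels.
#' @param x,y 0-based pixel coordinates.
#' @param nCols,nRows grid dimensions.
#' @return \code{patchOrigin}: integer c(x0, y0); \code{patchIndexAt}:
#'   integer patch index \code{gridRow * nCols + gridCol}.
#' @examples
#' patchOrigin(3, 1, 256)           # c(768, 256)
#' patchIndexAt(768, 256, 256, 4)   # 7
#' @export
patchOrigin <- function(gridCol, gridRow, size = 256L) {
  stopifnot(gridCol >= 0, gridRow >= 0)
  c(x0 = as.integer(gridCol * size), y0 = as.integer(gridRow * size))
}

#' @rdname patchOrigin
#' @export
patchIndexAt <- function(x, y, size = 256L, nCols, nRows = Inf) {
  gc <- x %/% size; gr <- y %/% size
  if (any(x < 0 | y < 0 | gc >= nCols | gr >= nRows))
    stop("coordinates outside the tile grid")
  as.integer(gr * nCols + gc)
}

#' Tissue detection for one patch
#'
#' A patch counts as tissue when the fraction of its pixels darker than
#' \code{lumaThreshold} (Rec. 601 luminance) exceeds
#' \code{minTissueFraction}. With \code{mode = "off"} every patch counts as
#' tissue, for pipelines that classify background too.
#'
#' @param patchPixels size x size x 3 array in [0, 1].
#' @param tissueParams list with \code{lumaThreshold} (default 230/255),
#'   \code{minTissueFraction} (default 0.05) and \code{mode} ("luminance" or
#'   "off").
#' @return logical.
#' @export
isTissue <- function(patchPixels,
                     tissueParams = list(lumaThreshold = 230 / 255,
                                         minTissueFraction = 0.05,
                                         mode = "luminance")) {
  if (identical(tissueParams$mode, "off")) return(TRUE)
  luma <- luminance(patchPixels)
  mean(luma < (tissueParams$lumaThreshold %||% (230 / 255))) >
    (tissueParams$minTissueFraction %||% 0.05)
}

#' Tile a slide into a PatchDB
#'
#' Builds the ceil(width/size) x ceil(height/size) tile grid, evaluates the
#' tissue detector on every tile (edge tiles white-padded), and returns the
#' per-slide index/location database.
#'
#' @param raster a \linkS4class{SlideRaster}.
#' @param patchSize tile edge in pixels (default 256).
#' @param tissueParams see \code{\link{isTissue}}.
#' @return a \linkS4class{PatchDB}.
#' @examples
#' r <- SlideRaster(array(1, c(512, 1024, 3)), "demo")
#' tileSlide(r)  # 4x2 grid, 8 patches, no tissue
#' @export
tileSlide <- function(raster, patchSize = 256L,
                      tissueParams = list(lumaThreshold = 230 / 255,
                                          minTissueFraction = 0.05,
                                          mode = "luminance")) {
  w <- slideWidth(raster); h <- slideHeight(raster)
  nCols <- as.integer(ceiling(w / patchSize))
  nRows <- as.integer(ceiling(h / patchSize))
  grid <- expand.grid(grid_col = 0:(nCols - 1), grid_row = 0:(nRows - 1))
  grid <- grid[order(grid$grid_row, grid$grid_col), ]
  rec <- data.frame(
    patch_index = grid$grid_row * nCols + grid$grid_col,
    grid_col = grid$grid_col, grid_row = grid$grid_row,
    x0 = grid$grid_col * as.integer(patchSize),
    y0 = grid$grid_row * as.integer(patchSize),
    size = as.integer(patchSize))
  rec$tissue_flag <- vapply(seq_len(nrow(rec)), function(i)
    isTissue(readRegion(raster, rec$x0[i], rec$y0[i], patchSize, patchSize),
             tissueParams), logical(1))
  rownames(rec) <- NULL
  new("PatchDB", slideId = slideId(raster),
      patchSize = as.integer(patchSize), nCols = nCols, nRows = nRows,
      records = rec)
}

#' Extract the pixel array of one patch
#'
#' @param raster a \linkS4class{SlideRaster}.
#' @param db its \linkS4class{PatchDB}.
#' @param patchIndex patch index.
#' @return size x size x 3 array (white-padded at slide edges).
#' @export
patchPixels <- function(raster, db, patchIndex) {
  r <- db@records[db@records$patch_index == patchIndex, ]
  if (!nrow(r)) stop("unknown patch_index ", patchIndex)
  readRegion(raster, r$x0, r$y0, r$size, r$size)
}

#' Extract labeled training patches from an annotated slide
#'
#' Implements the annotation-restricted training-data rule: for class N, all
#' tissue patches of the slide are labeled N (no annotation needed); for
#' classes M and D, only patches whose overlap with the annotation polygons
#' reaches \code{overlapMin} of the tile area are selected, labeled with the
#' slide's class, and nothing outside the annotations is used.
#'
#' @param raster a \linkS4class{SlideRaster}.
#' @param annotations list of lesion polygons (vertex matrices), or NULL for
#'   class N.
#' @param classLabel "M", "D" or "N".
#' @param patchSize tile edge in pixels.
#' @param overlapMin annotation-overlap threshold (default 0.25).
#' @param tissueParams see \code{\link{isTissue}}.
#' @return list with \code{patches} (list of pixel arrays), \code{labels}
#'   (character), and \code{indices} (patch indices in the slide grid).
#' @export
extractTrainingPatches <- function(raster, annotations = NULL, classLabel,
                                   patchSize = 256L, overlapMin = 0.25,
                                   tissueParams = list(
                                     lumaThreshold = 230 / 255,
                                     minTissueFraction = 0.05,
                                     mode = "luminance")) {
  stopifnot(classLabel %in% QC_CLASSES)
  if (classLabel != "N" && (is.null(annotations) || !length(annotations)))
    stop("annotations are required for class ", classLabel, " slides")
  db <- tileSlide(raster, patchSize, tissueParams)
  rec <- db@records
  if (classLabel == "N") {
    keep <- rec$patch_index[rec$tissue_flag]
  } else {
    ov <- tileOverlapFractions(annotations, slideWidth(raster),
                               slideHeight(raster), patchSize)
    # ov is nRows x nCols; flatten row-major to align with patch_index
    ovVec <- as.vector(t(ov))
    keep <- rec$patch_index[ovVec[rec$patch_index + 1] >= overlapMin]
  }
  list(patches = lapply(keep, function(i) patchPixels(raster, db, i)),
       labels = rep(classLabel, length(keep)),
       indices = keep)
}

#' Persist / reload a PatchDB as CSV
#'
#' Two CSV files are written next to each other: the patch record table and,
#' if present, the prediction table; a small JSON sidecar carries the slide
#' metadata. A written-then-reloaded database is field-identical.
#'
#' @param db a \linkS4class{PatchDB}.
#' @param path base path (without extension).
#' @return \code{writePatchDB}: the base path, invisibly;
#'   \code{readPatchDB}: the \linkS4class{PatchDB}.
#' @export
writePatchDB <- function(db, path) {
  utils::write.csv(db@records, paste0(path, ".records.csv"),
                   row.names = FALSE)
  utils::write.csv(db@predictions, paste0(path, ".predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(slideId = db@slideId, patchSize = db@patchSize,
                            nCols = db@nCols, nRows = db@nRows,
                            slideClass = db@slideClass),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePatchDB
#' @export
readPatchDB <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  rec <- utils::read.csv(paste0(path, ".records.csv"))
  rec$patch_index <- as.integer(rec$patch_index)
  for (cl in c("grid_col", "grid_row", "x0", "y0", "size"))
    rec[[cl]] <- as.integer(rec[[cl]])
  pred <- utils::read.csv(paste0(path, ".predictions.csv"),
                          colClasses = c(patch_index = "integer",
                                         p_M = "numeric", p_D = "numeric",
                                         p_N = "numeric",
                                         argmax_class = "character"))
  new("PatchDB", slideId = meta$slideId,
      patchSize = as.integer(meta$patchSize), nCols = as.integer(meta$nCols),
      nRows = as.integer(meta$nRows), records = rec, predictions = pred,
      slideClass = if (is.null(meta$slideClass)) NA_character_
                   else meta$slideClass)
}
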