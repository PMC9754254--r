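# Heatmap overlay: per-patch rectangles colored red (argmax M) or blue
# (argmax D); N and background are fully transparent, so the overlay can be
# masked on and off over the slide thumbnail without hiding negative tissue.

HEAT_COLORS <- list(M = c(1, 0, 0), D = c(0, 0, 1))

#' Render the patch-prediction heatmap overlay
#'
#' @param predictions data.frame with patch_index and argmax_class (e.g.
#'   \code{patchPredictions(db)}).
#' @param db the slide's \linkS4class{PatchDB}.
#' @param scale linear scale of the overlay relative to the slide (default
#'   0.5, the review-thumbnail magnification); each patch becomes a
#'   \code{patchSize * scale} pixel square.
#' @param opacity alpha of colored rectangles, in [0, 1].
#' @return RGBA array (height x width x 4) covering the scaled slide extent.
#' @export
renderHeatmap <- function(predictions, db, scale = 0.5, opacity = 0.45) {
  stopifnot(scale > 0, opacity >= 0, opacity <= 1)
  cell <- max(1L, round(db@patchSize * scale))
  H <- db@nRows * cell; W <- db@nCols * cell
  ov <- array(0, dim = c(H, W, 4))
  if (nrow(predictions)) {
    for (k in seq_len(nrow(predictions))) {
      cls <- predictions$argmax_class[k]
      if (!cls %in% names(HEAT_COLORS)) next  # N / background: no heat
      gr <- predictions$patch_index[k] %/% db@nCols
      gc <- predictions$patch_index[k] %% db@nCols
      ys <- gr * cell + seq_len(cell)
      xs <- gc * cell + seq_len(cell)
      for (ch in 1:3) ov[ys, xs, ch] <- HEAT_COLORS[[cls]][ch]
      ov[ys, xs, 4] <- opacity
    }
  }
  ov
}

#' Compose a heatmap overlay onto a slide thumbnail
#'
#' Standard source-over alpha blending; with the overlay "masked off" (not
#' composed) the thumbnail is returned unchanged, mirroring the viewer's
#' heatmap on/off toggle.
#'
#' @param thumbnail RGB array (e.g. \code{\link{slideThumbnail}}).
#' @param overlay RGBA array from \code{\link{renderHeatmap}} (cropped or
#'   padded to the thumbnail extent as needed).
#' @param maskOn logical; FALSE returns the bare thumbnail.
#' @return RGB array.
#' @export
composeHeatmap <- function(thumbnail, overlay, maskOn = TRUE) {
  if (!maskOn) return(thumbnail)
  h <- min(dim(thumbnail)[1], dim(overlay)[1])
  w <- min(dim(thumbnail)[2], dim(overlay)[2])
  out <- thumbnail
  a <- overlay[seq_len(h), seq_len(w), 4]
  for (ch in 1:3)
    out[seq_len(h), seq_len(w), ch] <-
      overlay[seq_len(h), seq_len(w), ch] * a +
      thumbnail[seq_len(h), seq_len(w), ch] * (1 - a)
  out
}

#' Write a heatmap (or composed image) as PNG
#'
#' @param img RGB or RGBA array in [0, 1].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeHeatmapPNG <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}
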