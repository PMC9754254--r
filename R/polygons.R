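# Polygon primitives for lesion annotations.
#
# Annotations are simple polygons in 0-based pixel coordinates (x right,
# y down), stored as two-column matrices of vertices. Rasterization uses
# even-odd scanline filling against pixel centers (x + 0.5, y + 0.5), and is
# the single definition of "pixels inside a polygon" used by both the
# synthetic generator and the annotation-restricted patch extractor, so
# ground-truth labels and training-patch selection can never disagree about
# boundary pixels.

#' Regular polygon approximating a disc
#'
#' @param cx,cy centre in pixel coordinates.
#' @param r radius in pixels.
#' @param nVertices number of vertices.
#' @return two-column matrix (x, y) of vertices, counter-clockwise.
#' @export
discPolygon <- function(cx, cy, r, nVertices = 32L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Rasterize polygons onto a pixel grid
#'
#' Even-odd scanline fill: a pixel belongs to the mask when its centre lies
#' inside an odd number of polygon boundaries of at least one polygon in the
#' list (polygons are unioned).
#'
#' @param polygons list of two-column (x, y) vertex matrices.
#' @param width,height raster dimensions in pixels.
#' @return logical matrix \code{height x width}.
#' @export
rasterizePolygons <- function(polygons, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  for (poly in polygons) {
    if (is.null(poly) || nrow(poly) < 3) next
    x <- poly[, 1]; y <- poly[, 2]
    nv <- length(x)
    x2 <- x[c(2:nv, 1)]; y2 <- y[c(2:nv, 1)]
    rowy <- seq_len(height) - 0.5
    cross <- vector("list", height)
    for (e in seq_len(nv)) {
      if (y[e] == y2[e]) next  # horizontal edges never cross a scanline
      ylo <- min(y[e], y2[e]); yhi <- max(y[e], y2[e])
      rows <- which(rowy >= ylo & rowy < yhi)
      if (!length(rows)) next
      xc <- x[e] + (rowy[rows] - y[e]) * (x2[e] - x[e]) / (y2[e] - y[e])
      for (k in seq_along(rows))
        cross[[rows[k]]] <- c(cross[[rows[k]]], xc[k])
    }
    for (ry in seq_len(height)) {
      cr <- cross[[ry]]
      if (length(cr) < 2) next
      cr <- sort(cr)
      for (p in seq(1, length(cr) - 1, by = 2)) {
        # pixel centres x + 0.5 strictly inside [cr[p], cr[p + 1])
        lo <- ceiling(cr[p] - 0.5 + 1e-9)
        hi <- floor(cr[p + 1] - 0.5 - 1e-9)
        if (hi >= lo) {
          lo <- max(lo, 0); hi <- min(hi, width - 1)
          if (hi >= lo) mask[ry, (lo:hi) + 1] <- TRUE
        }
      }
    }
  }
  mask
}

#' Fraction of a tile's area covered by a polygon set
#'
#' Pixel-counting overlap between each tile of a grid and the rasterized
#' polygon union; used for the annotation-overlap patch labeling rule.
#'
#' @param polygons list of vertex matrices.
#' @param width,height slide dimensions in pixels.
#' @param patchSize tile edge in pixels.
#' @return matrix \code{nRows x nCols} of per-tile covered-area fractions
#'   (relative to the full \code{patchSize^2} tile area, so edge tiles that
#'   extend past the slide can never reach 1).
#' @export
tileOverlapFractions <- function(polygons, width, height, patchSize = 256L) {
  mask <- rasterizePolygons(polygons, width, height)
  nCols <- ceiling(width / patchSize)
  nRows <- ceiling(height / patchSize)
  out <- matrix(0, nrow = nRows, ncol = nCols)
  for (r in seq_len(nRows)) {
    ys <- ((r - 1) * patchSize + 1):min(r * patchSize, height)
    for (cc in seq_len(nCols)) {
      xs <- ((cc - 1) * patchSize + 1):min(cc * patchSize, width)
      out[r, cc] <- sum(mask[ys, xs]) / patchSize^2
    }
  }
  out
}
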