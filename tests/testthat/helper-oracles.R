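# Independent oracles used by the tests; kept free of the package's own
# rasterization / aggregation code paths.

# crossing-number point-in-polygon over a full pixel grid: a pixel belongs
# to the mask when its centre (x + 0.5, y + 0.5 in 0-based coordinates) is
# inside the polygon
pipMask <- function(poly, width, height) {
  px <- rep(seq_len(width) - 0.5, each = height)   # 0-based centres
  py <- rep(seq_len(height) - 0.5, times = width)
  x <- poly[, 1]; y <- poly[, 2]
  nv <- nrow(poly)
  x2 <- x[c(2:nv, 1)]; y2 <- y[c(2:nv, 1)]
  inside <- rep(FALSE, width * height)
  for (e in seq_len(nv)) {
    crosses <- ((y[e] > py) != (y2[e] > py)) &
      (px < x[e] + (py - y[e]) * (x2[e] - x[e]) / (y2[e] - y[e]))
    inside <- xor(inside, crosses)
  }
  matrix(inside, nrow = height, ncol = width)
}

pipMaskUnion <- function(polys, width, height) {
  out <- matrix(FALSE, height, width)
  for (p in polys) out <- out | pipMask(p, width, height)
  out
}

# per-tile covered-area fractions recomputed from the oracle mask
oracleTileFractions <- function(polys, width, height, patchSize) {
  mask <- pipMaskUnion(polys, width, height)
  nCols <- ceiling(width / patchSize); nRows <- ceiling(height / patchSize)
  out <- matrix(0, nRows, nCols)
  for (r in seq_len(nRows)) for (cc in seq_len(nCols)) {
    ys <- ((r - 1) * patchSize + 1):min(r * patchSize, height)
    xs <- ((cc - 1) * patchSize + 1):min(cc * patchSize, width)
    out[r, cc] <- sum(mask[ys, xs]) / patchSize^2
  }
  out
}

# brute-force class aggregation: scan the priority list top-down
aggregateOracle <- function(classes) {
  for (cl in c("M", "U", "D", "N")) if (cl %in% classes) return(cl)
  stop("empty")
}

# flat mid-gray test slide (all tissue under the default luminance detector)
grayRaster <- function(w, h, value = 0.5, id = "gray") {
  SlideRaster(array(value, dim = c(h, w, 3)), id)
}
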