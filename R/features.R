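# Hand-crafted texture descriptors feeding the reference classifiers.
#
# The patch classifier is a pluggable interface; the reference
# implementation summarizes each 256x256 patch by a short vector of
# stain/texture statistics (luminance moments, dark-nucleus density at two
# thresholds, channel means, gradient energy, local-contrast quantiles) and
# feeds it to a single-hidden-layer neural network. The descriptors target
# what separates the three lesion textures: nuclear density, chromatin
# darkness and spatial irregularity.

# feature vector for one patch (H x W x 3 array in [0,1])
patchFeatureVector <- function(px) {
  luma <- luminance(px)
  v <- as.vector(luma)
  gx <- luma[, -1] - luma[, -ncol(luma)]
  gy <- luma[-1, ] - luma[-nrow(luma), ]
  dark1 <- mean(v < 0.55)            # dense chromatin
  dark2 <- mean(v < 0.35)            # very dark nuclei
  white <- mean(v > 0.90)            # background / lumen
  tis <- v[v <= 0.90]
  q <- if (length(tis) > 4) stats::quantile(tis, c(0.05, 0.25, 0.5, 0.75))
       else rep(1, 4)
  c(mean_luma = mean(v), sd_luma = stats::sd(v),
    dark_frac = dark1, verydark_frac = dark2, white_frac = white,
    mean_r = mean(px[, , 1]), mean_g = mean(px[, , 2]),
    mean_b = mean(px[, , 3]),
    grad_energy = mean(abs(gx)) + mean(abs(gy)),
    grad_p95 = stats::quantile(abs(gx), 0.95),
    q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4])
}

# feature matrix for a list of patches
patchFeatureMatrix <- function(patches) {
  t(vapply(patches, patchFeatureVector, numeric(14)))
}

# descriptor of a normalized reconstruction (T x T x 3 array) for the
# slide-level classifier: per-class mass, argmax fractions and the spatial
# coherence (largest 4-connected blob) of positive evidence
slideFeatureVector <- function(normGrid) {
  s <- normGrid[, , 1] + normGrid[, , 2] + normGrid[, , 3]
  tissue <- s > 0.5
  nt <- sum(tissue)
  if (nt == 0) return(c(n_tissue = 0, rep(0, 11)))
  pm <- normGrid[, , 1][tissue]; pd <- normGrid[, , 2][tissue]
  pn <- normGrid[, , 3][tissue]
  am <- apply(normGrid, c(1, 2), function(p)
    if (sum(p) > 0.5) which.max(p) else 0L)
  blob <- function(cls) {
    m <- am == cls
    if (!any(m)) return(0)
    lab <- EBImage::bwlabel(m * 1)
    max(tabulate(lab[lab > 0])) / nt
  }
  c(n_tissue = nt / length(s),
    mean_pm = mean(pm), mean_pd = mean(pd), mean_pn = mean(pn),
    max_pm = max(pm), max_pd = max(pd),
    frac_am_m = mean(am[tissue] == 1), frac_am_d = mean(am[tissue] == 2),
    frac_pm_hi = mean(pm > 0.5), frac_pd_hi = mean(pd > 0.5),
    blob_m = blob(1L), blob_d = blob(2L))
}
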