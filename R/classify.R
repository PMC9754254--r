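# Patch-level and slide-level classifiers.
#
#' @importFrom nnet nnet class.ind
NULL

#
# Both classifiers are pluggable: any object with a predictProbs() method
# mapping pixel arrays (patch model) or normalized reconstructions (slide
# model) to (M, D, N) probability triples can stand behind the pipeline.
# The reference implementation is texture features + a single-hidden-layer
# neural network (multinomial softmax output), trained with class-balanced
# sampling and one round of loss-based noise removal.

#' Class-balanced subsampling of a labeled patch set
#'
#' Randomly samples, without replacement, an equal number of patches per
#' class (the minimum class count), to balance the training pool and
#' minimize class bias.
#'
#' @param labels character vector over M/D/N.
#' @param seed integer seed.
#' @return integer vector of kept indices (sorted).
#' @export
balanceSample <- function(labels, seed = 1L) {
  tab <- table(factor(labels, levels = QC_CLASSES))
  if (any(tab == 0))
    stop("every class must be present to balance; missing: ",
         paste(names(tab)[tab == 0], collapse = ", "))
  k <- min(tab)
  withSeed(seed, {
    keep <- unlist(lapply(QC_CLASSES, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) == k) idx else sample(idx, k)
    }))
  })
  sort(keep)
}

#' Train the reference patch classifier
#'
#' Trains a texture-feature neural network on labeled patches. The training
#' pool is class-balanced first (unless \code{balance = FALSE}). With
#' \code{noiseRemovalFraction} q > 0, a warm-up model is fitted, the
#' top-q fraction of training patches by cross-entropy loss is removed (the
#' label-noise heuristic), and the final model is retrained on the
#' remainder.
#'
#' @param patches list of patch pixel arrays.
#' @param labels character vector over M/D/N, parallel to \code{patches}.
#' @param config list: \code{seed} (default 1), \code{balance} (default
#'   TRUE), \code{noiseRemovalFraction} in [0, 0.1] (default 0),
#'   \code{hiddenUnits} (default 8), \code{maxIterations} (default 200),
#'   \code{warmupIterations} (default 60), \code{decay} (default 5e-4).
#' @param minPerClass minimum patches required per class.
#' @return a \code{patchModel} object (features scaler + nnet fit + config).
#' @export
trainPatchClassifier <- function(patches, labels, config = list(),
                                 minPerClass = 10L) {
  cfg <- utils::modifyList(list(seed = 1L, balance = TRUE,
                                noiseRemovalFraction = 0,
                                hiddenUnits = 8L, maxIterations = 200L,
                                warmupIterations = 60L, decay = 5e-4),
                           config)
  if (cfg$noiseRemovalFraction < 0 || cfg$noiseRemovalFraction > 0.1)
    stop("noiseRemovalFraction must lie in [0, 0.1]")
  tab <- table(factor(labels, levels = QC_CLASSES))
  if (any(tab < minPerClass))
    stop("need at least ", minPerClass, " patches per class; got ",
         paste(tab, collapse = "/"))
  if (isTRUE(cfg$balance)) {
    keep <- balanceSample(labels, seed = cfg$seed)
    patches <- patches[keep]; labels <- labels[keep]
  }
  X <- patchFeatureMatrix(patches)
  mdl <- .fitFeatureNet(X, labels, cfg)
  mdl$kind <- "patch"
  mdl$nTrained <- nrow(mdl$X) %||% nrow(X)
  mdl$X <- NULL
  class(mdl) <- "patchModel"
  mdl
}

# shared fitting core: scale features, optional warmup + top-q loss trim,
# final multinomial net
.fitFeatureNet <- function(X, labels, cfg) {
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv < 1e-9] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  y <- factor(labels, levels = QC_CLASSES)
  Y <- nnet::class.ind(y)
  fitOnce <- function(Xm, Ym, iters, seed) {
    withSeed(seed, nnet::nnet(Xm, Ym, size = cfg$hiddenUnits,
                              softmax = TRUE, decay = cfg$decay,
                              maxit = iters, trace = FALSE, MaxNWts = 5000))
  }
  removed <- integer()
  if (cfg$noiseRemovalFraction > 0) {
    warm <- fitOnce(Xs, Y, cfg$warmupIterations, subSeed(cfg$seed, "warmup"))
    probs <- stats::predict(warm, Xs)
    eps <- 1e-12
    loss <- -log(pmax(probs[cbind(seq_len(nrow(Xs)),
                                  as.integer(y))], eps))
    nDrop <- floor(cfg$noiseRemovalFraction * nrow(Xs))
    if (nDrop > 0) {
      removed <- order(loss, decreasing = TRUE)[seq_len(nDrop)]
      Xs <- Xs[-removed, , drop = FALSE]
      Y <- Y[-removed, , drop = FALSE]
      y <- y[-removed]
    }
  }
  fit <- fitOnce(Xs, Y, cfg$maxIterations, subSeed(cfg$seed, "final"))
  list(fit = fit, center = mu, scale = sdv, config = cfg,
       removed = removed, X = Xs)
}

# probability triples from a feature matrix
.netProbs <- function(model, X) {
  Xs <- scale(X, center = model$center, scale = model$scale)
  p <- stats::predict(model$fit, Xs)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  p <- pmax(p, 0)
  p / rowSums(p)
}

#' Predict class probabilities for a list of patches
#'
#' @param model a \code{patchModel}.
#' @param patches list of patch pixel arrays.
#' @return data.frame with p_M, p_D, p_N and argmax_class per patch.
#' @export
predictPatchSet <- function(model, patches) {
  stopifnot(inherits(model, "patchModel"))
  P <- .netProbs(model, patchFeatureMatrix(patches))
  data.frame(p_M = P[, 1], p_D = P[, 2], p_N = P[, 3],
             argmax_class = apply(P, 1, argmaxClass),
             stringsAsFactors = FALSE)
}

#' Predict class probabilities for the patches of a slide
#'
#' Runs the patch model over every classified patch of a tiled slide and
#' stores the predictions (probability triple + argmax class, severity
#' tie-break M > D > N) in the PatchDB alongside the index/location records.
#'
#' @param model a \code{patchModel}.
#' @param db the slide's \linkS4class{PatchDB}.
#' @param raster the \linkS4class{SlideRaster}.
#' @param skipBackground if TRUE (default), background patches are not
#'   classified and are absent from the prediction table.
#' @return the \linkS4class{PatchDB} with its \code{predictions} filled.
#' @export
predictPatches <- function(model, db, raster, skipBackground = TRUE) {
  stopifnot(inherits(model, "patchModel"))
  rec <- db@records
  idx <- if (skipBackground) rec$patch_index[rec$tissue_flag]
         else rec$patch_index
  if (!length(idx)) {
    db@predictions <- db@predictions[0, ]
    return(db)
  }
  patches <- lapply(idx, function(i) patchPixels(raster, db, i))
  dims <- vapply(patches, function(p) dim(p)[1], numeric(1))
  if (length(unique(dims)) != 1)
    stop("patch size mismatch between model input and tiles")
  P <- .netProbs(model, patchFeatureMatrix(patches))
  db@predictions <- data.frame(
    patch_index = idx, p_M = P[, 1], p_D = P[, 2], p_N = P[, 3],
    argmax_class = apply(P, 1, argmaxClass), stringsAsFactors = FALSE)
  validObject(db)
  db
}

#' Build the reconstructed slide from patch predictions
#'
#' Pure placement: each patch's probability triple is written at its
#' (grid_row, grid_col) cell of an nRows x nCols x 3 array; background and
#' unclassified cells stay exact zero. The result is independent of the
#' order of the prediction rows and preserves the probabilities without
#' renormalization.
#'
#' @param predictions data.frame with patch_index, p_M, p_D, p_N (e.g.
#'   \code{patchPredictions(db)}).
#' @param db the slide's \linkS4class{PatchDB}.
#' @return a \linkS4class{ReconstructedSlide}.
#' @export
buildReconstruction <- function(predictions, db) {
  grid <- array(0, dim = c(db@nRows, db@nCols, 3))
  if (nrow(predictions)) {
    if (!all(predictions$patch_index %in% db@records$patch_index))
      stop("prediction references unknown patch_index")
    gr <- predictions$patch_index %/% db@nCols
    gc <- predictions$patch_index %% db@nCols
    for (k in seq_len(nrow(predictions))) {
      grid[gr[k] + 1, gc[k] + 1, ] <- c(predictions$p_M[k],
                                        predictions$p_D[k],
                                        predictions$p_N[k])
    }
  }
  new("ReconstructedSlide", slideId = db@slideId, grid = grid)
}

#' Normalize a reconstruction to a fixed grid
#'
#' The slide classifier needs a fixed-size input while tile grids vary with
#' slide size: grids no larger than the target are centred and zero-padded;
#' larger grids are first reduced by area averaging (source cells grouped
#' into target bins per axis).
#'
#' @param rs a \linkS4class{ReconstructedSlide}.
#' @param target integer c(rows, cols), default c(64, 64).
#' @return numeric array target[1] x target[2] x 3.
#' @export
normalizeReconstruction <- function(rs, target = c(64L, 64L)) {
  g <- rs@grid
  d <- dim(g)
  if (d[1] > target[1] || d[2] > target[2]) {
    rb <- floor(seq(0, d[1] - 1) * target[1] / d[1])
    cb <- floor(seq(0, d[2] - 1) * target[2] / d[2])
    out <- array(0, dim = c(target, 3))
    cnt <- matrix(0, target[1], target[2])
    for (r in seq_len(d[1])) for (cc in seq_len(d[2])) {
      out[rb[r] + 1, cb[cc] + 1, ] <- out[rb[r] + 1, cb[cc] + 1, ] + g[r, cc, ]
      cnt[rb[r] + 1, cb[cc] + 1] <- cnt[rb[r] + 1, cb[cc] + 1] + 1
    }
    for (ch in 1:3) out[, , ch] <- out[, , ch] / pmax(cnt, 1)
    g <- out
    d <- dim(g)
  }
  full <- array(0, dim = c(target, 3))
  r0 <- (target[1] - d[1]) %/% 2
  c0 <- (target[2] - d[2]) %/% 2
  full[r0 + seq_len(d[1]), c0 + seq_len(d[2]), ] <- g
  full
}

#' Train the slide-level classifier
#'
#' Fits the reference feature network on normalized reconstructions with
#' known slide labels. Models are trained per organ route; the caller is
#' responsible for passing only slides of one organ.
#'
#' @param reconstructions list of \linkS4class{ReconstructedSlide} (or
#'   already-normalized arrays).
#' @param labels character slide classes over M/D/N.
#' @param config as in \code{\link{trainPatchClassifier}} (noise removal is
#'   available but defaults to 0 here too).
#' @param target normalization target grid.
#' @return a \code{slideModel} object.
#' @export
trainSlideClassifier <- function(reconstructions, labels, config = list(),
                                 target = c(64L, 64L)) {
  cfg <- utils::modifyList(list(seed = 1L, balance = FALSE,
                                noiseRemovalFraction = 0,
                                hiddenUnits = 6L, maxIterations = 300L,
                                warmupIterations = 60L, decay = 1e-3),
                           config)
  if (any(!QC_CLASSES %in% labels))
    stop("every class must be present among the training slides")
  norm <- lapply(reconstructions, function(r)
    if (is(r, "ReconstructedSlide")) normalizeReconstruction(r, target)
    else r)
  X <- t(vapply(norm, slideFeatureVector, numeric(12)))
  if (isTRUE(cfg$balance)) {
    keep <- balanceSample(labels, seed = cfg$seed)
    X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  }
  mdl <- .fitFeatureNet(X, labels, cfg)
  mdl$X <- NULL
  mdl$kind <- "slide"
  mdl$target <- target
  class(mdl) <- "slideModel"
  mdl
}

#' End-to-end slide prediction
#'
#' Runs the full operational path for one slide: tile, classify patches,
#' reconstruct, normalize, slide-classify; all three information layers
#' (patch records, patch predictions, slide class) end up in the returned
#' PatchDB. A slide with no tissue patches is assigned the defined fallback
#' class N with flag \code{"no_tissue"}.
#'
#' @param models named list with elements \code{gastric} and/or
#'   \code{colorectal}, each \code{list(patch = patchModel, slide =
#'   slideModel)}.
#' @param raster a \linkS4class{SlideRaster}.
#' @param organ "gastric" or "colorectal" (selects the model).
#' @param patchSize tile edge.
#' @param tissueParams see \code{\link{isTissue}}.
#' @return list: \code{prediction} (a \linkS4class{SlidePrediction}),
#'   \code{db} (the filled \linkS4class{PatchDB}), \code{reconstruction}.
#' @export
predictSlide <- function(models, raster, organ = c("gastric", "colorectal"),
                         patchSize = 256L,
                         tissueParams = list(lumaThreshold = 230 / 255,
                                             minTissueFraction = 0.05,
                                             mode = "luminance")) {
  organ <- match.arg(organ)
  mdl <- models[[organ]]
  if (is.null(mdl))
    stop("no model available for organ route '", organ, "'")
  db <- tileSlide(raster, patchSize, tissueParams)
  if (!any(db@records$tissue_flag)) {
    pred <- new("SlidePrediction", slideId = slideId(raster),
                finalClass = "N", confidence = c(M = 0, D = 0, N = 1),
                modelId = organ, flags = "no_tissue")
    db@slideClass <- "N"
    return(list(prediction = pred, db = db,
                reconstruction = buildReconstruction(db@predictions, db)))
  }
  db <- predictPatches(mdl$patch, db, raster)
  rs <- buildReconstruction(db@predictions, db)
  norm <- normalizeReconstruction(rs, mdl$slide$target)
  P <- .netProbs(mdl$slide, matrix(slideFeatureVector(norm), nrow = 1))
  cls <- argmaxClass(P[1, ])
  db@slideClass <- cls
  pred <- new("SlidePrediction", slideId = slideId(raster),
              finalClass = cls,
              confidence = c(M = P[1, 1], D = P[1, 2], N = P[1, 3]),
              modelId = organ)
  list(prediction = pred, db = db, reconstruction = rs)
}

#' Save / load a model set
#'
#' Model checkpoints are single-file RDS archives bundling configuration and
#' weights for both organ routes.
#'
#' @param models named list as in \code{\link{predictSlide}}.
#' @param path output .rds path.
#' @return \code{saveModels}: path invisibly; \code{loadModels}: the list.
#' @export
saveModels <- function(models, path) {
  saveRDS(models, path)
  invisible(path)
}

#' @rdname saveModels
#' @export
loadModels <- function(path) readRDS(path)
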