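# Convenience layer: train and evaluate the reference models on synthetic
# corpora, mirroring the clinical three-step recipe (patch maker -> patch
# classifier -> slide classifier on reconstructions) with separate models per
# organ route.

#' Train the reference model set on synthetic data
#'
#' For each organ route, generates a balanced synthetic patch pool, trains
#' the patch classifier (with loss-based noise removal), runs it over a
#' synthetic slide corpus to build reconstructions, and trains the
#' slide-level classifier on them. Everything is seeded and in-memory.
#'
#' @param seed master seed; all sub-streams derive from it.
#' @param nPatchPerClass training patches per class and organ.
#' @param nSlidesPerClass training slides per class and organ.
#' @param noiseRemovalFraction top-loss fraction trimmed after warm-up.
#' @param lesionFractions lesion coverages cycled over the M/D training
#'   slides.
#' @return named list (gastric, colorectal) of
#'   \code{list(patch = patchModel, slide = slideModel)}, directly usable by
#'   \code{\link{predictSlide}} and \code{\link{runDailyQC}}.
#' @export
trainReferenceModels <- function(seed = 1L, nPatchPerClass = 350L,
                                 nSlidesPerClass = 16L,
                                 noiseRemovalFraction = 0.02,
                                 lesionFractions = c(0.3, 0.4, 0.5, 0.6)) {
  models <- list()
  for (organ in c("gastric", "colorectal")) {
    pool <- generatePatchSet(nPatchPerClass,
                             seed = subSeed(seed, paste0("patch-", organ)))
    patchModel <- trainPatchClassifier(
      pool$patches, pool$labels,
      config = list(seed = subSeed(seed, paste0("pfit-", organ)),
                    noiseRemovalFraction = noiseRemovalFraction))
    recons <- list(); labels <- character()
    for (cls in QC_CLASSES) {
      for (i in seq_len(nSlidesPerClass)) {
        lf <- lesionFractions[(i - 1) %% length(lesionFractions) + 1]
        spec <- syntheticSpec(
          seed = subSeed(seed, paste(organ, cls, i)), organ = organ,
          slideClass = cls, lesionFraction = lf)
        sl <- generateSlide(spec)
        db <- tileSlide(sl$raster, spec$patchSize)
        db <- predictPatches(patchModel, db, sl$raster)
        recons[[length(recons) + 1]] <- buildReconstruction(db@predictions, db)
        labels <- c(labels, cls)
      }
    }
    slideModel <- trainSlideClassifier(
      recons, labels,
      config = list(seed = subSeed(seed, paste0("sfit-", organ))))
    models[[organ]] <- list(patch = patchModel, slide = slideModel)
  }
  models
}

#' Evaluate the reference models on fresh synthetic data
#'
#' Measures held-out patch-level accuracy (fresh patch pool, generator
#' labels as truth) and slide-level accuracy (fresh slide corpus run through
#' the full tile/predict/reconstruct/classify path).
#'
#' @param models model set from \code{\link{trainReferenceModels}}.
#' @param seed evaluation seed (use a different stream than training).
#' @param nPatchPerClass held-out patches per class (split over organs).
#' @param nSlidesPerClass held-out slides per class and organ.
#' @return list: \code{patchAccuracy}, \code{slideAccuracy}, \code{nPatches},
#'   \code{nSlides}, and \code{slides} (per-slide truth/prediction table).
#' @export
evaluateReferenceModels <- function(models, seed = 999L,
                                    nPatchPerClass = 100L,
                                    nSlidesPerClass = 11L) {
  correct <- 0L; totalP <- 0L
  for (organ in names(models)) {
    pool <- generatePatchSet(nPatchPerClass,
                             seed = subSeed(seed, paste0("evalp-", organ)))
    pred <- predictPatchSet(models[[organ]]$patch, pool$patches)
    correct <- correct + sum(pred$argmax_class == pool$labels)
    totalP <- totalP + length(pool$labels)
  }
  rows <- list()
  for (organ in names(models)) {
    for (cls in QC_CLASSES) {
      for (i in seq_len(nSlidesPerClass)) {
        lf <- c(0.35, 0.45, 0.55)[(i - 1) %% 3 + 1]
        spec <- syntheticSpec(
          seed = subSeed(seed, paste("eval", organ, cls, i)), organ = organ,
          slideClass = cls, lesionFraction = lf)
        sl <- generateSlide(spec)
        out <- predictSlide(models, sl$raster, organ)
        rows[[length(rows) + 1]] <- data.frame(
          organ = organ, truth = cls,
          predicted = finalClass(out$prediction), stringsAsFactors = FALSE)
      }
    }
  }
  slides <- do.call(rbind, rows)
  list(patchAccuracy = correct / totalP,
       slideAccuracy = mean(slides$predicted == slides$truth),
       nPatches = totalP, nSlides = nrow(slides), slides = slides)
}

#' Ground-truth oracle classifier for a corpus
#'
#' Returns a function \code{(slideId, organ) -> class} that looks the slide
#' up in the corpus manifest and returns its planted class -- a stand-in for
#' a perfect image model, used to isolate text-side errors in QC drills.
#'
#' @param manifest corpus manifest from \code{\link{generateCorpus}}.
#' @return classifier function usable as \code{models} in
#'   \code{\link{runDailyQC}}.
#' @export
oracleClassifier <- function(manifest) {
  lookup <- stats::setNames(manifest$slide_class, manifest$slide_id)
  function(sid, organ) {
    cls <- lookup[[sid]]
    if (is.null(cls)) stop("slide not in manifest: ", sid)
    cls
  }
}
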