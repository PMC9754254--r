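# Trained reference models and their evaluation are expensive, and several
# test files exercise them; train once per test run and cache.

.qcCache <- new.env(parent = emptyenv())

# study-condition sizes: ~2,000 training patches (333 per class per organ),
# 150 training slides (25 per class per organ), 66 held-out evaluation slides
cachedModels <- function() {
  if (is.null(.qcCache$models))
    .qcCache$models <- trainReferenceModels(seed = 20240101,
                                            nPatchPerClass = 333L,
                                            nSlidesPerClass = 25L)
  .qcCache$models
}

cachedEvaluation <- function() {
  if (is.null(.qcCache$eval))
    .qcCache$eval <- evaluateReferenceModels(cachedModels(), seed = 77,
                                             nPatchPerClass = 100L,
                                             nSlidesPerClass = 11L)
  .qcCache$eval
}

# the daily-QC drill corpus: 60 primary specimens written to disk once
cachedBatch <- function() {
  if (is.null(.qcCache$batch)) {
    dir <- file.path(tempdir(), "qc-batch")
    manifest <- generateCorpus(
      60, classMix = c(M = 0.2, D = 0.3, N = 0.5),
      organMix = c(gastric = 0.5, colorectal = 0.5),
      seed = 424242, dir = dir, serialRate = 0.1)
    .qcCache$batch <- list(dir = dir, manifest = manifest)
  }
  .qcCache$batch
}

# deterministic error-injection plan over the batch: two missed-lesion text
# records, one entry error, one switched pair (five error slides in all)
injectionPlan <- function(manifest) {
  prim <- manifest[!duplicated(manifest$block_id), ]
  dSlides <- prim$slide_id[prim$slide_class == "D"]
  mSlides <- prim$slide_id[prim$slide_class == "M"]
  nSlides <- prim$slide_id[prim$slide_class == "N"]
  list(wrongClassIds = c(dSlides[1], mSlides[1]),
       entryErrorIds = nSlides[1],
       switchedPairs = list(c(dSlides[2], nSlides[2])))
}

injectedErrorIds <- function(plan) {
  c(plan$wrongClassIds, plan$entryErrorIds, unlist(plan$switchedPairs))
}

cachedBatchRecords <- function() {
  if (is.null(.qcCache$batchRecords)) {
    b <- cachedBatch()
    plan <- injectionPlan(b$manifest)
    .qcCache$batchRecords <- list(
      plan = plan,
      records = emitDxRecords(b$manifest,
                              entryErrorIds = plan$entryErrorIds,
                              wrongClassIds = plan$wrongClassIds,
                              switchedPairs = plan$switchedPairs,
                              seed = 515151))
  }
  .qcCache$batchRecords
}
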