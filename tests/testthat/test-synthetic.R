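# Synthetic slide generator: determinism, planted geometry, corpus plumbing.

smallSpec <- function(seed, cls = "N", ...) {
  syntheticSpec(seed = seed, widthPx = 512L, heightPx = 512L,
                slideClass = cls, ...)
}

test_that("identical spec and seed give byte-identical slides and truth", {
  a <- generateSlide(smallSpec(3, "D", lesionFraction = 0.5))
  b <- generateSlide(smallSpec(3, "D", lesionFraction = 0.5))
  expect_identical(a$raster@pixels, b$raster@pixels)
  expect_identical(a$groundTruth$labelGrid, b$groundTruth$labelGrid)
  expect_identical(a$groundTruth$diagnosis, b$groundTruth$diagnosis)
})

test_that("a negative slide has only N tissue labels and no lesion polygons", {
  sl <- generateSlide(smallSpec(1, "N"))
  gt <- sl$groundTruth
  expect_length(gt$polygons, 0)
  expect_true(all(gt$labelGrid %in% c("N", "background")))
  expect_gt(sum(gt$labelGrid == "N"), 0)
})

test_that("lesion coverage of tissue patches tracks the requested fraction", {
  sl <- generateSlide(syntheticSpec(seed = 7, slideClass = "M",
                                    lesionFraction = 0.3))
  gt <- sl$groundTruth
  tissue <- gt$labelGrid != "background"
  frac <- mean(gt$labelGrid[tissue] == "M")
  expect_lt(abs(frac - 0.3), 0.1)
})

test_that("ground-truth labels agree with an independent polygon oracle", {
  # recompute the per-tile lesion coverage from the emitted polygons with a
  # crossing-number rasterizer and re-derive the label grid
  sl <- generateSlide(syntheticSpec(seed = 5, widthPx = 768L, heightPx = 512L,
                                    slideClass = "D", lesionFraction = 0.4))
  gt <- sl$groundTruth
  expect_gt(length(gt$polygons), 0)
  ov <- oracleTileFractions(gt$polygons, 768, 512, gt$patchSize)
  tissue <- gt$tissueFractions >= gt$tissueMin
  lab <- matrix("background", nrow(ov), ncol(ov))
  lab[tissue] <- "N"
  lab[tissue & ov >= gt$overlapMin] <- "D"
  expect_identical(lab, gt$labelGrid)
})

test_that("every lesion polygon lies inside tissue", {
  sl <- generateSlide(syntheticSpec(seed = 21, widthPx = 768L,
                                    heightPx = 512L, slideClass = "M",
                                    lesionFraction = 0.5))
  gt <- sl$groundTruth
  # all lesion-labeled pixels must be tissue-coloured, i.e. darker than the
  # white background, at polygon vertices sampled inward
  for (poly in gt$polygons) {
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    mid <- cbind((poly[, 1] + cx) / 2, (poly[, 2] + cy) / 2)
    px <- sl$raster@pixels
    luma <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    vals <- luma[cbind(pmin(nrow(luma), pmax(1, round(mid[, 2]))),
                       pmin(ncol(luma), pmax(1, round(mid[, 1]))))]
    expect_true(all(vals < 230 / 255))
  }
})

test_that("raising artifact rates perturbs pixels but never labels", {
  clean <- generateSlide(smallSpec(6, "D", lesionFraction = 0.5,
                                   artifactParams = c(blur = 0, fold = 0,
                                                      stain_shift = 0,
                                                      bubble = 0)))
  noisy <- generateSlide(smallSpec(6, "D", lesionFraction = 0.5,
                                   artifactParams = c(blur = 3, fold = 3,
                                                      stain_shift = 3,
                                                      bubble = 3)))
  expect_identical(noisy$groundTruth$labelGrid, clean$groundTruth$labelGrid)
  expect_false(identical(noisy$raster@pixels, clean$raster@pixels))
  # the degraded slide still tiles and extracts without error
  db <- tileSlide(noisy$raster)
  expect_s4_class(db, "PatchDB")
  out <- extractTrainingPatches(noisy$raster, noisy$groundTruth$polygons,
                                "D")
  expect_gt(length(out$patches), 0)
})

test_that("undersized slide dimensions are rejected", {
  expect_error(syntheticSpec(widthPx = 100L, heightPx = 512L),
               "at least one patch")
  expect_error(syntheticSpec(slideClass = "M", lesionFraction = 0),
               "lesionFraction")
})

test_that("corpus class mix follows largest-remainder rounding", {
  dir <- withr::local_tempdir()
  man <- generateCorpus(10, classMix = c(M = 0.2, D = 0.3, N = 0.5),
                        seed = 2, dir = dir, serialRate = 0,
                        widthPx = 512L, heightPx = 512L)
  prim <- man[!duplicated(man$block_id), ]
  expect_equal(sum(prim$slide_class == "M"), 2)
  expect_equal(sum(prim$slide_class == "D"), 3)
  expect_equal(sum(prim$slide_class == "N"), 5)
  expect_error(generateCorpus(0), "positive")
})

test_that("corpus generation is reproducible and serial rate is honoured", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateCorpus(10, seed = 9, dir = d1, serialRate = 0.5,
                       widthPx = 512L, heightPx = 512L)
  m2 <- generateCorpus(10, seed = 9, dir = d2, serialRate = 0.5,
                       widthPx = 512L, heightPx = 512L)
  expect_identical(m1[setdiff(names(m1), c("path", "gt_path"))],
                   m2[setdiff(names(m2), c("path", "gt_path"))])
  perBlock <- table(m1$block_id)
  expect_equal(sum(perBlock >= 2), 5)   # half of 10 specimens are serial
  # serial slides share class and organ with their block mates
  for (b in names(perBlock[perBlock > 1])) {
    g <- m1[m1$block_id == b, ]
    expect_length(unique(g$slide_class), 1)
    expect_length(unique(g$organ), 1)
  }
})

test_that("splits are assigned at specimen level with exact counts", {
  # a manifest alone suffices; no images needed
  man <- data.frame(slide_id = sprintf("A%03d.B1.S1", 1:100),
                    block_id = sprintf("A%03d.B1", 1:100))
  sp <- splitCorpus(man, c(train = 0.8, val = 0.1, test = 0.1), seed = 4)
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(80, 10, 10))

  # serial specimens never straddle splits
  man2 <- data.frame(
    slide_id = c("A1.B1.S1", "A1.B1.S2", "A1.B1.S3", "A2.B1.S1", "A3.B1.S1"),
    block_id = c("A1.B1", "A1.B1", "A1.B1", "A2.B1", "A3.B1"))
  sp2 <- splitCorpus(man2, c(0.4, 0.3, 0.3), seed = 1)
  expect_length(unique(sp2$split[sp2$block_id == "A1.B1"]), 1)

  sp3 <- splitCorpus(man, c(1, 0, 0), seed = 1)
  expect_true(all(sp3$split == "train"))
  expect_error(splitCorpus(man[0, ]), "empty")
})

test_that("diagnosis records classify back to their intended class", {
  for (organ in c("gastric", "colorectal")) {
    for (cls in c("M", "D", "N")) {
      gt <- list(organ = organ, slideClass = cls, heading = "x")
      for (s in 1:5) {
        rec <- emitDxRecord(gt, "typical", seed = s)
        expect_identical(rec$dx_class, cls)
      }
    }
  }
})

test_that("entry-error records carry a spurious positive line", {
  gt <- list(organ = "colorectal", slideClass = "N", heading = "x")
  rec <- emitDxRecord(gt, "entry_error", seed = 3)
  expect_identical(rec$dx_class, "D")   # image is negative, text positive
  expect_match(rec$diagnosis, "low grade dysplasia")
})

test_that("switched pairs exchange texts between two slides", {
  man <- data.frame(slide_id = c("A1.B1.S1", "A2.B1.S1"),
                    accession = c("A1", "A2"),
                    block_id = c("A1.B1", "A2.B1"),
                    organ = "colorectal", slide_class = c("D", "N"),
                    heading = "Colon, colonoscopic biopsy")
  rec <- emitDxRecords(man, switchedPairs = list(c("A1.B1.S1", "A2.B1.S1")),
                       seed = 8)
  # D slide now carries the N text and vice versa
  expect_identical(rec$dx_class[rec$slide_id == "A1.B1.S1"], "N")
  expect_identical(rec$dx_class[rec$slide_id == "A2.B1.S1"], "D")
  expect_true(all(rec$style == "switched_pair"))
})

test_that("ground truth survives a JSON round trip", {
  sl <- generateSlide(smallSpec(13, "M", lesionFraction = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  writeGroundTruth(sl$groundTruth, path)
  gt2 <- readGroundTruth(path)
  expect_identical(gt2$labelGrid, sl$groundTruth$labelGrid)
  expect_identical(gt2$dxClass, sl$groundTruth$dxClass)
  expect_length(gt2$polygons, length(sl$groundTruth$polygons))
  for (i in seq_along(gt2$polygons))
    expect_equal(unname(as.matrix(gt2$polygons[[i]])),
                 unname(sl$groundTruth$polygons[[i]]), tolerance = 1e-9)
})
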