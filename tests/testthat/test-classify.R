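# Classifier mechanics that do not need trained models: balancing, noise
# removal arithmetic, reconstruction placement, normalization, heatmaps.

# tiny patches with class-dependent brightness, enough for the net to fit
tinyPatchSet <- function(n, seed = 1) {
  withr::with_seed(seed, {
    labels <- sample(rep(c("M", "D", "N"), length.out = n))
    patches <- lapply(labels, function(cl) {
      base <- c(M = 0.25, D = 0.55, N = 0.85)[[cl]]
      array(pmin(1, pmax(0, base + stats::rnorm(8 * 8 * 3, 0, 0.05))),
            dim = c(8, 8, 3))
    })
    list(patches = patches, labels = labels)
  })
}

test_that("balanced sampling equalizes class counts at the minimum", {
  labels <- c(rep("M", 100), rep("D", 40), rep("N", 400))
  keep <- balanceSample(labels, seed = 1)
  expect_equal(unname(table(labels[keep])[c("M", "D", "N")]),
               rep(40L, 3), ignore_attr = TRUE)
  # already balanced sets come back whole
  lab2 <- rep(c("M", "D", "N"), each = 5)
  expect_identical(balanceSample(lab2, seed = 3), seq_along(lab2))
  # seeded determinism
  expect_identical(balanceSample(labels, seed = 7),
                   balanceSample(labels, seed = 7))
  expect_error(balanceSample(rep("M", 5)), "missing")
})

test_that("noise removal trims exactly the top-q loss fraction", {
  ps <- tinyPatchSet(999, seed = 2)   # 333 per class
  m0 <- trainPatchClassifier(ps$patches, ps$labels,
                             config = list(seed = 1, balance = FALSE,
                                           noiseRemovalFraction = 0,
                                           maxIterations = 40),
                             minPerClass = 5)
  expect_equal(m0$nTrained, 999L)
  expect_length(m0$removed, 0)
  m2 <- trainPatchClassifier(ps$patches, ps$labels,
                             config = list(seed = 1, balance = FALSE,
                                           noiseRemovalFraction = 0.02,
                                           maxIterations = 40),
                             minPerClass = 5)
  expect_equal(m2$nTrained, 999L - floor(0.02 * 999))
  expect_length(m2$removed, floor(0.02 * 999))
  expect_error(trainPatchClassifier(ps$patches, ps$labels,
                                    config = list(noiseRemovalFraction = 0.5)),
               "noiseRemovalFraction")
})

test_that("patch predictions are proper probability triples", {
  ps <- tinyPatchSet(120, seed = 4)
  m <- trainPatchClassifier(ps$patches, ps$labels,
                            config = list(seed = 2, maxIterations = 60),
                            minPerClass = 5)
  pred <- predictPatchSet(m, ps$patches)
  sums <- pred$p_M + pred$p_D + pred$p_N
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(c(pred$p_M, pred$p_D, pred$p_N) >= 0))
  # the easy brightness classes are recovered
  expect_gt(mean(pred$argmax_class == ps$labels), 0.95)
  # training twice with the same seed gives identical predictions
  m2 <- trainPatchClassifier(ps$patches, ps$labels,
                             config = list(seed = 2, maxIterations = 60),
                             minPerClass = 5)
  expect_identical(predictPatchSet(m2, ps$patches), pred)
})

test_that("argmax ties break toward the more severe class", {
  expect_identical(BiopsyQC:::argmaxClass(c(0.4, 0.4, 0.2)), "M")
  expect_identical(BiopsyQC:::argmaxClass(c(0.1, 0.45, 0.45)), "D")
  expect_identical(BiopsyQC:::argmaxClass(c(1, 1, 1) / 3), "M")
  expect_identical(BiopsyQC:::argmaxClass(c(0.1, 0.2, 0.7)), "N")
})

test_that("reconstruction is pure placement, invariant to prediction order", {
  db <- tileSlide(grayRaster(768, 768))   # 3x3 toy grid
  withr::with_seed(9, {
    p <- matrix(stats::rexp(9 * 3), ncol = 3)
    p <- p / rowSums(p)
    pred <- data.frame(patch_index = 0:8, p_M = p[, 1], p_D = p[, 2],
                       p_N = p[, 3])
    rs <- buildReconstruction(pred, db)
    # placement identity: cell (r, c) holds the triple of patch r*3+c
    for (k in 1:9)
      expect_equal(rs@grid[(k - 1) %/% 3 + 1, (k - 1) %% 3 + 1, ],
                   unname(p[k, ]))
    for (rep in 1:25) {
      perm <- sample(9)
      expect_identical(buildReconstruction(pred[perm, ], db)@grid, rs@grid)
    }
  })
  expect_error(buildReconstruction(
    data.frame(patch_index = 99L, p_M = 1, p_D = 0, p_N = 0), db),
    "unknown patch_index")
})

test_that("reconstruction keeps background cells as exact zero", {
  db <- tileSlide(grayRaster(1024, 512))  # 4x2 grid
  pred <- data.frame(patch_index = c(0L, 5L), p_M = c(0.1, 0.2),
                     p_D = c(0.2, 0.3), p_N = c(0.7, 0.5))
  rs <- buildReconstruction(pred, db)
  s <- apply(rs@grid, c(1, 2), sum)
  expect_equal(sum(abs(s - 1) < 1e-9), 2)
  expect_equal(sum(s == 0), 6)
  expect_equal(rs@grid[1, 1, ], c(0.1, 0.2, 0.7))
})

test_that("normalization centres, pads and area-averages as documented", {
  # 2x4 grid centred in 64x64 zeros
  db <- tileSlide(grayRaster(1024, 512))
  pred <- data.frame(patch_index = 0:7, p_M = 1 / 3, p_D = 1 / 3,
                     p_N = 1 / 3)
  rs <- buildReconstruction(pred, db)
  norm <- normalizeReconstruction(rs, c(64L, 64L))
  expect_equal(dim(norm), c(64, 64, 3))
  expect_equal(sum(norm > 0), 8 * 3)
  occupied <- which(apply(norm, c(1, 2), sum) > 0, arr.ind = TRUE)
  expect_setequal(unique(occupied[, 1]), c(32, 33))       # centred rows
  expect_setequal(unique(occupied[, 2]), 31:34)           # centred cols

  # 64x64 input is unchanged
  g <- array(stats::runif(64 * 64 * 3), dim = c(64, 64, 3))
  g <- sweep(g, c(1, 2), apply(g, c(1, 2), sum), "/")
  rs64 <- new("ReconstructedSlide", slideId = "x", grid = g)
  expect_identical(normalizeReconstruction(rs64, c(64L, 64L)), g)

  # 128x128 is block-averaged 2x2 -> cell (1,1) is the mean of the source block
  g2 <- array(stats::runif(128 * 128 * 3), dim = c(128, 128, 3))
  g2 <- sweep(g2, c(1, 2), apply(g2, c(1, 2), sum), "/")
  rs128 <- new("ReconstructedSlide", slideId = "x", grid = g2)
  n2 <- normalizeReconstruction(rs128, c(64L, 64L))
  expect_equal(n2[1, 1, ], apply(g2[1:2, 1:2, ], 3, mean))
  expect_equal(n2[64, 64, ], apply(g2[127:128, 127:128, ], 3, mean))
})

test_that("heatmap rectangles have the documented geometry and colors", {
  db <- tileSlide(grayRaster(1024, 512))  # 4x2, patch 256
  # all-N predictions: fully transparent overlay
  predN <- data.frame(patch_index = 0:7, p_M = 0, p_D = 0, p_N = 1,
                      argmax_class = "N")
  ovN <- renderHeatmap(predN, db, scale = 0.5, opacity = 0.5)
  expect_equal(dim(ovN), c(256, 512, 4))
  expect_true(all(ovN[, , 4] == 0))

  # one M patch at grid (0,0): exactly one red 128x128 rectangle top-left
  predM <- data.frame(patch_index = 0L, p_M = 1, p_D = 0, p_N = 0,
                      argmax_class = "M")
  ov <- renderHeatmap(predM, db, scale = 0.5, opacity = 0.5)
  expect_true(all(ov[1:128, 1:128, 1] == 1))
  expect_true(all(ov[1:128, 1:128, 4] == 0.5))
  expect_equal(sum(ov[, , 4] > 0), 128 * 128)

  # blue for D, and composition blends only where heat exists
  predD <- data.frame(patch_index = 5L, p_M = 0, p_D = 1, p_N = 0,
                      argmax_class = "D")
  ovD <- renderHeatmap(predD, db, scale = 0.5, opacity = 1)
  expect_true(all(ovD[129:256, 129:256, 3] == 1))
  thumb <- array(0.5, dim = c(256, 512, 3))
  comp <- composeHeatmap(thumb, ovD)
  expect_equal(comp[1, 1, ], rep(0.5, 3))
  expect_equal(comp[200, 200, ], c(0, 0, 1))
  expect_identical(composeHeatmap(thumb, ovD, maskOn = FALSE), thumb)
})

test_that("an empty slide falls back to class N with a no_tissue flag", {
  models <- list(gastric = list(patch = NULL, slide = NULL))
  out <- predictSlide(models, SlideRaster(array(1, c(512, 512, 3)), "blank"),
                      "gastric")
  expect_identical(finalClass(out$prediction), "N")
  expect_true("no_tissue" %in% out$prediction@flags)
  expect_error(predictSlide(list(), grayRaster(256, 256), "gastric"),
               "no model")
})
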