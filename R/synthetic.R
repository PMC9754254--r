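# Deterministic synthetic "WSI-like" slide generator.
#
# Slides emulate the statistical structure the pipeline assumes, not real
# histology: a white scanner background, a few smooth tissue fragments, and
# class-distinct procedural nuclear textures -- sparse round nuclei with
# gland-like ring motifs for Negative (N), denser elongated dark nuclei for
# Dysplasia (D), and crowded irregular high-density chromatin for Malignant
# (M) -- plus routine slide/scan artifacts (focal blur, fold streaks, stain
# shift, air-bubble discs) injected at configurable rates. Artifacts perturb
# pixels only; they never change ground-truth labels.

DX_TEXT_BANK <- list(
  gastric = list(
    N = c("Chronic gastritis",
          "Chronic active gastritis with erosion",
          "Chronic gastritis with intestinal metaplasia",
          "Hyperplastic polyp",
          "Fundic gland polyp"),
    D = c("Tubular adenoma, low grade dysplasia",
          "Atypical glandular proliferation, indefinite for dysplasia"),
    M = c("Adenocarcinoma, moderately differentiated",
          "Tubular adenoma, high grade dysplasia",
          "Adenocarcinoma, poorly differentiated",
          "Malignant neoplasm")),
  colorectal = list(
    N = c("Hyperplastic polyp",
          "Nonspecific inflammation, inactive",
          "Inflammatory polyp",
          "Sessile serrated lesion"),
    D = c("Tubular adenoma, low grade dysplasia",
          "Tubulovillous adenoma, low grade dysplasia"),
    M = c("Adenocarcinoma, moderately differentiated",
          "Tubulovillous adenoma, low to focal high grade dysplasia",
          "Adenocarcinoma, well differentiated")))

AMBIGUOUS_TEXT <- c(
  M = "Atypical glandular proliferation, favor neoplastic",
  D = "Atypical glandular proliferation, indefinite for dysplasia",
  N = "Atypical glandular proliferation, undetermined significance")

HEADING_BANK <- list(
  gastric = c("Stomach, endoscopic biopsy",
              "Esophagogastric junction, endoscopic biopsy"),
  colorectal = c("Colon, colonoscopic biopsy",
                 "Rectum, colonoscopic biopsy",
                 "Cecum, colonoscopic biopsy",
                 "Terminal ileum, colonoscopic biopsy",
                 "Rectosigmoid junction, colonoscopic biopsy"))

# (base tissue colour, nucleus colour, nucleus pixel density) per class
TEXTURE_RECIPES <- list(
  N = list(base = c(0.93, 0.78, 0.85), nucleus = c(0.42, 0.30, 0.58),
           density = 0.004),
  D = list(base = c(0.84, 0.66, 0.80), nucleus = c(0.30, 0.20, 0.50),
           density = 0.020),
  M = list(base = c(0.74, 0.56, 0.70), nucleus = c(0.20, 0.12, 0.38),
           density = 0.060))

#' Specification for one synthetic slide
#'
#' @param seed integer; same spec + seed gives byte-identical pixels, ground
#'   truth and diagnosis text.
#' @param widthPx,heightPx slide dimensions in pixels (each at least
#'   \code{patchSize}).
#' @param organ "gastric" or "colorectal" (controls heading/diagnosis text
#'   only; the textures are organ-agnostic).
#' @param slideClass planted slide class: "M", "D" or "N".
#' @param lesionFraction target fraction of tissue patches carrying the
#'   lesion label (ignored for class N).
#' @param nTissueBlobs number of tissue fragments.
#' @param artifactParams named numeric: expected per-slide counts of
#'   \code{blur}, \code{fold}, \code{stain_shift} and \code{bubble}
#'   artifacts.
#' @param patchSize tile edge in pixels (default 256).
#' @return object of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed = 1L, widthPx = 1536L, heightPx = 1024L,
                          organ = c("gastric", "colorectal"),
                          slideClass = c("N", "D", "M"),
                          lesionFraction = 0.4, nTissueBlobs = 3L,
                          artifactParams = c(blur = 0.3, fold = 0.2,
                                             stain_shift = 0.3, bubble = 0.3),
                          patchSize = 256L) {
  organ <- match.arg(organ)
  slideClass <- match.arg(slideClass)
  if (widthPx < patchSize || heightPx < patchSize)
    stop("slide dimensions must be at least one patch (", patchSize,
         " px) in each direction")
  if (slideClass != "N" && (lesionFraction <= 0 || lesionFraction > 1))
    stop("lesionFraction must lie in (0, 1] for M/D slides")
  spec <- list(seed = as.integer(seed), widthPx = as.integer(widthPx),
               heightPx = as.integer(heightPx), organ = organ,
               slideClass = slideClass, lesionFraction = lesionFraction,
               nTissueBlobs = as.integer(nTissueBlobs),
               artifactParams = artifactParams,
               patchSize = as.integer(patchSize))
  class(spec) <- "SyntheticSpec"
  spec
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf("SyntheticSpec: %dx%d px, organ %s, class %s, seed %d\n",
              x$widthPx, x$heightPx, x$organ, x$slideClass, x$seed))
  invisible(x)
}

# tissue fragments: union of rotated ellipses (level set of an anisotropic
# Gaussian bump at half its peak)
tissueMask <- function(w, h, nBlobs) {
  mask <- matrix(FALSE, h, w)
  lim <- 2 * log(2)
  for (i in seq_len(nBlobs)) {
    cx <- runif(1, 0.2, 0.8) * w
    cy <- runif(1, 0.2, 0.8) * h
    sx <- runif(1, 0.10, 0.18) * w
    sy <- runif(1, 0.14, 0.24) * h
    th <- runif(1, 0, pi)
    # evaluate only inside the ellipse's bounding box
    hx <- sqrt(lim * ((cos(th) * sx)^2 + (sin(th) * sy)^2))
    hy <- sqrt(lim * ((sin(th) * sx)^2 + (cos(th) * sy)^2))
    xs <- max(1L, floor(cx - hx)):min(w, ceiling(cx + hx))
    ys <- max(1L, floor(cy - hy)):min(h, ceiling(cy + hy))
    dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
    u <- (cos(th) * dx + sin(th) * dy) / sx
    v <- (-sin(th) * dx + cos(th) * dy) / sy
    mask[ys, xs] <- mask[ys, xs] | (u * u + v * v < lim)
  }
  mask
}

# linear pixel indices stamped by a template around each centre, clipped to
# the canvas and restricted to 'mask' pixels
stampIndices <- function(centers, template, mask, h, w) {
  if (!length(centers)) return(integer())
  cy <- ((centers - 1) %% h) + 1
  cx <- ((centers - 1) %/% h) + 1
  yy <- rep(cy, each = nrow(template)) + template[, 1]
  xx <- rep(cx, each = nrow(template)) + template[, 2]
  ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  lin <- yy[ok] + (xx[ok] - 1) * h
  lin[mask[lin]]
}

# NB: flat-colour painting is inlined at call sites (not a helper function)
# so the canvas array is modified in place instead of being copied on every
# call; a slide canvas is ~100 MB of doubles.

discTemplate <- function(r) {
  d <- expand.grid(dy = -r:r, dx = -r:r)
  as.matrix(d[d$dy^2 + d$dx^2 <= r^2, ])
}

ringTemplate <- function(r, thickness = 1.6) {
  rr <- ceiling(r + thickness)
  d <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  dist <- sqrt(d$dy^2 + d$dx^2)
  as.matrix(d[abs(dist - r) <= thickness / 2 + 0.5, ])
}

strokeTemplate <- function(len, angle, thickness = 1L) {
  t <- seq(-len / 2, len / 2, by = 0.5)
  pts <- unique(round(cbind(dy = t * sin(angle), dx = t * cos(angle))))
  out <- pts
  for (o in seq_len(thickness))
    out <- rbind(out, cbind(pts[, 1] + o, pts[, 2]))
  unique(out)
}

# draw the procedural texture of one class over 'mask' pixels of px
paintTexture <- function(px, mask, classLabel) {
  rec <- TEXTURE_RECIPES[[classLabel]]
  h <- dim(px)[1]; w <- dim(px)[2]
  idx <- which(mask)
  if (!length(idx)) return(px)
  # base colour with mild low-frequency mottling (32 px cells)
  hc <- ceiling(h / 32); wc <- ceiling(w / 32)
  mot <- kronecker(matrix(stats::rnorm(hc * wc, 0, 0.03), hc, wc),
                   matrix(1, 32, 32))[seq_len(h), seq_len(w)]
  for (ch in 1:3)
    px[idx + (ch - 1) * h * w] <- clamp01(rec$base[ch] + mot[idx])
  nNuc <- round(rec$density * length(idx) /
                  switch(classLabel, N = 9, D = 12, M = 16))
  if (nNuc > 0) {
    centers <- sample(idx, min(nNuc, length(idx)))
    # gather (indices, colour) pairs, then write each channel in place
    sets <- list()
    if (classLabel == "N") {
      nRings <- max(1L, round(length(idx) / 60000))  # gland-like ring motifs
      ringC <- sample(idx, min(nRings, length(idx)))
      rim <- integer(); lum <- integer()
      for (r in ringC) {
        rad <- sample(8:14, 1)
        rim <- c(rim, stampIndices(r, ringTemplate(rad), mask, h, w))
        lum <- c(lum, stampIndices(r, discTemplate(max(2L, rad - 4L)),
                                   mask, h, w))
      }
      sets <- list(list(lin = rim, col = clamp01(rec$base - 0.18)),
                   list(lin = lum, col = clamp01(rec$base + 0.05)),
                   list(lin = stampIndices(centers, discTemplate(1),
                                           mask, h, w),
                        col = rec$nucleus))
    } else if (classLabel == "D") {
      angles <- runif(8, 0, pi)
      grp <- sample.int(8, length(centers), replace = TRUE)
      lin <- integer()
      for (g in 1:8)
        lin <- c(lin, stampIndices(centers[grp == g],
                                   strokeTemplate(6, angles[g], 2L),
                                   mask, h, w))
      sets <- list(list(lin = lin, col = rec$nucleus))
    } else {
      grp <- sample.int(3, length(centers), replace = TRUE)
      lin <- integer()
      for (g in 1:3)
        lin <- c(lin, stampIndices(centers[grp == g], discTemplate(g),
                                   mask, h, w))
      sets <- list(list(lin = lin, col = rec$nucleus))
    }
    for (s in sets) {
      if (!length(s$lin)) next
      for (ch in 1:3) px[s$lin + (ch - 1) * h * w] <- s$col[ch]
    }
  }
  px
}

# routine slide/scan artifacts; pixels only, labels untouched
applyArtifacts <- function(px, params) {
  h <- dim(px)[1]; w <- dim(px)[2]
  counts <- vapply(c("blur", "fold", "stain_shift", "bubble"), function(k)
    stats::rpois(1, if (k %in% names(params)) params[[k]] else 0), integer(1))
  for (i in seq_len(counts["blur"])) {       # focal out-of-focus region
    bw <- min(w, sample(150:350, 1)); bh <- min(h, sample(150:350, 1))
    x0 <- sample.int(w - bw + 1, 1); y0 <- sample.int(h - bh + 1, 1)
    sub <- px[y0:(y0 + bh - 1), x0:(x0 + bw - 1), , drop = FALSE]
    img <- EBImage::gblur(EBImage::Image(aperm(sub, c(2, 1, 3)),
                                         colormode = "Color"), sigma = 4)
    px[y0:(y0 + bh - 1), x0:(x0 + bw - 1), ] <- aperm(as.array(img), c(2, 1, 3))
  }
  for (i in seq_len(counts["fold"])) {       # dark tissue-fold streak
    x1 <- runif(1, 0, w); y1 <- runif(1, 0, h); th <- runif(1, 0, pi)
    xg <- matrix(seq_len(w), h, w, byrow = TRUE)
    yg <- matrix(seq_len(h), h, w)
    dist <- abs((xg - x1) * sin(th) - (yg - y1) * cos(th))
    band <- dist < runif(1, 3, 8)
    for (ch in 1:3) {
      plane <- px[, , ch]; plane[band] <- plane[band] * 0.55
      px[, , ch] <- plane
    }
  }
  for (i in seq_len(counts["stain_shift"])) { # regional stain-colour shift
    bw <- min(w, sample(200:500, 1)); bh <- min(h, sample(200:500, 1))
    x0 <- sample.int(w - bw + 1, 1); y0 <- sample.int(h - bh + 1, 1)
    fac <- c(runif(1, 0.9, 1.1), runif(1, 0.85, 1.05), runif(1, 0.9, 1.15))
    for (ch in 1:3)
      px[y0:(y0 + bh - 1), x0:(x0 + bw - 1), ch] <-
        clamp01(px[y0:(y0 + bh - 1), x0:(x0 + bw - 1), ch] * fac[ch])
  }
  for (i in seq_len(counts["bubble"])) {     # air bubble: bright disc, dark rim
    r <- sample(25:60, 1)
    cx <- sample.int(w, 1); cy <- sample.int(h, 1)
    c0 <- cy + (cx - 1) * h
    all <- matrix(TRUE, h, w)
    inner <- stampIndices(c0, discTemplate(r - 2L), all, h, w)
    rim <- stampIndices(c0, ringTemplate(r, 2.5), all, h, w)
    for (ch in 1:3) {
      ii <- inner + (ch - 1) * h * w
      px[ii] <- clamp01(px[ii] * 0.3 + 0.7)
      px[rim + (ch - 1) * h * w] <- 0.35
    }
  }
  px
}

# per-tile tissue fraction of a logical mask (relative to full tile area)
tileTissueFractions <- function(mask, patchSize) {
  h <- nrow(mask); w <- ncol(mask)
  nCols <- ceiling(w / patchSize); nRows <- ceiling(h / patchSize)
  out <- matrix(0, nRows, nCols)
  for (r in seq_len(nRows)) {
    ys <- ((r - 1) * patchSize + 1):min(r * patchSize, h)
    for (cc in seq_len(nCols)) {
      xs <- ((cc - 1) * patchSize + 1):min(cc * patchSize, w)
      out[r, cc] <- sum(mask[ys, xs]) / patchSize^2
    }
  }
  out
}

#' Generate one synthetic slide with ground truth
#'
#' Draws the tissue fragments, plants lesion polygons for M/D slides until
#' the target fraction of tissue patches carries the lesion label, renders
#' the class textures, injects artifacts, and computes the ground-truth patch
#' label grid from the planted geometry. A patch is labeled M/D when at least
#' \code{overlapMin} of its area intersects a lesion polygon, N when at least
#' \code{tissueMin} of its area is tissue, and background otherwise.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param overlapMin lesion-overlap labeling threshold (default 0.25).
#' @param tissueMin tissue-fraction threshold for a tissue patch (default
#'   0.05).
#' @return list with elements \code{raster} (a \linkS4class{SlideRaster}) and
#'   \code{groundTruth}: a list carrying \code{labelGrid} (nRows x nCols
#'   character matrix over \{"M","D","N","background"\}), \code{polygons}
#'   (lesion vertex matrices), \code{tissueFractions}, \code{heading},
#'   \code{diagnosis}, \code{dxClass}, \code{slideClass}, \code{organ}.
#' @examples
#' sl <- generateSlide(syntheticSpec(seed = 1, slideClass = "N"))
#' table(sl$groundTruth$labelGrid)
#' @export
generateSlide <- function(spec, overlapMin = 0.25, tissueMin = 0.05) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    w <- spec$widthPx; h <- spec$heightPx; ps <- spec$patchSize
    mask <- tissueMask(w, h, spec$nTissueBlobs)
    tf <- tileTissueFractions(mask, ps)
    tissueTiles <- tf >= tissueMin

    polygons <- list()
    lesionMask <- matrix(FALSE, h, w)
    if (spec$slideClass != "N" && any(tissueTiles)) {
      targetK <- max(1L, round(spec$lesionFraction * sum(tissueTiles)))
      dist <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
      ovCount <- matrix(0, nrow(tf), ncol(tf))  # lesion pixels per tile
      for (attempt in seq_len(60)) {
        if (sum(ovCount / ps^2 >= overlapMin & tissueTiles) >= targetK) break
        r <- sample(60:110, 1)
        cand <- which(dist > r * 0.9)
        if (!length(cand)) {
          r <- max(30, floor(max(dist)) - 2)
          cand <- which(dist > r * 0.9)
        }
        if (!length(cand)) break
        c0 <- cand[sample.int(length(cand), 1)]
        cy <- ((c0 - 1) %% h) + 1; cx <- ((c0 - 1) %/% h) + 1
        poly <- discPolygon(cx - 0.5, cy - 0.5, min(r, dist[c0] - 1), 32L)
        polygons[[length(polygons) + 1]] <- poly
        # rasterize only the polygon's bounding box (integer-translated, so
        # pixel-centre semantics match a full-slide rasterization exactly)
        bx0 <- max(0L, floor(min(poly[, 1])) - 1L)
        by0 <- max(0L, floor(min(poly[, 2])) - 1L)
        bx1 <- min(w, ceiling(max(poly[, 1])) + 1L)
        by1 <- min(h, ceiling(max(poly[, 2])) + 1L)
        local <- rasterizePolygons(
          list(cbind(poly[, 1] - bx0, poly[, 2] - by0)),
          bx1 - bx0, by1 - by0)
        ys <- (by0 + 1):by1; xs <- (bx0 + 1):bx1
        newPix <- local & mask[ys, xs, drop = FALSE] &
          !lesionMask[ys, xs, drop = FALSE]
        lesionMask[ys, xs][newPix] <- TRUE
        wy <- which(newPix, arr.ind = TRUE)
        if (nrow(wy)) {
          tr <- (by0 + wy[, 1] - 1) %/% ps + 1
          tc <- (bx0 + wy[, 2] - 1) %/% ps + 1
          lin <- tr + (tc - 1) * nrow(tf)
          inc <- tabulate(lin, nbins = length(tf))
          ovCount <- ovCount + matrix(inc, nrow(tf), ncol(tf))
        }
      }
    }

    px <- array(1, dim = c(h, w, 3))
    px <- paintTexture(px, mask & !lesionMask, "N")
    if (any(lesionMask))
      px <- paintTexture(px, lesionMask, spec$slideClass)
    px <- applyArtifacts(px, spec$artifactParams)

    # per-tile lesion coverage; polygons lie strictly inside tissue, so the
    # incrementally maintained pixel counts equal a full re-rasterization
    ovFinal <- if (length(polygons)) ovCount / ps^2 else 0 * tf
    labelGrid <- matrix("background", nrow(tf), ncol(tf))
    labelGrid[tissueTiles] <- "N"
    labelGrid[tissueTiles & ovFinal >= overlapMin] <- spec$slideClass

    heading <- sample(HEADING_BANK[[spec$organ]], 1)
    diagnosis <- sample(DX_TEXT_BANK[[spec$organ]][[spec$slideClass]], 1)
    gt <- list(labelGrid = labelGrid, polygons = polygons,
               tissueFractions = tf, lesionOverlap = ovFinal,
               heading = heading, diagnosis = diagnosis,
               dxClass = classifyDx(diagnosis),
               slideClass = spec$slideClass, organ = spec$organ,
               patchSize = ps, overlapMin = overlapMin,
               tissueMin = tissueMin)
    class(gt) <- "GroundTruth"
    list(raster = SlideRaster(px, sprintf("synthetic-%s-%d",
                                          spec$slideClass, spec$seed)),
         groundTruth = gt)
  })
}

#' Generate standalone labeled texture patches
#'
#' Fast path for patch-classifier training and evaluation, emulating the
#' tile population that annotation-restricted extraction produces on whole
#' slides. N patches are negative tissue texture (full tiles and
#' tissue-boundary tiles). M/D patches are a lesion disc painted over
#' negative tissue, covering between the labeling threshold (25 percent)
#' and the whole tile -- the same mixed-content tiles that a lesion
#' boundary yields at prediction time. All patches receive the same
#' artifact injection as full slides.
#'
#' @param nPerClass patches per class.
#' @param seed integer seed.
#' @param patchSize patch edge in pixels.
#' @param partialFraction fraction of patches with partial tissue coverage.
#' @param lesionCoverage range of the lesion-disc area fraction for M/D
#'   patches (relative to the tile area).
#' @param artifactParams per-patch expected artifact counts (scaled-down
#'   slide defaults).
#' @return list with \code{patches} (list of patchSize^2 x 3 arrays) and
#'   \code{labels} (character vector over M/D/N).
#' @export
generatePatchSet <- function(nPerClass, seed = 1L, patchSize = 256L,
                             partialFraction = 0.25,
                             lesionCoverage = c(0.3, 1),
                             artifactParams = c(blur = 0.05, fold = 0.03,
                                                stain_shift = 0.05,
                                                bubble = 0.03)) {
  withSeed(seed, {
    labels <- rep(QC_CLASSES, each = nPerClass)
    patches <- vector("list", length(labels))
    xg <- matrix(seq_len(patchSize), patchSize, patchSize, byrow = TRUE)
    yg <- matrix(seq_len(patchSize), patchSize, patchSize)
    for (i in seq_along(labels)) {
      if (runif(1) < partialFraction) {
        # tissue boundary crossing the patch: one Gaussian bump off-centre
        cx <- runif(1, -0.2, 1.2) * patchSize
        cy <- runif(1, -0.2, 1.2) * patchSize
        s <- runif(1, 0.5, 1.2) * patchSize
        mask <- exp(-0.5 * (((xg - cx) / s)^2 + ((yg - cy) / s)^2)) > 0.55
        if (mean(mask) < 0.1) mask <- (xg / patchSize + yg / patchSize) > 1
      } else mask <- matrix(TRUE, patchSize, patchSize)
      px <- array(1, dim = c(patchSize, patchSize, 3))
      px <- paintTexture(px, mask, "N")
      if (labels[i] != "N") {
        # lesion disc over the negative background, as at a lesion border
        frac <- runif(1, lesionCoverage[1], lesionCoverage[2])
        r <- patchSize * sqrt(frac / pi)
        cx <- runif(1, 0.35, 0.65) * patchSize
        cy <- runif(1, 0.35, 0.65) * patchSize
        dd <- (xg - cx)^2 + (yg - cy)^2
        lesion <- (dd <= r^2) & mask
        if (mean(lesion) < 0.25) lesion <- mask   # keep the label truthful
        px <- paintTexture(px, lesion, labels[i])
      }
      px <- applyArtifacts(px, artifactParams)
      patches[[i]] <- px
    }
    list(patches = patches, labels = labels)
  })
}

#' Emit a diagnosis record for a slide
#'
#' Produces the free-text record(s) a laboratory information system would
#' hold for a slide, in one of four styles: \code{typical} (keyword class
#' equals the slide class), \code{ambiguous} (gray-zone phrasing),
#' \code{entry_error} (a spurious positive line appended to an otherwise
#' typical diagnosis), or \code{wrong_class} (typical text of another class,
#' emulating a missed lesion in the microscopy field of view). Pair switching
#' is a corpus-level operation; see \code{\link{emitDxRecords}}.
#'
#' @param gt a \code{GroundTruth} (or any list with \code{organ},
#'   \code{slideClass}, \code{heading} fields).
#' @param style one of "typical", "ambiguous", "entry_error", "wrong_class".
#' @param accession,blockId,slideIdStr record identifiers.
#' @param seed integer seed for text selection.
#' @param wrongClass class whose typical text to emit for
#'   style = "wrong_class" (default "N", the false-negative direction).
#' @return one-row data.frame with columns accession, block_id, slide_id,
#'   organ, heading, diagnosis, dx_class, style.
#' @export
emitDxRecord <- function(gt, style = c("typical", "ambiguous", "entry_error",
                                       "wrong_class"),
                         accession = "A00001", blockId = "A00001.B1",
                         slideIdStr = "A00001.B1.S1", seed = 1L,
                         wrongClass = "N") {
  style <- match.arg(style)
  withSeed(seed, {
    bank <- DX_TEXT_BANK[[gt$organ]]
    diagnosis <- switch(style,
      typical = sample(bank[[gt$slideClass]], 1),
      ambiguous = AMBIGUOUS_TEXT[[gt$slideClass]],
      entry_error = paste0(sample(bank[[gt$slideClass]], 1), "\n",
                           "Tubular adenoma, low grade dysplasia"),
      wrong_class = sample(bank[[wrongClass]], 1))
    data.frame(accession = accession, block_id = blockId,
               slide_id = slideIdStr, organ = gt$organ,
               heading = gt$heading, diagnosis = diagnosis,
               dx_class = classifyDx(diagnosis), style = style,
               stringsAsFactors = FALSE)
  })
}

#' Emit diagnosis records for a corpus, with optional injected errors
#'
#' @param manifest corpus manifest from \code{\link{generateCorpus}}.
#' @param entryErrorIds slide ids receiving a spurious positive line.
#' @param wrongClassIds slide ids whose text reports a different (default
#'   negative) class than the planted lesion.
#' @param switchedPairs list of length-2 character vectors of slide ids whose
#'   heading/diagnosis texts are exchanged (specimen switching).
#' @param seed integer seed.
#' @return data.frame of diagnosis records, one row per slide.
#' @export
emitDxRecords <- function(manifest, entryErrorIds = character(),
                          wrongClassIds = character(),
                          switchedPairs = list(), seed = 1L) {
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    gt <- list(organ = m$organ, slideClass = m$slide_class,
               heading = m$heading)
    style <- if (m$slide_id %in% entryErrorIds) "entry_error"
             else if (m$slide_id %in% wrongClassIds) "wrong_class"
             else "typical"
    rows[[i]] <- emitDxRecord(gt, style, accession = m$accession,
                              blockId = m$block_id, slideIdStr = m$slide_id,
                              seed = subSeed(seed, m$slide_id))
  }
  rec <- do.call(rbind, rows)
  for (pair in switchedPairs) {
    i <- match(pair[1], rec$slide_id); j <- match(pair[2], rec$slide_id)
    if (is.na(i) || is.na(j)) stop("switched pair references unknown slide id")
    flds <- c("heading", "diagnosis", "dx_class")
    tmp <- rec[i, flds]; rec[i, flds] <- rec[j, flds]; rec[j, flds] <- tmp
    rec$style[c(i, j)] <- "switched_pair"
  }
  rec
}

#' Generate a synthetic slide corpus on disk
#'
#' Creates \code{nSlides} primary specimens (one slide each) with the given
#' class and organ mixes (largest-remainder rounding), plus one extra serial
#' section for a \code{serialRate} fraction of specimens (slides of one block
#' share the planted class and organ). Slides are written as PNG, ground
#' truth as JSON plus GeoJSON lesion polygons, and the manifest as CSV.
#'
#' @param nSlides number of primary specimens (> 0).
#' @param classMix named proportions over M/D/N, summing to 1.
#' @param organMix named proportions over gastric/colorectal, summing to 1.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param serialRate fraction of specimens receiving a second serial slide.
#' @param widthPx,heightPx,patchSize slide geometry.
#' @param lesionFraction lesion coverage for M/D slides.
#' @param artifactParams per-slide artifact rates.
#' @param accessionPrefix prefix for generated accession numbers.
#' @return the manifest data.frame (also written to \code{manifest.csv}),
#'   with one row per slide: slide_id, accession, block_id, organ,
#'   slide_class, heading, diagnosis, dx_class, path, gt_path, seed.
#' @export
generateCorpus <- function(nSlides, classMix = c(M = 1/3, D = 1/3, N = 1/3),
                           organMix = c(gastric = 0.5, colorectal = 0.5),
                           seed = 1L, dir = tempfile("corpus"),
                           serialRate = 0.1, widthPx = 1536L,
                           heightPx = 1024L, patchSize = 256L,
                           lesionFraction = 0.4,
                           artifactParams = c(blur = 0.3, fold = 0.2,
                                              stain_shift = 0.3,
                                              bubble = 0.3),
                           accessionPrefix = "A") {
  if (nSlides <= 0) stop("nSlides must be positive")
  stopifnot(abs(sum(classMix) - 1) < 1e-8, abs(sum(organMix) - 1) < 1e-8)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  classes <- rep(names(classMix), largestRemainder(nSlides, classMix))
  organs <- rep(names(organMix), largestRemainder(nSlides, organMix))
  nSerial <- round(serialRate * nSlides)
  withSeed(subSeed(seed, "corpus-layout"), {
    classes <- sample(classes)
    organs <- sample(organs)
    serialBlocks <- if (nSerial > 0) sample.int(nSlides, nSerial) else integer()
  })
  rows <- list()
  for (b in seq_len(nSlides)) {
    accession <- sprintf("%s%05d", accessionPrefix, b)
    blockId <- paste0(accession, ".B1")
    nCopies <- if (b %in% serialBlocks) 2L else 1L
    for (k in seq_len(nCopies)) {
      sid <- sprintf("%s.S%d", blockId, k)
      sseed <- subSeed(seed, sid)
      spec <- syntheticSpec(seed = sseed, widthPx = widthPx,
                            heightPx = heightPx, organ = organs[b],
                            slideClass = classes[b],
                            lesionFraction = lesionFraction,
                            artifactParams = artifactParams,
                            patchSize = patchSize)
      sl <- generateSlide(spec)
      path <- file.path(dir, paste0(sid, ".png"))
      writeSlide(sl$raster, path)
      gtPath <- file.path(dir, paste0(sid, ".gt.json"))
      writeGroundTruth(sl$groundTruth, gtPath)
      rows[[length(rows) + 1]] <- data.frame(
        slide_id = sid, accession = accession, block_id = blockId,
        organ = organs[b], slide_class = classes[b],
        heading = sl$groundTruth$heading,
        diagnosis = sl$groundTruth$diagnosis,
        dx_class = sl$groundTruth$dxClass,
        path = path, gt_path = gtPath, seed = sseed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Write / read ground truth as JSON (lesion polygons as GeoJSON)
#'
#' @param gt a \code{GroundTruth} list.
#' @param path output JSON path.
#' @return \code{writeGroundTruth}: the path, invisibly;
#'   \code{readGroundTruth}: the \code{GroundTruth} list.
#' @export
writeGroundTruth <- function(gt, path) {
  geo <- list(type = "FeatureCollection", features = lapply(gt$polygons,
    function(p) list(type = "Feature", properties = list(),
                     geometry = list(type = "Polygon",
                                     coordinates = list(rbind(p, p[1, , drop = FALSE]))))))
  out <- list(labelGrid = gt$labelGrid, heading = gt$heading,
              diagnosis = gt$diagnosis, dxClass = gt$dxClass,
              slideClass = gt$slideClass, organ = gt$organ,
              patchSize = gt$patchSize, overlapMin = gt$overlapMin,
              tissueMin = gt$tissueMin, lesions = geo)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gt <- list(labelGrid = as.matrix(x$labelGrid),
             polygons = lapply(x$lesions$features$geometry$coordinates,
                               function(cc) {
                                 m <- if (is.list(cc)) cc[[1]] else cc[1, , ]
                                 m <- as.matrix(m)
                                 m[-nrow(m), , drop = FALSE]
                               }),
             heading = x$heading, diagnosis = x$diagnosis,
             dxClass = x$dxClass, slideClass = x$slideClass,
             organ = x$organ, patchSize = x$patchSize,
             overlapMin = x$overlapMin, tissueMin = x$tissueMin)
  class(gt) <- "GroundTruth"
  gt
}

#' Split a corpus at specimen (block) level
#'
#' Assigns whole blocks to train/validation/test so that serial slides of one
#' specimen never straddle splits; block counts follow the ratios by largest
#' remainder.
#'
#' @param manifest corpus manifest.
#' @param ratios length-3 numeric (train, val, test) summing to 1.
#' @param seed integer seed for the block shuffle.
#' @return the manifest with an added \code{split} column.
#' @export
splitCorpus <- function(manifest, ratios = c(train = 0.8, val = 0.1,
                                             test = 0.1), seed = 1L) {
  if (!nrow(manifest)) stop("empty manifest")
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  if (is.null(names(ratios))) names(ratios) <- c("train", "val", "test")
  blocks <- unique(manifest$block_id)
  counts <- largestRemainder(length(blocks), ratios)
  shuffled <- withSeed(seed, sample(blocks))
  assign <- rep(names(counts), counts)
  names(assign) <- shuffled
  manifest$split <- unname(assign[manifest$block_id])
  manifest
}
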