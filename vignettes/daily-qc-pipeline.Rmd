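---
title: "Patch-based slide classification and daily QC for GI biopsy pathology"
author: "BiopsyQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based slide classification and daily QC for GI biopsy pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiopsyQC)
```

## The problem

Gastrointestinal endoscopic biopsies dominate the histopathology workload of
reference laboratories, and the most dangerous routine error is the false
negative: a missed fragment of carcinoma or dysplasia signed out as negative.
Conventional quality control — a monthly blinded review of a small random
sample of slides — catches such errors weeks late, if at all. The alternative
this package implements is a *post-analytic daily* QC loop: every signed-out
slide is digitized, classified by an image model into three classes

* **M** — malignancy, or high-grade dysplasia, cannot be ruled out,
* **D** — low-grade dysplasia cannot be ruled out,
* **N** — negative for dysplasia,

and the same three-way class is derived independently from the pathologist's
free-text diagnosis by a keyword rule engine. Discordant slides are listed
first for review the next morning. The model does not need to out-diagnose
the pathologist; it needs a high negative predictive value and an
independent, fast second look at everything.

## The image pipeline

A whole-slide image is far too large for a single classifier pass, so the
pipeline follows the standard patch-based decomposition:

1. **Patch maker.** The slide is cut into non-overlapping 256×256 pixel
   tiles (0-based, half-open `[x0, x0+256)` windows; edge tiles padded
   white, never dropped, so border lesions stay visible). Every tile gets a
   row in a per-slide `PatchDB` holding the bijection
   `patch_index = grid_row * n_cols + grid_col` ↔ pixel origin, plus a
   tissue flag from a luminance detector (a tile is tissue when more than
   5 % of its pixels are darker than 230/255; the detector is configurable
   and can be switched off).
2. **Patch classifier.** Each tissue tile is mapped to an (M, D, N)
   probability triple. Training uses class-balanced sampling (all classes
   subsampled to the minimum class count) and a single round of loss-based
   noise removal: after a warm-up fit, the top-*q* fraction of training
   patches by cross-entropy loss is dropped (default *q* = 0.02, capped at
   0.1) and the model is retrained. For M and D slides, training patches
   are restricted to annotation polygons — a tile qualifies when at least
   25 % of its area overlaps an annotation; N slides contribute all tissue
   tiles without annotation.
3. **Reconstructed slide.** The per-patch triples are placed at their grid
   positions in an `n_rows × n_cols × 3` array. Background cells stay exact
   zero vectors — no softmax output can be all-zero, so tissue and
   background remain distinguishable. Placement is pure: any ordering of
   the predictions yields the same array, and probabilities are never
   renormalized.
4. **Slide classifier.** The reconstruction is centred and zero-padded into
   a fixed 64×64 grid (larger grids are area-averaged first) and classified
   into the final slide class. Separate patch+slide model pairs are trained
   for the gastric and the colorectal route.
5. **Heatmap.** Per-patch rectangles at thumbnail scale (default 0.5×):
   red for argmax-M, blue for argmax-D, fully transparent for N and
   background, alpha-composable on and off over the slide thumbnail.

Ties in the argmax resolve toward the more severe class (M > D > N),
consistent with the QC philosophy of preferring the clinically serious
reading.

### The reference classifier

The classifiers are a pluggable interface: anything that maps pixel arrays
(or normalized reconstructions) to probability triples can stand behind the
pipeline, including a deep convolutional network. The *reference*
implementation shipped here is deliberately light: each patch is summarized
by fourteen stain/texture statistics (luminance moments, dark-pixel
fractions at two thresholds, white fraction, per-channel means, gradient
energy and quantiles of the tissue luminance distribution) and fed to a
single-hidden-layer softmax network (`nnet`, 8 hidden units, weight decay
5e-4). The slide classifier works the same way on twelve descriptors of the
normalized reconstruction (per-class mean and maximum confidence, argmax
fractions, and the largest 4-connected blob of M and of D evidence, which
captures spatial coherence of positive tissue). These models train in
minutes on one CPU and are fully seeded; the package's accuracy claims are
about this reference stack on synthetic data, not about any clinical-scale
network.

## The text side

`classifyDx()` classifies a free-text diagnosis by an ordered keyword table
(shipped as YAML, editable per institution):

* class **M** phrases: carcinoma, high, grade undetermined, grade
  uncertain, favor neoplastic, sarcoma, lymphoma, malignant, malignancy,
  cancer;
* class **U** phrases: neuroendocrine, carcinoid, NET (uppercase token
  only) — U marks diagnoses (e.g. neuroendocrine tumors) outside the
  ternary image model;
* class **D** phrases: dysplasia, adenoma, low, indefinite for dysplasia,
  undetermined significance;
* anything else is **N**.

Evaluation order is M, then U, then the sessile-serrated overrides
("sessile serrated adenoma/polyp", "sessile serrated adenoma", "sessile
serrated lesion" force N even though they contain the D keyword "adenoma"),
then D. Matching is token-based after collapsing whitespace and
punctuation: short keywords ("high", "low", "NET") fire only as whole
tokens, so "higher" never triggers M, while keywords of six or more
characters also match inside a token, so "carcinoma" fires in
"adenocarcinoma" and "carcinomatous" — the behaviour the worked clinical
examples require. The bare token "high" fires without a following "grade";
institutions that prefer the stricter reading can replace the phrase in the
YAML table.

`routeOrgan()` picks the gastric or colorectal model from the specimen
heading (stomach / esophagogastric junction / gastroesophageal junction
versus terminal ileum through rectum). Headings that match neither organ —
esophagus, duodenum, anus — or that mix both organs on one line are
*unrouted*: no model is run and the specimen is flagged.

When serial or recut slides of one block disagree, the specimen-level class
is the most serious one present (M > U > D > N): for post-analytic QC a
single suspicious level section outweighs any number of negative ones.

## The concordance engine

`compareClasses()` compares the two classes per slide: scan failures and
unrouted specimens pass through as their own statuses, class-U diagnoses
are excluded from the ternary comparison, everything else is concordant or
discordant by equality. The worklist lists discordant slides first (severe
M↔N, then moderate M↔D, then mild D↔N, then by diagnosis severity),
followed by unrouted, scan-failed, concordant and excluded records, stably
within groups. `computeMetrics()` reports the 3×3 confusion matrix, ternary
accuracy, NPV (fraction of AI-N slides whose diagnosis is also N) and the
binary M-vs-non-M metrics.

Comparison granularity is deliberately per-slide. The built-in fixture of
seven detected error cases includes a switched specimen pair whose
aggregated classes agree perfectly — the error is only visible slide by
slide. Specimen aggregates are computed and reported, but never suppress a
slide-level discordance. The severity taxonomy (severe = M↔N, moderate =
M↔D, mild = D↔N) is this package's own mapping; review verdict fields exist
on the records so confirmed FP/FN slides can be exported as retraining
material.

## The synthetic generator

Clinical slides cannot ship with a package, so every stage is exercised on
synthetic "WSI-like" slides: a white scanner background, a few smooth
elliptical tissue fragments, and procedural class textures — sparse round
nuclei with gland-like ring motifs (N), denser elongated dark nuclei (D),
crowded irregular high-density chromatin (M). Lesions are planted as disc
polygons strictly inside tissue until a target fraction of tissue tiles
carries the lesion label; the ground-truth label grid is recomputed from
exactly those polygons (25 % overlap rule), so generator and extractor can
never disagree about boundary tiles. Routine artifacts — focal blur, dark
fold streaks, regional stain shift, air-bubble discs — are injected at
configurable Poisson rates (defaults around 0.2–0.3 per slide each). They
perturb pixels only and never relabel anything: the pipeline is meant to
train and predict *through* artifacts rather than pretend they do not
exist.

Defaults: 1536×1024 px slides (a 6×4 tile grid), three tissue fragments,
lesion fraction 0.3–0.6 across training corpora, an even gastric/colorectal
mix, and a 20 % M / 30 % D / 50 % N class mix for daily batches (negatives
dominate real sign-out streams). Corpus generation assigns one in ten
specimens a second serial slide; splits are assigned at specimen level by
largest remainder so serial slides never straddle train/validation/test.
Every stream of randomness derives from one master seed, and identical
specs yield byte-identical slides.

What the generator does *not* emulate: real staining variability between
laboratories, the full morphological continuum between low- and high-grade
lesions, gigapixel slide sizes, or scanner-format quirks (images are plain
PNG/TIFF; pyramid formats are out of scope). Passing the synthetic recovery
tests therefore demonstrates that the pipeline's plumbing, bookkeeping and
learning dynamics are correct — not that the reference features would
separate real histology.

## Numerical choices and degenerate inputs

* Probability triples must sum to 1 within 1e-6; background cells are exact
  zeros.
* Argmax ties break M > D > N.
* A slide with no tissue tiles is classified N with a `no_tissue` flag
  rather than erroring.
* Unreadable slide files are retried (3 attempts) and then recorded as scan
  failures; they are excluded from metrics but kept on the worklist.
* Slides without a matching diagnosis record are flagged `no_report` and
  skipped, mirroring an accession mismatch in practice.
* Polygon rasterization uses even-odd scanline filling against pixel
  centres; the same routine defines lesion masks, ground-truth labels and
  annotation-restricted extraction.
* The empty diagnosis string classifies as N (the default class), keeping
  `classifyDx` total.

## Problem sizes used by the shipped studies

The package's own studies (test suite and acceptance script) train on
~2,000 synthetic patches (333 per class per organ) and 150 synthetic
slides (25 per class per organ), evaluate on 600 held-out patches and 66
held-out slides, and run the daily-QC drill on a 60-specimen batch with
five injected reporting errors (two missed-lesion texts, one data-entry
false positive, one switched pair). These sizes keep a full run around ten
minutes on one CPU while leaving the class-recovery margins wide; they are
the package's chosen study conditions, not tuning targets.

One distributional detail matters for anyone swapping in their own patch
source: M/D training patches are generated as a lesion disc over negative
tissue, covering between the 25 % labeling threshold and the whole tile.
This mirrors what annotation-restricted extraction actually labels M/D on
a slide — lesion-*boundary* tiles are mixtures of lesion and negative
texture — and a patch classifier trained only on pure textures
systematically under-calls such tiles at prediction time, which then
corrupts the slide-level features.

## Worked example

```{r example, eval = FALSE}
library(BiopsyQC)

# train the reference models on synthetic corpora (a few minutes, one CPU)
models <- trainReferenceModels(seed = 1)

# a daily batch: 60 specimens, with one data-entry error injected
dir <- tempfile("batch")
manifest <- generateCorpus(60, classMix = c(M = 0.2, D = 0.3, N = 0.5),
                           seed = 8, dir = dir, serialRate = 0.1)
nSlide <- manifest$slide_id[manifest$slide_class == "N"][1]
records <- emitDxRecords(manifest, entryErrorIds = nSlide, seed = 9)

report <- runDailyQC(manifest, records, models = models)
print(report)
head(report$worklist[, c("slide_id", "dx_class", "ai_class",
                         "status", "severity")])
```

The injected entry error surfaces at the top of the worklist as a mild
discordance (diagnosis D, image N), exactly the situation a reviewing
pathologist resolves by rereading the slide and correcting the report.

## Known limitations

* The reference classifiers are texture statistics + small neural
  networks; they are a faithful, fast stand-in for a convolutional
  backbone, not a drop-in clinical model. The interface accepts heavier
  models unchanged.
* The keyword engine is English-language and list-based by design; it does
  not attempt NLP, negation handling, or coded vocabularies.
* Slide I/O covers PNG and TIFF rasters loaded fully into memory;
  level-0-only reads of pyramid scanner formats are assumed upstream.
* Class U exists only on the text side, matching a ternary image model;
  U-diagnosed slides are excluded from metrics and surfaced as exclusions.
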