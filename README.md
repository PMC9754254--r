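# BiopsyQC

AI-assisted **daily quality control** for gastrointestinal endoscopic biopsy
histopathology, in R.

Pathology laboratories sign out thousands of GI biopsy slides; the dangerous
routine error is the false negative that conventional monthly random review
catches a month late. BiopsyQC implements a post-analytic daily QC loop:
every slide is classified twice — once by a patch-based image pipeline, once
by a keyword rule engine reading the pathologist's free-text diagnosis —
into the same three classes:

| class | meaning |
|-------|------------------------------------------------|
| **M** | malignancy / high-grade dysplasia cannot be ruled out |
| **D** | low-grade dysplasia cannot be ruled out |
| **N** | negative for dysplasia |

(plus **U**, uncategorized — e.g. neuroendocrine tumors — on the text side
only). Slides where the two classes disagree are listed first for review the
next morning, before an erroneous report reaches a patient.

## What is inside

* **Patch maker / `PatchDB`** — non-overlapping 256×256 tiling with a
  persistent index ↔ grid ↔ pixel-origin database
  (`patch_index = grid_row · n_cols + grid_col`), white-padded edge tiles,
  configurable luminance tissue detection, and annotation-restricted
  training-patch extraction (≥ 25 % polygon overlap for M/D, all tissue
  tiles for N).
* **Classifiers** — pluggable patch and slide classifiers; the shipped
  reference stack is texture features + a small softmax neural network,
  trained with class-balanced sampling and loss-based noise removal
  (top-*q* trimming after warm-up). Patch confidences are arranged into a
  *reconstructed slide* (grid of (M, D, N) triples, background = exact
  zero), normalized to a fixed 64×64 grid, and classified at slide level;
  separate models per gastric/colorectal route.
* **Heatmaps** — red (M) / blue (D) / transparent (N) patch rectangles at
  thumbnail scale, alpha-composable on and off over the slide.
* **Rule engine** — `classifyDx()` with the keyword table (YAML,
  institution-editable), priority M > U > D > N, sessile-serrated overrides,
  case-sensitive standalone "NET"; `routeOrgan()` for heading-based model
  routing; `aggregateClasses()` for serial-slide specimens.
* **QC engine** — per-slide concordance (`compareClasses`), a
  discordance-first stable worklist, metrics (3×3 confusion, ternary
  accuracy, NPV, binary M-vs-non-M), exclusions for scan failures /
  unrouted specimens / class-U diagnoses, and `runDailyQC()` orchestrating
  the whole loop over a directory of slides.
* **Synthetic generator** — deterministic WSI-like slides with three
  class-distinct procedural textures, planted lesion polygons, routine
  artifacts (blur, folds, stain shift, air bubbles), multi-slide serial
  specimens, diagnosis-text emission with injectable reporting errors
  (entry error, missed-lesion text, switched pair), and specimen-level
  train/val/test splitting. Everything downstream is testable without
  clinical data.

## Worked example

```r
library(BiopsyQC)

models <- trainReferenceModels(seed = 1)          # ~3 min, one CPU

dir <- tempfile("batch")
manifest <- generateCorpus(60, classMix = c(M = 0.2, D = 0.3, N = 0.5),
                           seed = 8, dir = dir, serialRate = 0.1)
nSlide <- manifest$slide_id[manifest$slide_class == "N"][1]
records <- emitDxRecords(manifest, entryErrorIds = nSlide, seed = 9)

report <- runDailyQC(manifest, records, models = models)
print(report)
#> Daily QC report: 66 slides; 1 discordant; 0 without report
#> QCMetrics on 66 slides: ternary accuracy 98.48%, NPV 96.88%, binary (M vs non-M) accuracy 100.00%
#>      M  D  N
#>   M 15  0  0
#>   D  0 19  1
#>   N  0  0 31

head(report$worklist[, c("slide_id", "dx_class", "ai_class", "status")], 3)
#>       slide_id dx_class ai_class     status
#> 2 A00002.B1.S1        D        N discordant
#> 4 A00003.B1.S1        M        M concordant
#> 5 A00004.B1.S1        M        M concordant
```

The single discordance is exactly the injected entry error: slide
`A00002.B1.S1` is negative tissue whose record carries a spurious
"TA, LGD" line, so the text classifies D while the image model says N — a
mild discordance a reviewer resolves by rereading the slide and correcting
the report. It also accounts for the NPV below 100 %: one of the 32 AI-N
slides has a (deliberately wrong) positive diagnosis. A command-line front
end (`inst/scripts/biopsyqc.R`) wraps the same functions as `train`,
`predict`, `classify-dx` and `qc-run` subcommands.

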