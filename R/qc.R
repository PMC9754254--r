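# Concordance / discordance QC engine.
#
# Every signed-out slide is compared 1:1 between its class by pathologic
# diagnosis and its class by image-model prediction. Discordant slides are
# listed first for review; slides with a class-U diagnosis are excluded from
# the ternary comparison, as are scan failures and specimens that could not
# be routed to an organ model. Comparison granularity is per slide --
# specimen-level aggregates are reported but never suppress a slide-level
# discordance (a switched pair of specimens is invisible after aggregation).

CONCORDANCE_STATUS <- c("concordant", "discordant", "scan_failed",
                        "unrouted", "excluded_U")

# severity of a discordance: severe = M vs N, moderate = M vs D, mild = D vs N
discordanceSeverity <- function(dxClass, aiClass) {
  pair <- paste(pmin(dxClass, aiClass), pmax(dxClass, aiClass))
  ifelse(pair == "M N", "severe", ifelse(pair == "D M", "moderate", "mild"))
}

#' Compare diagnosis class against AI class for one slide
#'
#' @param dxClass class by pathologic diagnosis, in M/D/N/U.
#' @param aiClass class by AI prediction (M/D/N), or "scan_failed" /
#'   "unrouted" / NA when no prediction exists.
#' @return status string: scan_failed and unrouted pass through, a class-U
#'   diagnosis is excluded from the ternary comparison, otherwise
#'   concordant/discordant by equality.
#' @examples
#' compareClasses("D", "M")   # "discordant"
#' compareClasses("U", "M")   # "excluded_U"
#' @export
compareClasses <- function(dxClass, aiClass) {
  stopifnot(dxClass %in% c(QC_CLASSES, "U"))
  if (is.na(aiClass) || aiClass %in% c("scan_failed", "unrouted"))
    return(if (is.na(aiClass) || aiClass == "scan_failed") "scan_failed"
           else "unrouted")
  if (dxClass == "U") return("excluded_U")
  if (dxClass == aiClass) "concordant" else "discordant"
}

# build the per-slide concordance table
concordanceTable <- function(records) {
  need <- c("slide_id", "accession", "dx_class", "ai_class")
  stopifnot(all(need %in% names(records)))
  records$status <- vapply(seq_len(nrow(records)), function(i)
    compareClasses(records$dx_class[i], records$ai_class[i]), character(1))
  records$severity <- NA_character_
  disc <- records$status == "discordant"
  records$severity[disc] <- discordanceSeverity(records$dx_class[disc],
                                                records$ai_class[disc])
  # review fields, filled in by the reviewing pathologist
  for (f in c("verdict", "feedback", "reviewed_at"))
    if (!f %in% names(records)) records[[f]] <- NA_character_
  records
}

#' Record a reviewer verdict on a QC record
#'
#' @param records concordance record table (from a \code{QCReport} or
#'   \code{\link{buildWorklist}}).
#' @param slideIdStr slide to annotate.
#' @param verdict one of "dx_correct" (AI false call), "ai_correct"
#'   (diagnosis error), "both_wrong", "unresolved".
#' @param feedback free-text reviewer note.
#' @return the updated record table.
#' @export
reviewRecord <- function(records, slideIdStr,
                         verdict = c("dx_correct", "ai_correct",
                                     "both_wrong", "unresolved"),
                         feedback = NA_character_) {
  verdict <- match.arg(verdict)
  i <- match(slideIdStr, records$slide_id)
  if (is.na(i)) stop("unknown slide_id: ", slideIdStr)
  records$verdict[i] <- verdict
  records$feedback[i] <- feedback
  records$reviewed_at[i] <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  records
}

#' Export reviewed discordances as retraining material
#'
#' Confirmed model errors (verdict \code{dx_correct}: the image model was
#' wrong) are split into false positives and false negatives relative to
#' the diagnosis class, for use as additional training data in a later
#' model update. Export only -- no automatic retraining loop.
#'
#' @param records reviewed concordance record table.
#' @return list with data.frames \code{falsePositives} (AI more severe than
#'   diagnosis) and \code{falseNegatives} (AI less severe).
#' @export
retrainingExport <- function(records) {
  err <- records[!is.na(records$verdict) & records$verdict == "dx_correct" &
                   records$status == "discordant", , drop = FALSE]
  rank <- c(N = 1, D = 2, M = 3)
  fp <- err[rank[err$ai_class] > rank[err$dx_class], , drop = FALSE]
  fn <- err[rank[err$ai_class] < rank[err$dx_class], , drop = FALSE]
  list(falsePositives = fp, falseNegatives = fn)
}

#' Order QC records into the daily review worklist
#'
#' Discordant slides come first (severe, then moderate, then mild; within a
#' severity band ordered by diagnosis-class seriousness M > D > N), then
#' unrouted specimens, scan failures, concordant slides and finally class-U
#' exclusions. Ordering is stable: ties keep their input (accession) order.
#'
#' @param records data.frame with slide_id, accession, dx_class, ai_class
#'   (status/severity columns are computed when absent).
#' @return the reordered data.frame with status and severity columns.
#' @export
buildWorklist <- function(records) {
  if (!"status" %in% names(records)) records <- concordanceTable(records)
  statusRank <- c(discordant = 1, unrouted = 2, scan_failed = 3,
                  concordant = 4, excluded_U = 5)
  sevRank <- c(severe = 1, moderate = 2, mild = 3)
  dxRank <- c(M = 1, U = 2, D = 3, N = 4)
  ord <- order(statusRank[records$status],
               ifelse(is.na(records$severity), 9,
                      sevRank[records$severity]),
               dxRank[records$dx_class])
  records[ord, , drop = FALSE]
}

#' Compute QC metrics from compared records
#'
#' Builds the 3x3 confusion matrix (diagnosis rows, AI columns; M, D, N)
#' over records included after exclusions and derives: ternary accuracy
#' (trace/total), NPV (fraction of AI-N slides with diagnosis class N), and
#' binary metrics after collapsing \{D, N\} into non-M with M positive.
#'
#' @param records data.frame with dx_class and ai_class (status computed if
#'   absent).
#' @return a \linkS4class{QCMetrics}.
#' @examples
#' rec <- data.frame(slide_id = letters[1:10], accession = letters[1:10],
#'                   dx_class = c(rep("N", 9), "D"), ai_class = "N")
#' computeMetrics(rec)  # NPV 0.9
#' @export
computeMetrics <- function(records) {
  if (!"status" %in% names(records)) records <- concordanceTable(records)
  excl <- table(factor(records$status,
                       levels = c("scan_failed", "unrouted", "excluded_U")))
  inc <- records[records$status %in% c("concordant", "discordant"), ]
  if (!nrow(inc)) stop("no records remain after exclusions")
  conf <- table(factor(inc$dx_class, levels = QC_CLASSES),
                factor(inc$ai_class, levels = QC_CLASSES))
  conf <- unclass(as.matrix(conf))
  total <- sum(conf)
  aiN <- sum(conf[, "N"])
  npv <- if (aiN > 0) conf["N", "N"] / aiN else NA_real_
  tp <- conf["M", "M"]
  fn <- sum(conf["M", c("D", "N")])
  fp <- sum(conf[c("D", "N"), "M"])
  tn <- sum(conf[c("D", "N"), c("D", "N")])
  new("QCMetrics", confusion = conf,
      ternaryAccuracy = sum(diag(conf)) / total,
      npv = npv,
      binaryAccuracy = (tp + tn) / total,
      binarySensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      binarySpecificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      excluded = stats::setNames(as.integer(excl), names(excl)),
      nIncluded = as.integer(total))
}

#' Built-in worked example: detected error cases
#'
#' A small fixture of seven historical error cases detected by a daily QC
#' run of this kind (false negatives, a data-entry false positive, and one
#' switched specimen pair recorded as two slides), encoded as per-slide
#' (class-by-diagnosis, class-by-AI) pairs.
#'
#' @return data.frame with case_id, slide_id, accession, error_type,
#'   dx_class, ai_class.
#' @export
demoErrorCases <- function() {
  path <- system.file("extdata", "detected_error_cases.csv",
                      package = "BiopsyQC")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the per-slide comparator over the error-case fixture
#'
#' Every case in the fixture contains at least one discordant slide; the
#' return value is the number of distinct cases flagged. The switched-pair
#' case also illustrates why comparison must stay per-slide: aggregating its
#' two slides per specimen makes both columns agree and the error vanishes.
#'
#' @param cases fixture data.frame (default \code{\link{demoErrorCases}}).
#' @return integer count of cases with at least one discordant slide.
#' @export
checkErrorCases <- function(cases = demoErrorCases()) {
  cases <- concordanceTable(cases)
  length(unique(cases$case_id[cases$status == "discordant"]))
}

#' Run the daily QC workflow over a batch of slides
#'
#' For every slide file in the batch: look up its diagnosis record by slide
#' id (file name), route the specimen heading to an organ model, predict the
#' slide class, classify the diagnosis text, and compare the two classes.
#' Slides without a diagnosis record are flagged \code{no_report}; unreadable
#' slides are retried and then marked scan failures; unrouted specimens get
#' no prediction. Specimen-level aggregates (priority order M > U > D > N
#' over the slides of one block) are reported alongside, but slide-level
#' discordances are never suppressed by them.
#'
#' @param slidePaths character vector of slide image paths (file name without
#'   extension = slide id), or a manifest data.frame with \code{path} and
#'   \code{slide_id} columns.
#' @param dxRecords data.frame with slide_id, accession, block_id, heading,
#'   diagnosis.
#' @param models model set as in \code{\link{predictSlide}}, or a function
#'   \code{(slideId, organ) -> class} standing in as a ground-truth oracle.
#' @param rules a \code{KeywordTable}.
#' @param maxRetries read attempts before a slide counts as a scan failure.
#' @param heatmapDir if non-NULL, write per-slide heatmap PNGs here.
#' @return list of class \code{QCReport}: \code{records} (per-slide statuses),
#'   \code{worklist}, \code{metrics} (a \linkS4class{QCMetrics}),
#'   \code{specimens} (block-level aggregate table), \code{unmatched}
#'   (slide ids without diagnosis records).
#' @export
runDailyQC <- function(slidePaths, dxRecords, models,
                       rules = loadKeywordTable(), maxRetries = 3L,
                       heatmapDir = NULL) {
  if (is.data.frame(slidePaths)) {
    paths <- slidePaths$path
    ids <- slidePaths$slide_id
  } else {
    paths <- slidePaths
    ids <- tools::file_path_sans_ext(basename(paths))
  }
  oracle <- is.function(models)
  rows <- list(); unmatched <- character()
  for (i in seq_along(paths)) {
    sid <- ids[i]
    ridx <- match(sid, dxRecords$slide_id)
    if (is.na(ridx)) { unmatched <- c(unmatched, sid); next }
    rec <- dxRecords[ridx, ]
    organ <- routeOrgan(rec$heading, rules)
    dxClass <- classifyDx(rec$diagnosis, rules)
    aiClass <- NA_character_
    flags <- character()
    if (organ == "unrouted") {
      aiClass <- "unrouted"
    } else if (oracle) {
      aiClass <- models(sid, organ)
    } else {
      pred <- NULL
      for (try in seq_len(maxRetries)) {
        pred <- tryCatch({
          raster <- readSlide(paths[i], slideId = sid)
          predictSlide(models, raster, organ)
        }, error = function(e) NULL)
        if (!is.null(pred)) break
      }
      if (is.null(pred)) {
        aiClass <- "scan_failed"
      } else {
        aiClass <- finalClass(pred$prediction)
        flags <- pred$prediction@flags
        if (!is.null(heatmapDir) && nrow(pred$db@predictions)) {
          dir.create(heatmapDir, showWarnings = FALSE, recursive = TRUE)
          hm <- renderHeatmap(pred$db@predictions, pred$db)
          writeHeatmapPNG(hm, file.path(heatmapDir, paste0(sid, ".heat.png")))
        }
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      slide_id = sid, accession = rec$accession, block_id = rec$block_id,
      organ = organ, dx_class = dxClass, ai_class = aiClass,
      flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  }
  records <- concordanceTable(do.call(rbind, rows))
  # block-level aggregation (reported, never overriding per-slide status)
  aggRows <- lapply(groupSpecimens(records), function(g) {
    keep <- !g$ai_class %in% c("scan_failed", "unrouted") & !is.na(g$ai_class)
    data.frame(block_id = g$block_id, n_slides = length(g$slide_ids),
               dx_final = aggregateClasses(g$dx_class),
               ai_final = if (any(keep)) aggregateClasses(g$ai_class[keep])
                          else NA_character_, stringsAsFactors = FALSE)
  })
  specimens <- do.call(rbind, aggRows)
  rownames(specimens) <- NULL
  out <- list(records = records, worklist = buildWorklist(records),
              metrics = computeMetrics(records), specimens = specimens,
              unmatched = unmatched)
  class(out) <- "QCReport"
  out
}

#' @export
print.QCReport <- function(x, ...) {
  cat("Daily QC report:", nrow(x$records), "slides;",
      sum(x$records$status == "discordant"), "discordant;",
      length(x$unmatched), "without report\n")
  show(x$metrics)
  invisible(x)
}

#' Write a QC report to disk
#'
#' JSON report (metrics + per-slide records + specimen aggregates) plus the
#' worklist as CSV.
#'
#' @param report a \code{QCReport}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeQCReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- report$metrics
  jsonlite::write_json(list(
    n_slides = nrow(report$records),
    ternary_accuracy = m@ternaryAccuracy, npv = m@npv,
    binary_accuracy = m@binaryAccuracy,
    confusion = m@confusion,
    excluded = as.list(m@excluded),
    records = report$records, specimens = report$specimens,
    unmatched = report$unmatched),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$worklist, file.path(dir, "worklist.csv"),
                   row.names = FALSE)
  invisible(dir)
}
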