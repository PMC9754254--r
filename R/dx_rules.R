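# Rule engine for free-text pathologic diagnoses.
#
# Diagnosis strings are classified into M (malignancy or high-grade dysplasia
# cannot be ruled out), D (low-grade dysplasia), N (negative for dysplasia)
# or U (uncategorized, e.g. neuroendocrine tumor) by an ordered keyword
# table; specimen headings are routed to the gastric or colorectal model.
# Classification is a pure, total function of the text given the table.

.rulesCache <- new.env(parent = emptyenv())

#' Load a keyword rule table
#'
#' Reads the YAML keyword table (class phrase lists, sessile-serrated
#' N-overrides, case-sensitive flags, substring threshold, organ routes).
#' With no argument, returns the packaged default table (cached).
#'
#' @param path YAML file; NULL for the packaged default.
#' @return a list of class \code{KeywordTable}.
#' @export
loadKeywordTable <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rulesCache$default)) return(.rulesCache$default)
    path <- system.file("extdata", "dx_keywords.yaml", package = "BiopsyQC")
    tab <- .parseKeywordTable(path)
    .rulesCache$default <- tab
    return(tab)
  }
  .parseKeywordTable(path)
}

.parseKeywordTable <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(all(c("classes", "n_overrides") %in% names(y)))
  if (any(!nzchar(unlist(y$classes)))) stop("empty keyword phrase in table")
  tab <- list(
    classes = lapply(y$classes, as.character),
    nOverrides = as.character(y$n_overrides),
    caseSensitive = as.character(y$case_sensitive %||% character()),
    substringMinChars = as.integer(y$substring_min_chars %||% 6L),
    organRoutes = lapply(y$organ_routes %||% list(), as.character))
  class(tab) <- "KeywordTable"
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tokenize on runs of non-alphanumeric characters, preserving case
.tokenize <- function(text) {
  toks <- strsplit(text, "[^[:alnum:]]+")[[1]]
  toks[nzchar(toks)]
}

# does a (possibly multi-word) keyword phrase match the token sequence?
# each phrase token must match the corresponding text token, contiguously;
# long keyword tokens (>= minSub chars) may match inside a text token
.phraseMatches <- function(phraseToks, textToks, minSub, caseSensitive) {
  np <- length(phraseToks); nt <- length(textToks)
  if (np == 0 || nt < np) return(FALSE)
  if (!caseSensitive) {
    phraseToks <- tolower(phraseToks)
    textToks <- tolower(textToks)
  }
  for (start in seq_len(nt - np + 1)) {
    ok <- TRUE
    for (k in seq_len(np)) {
      pt <- phraseToks[k]; tt <- textToks[start + k - 1]
      hit <- if (nchar(pt) >= minSub) grepl(pt, tt, fixed = TRUE)
             else pt == tt
      if (!hit) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

.anyPhrase <- function(phrases, textToks, tab) {
  for (ph in phrases) {
    phToks <- .tokenize(ph)
    cs <- ph %in% tab$caseSensitive
    if (.phraseMatches(phToks, textToks, tab$substringMinChars, cs))
      return(TRUE)
  }
  FALSE
}

#' Classify a free-text pathologic diagnosis
#'
#' Applies the keyword table in priority order M > U > D > N, with the
#' sessile-serrated phrases overriding class D (a sessile serrated lesion
#' contains the D keyword "adenoma" but is negative for dysplasia). Keywords
#' match case-insensitively at token level, except phrases flagged
#' case-sensitive ("NET" fires only as an uppercase standalone token); long
#' keywords also match within a token, so "carcinoma" fires inside
#' "adenocarcinoma". Any text matching nothing is class N.
#'
#' @param diagnosisText character vector of diagnosis strings (multi-line
#'   strings are classified over all their lines together).
#' @param table a \code{KeywordTable}; default the packaged table.
#' @return character vector over \{"M", "D", "N", "U"\}.
#' @examples
#' classifyDx("Tubular adenoma, low grade dysplasia")          # "D"
#' classifyDx("Tubulovillous adenoma, low to focal high grade dysplasia") # "M"
#' classifyDx("Sessile serrated lesion")                       # "N"
#' @export
classifyDx <- function(diagnosisText, table = loadKeywordTable()) {
  vapply(diagnosisText, function(txt) {
    if (is.na(txt)) return("N")
    toks <- .tokenize(txt)
    if (.anyPhrase(table$classes$M, toks, table)) return("M")
    if (.anyPhrase(table$classes$U, toks, table)) return("U")
    if (.anyPhrase(table$nOverrides, toks, table)) return("N")
    if (.anyPhrase(table$classes$D, toks, table)) return("D")
    "N"
  }, character(1), USE.NAMES = FALSE)
}

#' Route a specimen heading to an organ model
#'
#' Case-insensitive phrase match of the heading against the organ keyword
#' lists. Headings are split into lines (multi-part specimens); a line
#' matching keywords of both organs, or matching neither organ on every
#' line, returns "unrouted" -- no model is run for such specimens.
#'
#' @param heading character vector of specimen headings.
#' @param table a \code{KeywordTable} with an \code{organRoutes} element.
#' @return character vector over \{"gastric", "colorectal", "unrouted"\}.
#' @examples
#' routeOrgan("Stomach, endoscopic biopsy")              # "gastric"
#' routeOrgan("Duodenum, endoscopic biopsy")             # "unrouted"
#' @export
routeOrgan <- function(heading, table = loadKeywordTable()) {
  routes <- table$organRoutes
  vapply(heading, function(h) {
    if (is.na(h)) return("unrouted")
    lines <- strsplit(h, "\n", fixed = TRUE)[[1]]
    found <- character()
    for (ln in lines) {
      toks <- .tokenize(ln)
      hit <- names(routes)[vapply(routes, function(phr)
        .anyPhrase(phr, toks, list(caseSensitive = character(),
                                   substringMinChars = 100L)), logical(1))]
      if (length(hit) > 1) return("unrouted")  # both organs on one line
      found <- union(found, hit)
    }
    if (length(found) == 1) found else "unrouted"
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate per-slide classes into a specimen-level class
#'
#' Serial or recut slides of one block may receive different classes; the
#' final class is the most clinically serious one present, under the total
#' order M > U > D > N. The operation is the maximum under that order:
#' commutative, associative and idempotent.
#'
#' @param classes non-empty character vector over \{"M", "D", "N", "U"\}.
#' @return single class.
#' @examples
#' aggregateClasses(c("D", "D", "M", "N"))  # "M"
#' @export
aggregateClasses <- function(classes) {
  if (!length(classes)) stop("cannot aggregate an empty class list")
  bad <- setdiff(classes, names(CLASS_PRIORITY))
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  names(which.max(CLASS_PRIORITY[classes]))
}

#' Group slide records into specimens by block
#'
#' @param records data.frame with columns slide_id and block_id (and
#'   optionally per-slide ai_class / dx_class columns, which are carried
#'   along). Slides with a missing block id become singleton groups, with a
#'   warning.
#' @return list of \code{SpecimenGroup} lists: block_id, slide_ids, and any
#'   per-slide class columns present.
#' @export
groupSpecimens <- function(records) {
  stopifnot(all(c("slide_id", "block_id") %in% names(records)))
  miss <- is.na(records$block_id) | !nzchar(records$block_id)
  if (any(miss)) {
    warning(sum(miss), " slide(s) with missing block_id form singleton groups")
    records$block_id[miss] <- paste0("__singleton__", records$slide_id[miss])
  }
  lapply(split(records, records$block_id), function(g) {
    grp <- list(block_id = g$block_id[1], slide_ids = g$slide_id)
    for (cl in intersect(c("ai_class", "dx_class"), names(g)))
      grp[[cl]] <- g[[cl]]
    class(grp) <- "SpecimenGroup"
    grp
  })
}
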