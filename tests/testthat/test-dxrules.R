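# Keyword rule engine: golden diagnosis strings, organ routing, priority
# and override behaviour, serial-slide aggregation.

test_that("golden diagnosis strings map to their documented classes", {
  golden <- c(
    "Adenocarcinoma, moderately differentiated"              = "M",
    "Neoplastic lesion, suspicious for malignancy"           = "M",
    "Tubular adenoma, high grade dysplasia"                  = "M",
    "Tubulovillous adenoma, low to focal high grade dysplasia" = "M",
    "Adenoma with focal carcinomatous change"                = "M",
    "Tubular adenoma, grade uncertain"                       = "M",
    "Malignant neoplasm"                                     = "M",
    "Atypical glandular proliferation, favor neoplastic"     = "M",
    "Neuroendocrine carcinoma"                               = "M",
    "Tubular adenoma, low grade dysplasia"                   = "D",
    "Atypical glandular proliferation, favor dysplasia"      = "D",
    "Atypical glandular proliferation, indefinite for dysplasia" = "D",
    "Atypical glandular proliferation, undetermined significance" = "D",
    "Small cell nests with neuroendocrine feature"           = "U",
    "Neuroendocrine tumor, grade 1 (carcinoid tumor)"        = "U",
    "Sessile serrated lesion"                                = "N")
  got <- classifyDx(names(golden))
  expect_identical(got, unname(golden))
})

test_that("unmatched and empty strings default to class N", {
  expect_identical(classifyDx(""), "N")
  expect_identical(classifyDx("Chronic gastritis"), "N")
  expect_identical(classifyDx("Hyperplastic polyp"), "N")
  expect_identical(classifyDx(NA_character_), "N")
})

test_that("NET fires only as an uppercase standalone token", {
  expect_identical(classifyDx("NET, grade 1"), "U")
  expect_identical(classifyDx("a net-like growth pattern"), "N")
  expect_identical(classifyDx("Net proliferation"), "N")
  expect_identical(classifyDx("MAGNET sign"), "N")
})

test_that("short keywords respect word boundaries, long ones match inside tokens", {
  expect_identical(classifyDx("higher cellularity, no atypia"), "N")
  expect_identical(classifyDx("high grade dysplasia"), "M")
  expect_identical(classifyDx("lowering of crypt density"), "N")
  expect_identical(classifyDx("low grade dysplasia"), "D")
  # disease-root compounds
  expect_identical(classifyDx("cholangiocarcinoma metastasis"), "M")
  expect_identical(classifyDx("adenomatous change"), "D")
})

test_that("sessile-serrated phrases override class D keywords", {
  for (s in c("Sessile serrated adenoma/polyp", "Sessile serrated adenoma",
              "sessile serrated lesion with no dysplasia"))
    expect_identical(classifyDx(s), "N")
  # but an M keyword still wins over the override
  expect_identical(classifyDx("Sessile serrated lesion, high grade"), "M")
})

test_that("appending an M keyword to any string yields class M", {
  base <- c("", "Chronic gastritis", "Tubular adenoma, low grade dysplasia",
            "Sessile serrated lesion", "Neuroendocrine tumor, grade 1",
            "Atypical glandular proliferation, undetermined significance")
  mWords <- c("carcinoma", "malignancy", "cancer", "sarcoma")
  for (b in base) for (m in mWords)
    expect_identical(classifyDx(paste(b, m)), "M")
})

test_that("headings route to the documented organ models", {
  expect_identical(routeOrgan("Stomach, endoscopic biopsy"), "gastric")
  expect_identical(routeOrgan("Esophagogastric junction, biopsy"), "gastric")
  expect_identical(routeOrgan("Rectosigmoid junction, colonoscopic biopsy"),
                   "colorectal")
  expect_identical(routeOrgan(c("Terminal ileum, biopsy", "Cecum, biopsy",
                                "Colon and Rectum, biopsy")),
                   rep("colorectal", 3))
  # organs with no model stay unrouted
  expect_identical(routeOrgan("Duodenum, endoscopic biopsy"), "unrouted")
  expect_identical(routeOrgan("Esophagus, endoscopic biopsy"), "unrouted")
  expect_identical(routeOrgan("Anus, biopsy"), "unrouted")
  # one line naming both organs is flagged for review, not guessed
  expect_identical(routeOrgan("Stomach and colon, mapping biopsy"),
                   "unrouted")
  # multi-line headings route by their single consistent organ
  expect_identical(routeOrgan("A. Stomach, biopsy\nB. Stomach, biopsy"),
                   "gastric")
})

test_that("aggregation picks the most serious class, matching brute force", {
  expect_identical(aggregateClasses(c("D", "D", "M", "N")), "M")
  expect_identical(aggregateClasses("N"), "N")
  expect_identical(aggregateClasses(c("D", "U")), "U")
  # exhaustive agreement over all class lists of length <= 3
  classes <- c("M", "D", "N", "U")
  for (n in 1:3) {
    grids <- do.call(expand.grid, rep(list(classes), n))
    for (i in seq_len(nrow(grids))) {
      lst <- as.character(unlist(grids[i, ]))
      expect_identical(aggregateClasses(lst), aggregateOracle(lst))
    }
  }
  expect_error(aggregateClasses(character()), "empty")
})

test_that("aggregation is order-insensitive and idempotent", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      lst <- sample(c("M", "D", "N", "U"), sample(1:6, 1), replace = TRUE)
      a <- aggregateClasses(lst)
      expect_identical(aggregateClasses(sample(lst)), a)
      expect_identical(aggregateClasses(c(lst, a)), a)
    }
  })
})

test_that("specimens group by block with singleton fallback", {
  rec <- data.frame(slide_id = c("s1", "s2", "s3", "s4"),
                    block_id = c("B1", "B1", "B2", NA),
                    ai_class = c("D", "M", "N", "N"))
  expect_warning(groups <- groupSpecimens(rec), "singleton")
  expect_length(groups, 3)
  b1 <- groups[[which(vapply(groups, function(g) g$block_id == "B1",
                             logical(1)))]]
  expect_setequal(b1$slide_ids, c("s1", "s2"))
  expect_identical(aggregateClasses(b1$ai_class), "M")
})

test_that("a custom rule table can extend the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("substring_min_chars: 6",
               "classes:",
               "  M: [carcinoma]",
               "  U: []",
               "  D: [adenoma, 'my local phrase']",
               "n_overrides: []"), path)
  tab <- loadKeywordTable(path)
  expect_identical(classifyDx("my local phrase here", tab), "D")
  expect_identical(classifyDx("sessile serrated adenoma", tab), "D")
})
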