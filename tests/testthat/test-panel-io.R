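test_that("panel definitions validate their invariants on construction", {
  p <- toyPanel()
  expect_s4_class(p, "SplicingPanel")
  expect_length(p, 5L)
  expect_identical(referenceIds(p), c("REF1", "REF2"))
  b <- panelEvent(p, "#B")
  expect_identical(b$sizes[[1]], c(141L, 150L, 215L))
  expect_identical(b$relevant[[1]], c(150L, 215L))
  expect_identical(b$designated, 150L)  # smaller relevant product by default

  expect_error(SplicingPanel(c("#1", "#1"), event_type = "alt_5ss",
                             sizes = list(c(100L, 200L), c(100L, 200L))),
               "duplicate")
  expect_error(SplicingPanel("#1", event_type = "alt_5ss",
                             sizes = list(c(200L, 100L))),
               "strictly increasing")
  expect_error(SplicingPanel("#1", event_type = "alt_5ss",
                             sizes = list(c(100L, 200L)),
                             relevant = list(c(100L, 300L))),
               "subset")
  expect_error(SplicingPanel("#1", event_type = "alt_5ss",
                             sizes = list(c(100L, 200L)),
                             designated = 300L),
               "designated")
  expect_error(SplicingPanel("REF", event_type = "reference",
                             sizes = list(c(100L, 200L))),
               "exactly one")
})

test_that("panel TSV round-trips exactly and bad rows are named", {
  path <- tempfile(fileext = ".tsv")
  writePanelDefinition(toyPanel(), path)
  p2 <- readPanelDefinition(path)
  ev1 <- as.data.frame(panelEvents(toyPanel()))
  ev2 <- as.data.frame(panelEvents(p2))
  expect_identical(ev1, ev2)

  df <- data.frame(primer_pair = c("#1", "#1"), agi = "At1g00001",
                   description = "x", product_sizes = "100/200",
                   event_type = "alt_5ss")
  expect_error(readPanelDefinition(writeTempTsv(df)), "duplicate")

  df2 <- df[1, ]; df2$product_sizes <- "200/100"
  expect_error(readPanelDefinition(writeTempTsv(df2)), "row 1")

  df3 <- df[1, ]; df3$event_type <- "mystery"
  expect_error(readPanelDefinition(writeTempTsv(df3)), "mystery")
})

test_that("an empty panel file yields an empty panel with a warning", {
  path <- writeTempTsv(data.frame(primer_pair = character(),
                                  agi = character(),
                                  description = character(),
                                  product_sizes = character(),
                                  event_type = character()))
  expect_warning(p <- readPanelDefinition(path), "no events")
  expect_length(p, 0L)
})

test_that("the shipped example panel parses with its curated flags", {
  p <- readPanelDefinition(system.file("extdata", "grp7_example_panel.tsv",
                                       package = "ASpanel"))
  expect_identical(panelEvent(p, "#226")$sizes[[1]], c(143L, 309L))
  e12 <- panelEvent(p, "#12")
  expect_identical(e12$relevant[[1]], c(150L, 215L))
  expect_identical(e12$designated, 150L)
  expect_identical(sort(referenceIds(p)), c("REF_ACTIN11", "REF_RPL12c"))
})

test_that("peak tables are validated, extras ignored, unknowns reported", {
  df <- data.frame(sample_id = "s1", primer_pair = "#A",
                   size_bp = c(143.1, 309.0), area = c(10, 20),
                   dye = "FAM", height = c(5, 7))
  pk <- readPeakTable(writeTempTsv(df, ".csv"))
  expect_identical(nrow(pk), 2L)
  expect_identical(colnames(pk),
                   c("sample_id", "primer_pair", "size_bp", "area"))

  bad <- df; bad$area[2] <- -5
  expect_error(readPeakTable(writeTempTsv(bad, ".csv")), "row.*2")
  bad2 <- df; bad2$size_bp <- c("143.1", "oops")
  expect_error(readPeakTable(writeTempTsv(bad2, ".csv")), "row")

  df$primer_pair <- c("#A", "#ZZ")
  expect_warning(pk <- readPeakTable(writeTempTsv(df, ".csv"), toyPanel()),
                 "#ZZ")
  expect_identical(attr(pk, "unknown_primer_pairs"), "#ZZ")
  expect_identical(nrow(pk), 2L)  # kept, not dropped
})

test_that("peak assignment follows nearest-within-tolerance, area tie-break", {
  ev <- toyPanel()["#A"]  # sizes 158/316
  pk <- data.frame(size_bp = c(157.8, 316.2, 402.0), area = c(500, 30, 100))
  a <- assignPeaks(pk, ev)
  expect_equal(a$matched$area, c(500, 30))
  expect_false(any(a$matched$missing))
  expect_equal(a$unmatched$size_bp, 402.0)

  # no peaks at all: zero areas, missing flags set
  a0 <- assignPeaks(pk[0, ], toyPanel()["#C"])
  expect_equal(a0$matched$area, c(0, 0))
  expect_true(all(a0$matched$missing))

  # two candidates for one expected size: the nearer wins (enumerated rule)
  evB <- SplicingPanel("#one", event_type = "alt_5ss", sizes = list(150L))
  cand <- data.frame(size_bp = c(149.6, 150.3), area = c(10, 90))
  dists <- abs(cand$size_bp - 150)
  expect_identical(which.min(dists), 2L)  # oracle: enumerate both candidates
  expect_equal(assignPeaks(cand, evB)$matched$area, 90)

  # equidistant candidates: larger area wins
  tie <- data.frame(size_bp = c(149.7, 150.3), area = c(10, 90))
  expect_equal(assignPeaks(tie, evB)$matched$area, 90)

  # overlapping windows claiming one peak
  evO <- SplicingPanel("#two", event_type = "alt_3ss",
                       sizes = list(c(150L, 151L)))
  expect_error(assignPeaks(data.frame(size_bp = 150.5, area = 1), evO),
               "smaller tolerance")
  expect_error(assignPeaks(pk, ev, tolerance = 0), "positive")
})

test_that("assignment conserves area and ignores peak order", {
  set.seed(42)
  ev <- toyPanel()["#A"]
  for (i in 1:25) {
    n <- sample(0:6, 1)
    pk <- data.frame(size_bp = runif(n, 100, 400), area = rexp(n, 1 / 100))
    a <- assignPeaks(pk, ev)
    expect_equal(sum(a$matched$area) + sum(a$unmatched$area), sum(pk$area))
    perm <- pk[sample(seq_len(nrow(pk))), , drop = FALSE]
    b <- assignPeaks(perm, ev)
    expect_equal(a$matched$area, b$matched$area)
    expect_equal(sort(a$unmatched$size_bp), sort(b$unmatched$size_bp))
  }
})
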