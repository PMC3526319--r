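test_that("isoform percentages are relevant-area fractions times 100", {
  panel <- toyPanel()
  evA <- panel["#A"]
  a <- assignPeaks(data.frame(size_bp = c(158, 316), area = c(470, 30)), evA)
  prof <- isoformPercentages(a, evA)
  expect_equal(unname(prof$percent), c(94, 6))
  expect_false(prof$undefined)

  # single observed isoform carries 100%
  a1 <- assignPeaks(data.frame(size_bp = 158, area = 77), evA)
  expect_equal(unname(isoformPercentages(a1, evA)$percent), c(100, 0))

  # non-relevant isoform excluded from the denominator
  evB <- panel["#B"]  # sizes 141/150/215, relevant 150/215
  aB <- assignPeaks(data.frame(size_bp = c(141, 150, 215),
                               area = c(50, 30, 70)), evB)
  profB <- isoformPercentages(aB, evB)
  expect_equal(unname(profB$percent), c(NA, 30, 70))
  expect_equal(profB$total_area, 100)

  # zero relevant area: undefined, all NA
  a0 <- assignPeaks(data.frame(size_bp = numeric(), area = numeric()), evA)
  prof0 <- isoformPercentages(a0, evA)
  expect_true(prof0$undefined)
  expect_true(all(is.na(prof0$percent)))

  expect_error(isoformPercentages(a, evB), "belongs to")
})

test_that("percent assay conserves 100 and undefined profiles are tracked", {
  samples <- toySamples()
  ie <- toyExperiment(list("#A" = c(30, 31, 29, 60, 61, 59),
                           "#B" = 25, "#C" = 0))
  pct <- assay(ie, "percent")
  rel <- rowData(ie)$relevant
  sums <- rowsum(ifelse(is.na(pct[rel, ]), 0, pct[rel, ]),
                 rowData(ie)$primer_pair[rel])
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_identical(nrow(metadata(ie)$undefined), 0L)

  # drop one event's peaks in one sample -> undefined there, defined elsewhere
  pk <- toyPeaks(samples, list("#A" = 30, "#B" = 25, "#C" = 50))
  pk <- pk[!(pk$sample_id == "s_wt_1" & pk$primer_pair == "#A"), ]
  ie2 <- buildIsoformExperiment(pk, toyPanel(), samples)
  und <- metadata(ie2)$undefined
  expect_identical(und$primer_pair, "#A")
  expect_identical(und$sample_id, "s_wt_1")
  expect_true(all(is.na(assay(ie2, "percent")[rowData(ie2)$primer_pair == "#A",
                                              "s_wt_1"])))
})

test_that("percentages are scale invariant; expression ratios are not", {
  samples <- toySamples("wt", 2)
  pk <- toyPeaks(samples, list("#A" = 35, "#C" = 80))
  ie <- buildIsoformExperiment(pk, toyPanel(), samples)
  pk2 <- pk
  scale <- ifelse(pk2$sample_id == "s_wt_1" & !grepl("REF", pk2$primer_pair),
                  7, 1)
  pk2$area <- pk2$area * scale
  ie2 <- buildIsoformExperiment(pk2, toyPanel(), samples)
  expect_equal(assay(ie, "percent"), assay(ie2, "percent"))
  te <- totalExpression(ie)
  te2 <- totalExpression(ie2)
  r1 <- te$ratio[te$sample_id == "s_wt_1" & te$primer_pair == "#A" &
                   te$reference == "REF1"]
  r2 <- te2$ratio[te2$sample_id == "s_wt_1" & te2$primer_pair == "#A" &
                    te2$reference == "REF1"]
  expect_equal(r2, 7 * r1)
})

test_that("replicate summaries match a brute-force mean/SD/SEM", {
  ie <- toyExperiment(list("#A" = c(30, 31, 29, 40, 40, 40)))
  sm <- summarizeReplicates(ie, "wt")
  row <- sm[sm$primer_pair == "#A" & sm$size == 158, ]
  expect_equal(row$mean, 30)
  expect_equal(row$sd, 1)
  expect_equal(row$sem, 1 / sqrt(3))
  expect_identical(row$n, 3)

  # identical replicates: zero spread
  smOx <- summarizeReplicates(ie, "ox")
  rowOx <- smOx[smOx$primer_pair == "#A" & smOx$size == 158, ]
  expect_equal(rowOx$sd, 0)
  expect_equal(rowOx$sem, 0)

  # brute force over random percentages
  set.seed(3)
  vals <- round(runif(6, 10, 90), 3)
  ieR <- toyExperiment(list("#A" = vals))
  smR <- summarizeReplicates(ieR)
  for (g in c("wt", "ox")) {
    v <- vals[if (g == "wt") 1:3 else 4:6]
    r <- smR[smR$genotype == g & smR$primer_pair == "#A" & smR$size == 158, ]
    expect_equal(r$mean, mean(v))
    expect_equal(r$sd, sd(v))
    expect_equal(r$sem, sd(v) / sqrt(3))
  }

  # single replicate: descriptive only, spread flagged undefined-as-0
  ie1 <- toyExperiment(list("#A" = 42), samples = toySamples("wt", 1))
  sm1 <- summarizeReplicates(ie1)
  r1 <- sm1[sm1$primer_pair == "#A" & sm1$size == 158, ]
  expect_equal(r1$mean, 42)
  expect_equal(r1$sd, 0)
  expect_false(r1$sd_defined)
})

test_that("total expression is computed against both references", {
  # total relevant area 1000 per event; REF1 500, REF2 250
  ie <- toyExperiment(list("#A" = 30), samples = toySamples("wt", 2))
  te <- totalExpression(ie)
  a1 <- te[te$primer_pair == "#A" & te$reference == "REF1", "ratio"]
  a2 <- te[te$primer_pair == "#A" & te$reference == "REF2", "ratio"]
  expect_equal(unique(a1), 2)
  expect_equal(unique(a2), 4)

  expect_equal(expressionRatio(200, 100), 2)
  expect_error(expressionRatio(200, 0), "positive")

  # zero-area event: ratio 0 with flag
  samples <- toySamples("wt", 2)
  pk <- toyPeaks(samples, list("#A" = 30, "#C" = 50))
  pk$area[pk$primer_pair == "#C"] <- 0
  ieZ <- buildIsoformExperiment(pk, toyPanel(), samples)
  teZ <- totalExpression(ieZ)
  zc <- teZ[teZ$primer_pair == "#C" & teZ$reference == "REF1", ]
  expect_true(all(zc$ratio == 0) && all(zc$zero_total))

  # failed reference: NA ratios with a warning
  pkF <- toyPeaks(samples, list("#A" = 30))
  pkF$area[pkF$primer_pair == "REF1" & pkF$sample_id == "s_wt_1"] <- 0
  ieF <- buildIsoformExperiment(pkF, toyPanel(), samples)
  expect_warning(teF <- totalExpression(ieF), "zero")
  bad <- teF[teF$reference == "REF1" & teF$sample_id == "s_wt_1", ]
  expect_true(all(is.na(bad$ratio)) && all(bad$reference_failed))
})
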