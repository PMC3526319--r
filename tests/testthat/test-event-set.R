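test_that("hypergeometric point mass has closed-form and library concordance", {
  expect_equal(hypergeomPoint(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  # draws/successes symmetry
  set.seed(9)
  for (i in 1:40) {
    N <- sample(5:400, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- lo + sample.int(hi - lo + 1L, 1) - 1L
    p <- hypergeomPoint(N, K, n, k)
    expect_equal(p, hypergeomPoint(N, n, K, k), tolerance = 1e-12)
    expect_equal(p, dhyper(k, K, N - K, n), tolerance = 1e-12)
  }
  expect_error(hypergeomPoint(10, 5, 5, 6), "support")
  expect_error(hypergeomPoint(10, 12, 5, 3))
})

test_that("tail probabilities sum the point masses in the stated direction", {
  expect_equal(hypergeomTail(10, 5, 5, 5, "enriched"), 1 / 252,
               tolerance = 1e-12)
  set.seed(10)
  for (i in 1:20) {
    N <- sample(5:120, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    # full support sums to one
    expect_equal(sum(hypergeomPoint(N, K, n, lo:hi)), 1, tolerance = 1e-12)
    k <- lo + sample.int(hi - lo + 1L, 1) - 1L
    expect_equal(hypergeomTail(N, K, n, k, "enriched"),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(hypergeomTail(N, K, n, k, "depleted"),
                 phyper(k, K, N - K, n), tolerance = 1e-12)
  }
})

test_that("tails match exhaustive draw enumeration on a small instance", {
  # brute force: enumerate every 6-subset of 20 items of which 8 are successes
  N <- 20; K <- 8; n <- 6
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  for (k in 0:n) {
    expect_equal(hypergeomPoint(N, K, n, k), mean(hits == k),
                 tolerance = 1e-12)
    expect_equal(hypergeomTail(N, K, n, k, "enriched"), mean(hits >= k),
                 tolerance = 1e-12)
    expect_equal(hypergeomTail(N, K, n, k, "depleted"), mean(hits <= k),
                 tolerance = 1e-12)
  }
})

test_that("event-type enrichment censuses the panel and orients the test", {
  panel <- SplicingPanel(
    primer_pair = sprintf("#%02d", 1:11),
    event_type = c(rep("alt_3ss", 6), rep("alt_5ss", 4), "reference"),
    sizes = c(rep(list(c(100L, 200L)), 10), list(150L)))
  changed <- c("#07", "#08", "#09", "#10", "#01")  # 4 of 4 alt5, 1 of 6 alt3
  enr <- eventTypeEnrichment(panel, changed)
  expect_identical(nrow(enr), 2L)          # reference excluded from census
  a5 <- enr[enr$event_type == "alt_5ss", ]
  expect_identical(a5$K, 4L)
  expect_identical(a5$N, 10L)
  expect_identical(a5$k, 4L)
  expect_identical(a5$direction, "enriched")
  expect_equal(a5$p_point, hypergeomPoint(10, 4, 5, 4), tolerance = 1e-12)
  expect_equal(a5$p_tail, hypergeomTail(10, 4, 5, 4, "enriched"),
               tolerance = 1e-12)
  a3 <- enr[enr$event_type == "alt_3ss", ]
  expect_identical(a3$direction, "depleted")
  expect_gte(a3$p_tail, a3$p_point)

  expect_warning(e0 <- eventTypeEnrichment(panel, character()), "empty")
  expect_identical(nrow(e0), 0L)
  expect_error(eventTypeEnrichment(panel, "#11"), "reference")
  expect_error(eventTypeEnrichment(panel, "#99"), "absent")
})

test_that("overlap counts cover every Venn region", {
  v <- overlapCounts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
  both <- v$count[v$A & v$B]
  onlyA <- v$count[v$A & !v$B]
  onlyB <- v$count[!v$A & v$B]
  expect_identical(c(both, onlyA, onlyB), c(2L, 1L, 1L))

  same <- overlapCounts(list(A = c("x", "y"), B = c("x", "y")))
  expect_identical(same$count[same$A & same$B], 2L)
  expect_true(all(same$count[xor(same$A, same$B)] == 0L))

  disj <- overlapCounts(list(A = "x", B = "y"))
  expect_identical(disj$count[disj$A & disj$B], 0L)

  three <- overlapCounts(list(A = c("1", "2"), B = c("2", "3"),
                              C = c("2", "4")))
  expect_identical(nrow(three), 7L)
  expect_identical(sum(three$count), 4L)  # union size
})

test_that("dosage-series classification applies the opposite-direction rule", {
  mk <- function(id, delta, p) comparisonFromMeans(id, 0, delta, p)
  # both ox primary, kd primary and opposite -> strong
  tc <- classifyTargets(mk("#226", 28, 0.002), mk("#226", 27, 0.0004),
                        mk("#226", -12, 0.001))
  expect_identical(as.character(tc$call), "direct_strong")
  # kd small but significant and opposite -> weak
  tw <- classifyTargets(mk("e", 20, 0.01), mk("e", 20, 0.01),
                        mk("e", -4, 0.01))
  expect_identical(as.character(tw$call), "direct_weak")
  # kd significant, same sign -> same_direction
  ts <- classifyTargets(mk("e", 20, 0.01), mk("e", 20, 0.01),
                        mk("e", 8, 0.01))
  expect_identical(as.character(ts$call), "same_direction")
  # kd not significant -> ox_specific
  to <- classifyTargets(mk("e", 20, 0.01), mk("e", 20, 0.01),
                        mk("e", -8, 0.5))
  expect_identical(as.character(to$call), "ox_specific")
  # nothing significant -> unchanged
  tu <- classifyTargets(mk("e", 2, 0.5), mk("e", 1, 0.9), mk("e", -1, 0.7))
  expect_identical(as.character(tu$call), "unchanged")
  # a knockdown delta of exactly 0 has no direction and cannot be
  # significant, so it lands in the ox-only class
  tz <- classifyTargets(mk("e", 20, 0.01), mk("e", 20, 0.01), mk("e", 0, 0.01))
  expect_identical(as.character(tz$call), "ox_specific")
  expect_identical(mk("e", 0, 0.01)$direction, "0")
  # discordant ox signs cannot be a direct target
  td <- classifyTargets(mk("e", 20, 0.01), mk("e", -20, 0.01),
                        mk("e", -8, 0.01))
  expect_identical(as.character(td$call), "unchanged")

  # invariance to swapping the over-expression contrasts
  oxA <- mk(c("x", "y"), c(20, -10), c(0.01, 0.02))
  oxB <- mk(c("x", "y"), c(15, -30), c(0.02, 0.001))
  kd <- mk(c("x", "y"), c(-7, 6), c(0.01, 0.03))
  expect_identical(classifyTargets(oxA, oxB, kd)$call,
                   classifyTargets(oxB, oxA, kd)$call)

  # untestable contrast -> absent call with reason
  kdNA <- kd
  kdNA$tier <- factor(NA, levels = levels(kd$tier))
  tna <- classifyTargets(oxA, oxB, kdNA)
  expect_true(all(is.na(tna$call)))
  expect_match(tna$reason[1], "untestable")
})
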