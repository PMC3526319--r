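#' Two-sample t-test with degenerate-case handling
#'
#' Thin wrapper around \code{\link[stats]{t.test}} (two-sided; Welch by
#' default, pooled-variance Student form via \code{varEqual = TRUE}) that
#' handles the degenerate cases a splicing panel produces: when both groups
#' are constant and equal the test is defined as t = 0, p = 1; when both are
#' constant and unequal, p = 0 with a degenerate flag.
#'
#' The statistic is oriented as \code{b} versus \code{a}, matching the sign
#' of \code{mean(b) - mean(a)}.
#'
#' @param a,b Numeric vectors of per-replicate values (each length >= 2,
#'   finite).
#' @param varEqual Use the pooled-variance Student form (default FALSE =
#'   Welch).
#' @return A list: \code{statistic}, \code{p_value}, \code{df},
#'   \code{degenerate}.
#' @examples
#' tTestTwoSample(c(30, 31, 29), c(39, 41, 40))
#' @export
tTestTwoSample <- function(a, b, varEqual = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicates")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  degenerate = TRUE))
    return(list(statistic = sign(mean(b) - mean(a)) * Inf, p_value = 0,
                df = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, var.equal = varEqual)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Assign a significance tier to an isoform-ratio change
#'
#' The tiering rule combines effect size and the t-test: \code{primary} for
#' |delta| >= \code{primaryMin} (default 5 percentage points) with
#' p <= \code{alpha}; \code{secondary} for \code{secondaryMin} <= |delta| <
#' \code{primaryMin} (default band [3, 5)) with p <= \code{alpha};
#' \code{not_significant} otherwise. The secondary band exists because
#' technical replication of the assay shows a SEM of up to about 3 percentage
#' points, so smaller yet statistically significant shifts are still
#' reportable. Thresholds are applied with >= on unrounded means.
#'
#' @param delta Change in the designated isoform's percentage (b - a).
#' @param p Two-sided p-value(s).
#' @param alpha Significance cutoff (default 0.05, inclusive).
#' @param primaryMin Primary-tier effect threshold (default 5).
#' @param secondaryMin Lower edge of the secondary band (default 3).
#' @return Factor with levels \code{primary}, \code{secondary},
#'   \code{not_significant}.
#' @export
assignTier <- function(delta, p, alpha = 0.05, primaryMin = 5,
                       secondaryMin = 3) {
  stopifnot(alpha > 0, alpha < 1, primaryMin > 0, secondaryMin > 0,
            secondaryMin <= primaryMin)
  sig <- !is.na(p) & p <= alpha
  tier <- ifelse(sig & abs(delta) >= primaryMin, "primary",
          ifelse(sig & abs(delta) >= secondaryMin, "secondary",
                 "not_significant"))
  factor(tier, levels = c("primary", "secondary", "not_significant"))
}

#' Build a comparison record from reported group means
#'
#' For re-analysis of published summary tables, where per-replicate values
#' are unavailable but group means and p-values are reported: constructs the
#' same record that \code{\link{compareGenotypes}} produces, with the tier
#' assigned from the reported delta and p.
#'
#' @param primerPair Event identifiers.
#' @param meanA,meanB Designated-isoform mean percentages in the two
#'   genotypes.
#' @param p Reported p-values.
#' @param ... Passed to \code{\link{assignTier}}.
#' @param genotypeA,genotypeB Optional genotype labels.
#' @return A comparison data.frame (see \code{\link{compareGenotypes}}).
#' @export
comparisonFromMeans <- function(primerPair, meanA, meanB, p,
                                genotypeA = "a", genotypeB = "b", ...) {
  delta <- meanB - meanA
  data.frame(primer_pair = primerPair, genotype_a = genotypeA,
             genotype_b = genotypeB, n_a = NA_integer_, n_b = NA_integer_,
             mean_a = meanA, mean_b = meanB, delta = delta,
             statistic = NA_real_, p_value = p,
             tier = assignTier(delta, p, ...),
             direction = ifelse(delta > 0, "+", ifelse(delta < 0, "-", "0")),
             row.names = NULL)
}

#' Test one genotype contrast for every panel event
#'
#' For each non-reference event with at least two defined replicates in both
#' genotypes, runs the t-test on the designated isoform's per-replicate
#' percentages and reports delta = mean(b) - mean(a), the p-value and the
#' significance tier. Events with insufficient replicates are returned with
#' NA results and a reason. A Benjamini-Hochberg adjusted p-value column is
#' emitted for information only; the tiering itself applies no
#' multiple-testing correction.
#'
#' @param ie An \code{\linkS4class{IsoformExperiment}}.
#' @param genotypeA,genotypeB Genotype labels from the sample sheet
#'   (delta is \code{genotypeB - genotypeA}).
#' @param alpha,primaryMin,secondaryMin See \code{\link{assignTier}}.
#' @param varEqual Pooled-variance Student t instead of Welch.
#' @return A data.frame with one row per event: \code{primer_pair},
#'   \code{genotype_a}, \code{genotype_b}, \code{n_a}, \code{n_b},
#'   \code{mean_a}, \code{mean_b}, \code{delta}, \code{statistic},
#'   \code{p_value}, \code{tier}, \code{direction}, \code{p_adj_bh},
#'   \code{degenerate}, \code{reason}.
#' @export
compareGenotypes <- function(ie, genotypeA, genotypeB, alpha = 0.05,
                             primaryMin = 5, secondaryMin = 3,
                             varEqual = FALSE) {
  cd <- colData(ie)
  for (g in c(genotypeA, genotypeB))
    if (!g %in% cd$genotype) stop("unknown genotype: ", g)
  rd <- rowData(ie)
  pct <- assay(ie, "percent")
  rows <- which(rd$designated & !rd$is_reference)
  colsA <- which(cd$genotype == genotypeA)
  colsB <- which(cd$genotype == genotypeB)

  n <- length(rows)
  res <- data.frame(primer_pair = rd$primer_pair[rows],
                    genotype_a = genotypeA, genotype_b = genotypeB,
                    n_a = NA_integer_, n_b = NA_integer_,
                    mean_a = NA_real_, mean_b = NA_real_, delta = NA_real_,
                    statistic = NA_real_, p_value = NA_real_,
                    tier = factor(rep(NA, n),
                                  levels = levels(assignTier(0, 1))),
                    direction = NA_character_, degenerate = FALSE,
                    reason = NA_character_, row.names = NULL)
  for (i in seq_len(n)) {
    va <- pct[rows[i], colsA]
    vb <- pct[rows[i], colsB]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    res$n_a[i] <- length(va)
    res$n_b[i] <- length(vb)
    if (length(va) < 2L || length(vb) < 2L) {
      res$reason[i] <- "fewer than 2 defined replicates in a group"
      next
    }
    tt <- tTestTwoSample(va, vb, varEqual = varEqual)
    res$mean_a[i] <- mean(va)
    res$mean_b[i] <- mean(vb)
    res$delta[i] <- mean(vb) - mean(va)
    res$statistic[i] <- tt$statistic
    res$p_value[i] <- tt$p_value
    res$degenerate[i] <- tt$degenerate
  }
  ok <- is.na(res$reason)
  res$tier[ok] <- assignTier(res$delta[ok], res$p_value[ok], alpha = alpha,
                             primaryMin = primaryMin,
                             secondaryMin = secondaryMin)
  res$direction[ok] <- ifelse(res$delta[ok] > 0, "+",
                              ifelse(res$delta[ok] < 0, "-", "0"))
  res$p_adj_bh <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Steady-state abundance change between two genotypes
#'
#' Fold change of mean reference-normalized total expression (genotype b over
#' genotype a), computed separately for each reference transcript. An event
#' is called changed when the fold change is >= \code{fold} or <=
#' 1/\code{fold} (inclusive bounds) under at least one reference; events
#' where the two references disagree on the call are flagged.
#'
#' @param ie An \code{\linkS4class{IsoformExperiment}}.
#' @param genotypeA,genotypeB Genotype labels.
#' @param fold Fold-change threshold (default 2).
#' @param references Passed to \code{\link{totalExpression}}.
#' @return A data.frame with one row per (event, reference):
#'   \code{primer_pair}, \code{reference}, \code{mean_a}, \code{mean_b},
#'   \code{fold_change}, \code{changed_ref}, plus per-event columns
#'   \code{changed_2fold} (any reference) and \code{disagreement}.
#' @export
abundanceChange <- function(ie, genotypeA, genotypeB, fold = 2,
                            references = NULL) {
  stopifnot(fold > 1)
  te <- totalExpression(ie, references)
  cd <- colData(ie)
  te$genotype <- cd$genotype[match(te$sample_id, rownames(cd))]
  te <- te[te$genotype %in% c(genotypeA, genotypeB) & !is.na(te$ratio), ]
  agg <- stats::aggregate(ratio ~ primer_pair + reference + genotype,
                          data = te, FUN = mean)
  wa <- agg[agg$genotype == genotypeA, ]
  wb <- agg[agg$genotype == genotypeB, ]
  m <- merge(wa[c("primer_pair", "reference", "ratio")],
             wb[c("primer_pair", "reference", "ratio")],
             by = c("primer_pair", "reference"),
             suffixes = c("_a", "_b"))
  names(m)[names(m) == "ratio_a"] <- "mean_a"
  names(m)[names(m) == "ratio_b"] <- "mean_b"
  m$fold_change <- ifelse(m$mean_a > 0, m$mean_b / m$mean_a, NA_real_)
  m$changed_ref <- !is.na(m$fold_change) &
    (m$fold_change >= fold | m$fold_change <= 1 / fold)
  anyCall <- tapply(m$changed_ref, m$primer_pair, any)
  allCall <- tapply(m$changed_ref, m$primer_pair, all)
  m$changed_2fold <- as.vector(anyCall[m$primer_pair])
  m$disagreement <- as.vector((anyCall & !allCall)[m$primer_pair])
  m[order(m$primer_pair, m$reference), ]
}
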