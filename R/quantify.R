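#' Isoform percentages for one peak assignment
#'
#' The percentage of each relevant isoform is its peak area relative to the
#' sum of all relevant isoform areas, times 100; non-relevant isoforms are
#' excluded from the denominator and receive NA. When the total relevant
#' area is zero the profile is undefined: all percentages are NA and the
#' \code{undefined} flag is set, which bars the profile from downstream
#' replicate summaries and tests.
#'
#' @param assignment A \code{"PeakAssignment"} from \code{\link{assignPeaks}}.
#' @param event The matching event (single-event
#'   \code{\linkS4class{SplicingPanel}} or \code{\link{panelEvent}} list).
#' @return A list: \code{percent} (named by isoform size; NA for
#'   non-relevant), \code{total_area} (sum of relevant areas) and
#'   \code{undefined} (logical).
#' @examples
#' ev <- SplicingPanel("#90", event_type = "alt_5ss", sizes = list(c(158L, 316L)))
#' pk <- data.frame(size_bp = c(158.1, 315.9), area = c(470, 30))
#' isoformPercentages(assignPeaks(pk, ev), ev)
#' @export
isoformPercentages <- function(assignment, event) {
  if (is(event, "SplicingPanel")) {
    stopifnot(length(event) == 1L)
    event <- panelEvent(event, primerPairs(event))
  }
  if (!identical(assignment$primer_pair, event$primer_pair))
    stop("assignment belongs to ", assignment$primer_pair,
         ", not ", event$primer_pair)
  sizes <- assignment$matched$expected_size
  areas <- assignment$matched$area
  rel <- sizes %in% event$relevant[[1]]
  total <- sum(areas[rel])
  pct <- rep(NA_real_, length(sizes))
  if (total > 0) pct[rel] <- 100 * areas[rel] / total
  names(pct) <- sizes
  list(percent = pct, total_area = total, undefined = total <= 0)
}

#' Fill the percent assay of an IsoformExperiment
#'
#' Computes, for every event and sample, each relevant isoform's percentage
#' of the summed relevant areas. Samples where an event has zero total
#' relevant area yield NA percentages and are listed in
#' \code{metadata()$undefined}.
#'
#' @param ie An \code{\linkS4class{IsoformExperiment}} with an \code{area}
#'   assay.
#' @return The object with a \code{percent} assay.
#' @export
computePercentages <- function(ie) {
  a <- assay(ie, "area")
  rel <- rowData(ie)$relevant
  grp <- rowData(ie)$primer_pair
  arel <- a
  arel[!rel, ] <- 0
  totals <- rowsum(arel, group = grp, reorder = FALSE)     # event x sample
  tot <- totals[match(grp, rownames(totals)), , drop = FALSE]
  pct <- matrix(NA_real_, nrow(a), ncol(a), dimnames = dimnames(a))
  ok <- rel & tot > 0
  pct[ok] <- 100 * a[ok] / tot[ok]
  assays(ie)$percent <- pct

  zero <- which(totals <= 0, arr.ind = TRUE)
  metadata(ie)$undefined <- data.frame(
    primer_pair = rownames(totals)[zero[, 1]],
    sample_id = colnames(totals)[zero[, 2]])
  validObject(ie)
  ie
}

#' Summarize isoform percentages across biological replicates
#'
#' Per genotype, event and isoform: mean, SD and SEM of the per-replicate
#' percentages. SEM uses the sample SD (n - 1 denominator) divided by
#' sqrt(n). Undefined profiles (zero relevant area) are omitted and counted;
#' genotypes with a single defined replicate get SD/SEM 0 with
#' \code{sd_defined = FALSE} and are barred from testing downstream.
#'
#' @param ie An \code{\linkS4class{IsoformExperiment}} with a \code{percent}
#'   assay.
#' @param genotypes Optional subset of genotypes to summarize.
#' @return A data.frame with one row per (genotype, event, relevant isoform):
#'   \code{genotype}, \code{primer_pair}, \code{size}, \code{designated},
#'   \code{mean}, \code{sd}, \code{sem}, \code{n} (defined replicates),
#'   \code{n_total}, \code{sd_defined}.
#' @export
summarizeReplicates <- function(ie, genotypes = NULL) {
  pct <- assay(ie, "percent")
  rd <- rowData(ie)
  cd <- colData(ie)
  if (is.null(genotypes)) genotypes <- unique(cd$genotype)
  keep <- rd$relevant
  out <- vector("list", length(genotypes))
  for (gi in seq_along(genotypes)) {
    g <- genotypes[gi]
    cols <- which(cd$genotype == g)
    if (!length(cols)) stop("no samples for genotype: ", g)
    sub <- pct[keep, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[n == 0] <- NA_real_
    sdv <- apply(sub, 1L, function(x) stats::sd(x, na.rm = TRUE))
    sdv[n <= 1] <- 0
    out[[gi]] <- data.frame(
      genotype = g,
      primer_pair = rd$primer_pair[keep],
      size = rd$size[keep],
      designated = rd$designated[keep],
      mean = mu, sd = sdv, sem = ifelse(n > 0, sdv / sqrt(n), NA_real_),
      n = n, n_total = length(cols), sd_defined = n >= 2,
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Reference-normalized total transcript level
#'
#' The summed area of an event's relevant isoforms divided by the area of a
#' reference transcript (e.g. ACTIN11 or RPL12c) in the same sample - a
#' dimensionless proxy for total transcript abundance. Both panel references
#' are computed and reported side by side.
#'
#' @param totalArea Summed relevant peak area(s) (a.u., >= 0).
#' @param referenceArea Reference transcript peak area(s) (a.u., > 0).
#' @return \code{totalArea / referenceArea}.
#' @examples
#' expressionRatio(200, 100)  # 2.0
#' @export
expressionRatio <- function(totalArea, referenceArea) {
  if (any(referenceArea <= 0))
    stop("reference transcript area must be positive (reference failed)")
  totalArea / referenceArea
}

#' Total expression of every event relative to the panel references
#'
#' @param ie An \code{\linkS4class{IsoformExperiment}} built with a panel that
#'   flags its reference transcripts.
#' @param references Primer-pair identifiers of the reference transcripts;
#'   defaults to the panel's flagged references.
#' @return A data.frame with one row per (sample, event, reference):
#'   \code{sample_id}, \code{primer_pair}, \code{reference}, \code{ratio},
#'   \code{reference_failed} (reference area was zero in that sample; ratio
#'   NA) and \code{zero_total} (event area zero; ratio 0, flagged).
#' @export
totalExpression <- function(ie, references = NULL) {
  rd <- rowData(ie)
  a <- assay(ie, "area")
  if (is.null(references)) references <- unique(rd$primer_pair[rd$is_reference])
  if (!length(references))
    stop("no reference transcripts flagged on the panel")
  rel <- rd$relevant & !rd$is_reference
  totals <- rowsum(a[rel, , drop = FALSE], group = rd$primer_pair[rel],
                   reorder = FALSE)
  out <- vector("list", length(references))
  for (ri in seq_along(references)) {
    r <- references[ri]
    rrow <- which(rd$primer_pair == r)
    if (!length(rrow)) stop("unknown reference transcript: ", r)
    refArea <- colSums(a[rrow, , drop = FALSE])
    failed <- refArea <= 0
    ratio <- sweep(totals, 2L, ifelse(failed, NA_real_, refArea), "/")
    out[[ri]] <- data.frame(
      sample_id = rep(colnames(totals), each = nrow(totals)),
      primer_pair = rep(rownames(totals), times = ncol(totals)),
      reference = r,
      ratio = as.vector(ratio),
      reference_failed = rep(failed, each = nrow(totals)),
      zero_total = as.vector(totals == 0),
      row.names = NULL)
  }
  if (any(vapply(out, function(d) any(d$reference_failed), logical(1))))
    warning("reference transcript area was zero in some samples; ",
            "ratios set to NA")
  do.call(rbind, out)
}
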