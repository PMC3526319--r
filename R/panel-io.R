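#' Read a panel definition from TSV
#'
#' The panel TSV is the single source of truth for which isoforms of each
#' event are "relevant" (enter the ratio computation) and which isoform is
#' "designated" (defines the direction of change). Expected columns:
#' \code{primer_pair}, \code{agi}, \code{description}, \code{product_sizes}
#' (slash-separated bp, e.g. \code{"143/309"}), \code{event_type}; optional
#' \code{relevant_sizes} (slash-separated subset; empty means all),
#' \code{designated_size} (empty means smallest relevant) and
#' \code{is_reference} (TRUE/FALSE).
#'
#' @param path Path to a tab-separated panel definition.
#' @return A \code{\linkS4class{SplicingPanel}}.
#' @seealso \code{\link{writePanelDefinition}} for the inverse.
#' @export
readPanelDefinition <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  if (nrow(df) == 0L) {
    warning("panel definition '", path, "' contains no events")
    return(SplicingPanel(primer_pair = character(), event_type = character(),
                         sizes = list()))
  }
  need <- c("primer_pair", "agi", "description", "product_sizes", "event_type")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("panel definition is missing columns: ", paste(miss, collapse = ", "))

  dup <- unique(df$primer_pair[duplicated(df$primer_pair)])
  if (length(dup))
    stop("duplicate primer_pair in panel definition: ",
         paste(dup, collapse = ", "))
  bad <- !df$event_type %in% AS_EVENT_TYPES
  if (any(bad))
    stop("unknown event type in panel definition row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$event_type[bad]), collapse = ", "))

  parseSizes <- function(s) {
    if (is.na(s) || !nzchar(s)) return(integer(0))
    out <- suppressWarnings(as.integer(strsplit(s, "/", fixed = TRUE)[[1]]))
    if (anyNA(out)) stop("unparseable size field: '", s, "'")
    out
  }
  sizes <- lapply(df$product_sizes, parseSizes)
  for (i in seq_along(sizes))
    if (length(sizes[[i]]) == 0L || any(diff(sizes[[i]]) <= 0) ||
        any(sizes[[i]] <= 0))
      stop("product sizes not positive and strictly increasing in row ", i,
           " (", df$primer_pair[i], "): '", df$product_sizes[i], "'")

  relevant <- if ("relevant_sizes" %in% colnames(df)) {
    unname(mapply(function(s, all) if (is.na(s) || !nzchar(s)) all else
                    parseSizes(s),
                  df$relevant_sizes, sizes, SIMPLIFY = FALSE))
  } else sizes
  designated <- if ("designated_size" %in% colnames(df)) {
    unname(mapply(function(s, rl) if (is.na(s) || !nzchar(s)) min(rl)
                  else as.integer(s),
                  df$designated_size, relevant))
  } else vapply(relevant, min, integer(1))
  isRef <- if ("is_reference" %in% colnames(df))
    toupper(df$is_reference) %in% c("TRUE", "T", "1", "YES")
  else df$event_type == "reference"

  SplicingPanel(primer_pair = df$primer_pair, gene_id = df$agi,
                description = df$description, event_type = df$event_type,
                sizes = sizes, relevant = relevant,
                designated = designated, is_reference = isRef)
}

#' Write a panel definition to TSV
#'
#' Inverse of \code{\link{readPanelDefinition}}: round-tripping reproduces all
#' field values.
#'
#' @param panel A \code{\linkS4class{SplicingPanel}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePanelDefinition <- function(panel, path) {
  ev <- panelEvents(panel)
  join <- function(l) vapply(l, function(x) paste(x, collapse = "/"), character(1))
  out <- data.frame(primer_pair = ev$primer_pair, agi = ev$gene_id,
                    description = ev$description,
                    product_sizes = join(ev$sizes),
                    event_type = ev$event_type,
                    relevant_sizes = join(ev$relevant),
                    designated_size = ev$designated,
                    is_reference = ev$is_reference,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{genotype}, \code{ecotype},
#' \code{replicate}. Sample identifiers and (genotype, replicate) pairs must
#' be unique.
#'
#' @param path Path to the tab-separated sample sheet.
#' @return A data.frame, one row per biological sample.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "ecotype", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  key <- paste(df$genotype, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (genotype, replicate) in sample sheet: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1L)) stop("replicate indices must be positive")
  df
}

#' Read a fragment-analysis peak table
#'
#' Consumes a GeneMapper-style CSV export with columns \code{sample_id},
#' \code{primer_pair}, \code{size_bp} (sub-bp sizing is expected) and
#' \code{area} (fluorescent peak area); extra columns (dye, height, ...) are
#' ignored. Rows referring to primer pairs absent from \code{panel} are kept
#' but reported via a warning and the \code{"unknown_primer_pairs"} attribute,
#' never silently dropped.
#'
#' @param path Path to the CSV peak table.
#' @param panel Optional \code{\linkS4class{SplicingPanel}} used to flag
#'   unknown primer pairs.
#' @return A data.frame of peak records (\code{sample_id},
#'   \code{primer_pair}, \code{size_bp}, \code{area}).
#' @export
readPeakTable <- function(path, panel = NULL) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("sample_id", "primer_pair", "size_bp", "area")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("size_bp", "area")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("unparseable ", col, " in peak table row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(v))
      stop("missing ", col, " in peak table row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    df[[col]] <- v
  }
  if (any(df$area < 0))
    stop("negative peak area in row(s) ",
         paste(utils::head(which(df$area < 0), 5), collapse = ", "))
  if (any(df$size_bp <= 0))
    stop("non-positive fragment size in row(s) ",
         paste(utils::head(which(df$size_bp <= 0), 5), collapse = ", "))
  df <- df[need]
  unknown <- character(0)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(df$primer_pair), primerPairs(panel))
    if (length(unknown))
      warning("peak table contains ", length(unknown),
              " primer pair(s) absent from the panel: ",
              paste(utils::head(unknown, 10), collapse = ", "))
  }
  attr(df, "unknown_primer_pairs") <- unknown
  df
}

# Core matcher on bare vectors; returns integer index of the matched observed
# peak per expected size (NA = missing). Errors if one observed peak falls
# within the tolerance window of two expected sizes.
.matchPeaks <- function(obsSize, obsArea, expected, tolerance) {
  nExp <- length(expected)
  hit <- rep(NA_integer_, nExp)
  if (length(obsSize)) {
    d <- abs(outer(obsSize, expected, "-"))  # peaks x expected
    qual <- d <= tolerance
    claimed <- rowSums(qual)
    if (any(claimed > 1L))
      stop("observed peak at ", obsSize[which(claimed > 1L)[1]],
           " bp falls within the tolerance window of two expected sizes; ",
           "use a smaller tolerance")
    for (j in seq_len(nExp)) {
      cand <- which(qual[, j])
      if (!length(cand)) next
      best <- cand[order(d[cand, j], -obsArea[cand])][1]
      hit[j] <- best
    }
  }
  hit
}

#' Assign observed peaks to the expected isoform sizes of one event
#'
#' Each expected product size is matched to the observed peak within
#' \code{tolerance} bp; when several peaks qualify the nearest wins, ties
#' broken in favor of the larger area. An expected size with no qualifying
#' peak receives area 0 and a missing flag, so downstream percentages stay
#' computable and traceable. Peaks not matching any expected size are
#' reported, not dropped. Two expected sizes claiming the same observed peak
#' (overlapping tolerance windows) raise an error advising a smaller
#' tolerance. The result is invariant to the input order of the peaks.
#'
#' @param peaks Data.frame of peak records for one sample and one primer pair
#'   (columns \code{size_bp}, \code{area}; \code{sample_id}/\code{primer_pair}
#'   checked for uniqueness when present).
#' @param event A single-event \code{\linkS4class{SplicingPanel}} or the list
#'   returned by \code{\link{panelEvent}}.
#' @param tolerance Matching half-window in bp (> 0; default 1.0, matching
#'   the single-bp resolution of capillary sizing at these product lengths).
#' @return A list of class \code{"PeakAssignment"}: \code{matched}
#'   (data.frame \code{expected_size}, \code{size_bp}, \code{area},
#'   \code{missing}) and \code{unmatched} (data.frame \code{size_bp},
#'   \code{area}).
#' @examples
#' ev <- SplicingPanel("#90", event_type = "alt_5ss", sizes = list(c(158L, 316L)))
#' pk <- data.frame(size_bp = c(157.8, 316.2, 402.0), area = c(500, 30, 100))
#' assignPeaks(pk, ev)
#' @export
assignPeaks <- function(peaks, event, tolerance = 1.0) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("tolerance must be a single positive number (bp)")
  if (is(event, "SplicingPanel")) {
    stopifnot(length(event) == 1L)
    event <- panelEvent(event, primerPairs(event))
  }
  if ("sample_id" %in% colnames(peaks) &&
      length(unique(peaks$sample_id)) > 1L)
    stop("assignPeaks expects peaks from a single sample")
  if ("primer_pair" %in% colnames(peaks) &&
      length(unique(peaks$primer_pair)) > 1L)
    stop("assignPeaks expects peaks from a single primer pair")
  expected <- event$sizes[[1]]
  hit <- .matchPeaks(peaks$size_bp, peaks$area, expected, tolerance)
  matched <- data.frame(
    expected_size = expected,
    size_bp = ifelse(is.na(hit), NA_real_, peaks$size_bp[hit]),
    area = ifelse(is.na(hit), 0, peaks$area[hit]),
    missing = is.na(hit))
  un <- setdiff(seq_len(nrow(peaks)), hit[!is.na(hit)])
  unmatched <- data.frame(size_bp = peaks$size_bp[un], area = peaks$area[un])
  structure(list(primer_pair = event$primer_pair,
                 matched = matched, unmatched = unmatched),
            class = "PeakAssignment")
}

#' @export
print.PeakAssignment <- function(x, ...) {
  cat("PeakAssignment for", x$primer_pair, "\n")
  print(x$matched)
  if (nrow(x$unmatched)) {
    cat("unmatched peaks:\n")
    print(x$unmatched)
  }
  invisible(x)
}

#' Build an IsoformExperiment from peak records
#'
#' Matches every sample's peaks against every panel event (see
#' \code{\link{assignPeaks}}), assembles the (event, isoform) x sample area
#' matrix and computes the percent assay (see
#' \code{\link{isoformPercentages}}). Unmatched peaks and events whose total
#' relevant area is zero in a sample are recorded in the object metadata.
#'
#' @param peaks Peak records as returned by \code{\link{readPeakTable}}.
#' @param panel A \code{\linkS4class{SplicingPanel}}.
#' @param samples Sample sheet as returned by \code{\link{readSampleSheet}}.
#' @param tolerance Peak-matching tolerance in bp (default 1.0).
#' @return An \code{\linkS4class{IsoformExperiment}}.
#' @export
buildIsoformExperiment <- function(peaks, panel, samples, tolerance = 1.0) {
  ev <- panelEvents(panel)
  sampleIds <- samples$sample_id
  extra <- setdiff(unique(peaks$sample_id), sampleIds)
  if (length(extra))
    warning("peak table contains samples absent from the sample sheet ",
            "(ignored): ", paste(utils::head(extra, 5), collapse = ", "))

  nIso <- lengths(ev$sizes)
  rowPrimer <- rep(ev$primer_pair, nIso)
  rowSize <- unlist(ev$sizes, use.names = FALSE)
  rowRelevant <- unlist(mapply(function(s, r) s %in% r, ev$sizes, ev$relevant,
                               SIMPLIFY = FALSE), use.names = FALSE)
  rowDesignated <- rowSize == rep(ev$designated, nIso) & rowRelevant
  rowRef <- rep(ev$is_reference, nIso)
  rowIdx <- split(seq_along(rowPrimer), factor(rowPrimer, levels = ev$primer_pair))

  area <- matrix(0, nrow = length(rowPrimer), ncol = length(sampleIds),
                 dimnames = list(paste(rowPrimer, rowSize, sep = ":"), sampleIds))
  missing <- matrix(TRUE, nrow = nrow(area), ncol = ncol(area),
                    dimnames = dimnames(area))
  unmatched <- vector("list", 0L)

  keep <- peaks$sample_id %in% sampleIds & peaks$primer_pair %in% ev$primer_pair
  pk <- peaks[keep, , drop = FALSE]
  grp <- split(seq_len(nrow(pk)),
               list(factor(pk$sample_id, levels = sampleIds),
                    factor(pk$primer_pair, levels = ev$primer_pair)),
               drop = TRUE)
  for (g in grp) {
    sid <- pk$sample_id[g[1]]
    pid <- pk$primer_pair[g[1]]
    ei <- match(pid, ev$primer_pair)
    expected <- ev$sizes[[ei]]
    hit <- .matchPeaks(pk$size_bp[g], pk$area[g], expected, tolerance)
    rows <- rowIdx[[pid]]
    area[rows, sid] <- ifelse(is.na(hit), 0, pk$area[g][hit])
    missing[rows, sid] <- is.na(hit)
    un <- setdiff(seq_along(g), hit[!is.na(hit)])
    if (length(un))
      unmatched[[length(unmatched) + 1L]] <-
        data.frame(sample_id = sid, primer_pair = pid,
                   size_bp = pk$size_bp[g][un], area = pk$area[g][un])
  }
  unmatched <- if (length(unmatched)) do.call(rbind, unmatched) else
    data.frame(sample_id = character(), primer_pair = character(),
               size_bp = numeric(), area = numeric())

  rd <- DataFrame(primer_pair = rowPrimer, size = rowSize,
                  relevant = rowRelevant, designated = rowDesignated,
                  is_reference = rowRef)
  cd <- DataFrame(samples, row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(area = area, missing = missing),
                             rowData = rd, colData = cd)
  ie <- new("IsoformExperiment", se)
  metadata(ie)$panel <- panel
  metadata(ie)$unmatched <- unmatched
  metadata(ie)$tolerance <- tolerance
  computePercentages(ie)
}
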