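#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowData colData assayNames
NULL

#' Recognized alternative-splicing event types
#'
#' Event classes assayed on a fragment-length RT-PCR panel, plus
#' \code{"reference"} for the constitutively spliced normalizer transcripts
#' (e.g. ACTIN11, RPL12c) that carry a single expected product.
#'
#' @export
AS_EVENT_TYPES <- c("alt_3ss", "alt_5ss", "intron_retention",
                    "exon_skipping", "cryptic_intron", "reference")

#' SplicingPanel: definition of an RT-PCR alternative-splicing panel
#'
#' One row per assayed event: the primer pair, the locus, the expected RT-PCR
#' product sizes of the splice isoforms, the event type, the subset of
#' isoforms entering the ratio computation ("relevant" isoforms), and the
#' designated isoform whose percentage defines the direction of change
#' (by convention the smaller product of the considered pair).
#'
#' @slot events A \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{primer_pair} (character, unique), \code{gene_id},
#'   \code{description}, \code{event_type} (one of \code{\link{AS_EVENT_TYPES}}),
#'   \code{sizes} (list of strictly increasing integer vectors, bp),
#'   \code{relevant} (list of integer vectors, subsets of \code{sizes}),
#'   \code{designated} (integer, member of \code{relevant}) and
#'   \code{is_reference} (logical).
#'
#' @export
setClass("SplicingPanel", slots = c(events = "DataFrame"))

.validSplicingPanel <- function(object) {
  ev <- object@events
  need <- c("primer_pair", "gene_id", "description", "event_type",
            "sizes", "relevant", "designated", "is_reference")
  miss <- setdiff(need, colnames(ev))
  if (length(miss))
    return(paste("missing event columns:", paste(miss, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(ev$primer_pair))
    msgs <- c(msgs, paste("duplicate primer_pair:",
                          paste(unique(ev$primer_pair[duplicated(ev$primer_pair)]),
                                collapse = ", ")))
  bad <- setdiff(unique(ev$event_type), AS_EVENT_TYPES)
  if (length(bad))
    msgs <- c(msgs, paste("unknown event_type:", paste(bad, collapse = ", ")))
  for (i in seq_len(nrow(ev))) {
    id <- ev$primer_pair[i]
    sz <- ev$sizes[[i]]
    rl <- ev$relevant[[i]]
    if (any(sz <= 0) || any(diff(sz) <= 0))
      msgs <- c(msgs, paste0("event ", id,
                             ": expected sizes must be positive and strictly increasing"))
    if (length(rl) == 0L || !all(rl %in% sz))
      msgs <- c(msgs, paste0("event ", id,
                             ": relevant isoforms must be a non-empty subset of expected sizes"))
    if (!ev$designated[i] %in% rl)
      msgs <- c(msgs, paste0("event ", id,
                             ": designated isoform must be one of the relevant isoforms"))
    if (identical(ev$event_type[i], "reference") && length(sz) != 1L)
      msgs <- c(msgs, paste0("event ", id,
                             ": reference transcripts must have exactly one expected size"))
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SplicingPanel", .validSplicingPanel)

#' Construct a SplicingPanel
#'
#' @param primer_pair Character vector of unique primer-pair identifiers.
#' @param gene_id Locus identifiers (e.g. AGI codes); recycled if length 1.
#' @param description Free-text descriptions; recycled if length 1.
#' @param event_type One of \code{\link{AS_EVENT_TYPES}} per event.
#' @param sizes List of strictly increasing integer vectors: expected RT-PCR
#'   product sizes (bp) of the isoforms.
#' @param relevant List of integer vectors: the isoform sizes entering the
#'   ratio computation. Defaults to all expected sizes.
#' @param designated Integer vector: the isoform whose percentage defines the
#'   direction of change. Defaults to the smallest relevant size.
#' @param is_reference Logical: reference (normalizer) transcript?
#'   Defaults to \code{event_type == "reference"}.
#'
#' @return A validated \code{\linkS4class{SplicingPanel}}.
#' @examples
#' SplicingPanel(primer_pair = "#226", gene_id = "At4g24740",
#'               description = "AFC2", event_type = "exon_skipping",
#'               sizes = list(c(143L, 309L)))
#' @export
SplicingPanel <- function(primer_pair, gene_id = NA_character_,
                          description = NA_character_, event_type,
                          sizes, relevant = NULL, designated = NULL,
                          is_reference = NULL) {
  n <- length(primer_pair)
  sizes <- lapply(sizes, function(x) as.integer(x))
  if (is.null(relevant)) relevant <- sizes
  relevant <- lapply(relevant, as.integer)
  if (is.null(designated))
    designated <- vapply(relevant, function(x) min(x), integer(1))
  if (is.null(is_reference)) is_reference <- event_type == "reference"
  ev <- DataFrame(primer_pair = as.character(primer_pair),
                  gene_id = rep_len(as.character(gene_id), n),
                  description = rep_len(as.character(description), n),
                  event_type = rep_len(as.character(event_type), n),
                  is_reference = rep_len(as.logical(is_reference), n))
  ev$sizes <- sizes
  ev$relevant <- relevant
  ev$designated <- as.integer(designated)
  new("SplicingPanel", events = ev)
}

#' IsoformExperiment: per-sample isoform peak areas and percentages
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} whose rows are
#' (event, expected isoform size) pairs and whose columns are samples. The
#' \code{area} assay holds matched fluorescent peak areas (arbitrary units,
#' 0 for an expected but unobserved isoform); the \code{percent} assay holds
#' each relevant isoform's percentage of the summed relevant areas (NA for
#' non-relevant isoforms and for samples where the event had zero total
#' relevant area). Row metadata mirror the \code{\linkS4class{SplicingPanel}};
#' column metadata carry the sample sheet (genotype, replicate). Unmatched
#' peaks and undefined (zero-area) profiles are recorded in
#' \code{metadata()$unmatched} and \code{metadata()$undefined}.
#'
#' @export
setClass("IsoformExperiment", contains = "SummarizedExperiment")

.validIsoformExperiment <- function(object) {
  msgs <- character()
  if (!"area" %in% assayNames(object))
    msgs <- c(msgs, "assay 'area' is required")
  rd <- rowData(object)
  need <- c("primer_pair", "size", "relevant", "designated", "is_reference")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msgs <- c(msgs, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (!length(msgs) && "area" %in% assayNames(object)) {
    a <- assay(object, "area")
    if (any(a < 0, na.rm = TRUE)) msgs <- c(msgs, "peak areas must be non-negative")
  }
  if (!length(msgs) && "percent" %in% assayNames(object)) {
    p <- assay(object, "percent")
    if (any(p < -1e-9 | p > 100 + 1e-9, na.rm = TRUE))
      msgs <- c(msgs, "percentages must lie in [0, 100]")
    keep <- rowData(object)$relevant
    if (any(keep)) {
      sums <- rowsum(ifelse(is.na(p[keep, , drop = FALSE]), 0,
                            p[keep, , drop = FALSE]),
                     group = rowData(object)$primer_pair[keep])
      ok <- abs(sums - 100) < 1e-6 | sums == 0
      if (!all(ok))
        msgs <- c(msgs, "relevant isoform percentages must sum to 100 where defined")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("IsoformExperiment", .validIsoformExperiment)

#' @describeIn SplicingPanel-class Number of events on the panel.
#' @param x A \code{SplicingPanel}.
#' @export
setMethod("length", "SplicingPanel", function(x) nrow(x@events))

#' Accessors for SplicingPanel
#'
#' @param x A \code{\linkS4class{SplicingPanel}}.
#' @return \code{panelEvents} returns the event
#'   \code{\link[S4Vectors]{DataFrame}}; \code{primerPairs} the event
#'   identifiers; \code{referenceIds} the identifiers of the reference
#'   (normalizer) transcripts; \code{panelEvent} a single-row event list.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
panelEvents <- function(x) {
  stopifnot(is(x, "SplicingPanel"))
  x@events
}

#' @rdname panel-accessors
#' @export
primerPairs <- function(x) panelEvents(x)$primer_pair

#' @rdname panel-accessors
#' @export
referenceIds <- function(x) {
  ev <- panelEvents(x)
  ev$primer_pair[ev$is_reference]
}

#' @rdname panel-accessors
#' @param id A single primer-pair identifier.
#' @export
panelEvent <- function(x, id) {
  ev <- panelEvents(x)
  i <- match(id, ev$primer_pair)
  if (is.na(i)) stop("unknown primer pair: ", id)
  as.list(ev[i, ])
}

#' Subset a SplicingPanel by index, identifier or logical mask
#'
#' @param x A \code{SplicingPanel}.
#' @param i Numeric/logical index or character primer-pair identifiers.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "SplicingPanel", function(x, i, j, ..., drop = FALSE) {
  ev <- x@events
  if (is.character(i)) {
    idx <- match(i, ev$primer_pair)
    if (anyNA(idx)) stop("unknown primer pair: ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  initialize(x, events = ev[i, , drop = FALSE])
})

setMethod("show", "SplicingPanel", function(object) {
  ev <- object@events
  cat("SplicingPanel with", nrow(ev), "events (",
      sum(ev$is_reference), "reference )\n")
  if (nrow(ev)) {
    tab <- table(ev$event_type[!ev$is_reference])
    if (length(tab))
      cat("  event types:",
          paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  first events:",
        paste(utils::head(ev$primer_pair, 5), collapse = ", "),
        if (nrow(ev) > 5) "..." else "", "\n")
  }
  invisible(NULL)
})

setMethod("show", "IsoformExperiment", function(object) {
  callNextMethod()
  un <- metadata(object)$undefined
  if (!is.null(un) && nrow(un))
    cat("undefined profiles (zero relevant area):", nrow(un), "\n")
  um <- metadata(object)$unmatched
  if (!is.null(um) && nrow(um))
    cat("unmatched peaks:", nrow(um), "\n")
  invisible(NULL)
})
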