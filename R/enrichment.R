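.checkHyper <- function(N, K, n, k = NULL) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  if (!is.null(k)) {
    lo <- max(0, n + K - N)
    hi <- min(n, K)
    if (any(k < lo | k > hi))
      stop("k out of support [", lo, ", ", hi, "] for (N=", N, ", K=", K,
           ", n=", n, ")")
  }
  invisible(NULL)
}

#' Hypergeometric point probability
#'
#' The probability of observing exactly k successes when drawing n items
#' without replacement from a population of N containing K successes:
#' C(K,k) C(N-K,n-k) / C(N,n), computed in log space for numerical safety.
#' This point-mass form follows the spreadsheet HYPGEOMDIST convention that
#' many panel studies report as "hypergeometric test"; the proper one-sided
#' p-value is \code{\link{hypergeomTail}}.
#'
#' @param N Population size (e.g. events on the panel).
#' @param K Successes in the population (events of one type).
#' @param n Draws (changed events).
#' @param k Observed successes among the draws; vectorized.
#' @return P(X = k).
#' @examples
#' hypergeomPoint(10, 5, 5, 5)          # 1/252
#' round(hypergeomPoint(288, 67, 59, 24), 4)
#' @export
hypergeomPoint <- function(N, K, n, k) {
  .checkHyper(N, K, n, k)
  exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n))
}

#' Hypergeometric one-sided tail probability
#'
#' Sum of the point probabilities over j >= k (\code{direction =
#' "enriched"}) or j <= k (\code{"depleted"}).
#'
#' @inheritParams hypergeomPoint
#' @param k Observed successes (scalar).
#' @param direction \code{"enriched"} or \code{"depleted"}.
#' @return The one-sided tail probability.
#' @export
hypergeomTail <- function(N, K, n, k, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  .checkHyper(N, K, n, k)
  stopifnot(length(k) == 1L)
  j <- if (direction == "enriched") k:min(n, K) else max(0, n + K - N):k
  sum(hypergeomPoint(N, K, n, j))
}

#' Event-type enrichment among changed events
#'
#' For each alternative-splicing event type on the panel (reference
#' transcripts excluded), tests whether the type is over- or
#' under-represented among the changed events, reporting both the
#' hypergeometric point probability (the convention used in panel studies)
#' and the statistically proper one-sided tail probability in the direction
#' of the departure from the expectation n K / N.
#'
#' @param panel A \code{\linkS4class{SplicingPanel}}.
#' @param changed Character vector of changed event identifiers (subset of
#'   the panel; reference ids are dropped).
#' @return A data.frame with one row per event type: \code{event_type},
#'   \code{K} (panel count), \code{N} (panel total), \code{k} (changed
#'   count), \code{n} (changed total), \code{percent_panel},
#'   \code{percent_changed} (rounded to integers, as such tables are
#'   printed), \code{expected}, \code{direction}, \code{p_point},
#'   \code{p_tail}.
#' @export
eventTypeEnrichment <- function(panel, changed) {
  ev <- panelEvents(panel)
  ev <- ev[!ev$is_reference, , drop = FALSE]
  bad <- setdiff(changed, ev$primer_pair)
  if (length(bad))
    stop("changed set contains ids absent from the panel (or reference ",
         "transcripts): ", paste(utils::head(bad, 5), collapse = ", "))
  changed <- unique(changed)
  if (!length(changed)) {
    warning("empty changed set; no enrichment computed")
    return(data.frame(event_type = character(), K = integer(), N = integer(),
                      k = integer(), n = integer(), percent_panel = numeric(),
                      percent_changed = numeric(), expected = numeric(),
                      direction = character(), p_point = numeric(),
                      p_tail = numeric()))
  }
  N <- nrow(ev)
  n <- length(changed)
  types <- unique(ev$event_type)
  out <- lapply(types, function(ty) {
    K <- sum(ev$event_type == ty)
    k <- sum(ev$event_type[match(changed, ev$primer_pair)] == ty)
    expected <- n * K / N
    dir <- if (k >= expected) "enriched" else "depleted"
    data.frame(event_type = ty, K = K, N = N, k = k, n = n,
               percent_panel = round(100 * K / N),
               percent_changed = round(100 * k / n),
               expected = expected, direction = dir,
               p_point = hypergeomPoint(N, K, n, k),
               p_tail = hypergeomTail(N, K, n, k, dir))
  })
  do.call(rbind, out)
}

#' Intersection (Venn) counts of named event sets
#'
#' @param sets A named list of character vectors of event identifiers.
#' @return A data.frame with one row per membership region (every non-empty
#'   combination of sets): one logical column per set plus \code{count} and
#'   \code{ids} (comma-separated members).
#' @examples
#' overlapCounts(list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' @export
overlapCounts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  member <- matrix(member, nrow = length(ids),
                   dimnames = list(ids, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  res <- patterns
  res$count <- 0L
  res$ids <- ""
  for (i in seq_len(nrow(patterns))) {
    want <- as.logical(patterns[i, seq_along(sets)])
    inRegion <- apply(member, 1L, function(m) all(m == want))
    res$count[i] <- sum(inRegion)
    res$ids[i] <- paste(ids[inRegion], collapse = ",")
  }
  rownames(res) <- NULL
  res
}

#' Classify events along an expression dosage series
#'
#' Combines three genotype contrasts against the wild type - two independent
#' over-expression lines and one knockdown - into a direct-target call per
#' event, following the logic that a direct target of a dosage-varied
#' RNA-binding protein must respond to loss of the protein in the opposite
#' direction to its over-expression:
#' \itemize{
#'   \item \code{direct_strong}: both over-expression contrasts primary tier,
#'     the knockdown contrast primary tier, and the knockdown delta of
#'     opposite sign to both (equal-signed) over-expression deltas;
#'   \item \code{direct_weak}: as above but the knockdown contrast in the
#'     secondary tier (a smaller yet significant opposite change);
#'   \item \code{same_direction}: knockdown significant with the same sign as
#'     both significant over-expression contrasts (suggesting control by a
#'     complex containing the protein);
#'   \item \code{ox_specific}: over-expression contrasts significant, the
#'     knockdown not;
#'   \item \code{unchanged}: everything else (a knockdown delta of exactly 0
#'     counts as unchanged).
#' }
#' The call is invariant to swapping the two over-expression contrasts. With
#' \code{oxB = NULL} (a single over-expression line) the same rules apply to
#' the one available contrast.
#'
#' @param oxA,oxB Comparison data.frames (wild type to over-expression) from
#'   \code{\link{compareGenotypes}} or \code{\link{comparisonFromMeans}};
#'   \code{oxB} may be NULL.
#' @param kd Comparison data.frame (wild type to knockdown).
#' @return A data.frame with one row per event present in all supplied
#'   contrasts: \code{primer_pair}, \code{call}, the three deltas and tiers,
#'   and \code{reason} (NA unless the call is absent because a contrast was
#'   untestable).
#' @export
classifyTargets <- function(oxA, oxB = NULL, kd) {
  pick <- function(d, tag) {
    d <- d[c("primer_pair", "delta", "tier")]
    names(d)[2:3] <- paste0(c("delta_", "tier_"), tag)
    d
  }
  m <- merge(pick(oxA, "ox_a"), pick(kd, "kd"), by = "primer_pair")
  if (!is.null(oxB)) {
    m <- merge(m, pick(oxB, "ox_b"), by = "primer_pair")
  } else {
    m$delta_ox_b <- m$delta_ox_a
    m$tier_ox_b <- m$tier_ox_a
  }
  sig <- function(tier) !is.na(tier) & tier != "not_significant"
  prim <- function(tier) !is.na(tier) & tier == "primary"

  n <- nrow(m)
  call <- rep("unchanged", n)
  reason <- rep(NA_character_, n)
  untest <- is.na(m$tier_ox_a) | is.na(m$tier_ox_b) | is.na(m$tier_kd)
  oxSig <- sig(m$tier_ox_a) & sig(m$tier_ox_b) &
    sign(m$delta_ox_a) == sign(m$delta_ox_b)
  oxPrim <- prim(m$tier_ox_a) & prim(m$tier_ox_b) &
    sign(m$delta_ox_a) == sign(m$delta_ox_b)
  opposite <- m$delta_kd != 0 & sign(m$delta_kd) == -sign(m$delta_ox_a)
  same <- m$delta_kd != 0 & sign(m$delta_kd) == sign(m$delta_ox_a)

  call[oxSig & sig(m$tier_kd) & same] <- "same_direction"
  call[oxSig & !sig(m$tier_kd)] <- "ox_specific"
  call[oxPrim & sig(m$tier_kd) & m$tier_kd == "secondary" & opposite] <-
    "direct_weak"
  call[oxPrim & prim(m$tier_kd) & opposite] <- "direct_strong"
  call[untest] <- NA_character_
  reason[untest] <- "untestable contrast (insufficient replicates)"

  data.frame(primer_pair = m$primer_pair,
             call = factor(call, levels = c("direct_strong", "direct_weak",
                                            "same_direction", "ox_specific",
                                            "unchanged")),
             delta_ox_a = m$delta_ox_a, tier_ox_a = m$tier_ox_a,
             delta_ox_b = m$delta_ox_b, tier_ox_b = m$tier_ox_b,
             delta_kd = m$delta_kd, tier_kd = m$tier_kd,
             reason = reason, row.names = NULL)
}
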