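#' Read a RIP qPCR Ct table
#'
#' CSV with columns \code{replicate} (biological replicate index),
#' \code{fraction} (one of \code{input}, \code{IP_plus}, \code{IP_minus}),
#' \code{target} (transcript identifier, including the reference, e.g.
#' PP2A), \code{ct} (quantification cycle; \code{"n.d."}, empty or NA for
#' not detected) and \code{tech_rep} (technical duplicate index).
#'
#' @param path Path to the CSV file.
#' @return A data.frame; undetected reactions carry \code{ct = NA}.
#' @export
readCtTable <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("replicate", "fraction", "target", "ct", "tech_rep")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("Ct table is missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$fraction), c("input", "IP_plus", "IP_minus"))
  if (length(bad))
    stop("unknown fraction label(s): ", paste(bad, collapse = ", "))
  raw <- trimws(as.character(df$ct))
  nd <- raw %in% c("n.d.", "nd", "ND", "NA", "") | is.na(df$ct)
  ct <- suppressWarnings(as.numeric(raw))
  unparse <- which(is.na(ct) & !nd)
  if (length(unparse))
    stop("unparseable Ct in row(s) ",
         paste(utils::head(unparse, 5), collapse = ", "))
  df$ct <- ifelse(nd, NA_real_, ct)
  df$replicate <- as.integer(df$replicate)
  df
}

#' Transcript level relative to a reference from Ct values
#'
#' The delta-Ct model: level = efficiency^-(Ct_target - Ct_reference), with
#' the amplification efficiency fixed at 2 by default (a perfect doubling
#' per cycle). An undetected target (NA Ct) yields NA; an undetected
#' reference is an error, because nothing can be normalized in that
#' fraction/replicate.
#'
#' @param ctTarget,ctReference Quantification cycles (vectorized).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return Dimensionless relative level(s).
#' @examples
#' relativeLevel(21, 20)        # 0.5
#' relativeLevel(20 - 3.3219, 20)  # ~10
#' @export
relativeLevel <- function(ctTarget, ctReference, efficiency = 2) {
  stopifnot(efficiency > 1)
  if (any(is.na(ctReference)))
    stop("reference transcript not detected; cannot normalize this ",
         "fraction/replicate")
  efficiency^-(ctTarget - ctReference)
}

# Average technical duplicates on the Ct scale; all-n.d. stays NA.
.collapseTechReps <- function(ct) {
  agg <- stats::aggregate(ct ~ replicate + fraction + target, data = ct,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$ct[is.nan(agg$ct)] <- NA_real_
  agg
}

#' Per-replicate transcript levels relative to the input fraction
#'
#' Technical duplicates are first averaged on the Ct scale; each fraction's
#' reference-normalized level (see \code{\link{relativeLevel}}) is then
#' divided by the input level of the same biological replicate, so the input
#' level is 1 by construction. Undetected targets propagate as NA with a
#' detectability flag.
#'
#' @param ct Ct table as returned by \code{\link{readCtTable}} (must include
#'   the reference transcript in every fraction/replicate).
#' @param reference Reference transcript identifier (default \code{"PP2A"}).
#' @param efficiency Amplification efficiency (default 2).
#' @return A data.frame with one row per (target, replicate, fraction):
#'   \code{level} (relative to reference), \code{rel_input} (relative to the
#'   input fraction) and \code{detected}.
#' @export
ripRelativeLevels <- function(ct, reference = "PP2A", efficiency = 2) {
  if (!reference %in% ct$target)
    stop("reference transcript '", reference, "' absent from the Ct table")
  cc <- .collapseTechReps(ct)
  ref <- cc[cc$target == reference, c("replicate", "fraction", "ct")]
  names(ref)[3] <- "ct_ref"
  tg <- cc[cc$target != reference, ]
  m <- merge(tg, ref, by = c("replicate", "fraction"), all.x = TRUE)
  if (any(is.na(m$ct_ref)))
    stop("reference transcript not detected in some fraction/replicate; ",
         "cannot normalize")
  m$level <- ifelse(is.na(m$ct), NA_real_,
                    efficiency^-(m$ct - m$ct_ref))
  inp <- m[m$fraction == "input", c("replicate", "target", "level")]
  names(inp)[3] <- "level_input"
  m <- merge(m, inp, by = c("replicate", "target"), all.x = TRUE)
  if (any(is.na(m$level_input) | m$level_input <= 0))
    stop("input level undefined or non-positive for some target/replicate")
  m$rel_input <- m$level / m$level_input
  m$detected <- !is.na(m$ct)
  m[order(m$target, m$replicate, m$fraction),
    c("target", "replicate", "fraction", "ct", "ct_ref", "level",
      "level_input", "rel_input", "detected")]
}

#' IP+ versus IP- enrichment test
#'
#' Enrichment is the ratio of mean IP+ to mean IP- levels (each relative to
#' input), tested with a two-sided Student's t-test on the per-replicate
#' ratios. Stars: \code{"**"} for p < 0.005, \code{"*"} for p < 0.05,
#' \code{"n.s."} otherwise.
#'
#' @param ipPlus,ipMinus Per-replicate levels relative to input (NA = not
#'   detected).
#' @param floorLevel Detection-floor level used to report a lower-bound
#'   enrichment when the mock precipitate is entirely undetected (in which
#'   case no test is applied and the p-value is absent).
#' @param varEqual Pooled-variance Student form (default TRUE, the classical
#'   Student's t-test).
#' @return A list: \code{enrichment}, \code{lower_bound} (logical),
#'   \code{p_value} (NA when no test was applicable), \code{stars},
#'   \code{n_plus}, \code{n_minus}.
#' @examples
#' enrichmentTest(c(4, 5, 6), c(0.5, 0.4, 0.6))
#' @export
enrichmentTest <- function(ipPlus, ipMinus, floorLevel = NULL,
                           varEqual = TRUE) {
  plus <- ipPlus[!is.na(ipPlus)]
  minus <- ipMinus[!is.na(ipMinus)]
  if (length(plus) == 0L)
    return(list(enrichment = NA_real_, lower_bound = FALSE,
                p_value = NA_real_, stars = "n.d.",
                n_plus = 0L, n_minus = length(minus)))
  if (length(minus) == 0L) {
    enr <- if (!is.null(floorLevel) && floorLevel > 0)
      mean(plus) / floorLevel else NA_real_
    return(list(enrichment = enr, lower_bound = TRUE, p_value = NA_real_,
                stars = "n.d.", n_plus = length(plus), n_minus = 0L))
  }
  enr <- mean(plus) / mean(minus)
  p <- if (length(plus) >= 2L && length(minus) >= 2L)
    tTestTwoSample(minus, plus, varEqual = varEqual)$p_value else NA_real_
  stars <- if (is.na(p)) "n.s." else if (p < 0.005) "**" else
    if (p < 0.05) "*" else "n.s."
  list(enrichment = enr, lower_bound = FALSE, p_value = p, stars = stars,
       n_plus = length(plus), n_minus = length(minus))
}

#' Full RIP-qPCR analysis
#'
#' Runs \code{\link{ripRelativeLevels}} and \code{\link{enrichmentTest}} for
#' every target in a Ct table. When a target is undetected in all IP-
#' replicates, the enrichment is reported as a lower bound against the
#' detection floor (default Ct 40) and no statistical test is applied.
#'
#' @inheritParams ripRelativeLevels
#' @param floorCt Detection-floor quantification cycle (default 40).
#' @param varEqual See \code{\link{enrichmentTest}}.
#' @return A data.frame with one row per target: mean level per fraction
#'   relative to input (\code{input} is 1 by construction), \code{sd_ip_plus},
#'   \code{sd_ip_minus}, \code{enrichment}, \code{lower_bound},
#'   \code{p_value}, \code{stars}, \code{n_replicates}, and per-fraction
#'   detectability counts.
#' @export
ripAnalysis <- function(ct, reference = "PP2A", efficiency = 2, floorCt = 40,
                        varEqual = TRUE) {
  lv <- ripRelativeLevels(ct, reference = reference, efficiency = efficiency)
  out <- lapply(split(lv, lv$target), function(d) {
    byFrac <- split(d, d$fraction)
    getRel <- function(f) if (f %in% names(byFrac)) byFrac[[f]]$rel_input
      else numeric(0)
    plus <- getRel("IP_plus")
    minus <- getRel("IP_minus")
    # lower-bound level (relative to input) for an entirely undetected mock
    # precipitate: what the assay would report at the detection-floor cycle
    ipm <- byFrac[["IP_minus"]]
    floorLevel <- if (!is.null(ipm) && nrow(ipm))
      mean(efficiency^-(floorCt - ipm$ct_ref) / ipm$level_input) else NA_real_
    et <- enrichmentTest(plus, minus, floorLevel = floorLevel,
                         varEqual = varEqual)
    data.frame(target = d$target[1],
               level_input = 1,
               level_ip_plus = if (length(plus)) mean(plus, na.rm = TRUE)
                 else NA_real_,
               level_ip_minus = if (all(is.na(minus)) || !length(minus))
                 NA_real_ else mean(minus, na.rm = TRUE),
               sd_ip_plus = stats::sd(plus, na.rm = TRUE),
               sd_ip_minus = stats::sd(minus, na.rm = TRUE),
               enrichment = et$enrichment, lower_bound = et$lower_bound,
               p_value = et$p_value, stars = et$stars,
               n_replicates = length(unique(d$replicate)),
               detected_ip_plus = sum(!is.na(plus)),
               detected_ip_minus = sum(!is.na(minus)),
               row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
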