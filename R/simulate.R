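#' Configuration for the synthetic panel and RIP generators
#'
#' Defaults emulate the study design the package targets: a 288-event panel
#' with the published event-type composition, three biological replicates,
#' replicate noise of SD 3 percentage points (the assay's technical SEM is
#' up to about 3 points), a five-genotype expression dosage series
#' (knockdown, two wild types, two independent over-expression lines), a
#' 15-point dosage-monotone shift for planted direct targets, and a RIP
#' experiment with 10 candidate targets of which 7 are bound at 10x capture
#' over a 0.1x mock background.
#'
#' @param nEvents Number of alternative-splicing events (reference
#'   transcripts are added on top).
#' @param replicates Biological replicates per genotype (>= 2).
#' @param fractionDirect,fractionWeak,fractionSame Proportions of events
#'   planted as strong direct targets, weak direct targets (opposite but
#'   small knockdown response) and same-direction responders; the remainder
#'   are null.
#' @param effectSize Over-expression shift of the designated isoform
#'   (percentage points). Strong direct targets shift by the full
#'   \code{effectSize} in the opposite direction in the knockdown;
#'   same-direction events by half of it, with the same sign.
#' @param weakEffect Knockdown shift of weak direct targets (points).
#' @param noiseSD Replicate noise SD on the percentage scale (points).
#' @param expressionSD Log-normal SD of per-sample expression noise.
#' @param referenceLevel Mean peak area of the reference transcripts (a.u.).
#' @param ripTargets,ripBound Number of RIP candidate targets and how many
#'   of them are bound.
#' @param ripEnrichment Capture factor of bound targets in the specific
#'   precipitate (IP+), relative to input.
#' @param ripBackground Nonspecific capture factor (IP-, and IP+ of unbound
#'   targets).
#' @param ripUndetectedIPminus Number of bound targets whose mock-precipitate
#'   signal lies below the detection limit (emitted as n.d.).
#' @param ctNoise Gaussian noise SD on the Ct scale (cycles).
#' @param ctReference Baseline quantification cycle of the reference
#'   transcript.
#' @param techReps Technical qPCR duplicates.
#' @param seed Integer seed; all randomness in both generators flows from it.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nEvents = 288, replicates = 3,
                             fractionDirect = 10 / 288,
                             fractionWeak = 5 / 288,
                             fractionSame = 3 / 288,
                             effectSize = 15, weakEffect = 4, noiseSD = 3,
                             expressionSD = 0.5, referenceLevel = 10000,
                             ripTargets = 10, ripBound = 7,
                             ripEnrichment = 10, ripBackground = 0.1,
                             ripUndetectedIPminus = 2,
                             ctNoise = 0.2, ctReference = 20, techReps = 2,
                             seed = 1) {
  cfg <- list(nEvents = as.integer(nEvents), replicates = as.integer(replicates),
              fractionDirect = fractionDirect, fractionWeak = fractionWeak,
              fractionSame = fractionSame, effectSize = effectSize,
              weakEffect = weakEffect, noiseSD = noiseSD,
              expressionSD = expressionSD, referenceLevel = referenceLevel,
              ripTargets = as.integer(ripTargets), ripBound = as.integer(ripBound),
              ripEnrichment = ripEnrichment, ripBackground = ripBackground,
              ripUndetectedIPminus = as.integer(ripUndetectedIPminus),
              ctNoise = ctNoise, ctReference = ctReference,
              techReps = as.integer(techReps), seed = as.integer(seed))
  with(cfg, {
    stopifnot(nEvents >= 1, replicates >= 2,
              fractionDirect >= 0, fractionDirect <= 1,
              fractionWeak >= 0, fractionWeak <= 1,
              fractionSame >= 0, fractionSame <= 1,
              fractionDirect + fractionWeak + fractionSame <= 1,
              effectSize > 0, weakEffect > 0, noiseSD >= 0,
              expressionSD >= 0, referenceLevel > 0,
              ripBound <= ripTargets, ripUndetectedIPminus <= ripBound,
              ripEnrichment > 0, ripBackground >= 0, ctNoise >= 0,
              techReps >= 1)
  })
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nEvents, "events x", x$replicates,
      "replicates, effect", x$effectSize, "pts, noise SD", x$noiseSD,
      "pts, seed", x$seed, "\n")
  invisible(x)
}

.SIM_GENOTYPES <- data.frame(
  key = c("kd", "wt_col", "ox_col", "wt_c24", "ox_c24"),
  genotype = c("atgrp7-1 8i", "Col-2 wt", "AtGRP7-ox Col-2",
               "C24 wt", "AtGRP7-ox C24"),
  ecotype = c("Col-2", "Col-2", "Col-2", "C24", "C24"),
  stringsAsFactors = FALSE)

# Panel-like event-type composition (census of a ~288-event panel).
.SIM_TYPE_PROBS <- c(alt_3ss = 0.47, alt_5ss = 0.23, intron_retention = 0.17,
                     exon_skipping = 0.12, cryptic_intron = 0.01)

#' Simulate a fragment-analysis splicing panel with known ground truth
#'
#' Generates a panel definition (two-isoform events with panel-like
#' event-type composition plus two reference transcripts), a sample sheet
#' over the five-genotype dosage series, and per-sample peak records. For
#' each event, genotype and replicate, the replicate's isoform percentages
#' are the true fractions perturbed by Gaussian noise of SD \code{noiseSD}
#' on the percentage scale, clipped to [0, 100] and renormalized to 100;
#' peak areas are the percentages scaled by a log-normally noisy expression
#' level, and reference-transcript peaks are emitted for every sample.
#' Planted direct targets shift the designated isoform dosage-monotonically:
#' the over-expression lines by +/- \code{effectSize} points and the
#' knockdown by the same amount in the opposite direction (weak targets by
#' only \code{weakEffect} points in the knockdown).
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A list of class \code{"PanelSimulation"}: \code{peaks} (data.frame
#'   as from \code{\link{readPeakTable}}), \code{samples} (sample sheet),
#'   \code{panel} (a \code{\linkS4class{SplicingPanel}}), and \code{truth}
#'   (per-event planted class, effect sign and true designated-isoform
#'   fraction per genotype; \code{boundary_events} lists events clipped at
#'   the percentage boundary).
#' @export
simulatePanel <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nE <- config$nEvents

  ids <- sprintf("E%03d", seq_len(nE))
  types <- sample(names(.SIM_TYPE_PROBS), nE, replace = TRUE,
                  prob = .SIM_TYPE_PROBS)
  small <- sample(100:300, nE, replace = TRUE)
  large <- small + sample(30:200, nE, replace = TRUE)
  sizes <- mapply(function(a, b) c(a, b), small, large, SIMPLIFY = FALSE)

  refs <- data.frame(id = c("REF_ACTIN11", "REF_RPL12c"),
                     gene = c("At3g12110", "At2g37190"),
                     desc = c("ACTIN11", "RPL12c"), size = c(180L, 210L))
  panel <- SplicingPanel(
    primer_pair = c(ids, refs$id),
    gene_id = c(sprintf("At%dg%05d", sample(1:5, nE, TRUE),
                        sample(1:79999, nE)), refs$gene),
    description = c(paste("simulated", types, "event"), refs$desc),
    event_type = c(types, rep("reference", 2L)),
    sizes = c(sizes, as.list(refs$size)))

  gt <- .SIM_GENOTYPES
  samples <- data.frame(
    sample_id = paste0("s_", rep(gt$key, each = config$replicates), "_",
                       rep(seq_len(config$replicates), times = nrow(gt))),
    genotype = rep(gt$genotype, each = config$replicates),
    ecotype = rep(gt$ecotype, each = config$replicates),
    replicate = rep(seq_len(config$replicates), times = nrow(gt)),
    stringsAsFactors = FALSE)

  nDirect <- round(config$fractionDirect * nE)
  nWeak <- round(config$fractionWeak * nE)
  nSame <- round(config$fractionSame * nE)
  cls <- rep("null", nE)
  cls[seq_len(min(nE, nDirect + nWeak + nSame))] <-
    rep(c("direct_strong", "direct_weak", "same_direction"),
        c(nDirect, nWeak, nSame))[seq_len(min(nE, nDirect + nWeak + nSame))]
  cls <- sample(cls)
  sgn <- sample(c(-1, 1), nE, replace = TRUE)

  f0 <- stats::runif(nE, 0.25, 0.75)
  e <- config$effectSize / 100
  w <- config$weakEffect / 100
  oxShift <- ifelse(cls == "null", 0, sgn * e)
  kdShift <- ifelse(cls == "direct_strong", -sgn * e,
             ifelse(cls == "direct_weak", -sgn * w,
             ifelse(cls == "same_direction", sgn * e / 2, 0)))
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  truth <- data.frame(primer_pair = ids, class = cls, sign = sgn,
                      frac_wt_col = f0, frac_wt_c24 = f0,
                      frac_ox_col = clip01(f0 + oxShift),
                      frac_ox_c24 = clip01(f0 + oxShift),
                      frac_kd = clip01(f0 + kdShift),
                      stringsAsFactors = FALSE)

  baseExpr <- config$referenceLevel *
    stats::rlnorm(nE, meanlog = log(0.5), sdlog = 0.8)
  fracCols <- c(kd = "frac_kd", wt_col = "frac_wt_col", ox_col = "frac_ox_col",
                wt_c24 = "frac_wt_c24", ox_c24 = "frac_ox_c24")
  boundary <- character(0)

  nS <- nrow(samples)
  sizeMat <- rbind(small, large)
  peakList <- vector("list", nS)
  for (si in seq_len(nS)) {
    key <- gt$key[match(samples$genotype[si], gt$genotype)]
    f <- truth[[fracCols[[key]]]]
    truePct <- rbind(f, 1 - f) * 100
    noisy <- truePct + matrix(stats::rnorm(2 * nE, 0, config$noiseSD), 2L, nE)
    clipped <- pmin(pmax(noisy, 0), 100)
    if (any(clipped != noisy))
      boundary <- union(boundary, ids[colSums(clipped != noisy) > 0])
    tot <- colSums(clipped)
    dead <- tot <= 0
    if (any(dead)) {  # fully clipped out: fall back to the true fractions
      clipped[, dead] <- truePct[, dead]
      tot[dead] <- colSums(truePct[, dead, drop = FALSE])
    }
    pct <- sweep(clipped, 2L, tot, "/") * 100
    expr <- baseExpr * stats::rlnorm(nE, 0, config$expressionSD)
    areas <- sweep(pct / 100, 2L, expr, "*")
    refAreas <- config$referenceLevel * stats::rlnorm(2L, 0, config$expressionSD)
    peakList[[si]] <- data.frame(
      sample_id = samples$sample_id[si],
      primer_pair = c(rep(ids, each = 2L), refs$id),
      size_bp = c(as.vector(sizeMat) + stats::runif(2 * nE, -0.3, 0.3),
                  refs$size + stats::runif(2L, -0.3, 0.3)),
      area = c(as.vector(areas), refAreas),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peakList)
  rownames(peaks) <- NULL

  structure(list(peaks = peaks, samples = samples, panel = panel,
                 truth = truth, boundary_events = boundary, config = config),
            class = "PanelSimulation")
}

#' @export
print.PanelSimulation <- function(x, ...) {
  cat("PanelSimulation:", nrow(x$truth), "events,",
      nrow(x$samples), "samples,", nrow(x$peaks), "peaks\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Simulate a RIP-qPCR Ct table with known ground truth
#'
#' Concentrations relative to the reference transcript (PP2A, fixed at 1 in
#' every fraction): each target's input concentration is log-normal; the
#' specific precipitate (IP+) captures \code{ripEnrichment} x input for
#' bound targets and \code{ripBackground} x input for unbound ones; the mock
#' precipitate (IP-) always captures background. Quantification cycles are
#' \code{ctReference - log2(concentration) + noise} with Gaussian noise of
#' SD \code{ctNoise} per well, emitted in technical duplicates; wells whose
#' expected cycle exceeds the detection floor (and targets configured as
#' below the mock detection limit) are emitted as n.d.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param floorCt Detection floor (cycles, default 40).
#' @return A list of class \code{"RipSimulation"}: \code{ct} (data.frame as
#'   from \code{\link{readCtTable}}) and \code{truth} (per-target bound
#'   label and planted IP+/IP- enrichment).
#' @export
simulateRip <- function(config = simulationConfig(), floorCt = 40) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  nT <- config$ripTargets
  targets <- sprintf("T%02d", seq_len(nT))
  bound <- rep(c(TRUE, FALSE), c(config$ripBound, nT - config$ripBound))
  ndMinus <- bound & seq_len(nT) <= config$ripUndetectedIPminus

  inputConc <- stats::rlnorm(nT, meanlog = log(0.05), sdlog = 0.7)
  fractions <- c("input", "IP_plus", "IP_minus")
  rows <- expand.grid(tech_rep = seq_len(config$techReps),
                      target = c(targets, "PP2A"),
                      fraction = fractions,
                      replicate = seq_len(config$replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conc <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    tg <- rows$target[i]
    if (tg == "PP2A") { conc[i] <- 1; next }
    j <- match(tg, targets)
    conc[i] <- switch(rows$fraction[i],
      input = inputConc[j],
      IP_plus = inputConc[j] *
        (if (bound[j]) config$ripEnrichment else config$ripBackground),
      IP_minus = if (ndMinus[j]) 0 else inputConc[j] * config$ripBackground)
  }
  ct <- ifelse(conc > 0,
               config$ctReference - log2(conc) +
                 stats::rnorm(nrow(rows), 0, config$ctNoise),
               NA_real_)
  ct[!is.na(ct) & ct > floorCt] <- NA_real_
  out <- data.frame(replicate = rows$replicate, fraction = rows$fraction,
                    target = rows$target, ct = ct,
                    tech_rep = rows$tech_rep, stringsAsFactors = FALSE)
  truth <- data.frame(
    target = targets, bound = bound, input_conc = inputConc,
    nd_ip_minus = ndMinus,
    planted_enrichment = ifelse(ndMinus, Inf,
      ifelse(bound, config$ripEnrichment / config$ripBackground, 1)),
    stringsAsFactors = FALSE)
  structure(list(ct = out, truth = truth, config = config),
            class = "RipSimulation")
}

#' Write a panel simulation to disk
#'
#' Emits \code{peaks.csv}, \code{samples.tsv}, \code{panel.tsv} and
#' \code{truth.tsv} into a directory, in the formats the readers consume.
#'
#' @param sim A \code{"PanelSimulation"} from \code{\link{simulatePanel}}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(inherits(sim, "PanelSimulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$peaks, file.path(dir, "peaks.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writePanelDefinition(sim$panel, file.path(dir, "panel.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
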