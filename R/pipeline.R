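#' Read a pipeline run configuration
#'
#' YAML with input paths (\code{panel}, \code{peaks}, \code{samples},
#' optionally \code{qpcr}), an output directory (\code{out_dir}), the
#' contrast definitions (\code{contrasts}: list of \code{{a, b}} genotype
#' pairs), an optional dosage-series block (\code{dosage}: \code{wt},
#' \code{ox_a}, \code{ox_b}, \code{kd}, and optionally \code{wt_b} as the
#' wild type of the second over-expression background) and thresholds
#' (\code{tolerance} 1.0 bp, \code{alpha} 0.05, \code{primary_threshold}
#' 5.0, \code{secondary_threshold} 3.0, \code{fold_threshold} 2.0,
#' \code{pooled_ttest} FALSE). All thresholds are echoed into the run log
#' for provenance.
#'
#' @param path Path to a YAML configuration file.
#' @return A named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(tolerance = 1.0, alpha = 0.05, primary_threshold = 5.0,
                   secondary_threshold = 3.0, fold_threshold = 2.0,
                   pooled_ttest = FALSE, out_dir = "aspanel_out")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("panel", "peaks", "samples"))
    if (is.null(cfg[[k]]))
      stop("run configuration is missing required path: ", k)
  for (k in c("panel", "peaks", "samples", "qpcr"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configured file does not exist: ", cfg[[k]])
  stopifnot(cfg$tolerance > 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$primary_threshold > 0,
            cfg$secondary_threshold > 0,
            cfg$secondary_threshold <= cfg$primary_threshold,
            cfg$fold_threshold > 1)
  cfg
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.contrastLabel <- function(a, b) {
  gsub("[^A-Za-z0-9._-]", "_", paste(a, "vs", b))
}

#' Run the full splicing-panel pipeline
#'
#' Reads the panel, sample sheet, peak table and (optionally) RIP Ct table
#' named in the configuration, then writes to the output directory:
#' per-sample isoform profiles, one contrast table per configured genotype
#' pair (means, delta, p-value, tier, plus integer-rounded display columns),
#' an event-type census with hypergeometric enrichment per contrast, a
#' direct-target classification (when a dosage block is configured), Venn
#' counts of the changed sets across contrasts, RIP results, and a run log
#' recording package version, thresholds and inputs.
#'
#' @param config A list as returned by \code{\link{readRunConfig}}, or a path
#'   to a YAML file.
#' @return Invisibly, a named list of the objects computed (profiles
#'   experiment, contrast tables, enrichment tables, target calls, RIP
#'   results, output paths).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  panel <- readPanelDefinition(config$panel)
  samples <- readSampleSheet(config$samples)
  peaks <- readPeakTable(config$peaks, panel)
  ie <- buildIsoformExperiment(peaks, panel, samples,
                               tolerance = config$tolerance)

  rd <- rowData(ie)
  profiles <- data.frame(
    sample_id = rep(colnames(ie), each = nrow(ie)),
    primer_pair = rep(rd$primer_pair, times = ncol(ie)),
    size = rep(rd$size, times = ncol(ie)),
    area = as.vector(assay(ie, "area")),
    percent = as.vector(assay(ie, "percent")))
  paths <- c(paths, .writeTsv(profiles, file.path(outDir, "profiles.tsv")))

  contrasts <- config$contrasts
  if (is.null(contrasts)) stop("run configuration defines no contrasts")
  comparisons <- list()
  enrichments <- list()
  changedSets <- list()
  for (ctr in contrasts) {
    if (is.null(ctr$a) || is.null(ctr$b))
      stop("each contrast needs genotypes 'a' and 'b'")
    lbl <- .contrastLabel(ctr$a, ctr$b)
    cmp <- compareGenotypes(ie, ctr$a, ctr$b, alpha = config$alpha,
                            primaryMin = config$primary_threshold,
                            secondaryMin = config$secondary_threshold,
                            varEqual = isTRUE(config$pooled_ttest))
    disp <- cmp
    disp$mean_a_pct <- round(disp$mean_a)
    disp$mean_b_pct <- round(disp$mean_b)
    disp$p_display <- ifelse(is.na(disp$p_value), NA,
                             format(round(disp$p_value, 4), nsmall = 4))
    paths <- c(paths, .writeTsv(disp,
      file.path(outDir, paste0("contrast_", lbl, ".tsv"))))
    comparisons[[lbl]] <- cmp
    changed <- cmp$primer_pair[!is.na(cmp$tier) & cmp$tier == "primary"]
    changedSets[[lbl]] <- changed
    if (length(changed)) {
      enr <- eventTypeEnrichment(panel, changed)
      paths <- c(paths, .writeTsv(enr,
        file.path(outDir, paste0("census_", lbl, ".tsv"))))
      enrichments[[lbl]] <- enr
    }
  }

  if (length(changedSets) >= 2L) {
    venn <- overlapCounts(changedSets)
    paths <- c(paths, .writeTsv(venn, file.path(outDir, "venn_counts.tsv")))
  } else venn <- NULL

  targets <- NULL
  ds <- config$dosage
  if (!is.null(ds)) {
    for (k in c("wt", "ox_a", "kd"))
      if (is.null(ds[[k]])) stop("dosage block needs genotype '", k, "'")
    oxA <- compareGenotypes(ie, ds$wt, ds$ox_a, alpha = config$alpha,
                            primaryMin = config$primary_threshold,
                            secondaryMin = config$secondary_threshold,
                            varEqual = isTRUE(config$pooled_ttest))
    oxB <- if (!is.null(ds$ox_b))
      compareGenotypes(ie, if (is.null(ds$wt_b)) ds$wt else ds$wt_b, ds$ox_b,
                       alpha = config$alpha,
                       primaryMin = config$primary_threshold,
                       secondaryMin = config$secondary_threshold,
                       varEqual = isTRUE(config$pooled_ttest)) else NULL
    kd <- compareGenotypes(ie, ds$wt, ds$kd, alpha = config$alpha,
                           primaryMin = config$primary_threshold,
                           secondaryMin = config$secondary_threshold,
                           varEqual = isTRUE(config$pooled_ttest))
    targets <- classifyTargets(oxA, oxB, kd)
    paths <- c(paths, .writeTsv(targets,
                                file.path(outDir, "direct_targets.tsv")))
    ab <- abundanceChange(ie, ds$wt, ds$ox_a, fold = config$fold_threshold)
    paths <- c(paths, .writeTsv(ab,
                                file.path(outDir, "abundance_change.tsv")))
  }

  rip <- NULL
  if (!is.null(config$qpcr)) {
    ctTab <- readCtTable(config$qpcr)
    rip <- ripAnalysis(ctTab)
    paths <- c(paths, .writeTsv(rip, file.path(outDir, "rip_results.tsv")))
  }

  log <- c(paste0("ASpanel ", as.character(utils::packageVersion("ASpanel")),
                  " on R ", getRversion()),
           paste0("panel=", config$panel),
           paste0("peaks=", config$peaks),
           paste0("samples=", config$samples),
           paste0("qpcr=", if (is.null(config$qpcr)) "-" else config$qpcr),
           paste0("tolerance_bp=", config$tolerance),
           paste0("alpha=", config$alpha),
           paste0("primary_threshold=", config$primary_threshold),
           paste0("secondary_threshold=", config$secondary_threshold),
           paste0("fold_threshold=", config$fold_threshold),
           paste0("pooled_ttest=", isTRUE(config$pooled_ttest)),
           paste0("seed=", if (is.null(config$seed)) "-" else config$seed),
           paste0("events=", length(panel), " samples=", nrow(samples)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  paths <- c(paths, file.path(outDir, "run_log.txt"))

  invisible(list(experiment = ie, comparisons = comparisons,
                 enrichment = enrichments, venn = venn, targets = targets,
                 rip = rip, paths = paths))
}
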