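# Fixtures built in code: a small panel, deterministic peak tables, and a
# constructor that turns target designated-isoform percentages into a full
# IsoformExperiment via the real peak-matching path.

toyPanel <- function() {
  SplicingPanel(
    primer_pair = c("#A", "#B", "#C", "REF1", "REF2"),
    gene_id = c("At1g00001", "At1g00002", "At1g00003", "At3g12110", "At2g37190"),
    description = c("alt 5'ss event", "three-isoform event", "exon skip",
                    "reference 1", "reference 2"),
    event_type = c("alt_5ss", "alt_3ss", "exon_skipping",
                   "reference", "reference"),
    sizes = list(c(158L, 316L), c(141L, 150L, 215L), c(143L, 309L),
                 180L, 210L),
    relevant = list(c(158L, 316L), c(150L, 215L), c(143L, 309L),
                    180L, 210L))
}

toySamples <- function(genotypes = c("wt", "ox"), replicates = 3) {
  data.frame(
    sample_id = paste0("s_", rep(genotypes, each = replicates), "_",
                       rep(seq_len(replicates), length(genotypes))),
    genotype = rep(genotypes, each = replicates),
    ecotype = "Col-2",
    replicate = rep(seq_len(replicates), length(genotypes)),
    stringsAsFactors = FALSE)
}

# Peaks for toyPanel(): `designatedPct` is a list mapping event id ->
# per-sample percentage of the smallest relevant isoform (other relevant
# isoforms share the remainder equally); `expr` scales the event's total
# relevant area per sample; reference areas fixed per sample.
toyPeaks <- function(samples, designatedPct, expr = 1000,
                     refArea = c(REF1 = 500, REF2 = 250)) {
  panel <- toyPanel()
  ev <- panelEvents(panel)
  expr <- rep_len(expr, nrow(samples))
  rows <- list()
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    for (id in names(designatedPct)) {
      e <- ev[match(id, ev$primer_pair), ]
      rel <- sort(e$relevant[[1]])
      p <- rep_len(designatedPct[[id]], nrow(samples))[si]
      pcts <- c(p, rep((100 - p) / (length(rel) - 1), length(rel) - 1))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, primer_pair = id, size_bp = as.numeric(rel),
        area = expr[si] * pcts / 100)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sid, primer_pair = c("REF1", "REF2"),
      size_bp = c(180, 210), area = as.numeric(refArea))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

toyExperiment <- function(designatedPct, samples = toySamples(),
                          expr = 1000, refArea = c(REF1 = 500, REF2 = 250)) {
  buildIsoformExperiment(toyPeaks(samples, designatedPct, expr, refArea),
                         toyPanel(), samples)
}

writeTempTsv <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
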