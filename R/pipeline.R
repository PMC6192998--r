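## End-to-end orchestration: simulate an experiment, write its files,
## re-ingest them through the standard readers, run every analysis
## stage, and emit tab-delimited report tables plus a machine-readable
## summary. Deterministic for a given seed.

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates a synthetic CLIP co-occupancy experiment, writes all input
#' files (UTR table + FASTA, per-protein site/count tables, sample
#' designs, mRNA LFC table, ground truth), reads them back through the
#' package ingest path, and runs the analysis stages: read-count
#' filtering (cutoff = number of samples per set), transcript-level
#' co-occupancy Venn counts, the AGO2-vs-PUM2 overlap z-score against
#' the within-UTR randomization null, the PUM-motif density profile
#' around PUM2 sites with permutation envelope, mRNA-normalized AGO2
#' LFCs upon PUM knockdown with per-UTR extremes and KS comparisons of
#' co-bound vs AGO2-only UTR classes, PUM2 LFCs upon DICER loss
#' stratified by AGO2 overlap, the mRNA-level KS comparison of bound
#' transcript classes, and the miRNA seed repertoire correlation
#' between PUM2-overlapping and non-overlapping AGO2 sites.
#'
#' @param config a [simConfig()].
#' @param outDir output directory (created if needed); inputs under
#'   `inputs/`, report tables and `summary.json` at the top level.
#' @param seed integer seed governing every random draw (simulation and
#'   randomization nulls); the same seed reproduces identical outputs.
#' @param nRandomizations randomizations for the overlap null and
#'   density envelope (default 100).
#' @param densityWindow,densityBin density profile geometry in nt.
#' @return The summary list (also written to `summary.json`),
#'   invisibly.
#' @export
runPipeline <- function(config = simConfig(), outDir, seed = 1L,
                        nRandomizations = 100L, densityWindow = 200L,
                        densityBin = 10L) {
  dir.create(file.path(outDir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  withSeed(seed, {
    inp <- function(f) file.path(outDir, "inputs", f)
    out <- function(f) file.path(outDir, f)
    sim <- simulateExperiment(config)

    ## ---- emit inputs and re-ingest through the standard readers ----
    writeHostFeatures(sim$features, inp("utrs.tsv"), inp("utrs.fa"))
    .writeTsv(mrnaLfc(sim$features), inp("mrna_lfc.tsv"))
    for (p in names(sim$sites)) {
      writeSites(sim$sites[[p]], inp(sprintf("sites_%s.tsv", p)))
      .writeTsv(sim$designs[[p]], inp(sprintf("design_%s.tsv", p)))
    }
    .writeTsv(sim$truth$utrs, inp("truth_utrs.tsv"))
    .writeTsv(sim$truth$sites, inp("truth_sites.tsv"))
    if (!is.null(sim$truth$plants))
      .writeTsv(sim$truth$plants, inp("truth_plants.tsv"))

    features <- readHostFeatures(inp("utrs.tsv"), inp("utrs.fa"))
    mrnaLfc(features) <- readMrnaLfc(inp("mrna_lfc.tsv"))
    readDesign <- function(p) {
      d <- utils::read.delim(inp(sprintf("design_%s.tsv", p)),
                             stringsAsFactors = FALSE)
      sampleDesign(d$sample, d$condition, d$replicate, d$library_size)
    }
    sites <- lapply(stats::setNames(nm = names(sim$sites)), function(p)
      readSites(inp(sprintf("sites_%s.tsv", p)), features))
    designs <- lapply(stats::setNames(nm = names(sim$sites)), readDesign)

    ## read-support filter: cutoff = number of samples in each set
    sites <- lapply(sites, filterSitesByCount)

    ## ---- transcript-level co-occupancy ----
    cooc <- utrCooccupancy(sites, features)
    .writeTsv(data.frame(combination = names(cooc$venn),
                         n_utrs = cooc$venn), out("venn.tsv"))

    ## ---- site-level overlap with randomization null ----
    oz <- overlapZscore(sites$AGO2, sites$PUM2, which = "a",
                        n = nRandomizations)
    .writeTsv(data.frame(observed = oz$observed, null_mean = oz$null_mean,
                         null_sd = oz$null_sd, z = oz$z,
                         n_randomizations = oz$n_randomizations),
              out("overlap_zscore.tsv"))

    ## ---- PUM motif density around PUM2 sites ----
    motifHits <- scanPumMotifs(features)
    dens <- densityProfile(sites$PUM2, motifHits,
                           window = densityWindow, bin = densityBin,
                           n = nRandomizations)
    .writeTsv(as.data.frame(dens), out("density_pum_motif.tsv"))

    ## ---- AGO2 differential binding upon PUM knockdown ----
    agoLfc <- computeLfc(sites$AGO2, designs$AGO2, "control", "PUMKD")
    agoLfc <- normalizeLfc(agoLfc, features, "PUMKD")
    .writeTsv(agoLfc, out("ago2_site_lfc.tsv"))
    ext <- utrExtremes(agoLfc)
    .writeTsv(ext, out("ago2_utr_extremes.tsv"))
    mem <- cooc$membership
    cobound <- rownames(mem)[mem[, "AGO2"] & mem[, "PUM2"]]
    agoOnly <- rownames(mem)[mem[, "AGO2"] & !mem[, "PUM2"]]
    ksMin <- ksClassCompare(
      list(cobound = ext$min_lfc[ext$feature_id %in% cobound],
           ago2_only = ext$min_lfc[ext$feature_id %in% agoOnly]),
      "cobound", "ago2_only")
    ksMax <- ksClassCompare(
      list(cobound = ext$max_lfc[ext$feature_id %in% cobound],
           ago2_only = ext$max_lfc[ext$feature_id %in% agoOnly]),
      "cobound", "ago2_only")

    ## ---- PUM2 binding upon DICER loss, stratified by AGO2 overlap ----
    pumLfc <- computeLfc(sites$PUM2, designs$PUM2, "WT", "DICERKO")
    pumLfc <- normalizeLfc(pumLfc, features, "DICERKO")
    strat <- stratifySitesByOverlap(sites$PUM2, sites$AGO2)
    pumLfc$ago2_overlap <- as.character(strat[pumLfc$site_id])
    .writeTsv(pumLfc, out("pum2_site_lfc.tsv"))
    ksStrat <- ksClassCompare(
      split(pumLfc$normalized_lfc, pumLfc$ago2_overlap),
      "overlapping", "non_overlapping")

    ## ---- mRNA-level KS of bound transcript classes ----
    mvals <- mrnaLfc(features, "PUMKD")
    ksMrna <- ksClassCompare(
      list(pum2_bound = mvals[rownames(mem)[mem[, "PUM2"]]],
           unbound = mvals[rownames(mem)[!mem[, "PUM2"]]]),
      "pum2_bound", "unbound")

    ## ---- miRNA repertoire of AGO2 sites by PUM2 overlap ----
    agoStrat <- stratifySitesByOverlap(sites$AGO2, sites$PUM2)
    rep_ <- seedRepertoireCorrelation(
      sites$AGO2[agoStrat == "overlapping"],
      sites$AGO2[agoStrat == "non_overlapping"],
      config$mirnas, features)
    .writeTsv(rep_$tallies, out("seed_repertoire.tsv"))

    ksRow <- function(tag, k)
      data.frame(comparison = tag, class_a = k$classes[1L],
                 class_b = k$classes[2L], n_a = k$n[1L], n_b = k$n[2L],
                 D = k$D, p_value = k$p_value, stringsAsFactors = FALSE)
    .writeTsv(rbind(ksRow("min_lfc_cobound_vs_ago2only", ksMin),
                    ksRow("max_lfc_cobound_vs_ago2only", ksMax),
                    ksRow("pum2_lfc_by_ago2_overlap", ksStrat),
                    ksRow("mrna_lfc_pum2bound_vs_unbound", ksMrna)),
              out("ks_report.tsv"))

    peakBin <- which.min(abs(dens$offset))
    summary <- list(
      seed = as.integer(seed),
      n_utrs = nFeatures(features),
      n_sites = lapply(sites, nSites),
      venn = as.list(cooc$venn),
      overlap_z = oz$z,
      overlap_observed = oz$observed,
      overlap_null_mean = oz$null_mean,
      motif_density_peak_ratio =
        unname(dens$observed[peakBin] / max(dens$null_mean[peakBin],
                                            1e-9)),
      ks_min_lfc = list(D = ksMin$D, p = ksMin$p_value),
      ks_max_lfc = list(D = ksMax$D, p = ksMax$p_value),
      ks_pum2_overlap = list(D = ksStrat$D, p = ksStrat$p_value),
      ks_mrna = list(D = ksMrna$D, p = ksMrna$p_value),
      seed_repertoire_rho = rep_$rho,
      median_min_lfc = list(
        cobound = stats::median(ext$min_lfc[ext$feature_id %in% cobound]),
        ago2_only = stats::median(ext$min_lfc[ext$feature_id %in% agoOnly])),
      median_max_lfc = list(
        cobound = stats::median(ext$max_lfc[ext$feature_id %in% cobound]),
        ago2_only = stats::median(ext$max_lfc[ext$feature_id %in% agoOnly]))
    )
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(c(
      sprintf("clipcoreg pipeline run"),
      sprintf("seed: %d", as.integer(seed)),
      sprintf("n_randomizations: %d", as.integer(nRandomizations)),
      sprintf("density window/bin: %d/%d nt", as.integer(densityWindow),
              as.integer(densityBin)),
      sprintf("config: n_utrs=%d coupling=%s/%s", config$n_utrs,
              config$coupling[["cooperative"]],
              config$coupling[["antagonistic"]])
    ), out("log.txt"))
    invisible(summary)
  })
}
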