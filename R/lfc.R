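## Differential CLIP binding: per-site signal quantification, condition
## log fold changes normalized to transcript-level mRNA changes,
## per-UTR extreme-site statistics, KS class comparisons and miRNA
## repertoire correlation.

#' Describe the samples of a CLIP experiment
#'
#' @param sample sample labels matching count column names.
#' @param condition condition label per sample.
#' @param replicate optional replicate index per sample (autonumbered
#'   within condition when `NULL`).
#' @param librarySize positive total collapsed read count per sample,
#'   used for counts-per-million scaling.
#' @return A `SampleDesign` data.frame with columns `sample`,
#'   `condition`, `replicate`, `library_size`.
#' @export
sampleDesign <- function(sample, condition, replicate = NULL,
                         librarySize) {
  sample <- as.character(sample)
  condition <- as.character(condition)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(sample), condition,
                            FUN = seq_along)
  librarySize <- as.numeric(librarySize)
  if (any(!is.finite(librarySize)) || any(librarySize <= 0))
    stop("library sizes must be positive")
  if (anyDuplicated(sample)) stop("duplicated sample labels")
  df <- data.frame(sample = sample, condition = condition,
                   replicate = as.integer(replicate),
                   library_size = librarySize,
                   stringsAsFactors = FALSE)
  class(df) <- c("SampleDesign", "data.frame")
  df
}

#' Per-site CLIP signal in one condition
#'
#' Scales each sample's collapsed read counts to counts per million by
#' its library size, then averages across the condition's replicates.
#'
#' @param x a [BindingSiteSet] with count columns.
#' @param design a [sampleDesign()] table.
#' @param condition condition label to quantify.
#' @return Named numeric vector (CPM) per site.
#' @export
siteSignal <- function(x, design, condition) {
  samples <- design$sample[design$condition == condition]
  if (!length(samples))
    stop("no samples for condition '", condition, "'")
  cts <- siteCounts(x)
  missing <- setdiff(samples, colnames(cts))
  if (length(missing))
    stop("missing count columns for sample(s): ",
         paste(missing, collapse = ", "))
  lib <- stats::setNames(design$library_size, design$sample)[samples]
  cpm <- sweep(cts[, samples, drop = FALSE], 2L, lib, "/") * 1e6
  stats::setNames(rowMeans(cpm), siteIds(x))
}

#' Raw per-site log fold change between two conditions
#'
#' Computes `log2((signal_perturbed + pseudocount) /
#' (signal_control + pseudocount))` on the condition-averaged CPM
#' signal. The pseudocount (1 CPM by default) stabilizes low-signal
#' sites; two all-zero conditions give an LFC of exactly 0.
#'
#' @param x a [BindingSiteSet] with counts for both conditions.
#' @param design a [sampleDesign()] table.
#' @param control,perturbed condition labels.
#' @param pseudocount non-negative CPM offset (default 1).
#' @return `data.frame` with columns `site_id`, `feature_id`,
#'   `protein`, `signal_control`, `signal_perturbed`, `raw_lfc`.
#' @export
computeLfc <- function(x, design, control, perturbed,
                       pseudocount = 1.0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  sc <- siteSignal(x, design, control)
  sp <- siteSignal(x, design, perturbed)
  data.frame(
    site_id = siteIds(x),
    feature_id = featureIds(x),
    protein = proteins(x),
    signal_control = unname(sc),
    signal_perturbed = unname(sp),
    raw_lfc = log2((sp + pseudocount) / (sc + pseudocount)),
    stringsAsFactors = FALSE
  )
}

#' Normalize site log fold changes to mRNA-level changes
#'
#' CLIP signal at a site tracks both binding and transcript abundance;
#' subtracting the transcript's mRNA log2 fold change for the same
#' perturbation (an external measurement supplied with the host
#' features) isolates the binding change:
#' `normalized_lfc = raw_lfc - mrna_lfc`. Sites on transcripts without
#' an mRNA measurement are excluded, reported via a message and in the
#' `"excluded"` attribute of the result.
#'
#' @param lfc a `data.frame` from [computeLfc()] (columns `site_id`,
#'   `feature_id`, `raw_lfc` required).
#' @param features a [HostFeatureSet] carrying `mrnaLfc` for
#'   `condition`.
#' @param condition condition label of the mRNA measurement.
#' @return The input with added columns `mrna_lfc` and
#'   `normalized_lfc`; excluded sites in `attr(, "excluded")`.
#' @export
normalizeLfc <- function(lfc, features, condition) {
  m <- mrnaLfc(features, condition)
  mr <- m[lfc$feature_id]
  miss <- is.na(mr)
  excluded <- data.frame(site_id = lfc$site_id[miss],
                         feature_id = lfc$feature_id[miss],
                         reason = rep(sprintf("no mRNA LFC for condition '%s'",
                                              condition), sum(miss)),
                         stringsAsFactors = FALSE)
  if (any(miss))
    message(sum(miss), " site(s) excluded: host transcript has no mRNA ",
            "LFC for condition '", condition, "'")
  out <- lfc[!miss, , drop = FALSE]
  out$mrna_lfc <- unname(mr[!miss])
  out$normalized_lfc <- out$raw_lfc - out$mrna_lfc
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "condition") <- condition
  out
}

#' Extreme-site statistics per UTR
#'
#' The sites with the minimal and maximal (normalized) LFC within each
#' UTR are the most likely candidates for interaction; this extracts
#' the exact per-feature minimum and maximum.
#'
#' @param lfc `data.frame` with columns `feature_id` and the value
#'   column.
#' @param value name of the LFC column (default `"normalized_lfc"`).
#' @return `data.frame` with columns `feature_id`, `min_lfc`,
#'   `max_lfc`, `n_sites`.
#' @export
utrExtremes <- function(lfc, value = "normalized_lfc") {
  if (!value %in% names(lfc))
    stop("no column '", value, "' in the LFC table")
  sp <- split(lfc[[value]], lfc$feature_id)
  sp <- sp[lengths(sp) > 0L]
  data.frame(
    feature_id = names(sp),
    min_lfc = vapply(sp, min, numeric(1L)),
    max_lfc = vapply(sp, max, numeric(1L)),
    n_sites = lengths(sp),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Kolmogorov-Smirnov comparison of two transcript classes
#'
#' Two-sided two-sample KS test (asymptotic p-value) between the value
#' distributions of two classes, with the empirical CDFs returned for
#' cumulative-distribution plots.
#'
#' @param valuesByClass named list of numeric vectors, one per class.
#' @param classA,classB names of the two classes to compare (each with
#'   n >= 2 values).
#' @return Object of class `ClassComparison`: list with `classes`, `n`,
#'   `D` (sup-norm ECDF distance), `p_value`, and `ecdf` (list of
#'   two data.frames with columns `value`, `ecdf`).
#' @export
ksClassCompare <- function(valuesByClass, classA, classB) {
  for (cl in c(classA, classB)) {
    if (!cl %in% names(valuesByClass))
      stop("unknown class '", cl, "'")
    if (length(valuesByClass[[cl]]) < 2L)
      stop("class '", cl, "' has fewer than 2 values")
  }
  x <- valuesByClass[[classA]]
  y <- valuesByClass[[classB]]
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  mkEcdf <- function(v) {
    v <- sort(v)
    data.frame(value = v, ecdf = seq_along(v) / length(v))
  }
  out <- list(
    classes = c(classA, classB),
    n = stats::setNames(c(length(x), length(y)), c(classA, classB)),
    D = unname(kt$statistic),
    p_value = unname(kt$p.value),
    ecdf = stats::setNames(list(mkEcdf(x), mkEcdf(y)),
                           c(classA, classB))
  )
  class(out) <- "ClassComparison"
  out
}

#' @export
print.ClassComparison <- function(x, ...) {
  cat(sprintf("KS comparison %s (n=%d) vs %s (n=%d): D = %.4f, p = %.3g\n",
              x$classes[1L], x$n[1L], x$classes[2L], x$n[2L],
              x$D, x$p_value))
  invisible(x)
}

#' miRNA repertoire similarity between two site populations
#'
#' Tallies seed-complement occurrences per miRNA family within each
#' group of sites (via [motifTallyPerSite()], window 0) and reports the
#' Spearman rank correlation (average ranks on ties) between the two
#' per-family tally vectors.
#'
#' @param sitesGroup1,sitesGroup2 [BindingSiteSet] objects (e.g.
#'   PUM-overlapping and non-overlapping AGO2 sites).
#' @param mirnas miRNA sequences (named character vector); families are
#'   deduplicated by seed.
#' @param features [HostFeatureSet] with sequences to scan.
#' @param window flank added around sites when tallying (default 0).
#' @return List with `rho` (`NA` with `rho_defined = FALSE` when a
#'   tally vector is constant), `tallies` (per-family data.frame) and
#'   `n_families`.
#' @export
seedRepertoireCorrelation <- function(sitesGroup1, sitesGroup2, mirnas,
                                      features, window = 0L) {
  matches <- scanSeedComplements(features, mirnas)
  rna <- .asRnaChar(mirnas)
  seeds <- substr(rna, 2L, 8L)
  fam <- if (!is.null(names(mirnas)) && all(nzchar(names(mirnas))))
    names(mirnas) else seeds
  famLabels <- fam[!duplicated(seeds)]
  tally <- function(s) {
    m <- motifTallyPerSite(s, matches, window = window,
                           by = "mirna_family")
    tot <- stats::setNames(numeric(length(famLabels)), famLabels)
    if (ncol(m)) {
      cs <- colSums(m)
      tot[names(cs)] <- cs
    }
    tot
  }
  t1 <- tally(sitesGroup1)
  t2 <- tally(sitesGroup2)
  if (sum(t1 + t2 > 0) < 3L)
    stop("need at least 3 miRNA families with nonzero tallies")
  defined <- sd(t1) > 0 && sd(t2) > 0
  list(
    rho = if (defined) cor(t1, t2, method = "spearman") else NA_real_,
    rho_defined = defined,
    tallies = data.frame(mirna_family = famLabels,
                         group1 = unname(t1), group2 = unname(t2),
                         stringsAsFactors = FALSE),
    n_families = length(famLabels)
  )
}
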