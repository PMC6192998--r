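## Luciferase reporter-assay statistics: technical-replicate CV
## filtering, WT/mutant activity ratios, paired and Welch t-tests.

#' Coefficient-of-variation filter for technical replicates
#'
#' A measurement (set of technical replicates of normalized
#' luminescence) is omitted when its coefficient of variation
#' (SD / mean) exceeds the threshold; a CV exactly at the threshold is
#' kept (strict inequality). The filter is monotone in the threshold.
#'
#' @param values numeric vector of >= 2 positive technical-replicate
#'   values.
#' @param threshold CV cutoff (default 0.5, i.e. 50%).
#' @return List with `keep` (logical) and `cv`.
#' @examples
#' cvFilter(c(1, 1))       # CV 0, keep
#' cvFilter(c(1, 3))       # CV ~0.71, omit
#' @export
cvFilter <- function(values, threshold = 0.5) {
  if (length(values) < 2L)
    stop("need at least 2 technical replicates")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("non-positive mean")
  cv <- sd(values) / m
  list(keep = !(cv > threshold), cv = cv)
}

#' Wildtype / mutant activity ratio
#'
#' Ratio of the mean normalized luminescence of the wildtype construct
#' to that of its site-mutant counterpart within one biological
#' replicate. A ratio below 1 indicates a repressive site.
#'
#' @param wt,mut numeric vectors of technical-replicate normalized
#'   values for the paired constructs.
#' @return The WT/mut ratio (scalar).
#' @examples
#' wtMutRatio(c(2, 2, 2), c(1, 1, 3))  # 1.2
#' @export
wtMutRatio <- function(wt, mut) {
  mean(wt) / mean(mut)
}

.pairedP <- function(d) {
  ## Two-tailed one-sample t on the differences; an all-zero difference
  ## vector is degenerate (no evidence of effect, p = 1 by convention).
  eps <- 1e-12
  if (sd(d) < eps) {
    if (max(abs(d)) < eps) return(list(p = 1, degenerate = TRUE))
    return(list(p = 0, degenerate = TRUE))
  }
  list(p = t.test(d)$p.value, degenerate = FALSE)
}

#' Reporter-assay statistics across biological replicates
#'
#' Computes, from raw dual-luciferase measurements: per-technical-set
#' normalized values (renilla / firefly), the CV filter (biological
#' replicates where either construct fails are dropped), per-replicate
#' WT/mut ratios, a two-tailed paired t-test of WT vs mutant within
#' each condition (on log2-transformed values by default, since ratios
#' are multiplicative), and two-tailed Welch t-tests of the WT/mut
#' ratios between all condition pairs. Significance is assessed at
#' alpha = 0.05.
#'
#' @param data `data.frame` with columns `construct` (`"WT"`/`"mut"`),
#'   `condition`, `bio_rep`, `tech_rep`, `renilla`, `firefly`.
#' @param cvThreshold technical-replicate CV cutoff (default 0.5).
#' @param logRatios analyze log2 ratios (default `TRUE`); `FALSE` uses
#'   the raw scale.
#' @param wtLabel,mutLabel construct labels (defaults `"WT"`, `"mut"`).
#' @return Object of class `ReporterResult`: list with `ratios`
#'   (per condition x biological replicate), `per_condition`
#'   (n, mean ratio, paired p, degeneracy flag, significance),
#'   `between` (condition pairs with Welch p), `omitted`
#'   (CV-filtered measurements), `alpha`.
#' @export
reporterTests <- function(data, cvThreshold = 0.5, logRatios = TRUE,
                          wtLabel = "WT", mutLabel = "mut") {
  need <- c("construct", "condition", "bio_rep", "tech_rep",
            "renilla", "firefly")
  if (!all(need %in% names(data)))
    stop("reporter data must have columns: ", paste(need, collapse = ", "))
  if (any(data$renilla <= 0) || any(data$firefly <= 0))
    stop("luminescence values must be positive")
  data$value <- data$renilla / data$firefly
  key <- interaction(data$condition, data$bio_rep, data$construct,
                     drop = TRUE)
  groups <- split(data, key)
  meta <- do.call(rbind, lapply(groups, function(g) {
    f <- cvFilter(g$value, cvThreshold)
    data.frame(condition = g$condition[1L], bio_rep = g$bio_rep[1L],
               construct = g$construct[1L], mean_value = mean(g$value),
               cv = f$cv, keep = f$keep, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  omitted <- meta[!meta$keep, c("condition", "bio_rep", "construct", "cv")]
  ## a biological replicate survives only if both constructs pass
  keepRep <- stats::aggregate(keep ~ condition + bio_rep, meta, all)
  meta <- merge(meta[, setdiff(names(meta), "keep")], keepRep,
                by = c("condition", "bio_rep"))
  meta <- meta[meta$keep, , drop = FALSE]
  wt <- meta[meta$construct == wtLabel, ]
  mut <- meta[meta$construct == mutLabel, ]
  pr <- merge(wt[, c("condition", "bio_rep", "mean_value")],
              mut[, c("condition", "bio_rep", "mean_value")],
              by = c("condition", "bio_rep"),
              suffixes = c("_wt", "_mut"))
  if (nrow(pr) < nrow(wt) || nrow(pr) < nrow(mut))
    stop("unpaired biological replicates between constructs")
  pr$ratio <- pr$mean_value_wt / pr$mean_value_mut
  perCond <- do.call(rbind, lapply(split(pr, pr$condition), function(g) {
    if (nrow(g) < 3L)
      stop("condition '", g$condition[1L],
           "' has fewer than 3 biological replicates")
    d <- if (logRatios) log2(g$mean_value_wt) - log2(g$mean_value_mut)
         else g$mean_value_wt - g$mean_value_mut
    pt_ <- .pairedP(d)
    data.frame(condition = g$condition[1L], n = nrow(g),
               mean_ratio = mean(g$ratio), paired_p = pt_$p,
               degenerate = pt_$degenerate,
               significant = pt_$p < 0.05, stringsAsFactors = FALSE)
  }))
  rownames(perCond) <- NULL
  conds <- unique(pr$condition)
  between <- NULL
  if (length(conds) > 1L) {
    cmb <- utils::combn(conds, 2L)
    between <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      ra <- pr$ratio[pr$condition == cmb[1L, j]]
      rb <- pr$ratio[pr$condition == cmb[2L, j]]
      if (logRatios) { ra <- log2(ra); rb <- log2(rb) }
      p <- tryCatch(t.test(ra, rb, var.equal = FALSE)$p.value,
                    error = function(e) 1)
      data.frame(condition_a = cmb[1L, j], condition_b = cmb[2L, j],
                 welch_p = p, significant = p < 0.05,
                 stringsAsFactors = FALSE)
    }))
    rownames(between) <- NULL
  }
  out <- list(ratios = pr[, c("condition", "bio_rep", "ratio")],
              per_condition = perCond, between = between,
              omitted = omitted, alpha = 0.05,
              log_ratios = logRatios)
  class(out) <- "ReporterResult"
  out
}

#' @export
print.ReporterResult <- function(x, ...) {
  cat("Reporter assay (", if (x$log_ratios) "log2" else "raw",
      " scale, alpha = ", x$alpha, ")\n", sep = "")
  print(x$per_condition, row.names = FALSE)
  if (!is.null(x$between)) {
    cat("Between conditions (Welch t on WT/mut ratios):\n")
    print(x$between, row.names = FALSE)
  }
  if (nrow(x$omitted))
    cat(nrow(x$omitted), "measurement(s) omitted by the CV filter\n")
  invisible(x)
}
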