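## Site- and transcript-level co-occupancy statistics: overlap counting,
## within-UTR randomization nulls with z-scores, and positional density
## profiles with permutation envelopes.

#' Overlapping site pairs between two binding-site sets
#'
#' Two sites overlap when they lie on the same host feature and share at
#' least one nucleotide (half-open interval arithmetic: abutting sites
#' do not overlap).
#'
#' @param a,b [BindingSiteSet] objects validated on a shared feature
#'   universe.
#' @return List with elements `pairs` (data.frame of `site_a`,
#'   `site_b` ids), `n_a_overlapping` and `n_b_overlapping` (numbers of
#'   distinct sites in each set having at least one partner).
#' @export
overlapSites <- function(a, b) {
  fo <- GenomicRanges::findOverlaps(siteRanges(a), siteRanges(b),
                                    minoverlap = 1L)
  qh <- S4Vectors::queryHits(fo)
  sh <- S4Vectors::subjectHits(fo)
  list(
    pairs = data.frame(site_a = siteIds(a)[qh],
                       site_b = siteIds(b)[sh],
                       stringsAsFactors = FALSE),
    n_a_overlapping = length(unique(qh)),
    n_b_overlapping = length(unique(sh))
  )
}

#' Transcript-level co-occupancy classes and Venn counts
#'
#' Computes, for every feature in the universe, which proteins have at
#' least one binding site on it, and the counts of all Venn regions
#' (which sum to the universe size).
#'
#' @param siteSets named list of [BindingSiteSet] objects, one per
#'   protein.
#' @param universe [HostFeatureSet] containing every referenced
#'   feature.
#' @return Object of class `CooccupancyClasses`: a list with
#'   `membership` (logical feature x protein matrix), `venn` (named
#'   counts of exclusive combinations, `"none"` for unbound features)
#'   and `universe_size`.
#' @export
utrCooccupancy <- function(siteSets, universe) {
  if (is.null(names(siteSets)) || !all(nzchar(names(siteSets))))
    stop("siteSets must be a named list (one name per protein)")
  uids <- featureIds(universe)
  membership <- sapply(siteSets, function(s) {
    outside <- setdiff(featureIds(s), uids)
    if (length(outside))
      stop("site(s) on features outside the universe: ",
           paste(utils::head(outside, 3L), collapse = ", "))
    uids %in% featureIds(s)
  })
  membership <- matrix(membership, nrow = length(uids),
                       dimnames = list(uids, names(siteSets)))
  combo <- apply(membership, 1L, function(row) {
    if (!any(row)) "none" else paste(names(siteSets)[row], collapse = "+")
  })
  venn <- table(combo)
  out <- list(membership = membership,
              venn = stats::setNames(as.integer(venn), names(venn)),
              universe_size = length(uids))
  class(out) <- "CooccupancyClasses"
  out
}

#' @export
print.CooccupancyClasses <- function(x, ...) {
  cat("Co-occupancy over", x$universe_size, "features\n")
  print(x$venn)
  invisible(x)
}

## Reposition GRanges uniformly within their hosts, widths preserved.
.randomizeGr <- function(gr) {
  L <- GenomeInfoDb::seqlengths(gr)[as.character(GenomicRanges::seqnames(gr))]
  w <- GenomicRanges::width(gr)
  if (any(w > L)) {
    off <- which(w > L)[1L]
    stop("site ", S4Vectors::mcols(gr)$site_id[off],
         " is wider than its host feature")
  }
  newStart0 <- .runifInt0(L - w + 1)
  GenomicRanges::ranges(gr) <- IRanges::IRanges(start = newStart0 + 1L,
                                                width = w)
  gr
}

#' Randomize site positions within their host features
#'
#' Each site is independently repositioned uniformly among all
#' `length - width + 1` valid starts on its own host feature; widths
#' and counts are preserved. Randomized sites may overlap each other
#' (no rejection sampling), keeping the null unbiased on short UTRs.
#'
#' @param x a [BindingSiteSet].
#' @param seed optional integer seed; the same seed reproduces the same
#'   placement. `NULL` draws from the ambient RNG stream.
#' @return A [BindingSiteSet] with randomized positions.
#' @export
randomizeWithinHost <- function(x, seed = NULL) {
  withSeed(seed, {
    new("BindingSiteSet", sites = .randomizeGr(siteRanges(x)),
        counts = siteCounts(x))
  })
}

#' Overlap z-score against a within-UTR randomization null
#'
#' Counts the sites of one set that overlap the other, then estimates
#' the background expectation by repeating the count in `n` control
#' experiments in which the positions of the chosen set are randomized
#' within their host UTRs. The z-score is
#' `(observed - null mean) / null SD`; it is flagged undefined when the
#' null SD is zero (e.g. a saturated null).
#'
#' @param a,b [BindingSiteSet] objects on a shared feature universe.
#' @param which which set is randomized for the null (and counted):
#'   `"a"` (default) or `"b"`.
#' @param n number of randomizations (>= 2); 100 by default.
#' @param seed optional integer seed for reproducible nulls.
#' @return Object of class `OverlapNull`: list with `observed`,
#'   `null_mean`, `null_sd`, `z` (`NA` when undefined), `z_defined`,
#'   `n_randomizations`, `which`.
#' @export
overlapZscore <- function(a, b, which = c("a", "b"), n = 100L,
                          seed = NULL) {
  which <- match.arg(which)
  if (n < 2) stop("n must be >= 2")
  if (!nSites(a) || !nSites(b)) stop("empty site set")
  ov <- overlapSites(a, b)
  observed <- if (which == "a") ov$n_a_overlapping else ov$n_b_overlapping
  ## permutation null in direct interval arithmetic (this loop is the
  ## hot path): each moving site is redrawn uniformly on its host and
  ## tested against the fixed set's intervals on the same feature
  moving <- if (which == "a") a else b
  fixed <- if (which == "b") a else b
  mFeat <- featureIds(moving)
  mW <- siteWidths(moving)
  mL <- GenomeInfoDb::seqlengths(siteRanges(moving))[mFeat]
  if (any(mW > mL)) stop("site wider than its host feature")
  k <- mL - mW + 1L
  fS <- split(siteStarts(fixed), featureIds(fixed))
  fE <- split(siteEnds(fixed), featureIds(fixed))
  perS <- fS[mFeat]
  perE <- fE[mFeat]
  m <- nSites(moving)
  nulls <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      s0 <- .runifInt0(k)
      sum(vapply(seq_len(m), function(j) {
        S <- perS[[j]]
        length(S) > 0L && any(s0[j] < perE[[j]] & s0[j] + mW[j] > S)
      }, logical(1L)))
    }, numeric(1L))
  })
  nm <- mean(nulls)
  ns <- sd(nulls)
  out <- list(
    observed = observed,
    null_mean = nm,
    null_sd = ns,
    z = if (ns > 0) (observed - nm) / ns else NA_real_,
    z_defined = ns > 0,
    n_randomizations = as.integer(n),
    which = which
  )
  class(out) <- "OverlapNull"
  out
}

#' @export
print.OverlapNull <- function(x, ...) {
  cat(sprintf(
    "Overlap: observed %d, null %.2f +/- %.2f (%d randomizations of set %s)\n",
    x$observed, x$null_mean, x$null_sd, x$n_randomizations, x$which))
  if (x$z_defined) cat(sprintf("  z = %.2f\n", x$z))
  else cat("  z undefined (null SD = 0)\n")
  invisible(x)
}

## 0-based centers; for even widths the center rounds half-down.
.centers0 <- function(gr) {
  (GenomicRanges::start(gr) - 1L) + (GenomicRanges::width(gr) - 1L) %/% 2L
}

## Coerce a query (BindingSiteSet or hit table) to GRanges on the
## reference's seqinfo; hit tables get `width` nt intervals (default 8).
.asQueryGr <- function(query, si, defaultWidth = 8L) {
  if (is(query, "BindingSiteSet")) return(siteRanges(query))
  query <- as.data.frame(query)
  if (!all(c("feature_id", "position") %in% names(query)))
    stop("query table must have columns feature_id and position")
  unknown <- setdiff(query$feature_id, GenomeInfoDb::seqlevels(si))
  if (length(unknown))
    stop("query features absent from reference universe: ",
         paste(utils::head(unique(unknown), 3L), collapse = ", "))
  w <- if ("width" %in% names(query)) query$width else defaultWidth
  gr <- GenomicRanges::GRanges(
    seqnames = factor(query$feature_id,
                      levels = GenomeInfoDb::seqlevels(si)),
    ranges = IRanges::IRanges(start = query$position + 1L, width = w),
    seqinfo = si
  )
  S4Vectors::mcols(gr)$site_id <- sprintf("q%06d", seq_along(gr))
  gr
}

## Signed center-to-center offsets of queries around references,
## restricted to [-window, window), tabulated into `nbins` bins.
.binOffsets <- function(refCenters, refFeat, qCenters, qFeat, window, bin) {
  nbins <- as.integer(2L * window / bin)
  counts <- integer(nbins)
  for (f in intersect(unique(refFeat), unique(qFeat))) {
    rc <- refCenters[refFeat == f]
    qc <- qCenters[qFeat == f]
    off <- as.vector(outer(qc, rc, "-"))
    off <- off[off >= -window & off < window]
    if (length(off)) {
      idx <- (off + window) %/% bin + 1L
      counts <- counts + tabulate(idx, nbins)
    }
  }
  counts
}

#' Positional density of query elements around reference sites
#'
#' For every reference site, signed center-to-center offsets of query
#' elements on the same feature are collected (positive = query is 3'
#' of the reference; centers round half-down for even widths), binned,
#' and divided by the number of reference sites. A null envelope (mean
#' +/- 1 SD per bin) is computed from `n` control experiments in which
#' the query elements are randomized within their host UTRs.
#'
#' @param reference a non-empty [BindingSiteSet] of anchor sites.
#' @param query a [BindingSiteSet], or a hit table with columns
#'   `feature_id`, `position` (0-based) and optionally `width`
#'   (default 8 nt) as returned by the scanners.
#' @param window half-width of the profile in nt (must be a multiple of
#'   `bin`); offsets in `[-window, window)` are kept.
#' @param bin bin width in nt.
#' @param n number of randomizations for the envelope.
#' @param seed optional integer seed.
#' @return Object of class `DensityProfile`: list with `offset` (bin
#'   centers), `observed`, `null_mean`, `null_sd` (densities per
#'   reference site), plus `n_randomizations`, `n_reference`, `window`,
#'   `bin`. `as.data.frame()` gives a plotting-ready table.
#' @export
densityProfile <- function(reference, query, window = 500L, bin = 10L,
                           n = 100L, seed = NULL) {
  if (!nSites(reference)) stop("no reference sites")
  if (window <= 0 || bin <= 0 || window %% bin != 0)
    stop("window must be a positive multiple of bin")
  refGr <- siteRanges(reference)
  qGr <- .asQueryGr(query, GenomeInfoDb::seqinfo(refGr))
  nRef <- length(refGr)
  rc <- .centers0(refGr)
  rf <- as.character(GenomicRanges::seqnames(refGr))
  qc <- .centers0(qGr)
  qf <- as.character(GenomicRanges::seqnames(qGr))
  obs <- .binOffsets(rc, rf, qc, qf, window, bin) / nRef
  nullMat <- withSeed(seed, {
    vapply(seq_len(n), function(i) {
      rgr <- .randomizeGr(qGr)
      .binOffsets(rc, rf, .centers0(rgr),
                  as.character(GenomicRanges::seqnames(rgr)),
                  window, bin) / nRef
    }, numeric(length(obs)))
  })
  nullMat <- matrix(nullMat, nrow = length(obs))
  edges <- seq(-window, window - bin, by = bin)
  out <- list(
    offset = edges + bin / 2,
    observed = obs,
    null_mean = rowMeans(nullMat),
    null_sd = apply(nullMat, 1L, sd),
    n_randomizations = as.integer(n),
    n_reference = nRef,
    window = as.integer(window),
    bin = as.integer(bin)
  )
  class(out) <- "DensityProfile"
  out
}

#' @export
as.data.frame.DensityProfile <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(offset = x$offset, observed = x$observed,
             null_mean = x$null_mean, null_sd = x$null_sd)
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf(
    "DensityProfile: %d bins of %d nt over +/-%d nt around %d reference sites\n",
    length(x$offset), x$bin, x$window, x$n_reference))
  pk <- which.max(x$observed)
  cat(sprintf("  peak at offset %+g (density %.3f; null %.3f +/- %.3f)\n",
              x$offset[pk], x$observed[pk], x$null_mean[pk], x$null_sd[pk]))
  invisible(x)
}

#' Label sites of one set by overlap with another
#'
#' Exhaustive, exclusive partition of the sites of `a` into those that
#' overlap at least one site of `b` (>= 1 shared nt on the same
#' feature) and those that do not.
#'
#' @param a,b [BindingSiteSet] objects.
#' @return Factor with levels `"overlapping"`, `"non_overlapping"`,
#'   named by the site ids of `a`.
#' @export
stratifySitesByOverlap <- function(a, b) {
  fo <- GenomicRanges::findOverlaps(siteRanges(a), siteRanges(b),
                                    minoverlap = 1L)
  lab <- rep("non_overlapping", nSites(a))
  lab[unique(S4Vectors::queryHits(fo))] <- "overlapping"
  factor(stats::setNames(lab, siteIds(a)),
         levels = c("overlapping", "non_overlapping"))
}
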