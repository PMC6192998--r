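## Pumilio motif scanning and miRNA seed-complement site typing.
##
## The Pumilio recognition element is the 8-mer 5'-UGUAnAUA (position 5
## is unconstrained). Degenerate variants relax one additional position
## in the 3' half: UGUAnnUA, UGUAnAnA, UGUAnAUn. Scanning is
## sense-strand only on the mature mRNA.

.PUM_CLASSES <- c("PERFECT", "UGUAnnUA", "UGUAnAnA", "UGUAnAUn")

## Classify every 8-mer window of one RNA-alphabet sequence.
## Returns integer positions (0-based) and class labels.
.scanPumOne <- function(seq, allowDegenerate) {
  L <- nchar(seq)
  if (L < 8L)
    return(data.frame(position = integer(), motif_class = character(),
                      stringsAsFactors = FALSE))
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- L - 7L
  idx <- seq_len(n)
  c1 <- ch[idx];      c2 <- ch[idx + 1L]; c3 <- ch[idx + 2L]
  c4 <- ch[idx + 3L]; c5 <- ch[idx + 4L]; c6 <- ch[idx + 5L]
  c7 <- ch[idx + 6L]; c8 <- ch[idx + 7L]
  hasN <- c1 == "N" | c2 == "N" | c3 == "N" | c4 == "N" |
          c5 == "N" | c6 == "N" | c7 == "N" | c8 == "N"
  prefix <- c1 == "U" & c2 == "G" & c3 == "U" & c4 == "A" & !hasN
  perfect <- prefix & c6 == "A" & c7 == "U" & c8 == "A"
  cls <- rep(NA_character_, n)
  cls[perfect] <- "PERFECT"
  if (allowDegenerate) {
    rest <- prefix & !perfect
    d1 <- rest & c7 == "U" & c8 == "A"            # UGUAnnUA
    d2 <- rest & !d1 & c6 == "A" & c8 == "A"      # UGUAnAnA
    d3 <- rest & !d1 & !d2 & c6 == "A" & c7 == "U" # UGUAnAUn
    cls[d1] <- "UGUAnnUA"
    cls[d2] <- "UGUAnAnA"
    cls[d3] <- "UGUAnAUn"
  }
  hit <- !is.na(cls)
  data.frame(position = idx[hit] - 1L, motif_class = cls[hit],
             stringsAsFactors = FALSE)
}

#' Scan host-feature sequences for Pumilio recognition elements
#'
#' Tests every 8-nt window of each feature sequence against the
#' consensus `UGUAnAUA` (`PERFECT`; `n` = any of A/C/G/U). With
#' `allowDegenerate = TRUE`, windows that are not perfect are also
#' tested against the relaxed classes `UGUAnnUA`, `UGUAnAnA` and
#' `UGUAnAUn`; a window is reported with at most one class, with
#' precedence `UGUAnnUA` > `UGUAnAnA` > `UGUAnAUn` (the first subsumes
#' the other two). Windows containing `N` are skipped. Overlapping hits
#' are all reported.
#'
#' @param features a [HostFeatureSet]; every feature must carry a
#'   sequence.
#' @param allowDegenerate also report the degenerate motif classes.
#' @return `data.frame` with columns `feature_id`, `position` (0-based
#'   start of the 8-mer) and `motif_class`.
#' @examples
#' hf <- HostFeatureSet("u1", 12L, sequences = c(u1 = "UGUAUGUAAAUA"))
#' scanPumMotifs(hf, allowDegenerate = TRUE)
#' @export
scanPumMotifs <- function(features, allowDegenerate = FALSE) {
  seqs <- featureSequences(features)
  ids <- featureIds(features)
  missing <- setdiff(ids, names(seqs))
  if (is.null(seqs) || length(missing))
    stop("missing sequence for feature(s): ",
         paste(utils::head(if (is.null(seqs)) ids else missing, 3L),
               collapse = ", "))
  res <- lapply(ids, function(id) {
    hits <- .scanPumOne(.asRnaChar(as.character(seqs[[id]])),
                        allowDegenerate)
    if (nrow(hits)) cbind(feature_id = id, hits, stringsAsFactors = FALSE)
    else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(feature_id = character(), position = integer(),
                      motif_class = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Derive canonical target-site patterns from a miRNA sequence
#'
#' Builds the reverse-complement patterns that define canonical miRNA
#' target sites in an mRNA: `7mer-m8` is the reverse complement of
#' miRNA nucleotides 2-8; `7mer-A1` is the reverse complement of
#' nucleotides 2-7 followed by an `A`; `8mer` is the `7mer-m8` pattern
#' followed by an `A`.
#'
#' @param mirnaSequence miRNA sequence (RNA or DNA alphabet),
#'   length >= 8.
#' @return Named character vector (RNA alphabet) with elements
#'   `"8mer"`, `"7mer-m8"`, `"7mer-A1"`.
#' @examples
#' seedPatterns("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a
#' @export
seedPatterns <- function(mirnaSequence) {
  s <- .asRnaChar(mirnaSequence)
  if (nchar(s) < 8L)
    stop("miRNA sequence must be at least 8 nt (got ", nchar(s), ")")
  m8 <- .revCompRna(substr(s, 2L, 8L))
  a1 <- paste0(.revCompRna(substr(s, 2L, 7L)), "A")
  c("8mer" = paste0(m8, "A"), "7mer-m8" = m8, "7mer-A1" = a1)
}

## Overlapping occurrences of a literal pattern; 0-based starts.
.findAll0 <- function(pattern, seq) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits) - 1L
}

#' Scan host features for miRNA seed-complement sites
#'
#' Finds canonical seed-complement matches for each miRNA family and
#' types them by the longest-matching site class with precedence
#' `8mer` > `7mer-m8` > `7mer-A1`: a 7mer call contained in an 8mer
#' match at the same locus is suppressed, so each (family, locus)
#' yields one match. Families are deduplicated by seed (miRNA nt 2-8).
#'
#' @param features a [HostFeatureSet] with sequences.
#' @param mirnas character vector of miRNA sequences, optionally named
#'   (names become family labels; unnamed families are labelled by
#'   their seed).
#' @return `data.frame` with columns `feature_id`, `position` (0-based
#'   match start), `mirna_family`, `site_type` and `width` (7 or 8 nt).
#' @export
scanSeedComplements <- function(features, mirnas) {
  seqs <- featureSequences(features)
  ids <- featureIds(features)
  missing <- setdiff(ids, names(seqs))
  if (is.null(seqs) || length(missing))
    stop("missing sequence for feature(s): ",
         paste(utils::head(if (is.null(seqs)) ids else missing, 3L),
               collapse = ", "))
  empty <- data.frame(feature_id = character(), position = integer(),
                      mirna_family = character(), site_type = character(),
                      width = integer(), stringsAsFactors = FALSE)
  if (!length(mirnas)) return(empty)
  mirnas <- .asRnaChar(mirnas)
  seeds <- substr(mirnas, 2L, 8L)
  fam <- if (!is.null(names(mirnas)) && all(nzchar(names(mirnas))))
    names(mirnas) else seeds
  keep <- !duplicated(seeds)
  mirnas <- mirnas[keep]; fam <- fam[keep]
  out <- list()
  for (id in ids) {
    seq <- .asRnaChar(as.character(seqs[[id]]))
    for (k in seq_along(mirnas)) {
      pat <- seedPatterns(mirnas[k])
      p8 <- .findAll0(pat[["8mer"]], seq)
      pm8 <- setdiff(.findAll0(pat[["7mer-m8"]], seq), p8)
      pa1 <- setdiff(.findAll0(pat[["7mer-A1"]], seq), p8 + 1L)
      n8 <- length(p8); nm8 <- length(pm8); na1 <- length(pa1)
      if (n8 + nm8 + na1 == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        feature_id = id,
        position = c(p8, pm8, pa1),
        mirna_family = fam[k],
        site_type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                        c(n8, nm8, na1)),
        width = rep(c(8L, 7L, 7L), c(n8, nm8, na1)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$feature_id, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tally motif or seed hits within (windowed) binding sites
#'
#' Counts hits whose start position lies within
#' `[site start - window, site end + window)` of each site.
#'
#' @param sites a [BindingSiteSet].
#' @param hits `data.frame` with columns `feature_id` and `position`
#'   (0-based), e.g. from [scanPumMotifs()] or [scanSeedComplements()].
#' @param window non-negative flank in nt added on both sides.
#' @param by optional name of a column of `hits` (e.g.
#'   `"mirna_family"`); when given, returns a site x level count matrix
#'   instead of a vector.
#' @return Named integer vector of per-site counts, or a matrix when
#'   `by` is given.
#' @export
motifTallyPerSite <- function(sites, hits, window = 0L, by = NULL) {
  if (window < 0) stop("window must be >= 0")
  ids <- siteIds(sites)
  lo <- siteStarts(sites) - window
  hi <- siteEnds(sites) + window
  feat <- featureIds(sites)
  if (!is.null(by)) {
    levs <- sort(unique(hits[[by]]))
    m <- matrix(0L, nrow = length(ids), ncol = length(levs),
                dimnames = list(ids, levs))
    for (i in seq_along(ids)) {
      sel <- hits$feature_id == feat[i] &
        hits$position >= lo[i] & hits$position < hi[i]
      if (any(sel)) {
        tab <- table(hits[[by]][sel])
        m[i, names(tab)] <- as.integer(tab)
      }
    }
    return(m)
  }
  out <- integer(length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    out[i] <- sum(hits$feature_id == feat[i] &
                    hits$position >= lo[i] & hits$position < hi[i])
  }
  out
}
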