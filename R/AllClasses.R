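#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' Host features: the regions within which binding sites live
#'
#' A `HostFeatureSet` holds transcript-relative regions (3'UTRs by default)
#' together with optional sequences and per-transcript mRNA log2 fold
#' changes measured under perturbation conditions. All binding-site
#' coordinates in the package are relative to these features, 0-based and
#' half-open, 5'->3' on the mature mRNA.
#'
#' @slot features `data.frame` with columns `feature_id` (unique),
#'   `length` (nt, >= 1) and `category` (one of `"UTR3"`, `"UTR5"`,
#'   `"CDS"`, `"ncRNA"`).
#' @slot sequences optional [Biostrings::DNAStringSet] named by feature id;
#'   widths must equal the declared lengths. Stored in the DNA alphabet;
#'   `T`/`U` are interchangeable on input.
#' @slot mrnaLfc `data.frame` with columns `feature_id`, `condition`,
#'   `lfc` (log2 units): transcript-level mRNA changes used to normalize
#'   CLIP signal changes.
#'
#' @seealso [HostFeatureSet()], [readHostFeatures()], [BindingSiteSet]
#' @aliases HostFeatureSet-class
#' @exportClass HostFeatureSet
setClass("HostFeatureSet",
  slots = c(
    features  = "data.frame",
    sequences = "DNAStringSetOrNULL",
    mrnaLfc   = "data.frame"
  )
)

.FEATURE_CATEGORIES <- c("UTR3", "UTR5", "CDS", "ncRNA")

setValidity("HostFeatureSet", function(object) {
  f <- object@features
  msgs <- character()
  need <- c("feature_id", "length", "category")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(f$feature_id))
    msgs <- c(msgs, "duplicated feature_id values")
  if (nrow(f) > 0 && (!is.numeric(f$length) || any(f$length < 1) ||
                      any(f$length != floor(f$length))))
    msgs <- c(msgs, "length must be integer >= 1")
  if (!all(f$category %in% .FEATURE_CATEGORIES))
    msgs <- c(msgs, paste("category must be one of",
                          paste(.FEATURE_CATEGORIES, collapse = "/")))
  s <- object@sequences
  if (!is.null(s)) {
    if (is.null(names(s)) || !all(names(s) %in% f$feature_id))
      msgs <- c(msgs, "sequence names must be feature ids")
    idx <- match(names(s), f$feature_id)
    if (length(s) && any(Biostrings::width(s) != f$length[idx]))
      msgs <- c(msgs, "sequence widths must equal declared feature lengths")
  }
  m <- object@mrnaLfc
  if (!all(c("feature_id", "condition", "lfc") %in% names(m)))
    msgs <- c(msgs, "mrnaLfc must have columns feature_id, condition, lfc")
  else if (nrow(m) > 0 && any(!is.finite(m$lfc)))
    msgs <- c(msgs, "mrnaLfc values must be finite")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a HostFeatureSet
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param length integer vector of feature lengths in nucleotides.
#' @param category feature annotation category, recycled; one of
#'   `"UTR3"` (default), `"UTR5"`, `"CDS"`, `"ncRNA"`.
#' @param sequences optional named character vector or
#'   [Biostrings::DNAStringSet] of feature sequences (`T`/`U`
#'   interchangeable; upper-cased on ingest).
#' @param mrnaLfc optional `data.frame` with columns `feature_id`,
#'   `condition`, `lfc` (log2 mRNA fold change per condition).
#' @return A [HostFeatureSet] object.
#' @examples
#' hf <- HostFeatureSet(c("utrA", "utrB"), c(300L, 500L))
#' hf
#' @export
HostFeatureSet <- function(feature_id = character(), length = integer(),
                           category = "UTR3", sequences = NULL,
                           mrnaLfc = NULL) {
  feature_id <- as.character(feature_id)
  f <- data.frame(
    feature_id = feature_id,
    length = as.integer(length),
    category = rep_len(as.character(category), length(feature_id)),
    stringsAsFactors = FALSE
  )
  if (!is.null(sequences)) {
    if (is.character(sequences)) {
      .checkAlphabet(sequences)
      sequences <- Biostrings::DNAStringSet(.asDnaChar(sequences))
    }
    if (is.null(names(sequences)) && length(sequences) == nrow(f))
      names(sequences) <- f$feature_id
  }
  if (is.null(mrnaLfc))
    mrnaLfc <- data.frame(feature_id = character(), condition = character(),
                          lfc = numeric(), stringsAsFactors = FALSE)
  new("HostFeatureSet", features = f, sequences = sequences,
      mrnaLfc = mrnaLfc)
}

#' Binding sites of one or more proteins on host features
#'
#' A `BindingSiteSet` stores CLIP peaks as a [GenomicRanges::GRanges]
#' whose seqnames are host-feature ids (with seqlengths set to the host
#' lengths), plus a per-site count matrix of PCR-collapsed read counts,
#' one column per sample. User-facing coordinates are 0-based, half-open;
#' use [siteStarts()] / [siteEnds()] rather than touching the ranges.
#'
#' @slot sites [GenomicRanges::GRanges] with metadata columns `site_id`
#'   (unique) and `protein`.
#' @slot counts numeric matrix, one row per site (possibly 0 columns),
#'   non-negative integers.
#'
#' @seealso [BindingSiteSet()], [readSites()], [overlapSites()]
#' @aliases BindingSiteSet-class
#' @exportClass BindingSiteSet
setClass("BindingSiteSet",
  slots = c(sites = "GRanges", counts = "matrix")
)

setValidity("BindingSiteSet", function(object) {
  gr <- object@sites
  msgs <- character()
  mc <- S4Vectors::mcols(gr)
  if (!all(c("site_id", "protein") %in% names(mc)))
    return("sites must carry metadata columns site_id and protein")
  if (anyDuplicated(mc$site_id))
    msgs <- c(msgs, "duplicated site_id values")
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(is.na(sl)))
    msgs <- c(msgs, "all host features must have known lengths")
  if (length(gr)) {
    hostLen <- sl[as.character(GenomicRanges::seqnames(gr))]
    if (any(GenomicRanges::end(gr) > hostLen))
      msgs <- c(msgs, "site end exceeds host feature length")
    if (any(GenomicRanges::start(gr) < 1))
      msgs <- c(msgs, "site start below 0")
    if (any(GenomicRanges::width(gr) < 1))
      msgs <- c(msgs, "site width must be >= 1")
  }
  cts <- object@counts
  if (nrow(cts) != length(gr))
    msgs <- c(msgs, "counts must have one row per site")
  if (length(cts) && (any(!is.finite(cts)) || any(cts < 0) ||
                      any(cts != floor(cts))))
    msgs <- c(msgs, "counts must be non-negative integers")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a BindingSiteSet
#'
#' Coordinates are transcript-relative, 0-based and half-open
#' (`start` inclusive, `end` exclusive), matching BED conventions.
#'
#' @param feature_id host feature id per site.
#' @param start,end integer site coordinates (0-based half-open).
#' @param protein protein label per site (recycled), e.g. `"AGO2"`.
#' @param site_id unique site identifiers; autogenerated when `NULL`.
#' @param counts optional matrix/data.frame of per-sample collapsed read
#'   counts, one row per site, columns named by sample.
#' @param features the [HostFeatureSet] the sites live on (supplies host
#'   lengths for validation).
#' @return A [BindingSiteSet].
#' @examples
#' hf <- HostFeatureSet("utrA", 300L)
#' bs <- BindingSiteSet("utrA", 10, 30, protein = "AGO2", features = hf)
#' siteWidths(bs)
#' @export
BindingSiteSet <- function(feature_id = character(), start = integer(),
                           end = integer(), protein = character(),
                           site_id = NULL, counts = NULL, features) {
  if (!is(features, "HostFeatureSet"))
    stop("'features' must be a HostFeatureSet")
  feature_id <- as.character(feature_id)
  unknown <- setdiff(feature_id, featureIds(features))
  if (length(unknown))
    stop("unknown feature id(s): ", paste(unique(unknown), collapse = ", "))
  n <- length(feature_id)
  if (is.null(site_id)) {
    site_id <- if (n) sprintf("site%05d", seq_len(n)) else character()
  }
  protein <- rep_len(as.character(protein), n)
  if (any(end <= start))
    stop("all sites must satisfy start < end")
  si <- .hostSeqinfo(features)
  ## GRanges itself warns on out-of-bound ranges; the validity method
  ## below turns them into a clearer error instead
  gr <- suppressWarnings(GenomicRanges::GRanges(
    seqnames = factor(feature_id, levels = GenomeInfoDb::seqlevels(si)),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqinfo = si
  ))
  S4Vectors::mcols(gr)$site_id <- as.character(site_id)
  S4Vectors::mcols(gr)$protein <- protein
  if (is.null(counts)) {
    counts <- matrix(numeric(), nrow = n, ncol = 0)
  } else {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
  }
  rownames(counts) <- as.character(site_id)
  new("BindingSiteSet", sites = gr, counts = counts)
}

.hostSeqinfo <- function(features) {
  f <- features@features
  GenomeInfoDb::Seqinfo(seqnames = f$feature_id,
                        seqlengths = f$length)
}
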