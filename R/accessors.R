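## Generics and accessor methods for the two container classes.

#' Accessors for HostFeatureSet
#'
#' @param x a [HostFeatureSet] (for `featureIds`, also a
#'   [BindingSiteSet], where it returns the host feature of each site).
#' @param condition optional condition label; when given, `mrnaLfc()`
#'   returns a named numeric vector of log2 mRNA fold changes for that
#'   condition, otherwise the full long-format table.
#' @param value for `mrnaLfc<-`, a `data.frame` with columns
#'   `feature_id` (or `transcript_id`), `condition`, `lfc` (or
#'   `log2fc`).
#' @return `featureIds`: character vector; `featureLengths`,
#'   `featureCategories`: named vectors; `featureSequences`: a
#'   [Biostrings::DNAStringSet] or `NULL`; `nFeatures`: integer.
#' @name HostFeatureSet-accessors
#' @examples
#' hf <- HostFeatureSet(c("utrA", "utrB"), c(300L, 500L))
#' featureLengths(hf)
NULL

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("featureCategories",
           function(x) standardGeneric("featureCategories"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("featureSequences",
           function(x) standardGeneric("featureSequences"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("mrnaLfc", function(x, condition = NULL) standardGeneric("mrnaLfc"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("mrnaLfc<-", function(x, value) standardGeneric("mrnaLfc<-"))

#' @rdname HostFeatureSet-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Accessors for BindingSiteSet
#'
#' Coordinates returned by `siteStarts()`/`siteEnds()` are 0-based
#' half-open, the package-wide convention.
#'
#' @param x a [BindingSiteSet]
#' @return `siteIds`, `proteins`: character vectors; `siteCounts`: the
#'   per-sample count matrix; `siteRanges`: the underlying
#'   [GenomicRanges::GRanges]; `siteStarts`, `siteEnds`, `siteWidths`:
#'   integer vectors; `nSites`: integer.
#' @name BindingSiteSet-accessors
NULL

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteCounts", function(x) standardGeneric("siteCounts"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteStarts", function(x) standardGeneric("siteStarts"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteEnds", function(x) standardGeneric("siteEnds"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("siteWidths", function(x) standardGeneric("siteWidths"))

#' @rdname BindingSiteSet-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

setMethod("featureIds", "HostFeatureSet",
          function(x) x@features$feature_id)

setMethod("featureLengths", "HostFeatureSet", function(x) {
  stats::setNames(x@features$length, x@features$feature_id)
})

setMethod("featureCategories", "HostFeatureSet", function(x) {
  stats::setNames(x@features$category, x@features$feature_id)
})

setMethod("featureSequences", "HostFeatureSet", function(x) x@sequences)

setMethod("mrnaLfc", "HostFeatureSet", function(x, condition = NULL) {
  if (is.null(condition)) return(x@mrnaLfc)
  m <- x@mrnaLfc[x@mrnaLfc$condition == condition, , drop = FALSE]
  stats::setNames(m$lfc, m$feature_id)
})

setReplaceMethod("mrnaLfc", "HostFeatureSet", function(x, value) {
  value <- as.data.frame(value)
  names(value)[names(value) == "transcript_id"] <- "feature_id"
  names(value)[names(value) == "log2fc"] <- "lfc"
  x@mrnaLfc <- value[, c("feature_id", "condition", "lfc")]
  validObject(x)
  x
})

setMethod("nFeatures", "HostFeatureSet", function(x) nrow(x@features))

setMethod("length", "HostFeatureSet", function(x) nrow(x@features))

setMethod("show", "HostFeatureSet", function(object) {
  cat("HostFeatureSet with", nrow(object@features), "features\n")
  if (nrow(object@features)) {
    cat("  categories:",
        paste(names(table(object@features$category)), collapse = ", "), "\n")
    cat("  length range:", min(object@features$length), "-",
        max(object@features$length), "nt\n")
  }
  cat("  sequences:",
      if (is.null(object@sequences)) "none"
      else paste0(length(object@sequences), " attached"), "\n")
  conds <- unique(object@mrnaLfc$condition)
  cat("  mRNA LFC conditions:",
      if (length(conds)) paste(conds, collapse = ", ") else "none", "\n")
})

setMethod("[", "HostFeatureSet", function(x, i, j, ..., drop = TRUE) {
  f <- x@features
  if (is.character(i)) i <- match(i, f$feature_id)
  f <- f[i, , drop = FALSE]
  s <- x@sequences
  if (!is.null(s)) s <- s[names(s) %in% f$feature_id]
  m <- x@mrnaLfc[x@mrnaLfc$feature_id %in% f$feature_id, , drop = FALSE]
  new("HostFeatureSet", features = f, sequences = s, mrnaLfc = m)
})

## ---- BindingSiteSet accessors ----

setMethod("siteIds", "BindingSiteSet",
          function(x) S4Vectors::mcols(x@sites)$site_id)

setMethod("proteins", "BindingSiteSet",
          function(x) S4Vectors::mcols(x@sites)$protein)

setMethod("siteCounts", "BindingSiteSet", function(x) x@counts)

setMethod("siteRanges", "BindingSiteSet", function(x) x@sites)

setMethod("featureIds", "BindingSiteSet",
          function(x) as.character(GenomicRanges::seqnames(x@sites)))

setMethod("siteStarts", "BindingSiteSet",
          function(x) GenomicRanges::start(x@sites) - 1L)

setMethod("siteEnds", "BindingSiteSet",
          function(x) GenomicRanges::end(x@sites))

setMethod("siteWidths", "BindingSiteSet",
          function(x) GenomicRanges::width(x@sites))

setMethod("nSites", "BindingSiteSet", function(x) length(x@sites))

setMethod("length", "BindingSiteSet", function(x) length(x@sites))

setMethod("show", "BindingSiteSet", function(object) {
  cat("BindingSiteSet with", length(object@sites), "sites on",
      length(unique(as.character(GenomicRanges::seqnames(object@sites)))),
      "features\n")
  if (length(object@sites))
    cat("  proteins:",
        paste(unique(S4Vectors::mcols(object@sites)$protein),
              collapse = ", "), "\n")
  cat("  count columns:", ncol(object@counts), "\n")
})

setMethod("[", "BindingSiteSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, siteIds(x))
  if (is.logical(i)) i <- which(i)
  new("BindingSiteSet", sites = x@sites[i],
      counts = x@counts[i, , drop = FALSE])
})

#' Convert a BindingSiteSet to a data.frame
#'
#' @param x a [BindingSiteSet]
#' @param row.names,optional,... ignored, present for generic
#'   consistency.
#' @return `data.frame` with columns `feature_id`, `start`, `end`
#'   (0-based half-open), `site_id`, `protein` and one column per count
#'   sample.
#' @export
as.data.frame.BindingSiteSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  df <- data.frame(
    feature_id = featureIds(x),
    start = siteStarts(x),
    end = siteEnds(x),
    site_id = siteIds(x),
    protein = proteins(x),
    stringsAsFactors = FALSE
  )
  if (ncol(x@counts)) df <- cbind(df, as.data.frame(x@counts))
  rownames(df) <- NULL
  df
}
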