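## Readers and writers for host features, binding sites, counts and
## mRNA log fold changes. Two tab-delimited dialects are supported:
## a header table (transcript-relative, lossless, carries counts) and
## headerless BED6. All files use 0-based half-open coordinates by
## default; set zeroBased = FALSE for 1-based inclusive input.

.readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

.splitFields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

.isHeaderTable <- function(firstLine) {
  grepl("feature_id", firstLine, fixed = TRUE)
}

.parseNum <- function(x, what, lineNo) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop("parse error at line ", lineNo[which(is.na(v))[1L]],
         ": non-numeric ", what)
  v
}

#' Read host features from a table or BED6 file
#'
#' Accepts either a header table with columns `feature_id`, `length`
#' and optionally `category`, or a headerless BED6 file
#' (`chrom start end name score strand`) from which the feature id is
#' taken from the `name` column and the length as `end - start`.
#' When a FASTA file is supplied its record ids must match feature ids
#' and record lengths must equal the declared lengths.
#'
#' @param path path to the feature table.
#' @param fastaPath optional FASTA file of feature sequences.
#' @return A [HostFeatureSet]; an empty input file yields an empty set.
#' @seealso [readSites()], [readMrnaLfc()]
#' @export
readHostFeatures <- function(path, fastaPath = NULL) {
  lines <- .readLinesChecked(path)
  if (!length(lines)) {
    hf <- HostFeatureSet()
  } else if (.isHeaderTable(lines[1L])) {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (!all(c("feature_id", "length") %in% hdr))
      stop("feature table header must contain feature_id and length")
    fields <- .splitFields(lines[-1L])
    if (!length(fields)) return(HostFeatureSet())
    lineNo <- seq_along(fields) + 1L
    bad <- lengths(fields) != length(hdr)
    if (any(bad))
      stop("parse error at line ", lineNo[which(bad)[1L]],
           ": expected ", length(hdr), " fields")
    m <- do.call(rbind, fields)
    colnames(m) <- hdr
    len <- .parseNum(m[, "length"], "length", lineNo)
    cat_ <- if ("category" %in% hdr) m[, "category"] else "UTR3"
    hf <- HostFeatureSet(m[, "feature_id"], len, category = cat_)
  } else {
    fields <- .splitFields(lines)
    lineNo <- seq_along(fields)
    bad <- lengths(fields) < 4L
    if (any(bad))
      stop("parse error at line ", lineNo[which(bad)[1L]],
           ": BED feature records need at least 4 fields")
    m <- do.call(rbind, lapply(fields, `[`, 1:4))
    start <- .parseNum(m[, 2L], "start", lineNo)
    end <- .parseNum(m[, 3L], "end", lineNo)
    hf <- HostFeatureSet(m[, 4L], end - start)
  }
  if (!is.null(fastaPath)) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    unknown <- setdiff(names(seqs), featureIds(hf))
    if (length(unknown))
      stop("FASTA records with unknown feature ids: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    idx <- match(names(seqs), featureIds(hf))
    declared <- featureLengths(hf)[idx]
    if (any(Biostrings::width(seqs) != declared)) {
      off <- which(Biostrings::width(seqs) != declared)[1L]
      stop("sequence length mismatch for ", names(seqs)[off], ": declared ",
           declared[off], " nt, FASTA has ", Biostrings::width(seqs)[off])
    }
    hf@sequences <- seqs
    validObject(hf)
  }
  hf
}

#' Read a transcript-level mRNA log fold change table
#'
#' Expects a tab-delimited file with header columns
#' `transcript_id` (or `feature_id`), `condition` and `log2fc`
#' (or `lfc`). Attach the result to a [HostFeatureSet] with
#' `mrnaLfc(features) <- readMrnaLfc(path)`.
#'
#' @param path path to the table.
#' @return `data.frame` with columns `feature_id`, `condition`, `lfc`.
#' @export
readMrnaLfc <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "transcript_id"] <- "feature_id"
  names(df)[names(df) == "log2fc"] <- "lfc"
  need <- c("feature_id", "condition", "lfc")
  if (!all(need %in% names(df)))
    stop("mRNA LFC table must have columns transcript_id, condition, log2fc")
  df$lfc <- as.numeric(df$lfc)
  if (any(!is.finite(df$lfc))) stop("non-finite mRNA LFC values")
  df[, need]
}

#' Read binding sites from a table or BED6 file
#'
#' The header-table dialect has columns `feature_id`, `start`, `end`,
#' `site_id`, `protein` followed by any number of per-sample count
#' columns. Headerless BED6 input (`chrom start end name score strand`)
#' takes the feature id from `chrom`, the site id from `name`, and
#' requires the `protein` argument.
#'
#' @param path path to the site table.
#' @param features the [HostFeatureSet] the coordinates refer to.
#' @param zeroBased logical; `TRUE` (default) for 0-based half-open
#'   coordinates, `FALSE` for 1-based inclusive.
#' @param protein protein label used for BED6 input (which carries none).
#' @return A [BindingSiteSet] with any count columns attached.
#' @export
readSites <- function(path, features, zeroBased = TRUE, protein = NULL) {
  lines <- .readLinesChecked(path)
  if (!length(lines))
    return(BindingSiteSet(features = features))
  counts <- NULL
  if (.isHeaderTable(lines[1L])) {
    hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("feature_id", "start", "end", "site_id", "protein")
    if (!all(need %in% hdr))
      stop("site table header must contain: ", paste(need, collapse = ", "))
    fields <- .splitFields(lines[-1L])
    if (!length(fields))
      return(BindingSiteSet(features = features))
    lineNo <- seq_along(fields) + 1L
    bad <- lengths(fields) != length(hdr)
    if (any(bad))
      stop("parse error at line ", lineNo[which(bad)[1L]],
           ": expected ", length(hdr), " fields")
    m <- do.call(rbind, fields)
    colnames(m) <- hdr
    start <- .parseNum(m[, "start"], "start", lineNo)
    end <- .parseNum(m[, "end"], "end", lineNo)
    featId <- m[, "feature_id"]
    siteId <- m[, "site_id"]
    prot <- m[, "protein"]
    sampleCols <- setdiff(hdr, need)
    if (length(sampleCols)) {
      counts <- sapply(sampleCols, function(cn)
        .parseNum(m[, cn], paste0("count '", cn, "'"), lineNo))
      counts <- matrix(counts, nrow = nrow(m),
                       dimnames = list(NULL, sampleCols))
    }
  } else {
    fields <- .splitFields(lines)
    lineNo <- seq_along(fields)
    bad <- lengths(fields) < 6L
    if (any(bad))
      stop("parse error at line ", lineNo[which(bad)[1L]],
           ": BED6 site records need 6 fields")
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start <- .parseNum(m[, 2L], "start", lineNo)
    end <- .parseNum(m[, 3L], "end", lineNo)
    featId <- m[, 1L]
    siteId <- m[, 4L]
    if (is.null(protein))
      stop("BED6 site input requires the 'protein' argument")
    prot <- protein
  }
  if (!zeroBased) start <- start - 1
  if (anyDuplicated(siteId))
    stop("duplicate site_id: ",
         siteId[duplicated(siteId)][1L])
  unknown <- setdiff(featId, featureIds(features))
  if (length(unknown))
    stop("unknown feature id(s) in site table: ",
         paste(utils::head(unique(unknown), 3L), collapse = ", "))
  hostLen <- featureLengths(features)[featId]
  if (any(end > hostLen)) {
    off <- which(end > hostLen)[1L]
    stop("site ", siteId[off], " extends past the end of ", featId[off],
         " (end ", end[off], " > length ", hostLen[off], ")")
  }
  if (any(start < 0)) stop("negative site start")
  BindingSiteSet(featId, start, end, protein = prot, site_id = siteId,
                 counts = counts, features = features)
}

#' Write binding sites to disk
#'
#' The default `"tsv"` format writes the header-table dialect read by
#' [readSites()], including all count columns, sorted by
#' `(feature_id, start)`; it round-trips losslessly. `"bed6"` writes
#' headerless BED6 with the summed collapsed counts in the score column.
#'
#' @param x a [BindingSiteSet].
#' @param path output path.
#' @param format `"tsv"` (default, lossless) or `"bed6"`.
#' @return `path`, invisibly.
#' @export
writeSites <- function(x, path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  ord <- order(df$feature_id, df$start)
  df <- df[ord, , drop = FALSE]
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    score <- if (ncol(siteCounts(x)))
      rowSums(siteCounts(x))[ord] else 0
    bed <- data.frame(df$feature_id, df$start, df$end, df$site_id,
                      score, "+")
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write host features (table and optional FASTA)
#'
#' @param x a [HostFeatureSet].
#' @param path output path for the feature table.
#' @param fastaPath optional output path for the sequences.
#' @return `path`, invisibly.
#' @export
writeHostFeatures <- function(x, path, fastaPath = NULL) {
  write.table(x@features, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fastaPath)) {
    if (is.null(x@sequences))
      stop("no sequences attached to write")
    Biostrings::writeXStringSet(x@sequences, fastaPath)
  }
  invisible(path)
}

#' Filter sites by total collapsed read count
#'
#' Retains sites whose summed PCR-collapsed read counts across all
#' samples reach `minTotal`. The default cutoff equals the number of
#' samples in the set, the standard read-support filter for CLIP site
#' sets (at least one collapsed read per sample on average).
#'
#' @param x a [BindingSiteSet] with count columns.
#' @param minTotal non-negative integer cutoff; defaults to
#'   `ncol(siteCounts(x))`.
#' @return The filtered [BindingSiteSet]. Idempotent, and monotone in
#'   `minTotal` (larger cutoffs keep subsets of smaller ones).
#' @export
filterSitesByCount <- function(x, minTotal = NULL) {
  if (is.null(minTotal)) minTotal <- ncol(siteCounts(x))
  if (minTotal < 0) stop("minTotal must be >= 0")
  if (minTotal == 0) return(x)
  if (!ncol(siteCounts(x)))
    stop("site set has no count columns; cannot apply a count filter")
  keep <- rowSums(siteCounts(x)) >= minTotal
  x[which(keep)]
}
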