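# Programmatic fixtures shared across the test files.

makeFeatures <- function(n = 4L, len = 300L, seqs = FALSE, seed = 1L) {
  ids <- sprintf("utr%02d", seq_len(n))
  lens <- rep_len(len, n)
  s <- NULL
  if (seqs) {
    s <- withr_seed(seed, vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1L)))
    names(s) <- ids
  }
  HostFeatureSet(ids, lens, sequences = s)
}

## local seed helper (tests avoid touching the global stream)
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

makeSites <- function(features, feature_id, start, end, protein = "A",
                      site_id = NULL, counts = NULL) {
  BindingSiteSet(feature_id, start, end, protein = protein,
                 site_id = site_id, counts = counts,
                 features = features)
}

## n sites placed uniformly at random on the features (widths wmin..wmax)
randomSites <- function(features, n, protein = "A", wmin = 5L,
                        wmax = 20L, seed = 1L) {
  withr_seed(seed, {
    ids <- featureIds(features)
    lens <- featureLengths(features)
    feat <- sample(ids, n, replace = TRUE)
    w <- sample(wmin:wmax, n, replace = TRUE)
    start <- vapply(seq_len(n), function(i)
      sample.int(lens[feat[i]] - w[i] + 1L, 1L) - 1L, integer(1L))
    makeSites(features, feat, start, start + w, protein = protein,
              site_id = sprintf("%s%04d", protein, seq_len(n)))
  })
}

## brute-force O(n^2) overlap oracle on 0-based half-open coordinates
bruteOverlap <- function(a, b) {
  da <- as.data.frame(a); db <- as.data.frame(b)
  pairs <- list()
  for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db))) {
    if (da$feature_id[i] == db$feature_id[j] &&
        da$start[i] < db$end[j] && da$end[i] > db$start[j])
      pairs[[length(pairs) + 1L]] <- c(da$site_id[i], db$site_id[j])
  }
  m <- if (length(pairs)) do.call(rbind, pairs)
  else matrix(character(), ncol = 2L)
  list(pairs = m, n_a = length(unique(m[, 1L])),
       n_b = length(unique(m[, 2L])))
}

## regex oracle for the Pumilio motif scanner (overlapping matches)
regexPumOracle <- function(seq, allowDegenerate = FALSE) {
  seq <- chartr("T", "U", toupper(seq))
  find <- function(re) {
    h <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1L]]
    if (h[1L] == -1L) integer() else as.integer(h) - 1L
  }
  perfect <- find("UGUA[ACGU]AUA")
  out <- data.frame(position = perfect,
                    motif_class = rep("PERFECT", length(perfect)),
                    stringsAsFactors = FALSE)
  if (allowDegenerate) {
    d1 <- setdiff(find("UGUA[ACGU][ACGU]UA"), perfect)
    d2 <- setdiff(find("UGUA[ACGU]A[ACGU]A"), c(perfect, d1))
    d3 <- setdiff(find("UGUA[ACGU]AU[ACGU]"), c(perfect, d1, d2))
    out <- rbind(out,
                 data.frame(position = d1,
                            motif_class = rep("UGUAnnUA", length(d1))),
                 data.frame(position = d2,
                            motif_class = rep("UGUAnAnA", length(d2))),
                 data.frame(position = d3,
                            motif_class = rep("UGUAnAUn", length(d3))))
  }
  out[order(out$position), , drop = FALSE]
}

## random sequence over ACGU (optionally with N)
randomSeq <- function(L, withN = FALSE) {
  alpha <- c("A", "C", "G", "U", if (withN) "N")
  paste(sample(alpha, L, replace = TRUE), collapse = "")
}
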