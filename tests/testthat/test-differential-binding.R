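# Signal quantification, mRNA-normalized LFCs, per-UTR extremes,
# KS class comparisons and repertoire correlation.

mkCountedSites <- function() {
  hf <- makeFeatures(2, len = 100)
  counts <- cbind(c1 = c(10, 0), c2 = c(30, 0),
                  p1 = c(20, 0), p2 = c(20, 0))
  bs <- makeSites(hf, c("utr01", "utr02"), c(0, 0), c(20, 20),
                  site_id = c("sA", "sB"), counts = counts)
  des <- sampleDesign(c("c1", "c2", "p1", "p2"),
                      c("ctrl", "ctrl", "pert", "pert"),
                      librarySize = rep(1e6, 4))
  list(hf = hf, bs = bs, des = des)
}

test_that("site signal is library-scaled CPM averaged over replicates", {
  f <- mkCountedSites()
  # one sample, count 10, library 1e6 -> 10 CPM; mean of 10 and 30 -> 20
  expect_equal(unname(siteSignal(f$bs, f$des, "ctrl")), c(20, 0))
  expect_equal(unname(siteSignal(f$bs, f$des, "pert")), c(20, 0))
  # library size scaling
  des2 <- sampleDesign(c("c1", "c2", "p1", "p2"), rep(c("ctrl", "pert"),
                       each = 2), librarySize = rep(2e6, 4))
  expect_equal(unname(siteSignal(f$bs, des2, "ctrl")), c(10, 0))
  expect_error(siteSignal(f$bs, f$des, "nope"), "no samples")
  badDes <- sampleDesign("x1", "ctrl", librarySize = 1e6)
  expect_error(siteSignal(f$bs, badDes, "ctrl"), "missing count")
})

test_that("raw LFC follows the pseudocount-stabilized log2 ratio", {
  f <- mkCountedSites()
  lfc <- computeLfc(f$bs, f$des, "ctrl", "pert")
  # equal signals -> 0; zero counts both sides -> 0 via the pseudocount
  expect_equal(lfc$raw_lfc, c(0, 0))
  # doubled signal is ~1 up to pseudocount shrinkage
  counts <- cbind(c1 = 500, p1 = 1000)
  bs <- makeSites(f$hf, "utr01", 0, 20, site_id = "s",
                  counts = counts)
  des <- sampleDesign(c("c1", "p1"), c("ctrl", "pert"),
                      librarySize = c(1e6, 1e6))
  l2 <- computeLfc(bs, des, "ctrl", "pert")
  expect_equal(l2$raw_lfc, log2(1001 / 501))
  expect_lt(abs(l2$raw_lfc - 1), 0.01)
  expect_error(computeLfc(bs, des, "ctrl", "pert", pseudocount = -1),
               "pseudocount")
})

test_that("mRNA normalization subtracts in log2 space and excludes
           unannotated transcripts", {
  hf <- makeFeatures(3, len = 100)
  mrnaLfc(hf) <- data.frame(feature_id = c("utr01", "utr02"),
                            condition = "KD", lfc = c(0, 0.5))
  lfc <- data.frame(site_id = c("s1", "s2", "s3"),
                    feature_id = c("utr01", "utr02", "utr03"),
                    raw_lfc = c(0.5, 0.5, -1.2))
  expect_message(out <- normalizeLfc(lfc, hf, "KD"), "excluded")
  # identity when the mRNA is unchanged; full attribution when equal
  expect_equal(out$normalized_lfc, c(0.5, 0.0))
  expect_equal(attr(out, "excluded")$site_id, "s3")
  # plain subtraction
  mrnaLfc(hf) <- data.frame(feature_id = "utr03", condition = "KD",
                            lfc = -0.4)
  out2 <- normalizeLfc(lfc[3, ], hf, "KD")
  expect_equal(out2$normalized_lfc, -0.8)
})

test_that("normalization is the identity for all raw values at mRNA 0", {
  hf <- makeFeatures(1, len = 100)
  mrnaLfc(hf) <- data.frame(feature_id = "utr01", condition = "KD",
                            lfc = 0)
  raw <- withr_seed(3, rnorm(50, 0, 2))
  lfc <- data.frame(site_id = sprintf("s%02d", 1:50),
                    feature_id = "utr01", raw_lfc = raw)
  expect_equal(normalizeLfc(lfc, hf, "KD")$normalized_lfc, raw)
})

test_that("per-UTR extremes are exact and form a monotone envelope", {
  lfc <- data.frame(feature_id = c("a", "b", "b", "b", "c", "c"),
                    normalized_lfc = c(0.7, -1, 0, 2, 1, 1))
  ext <- utrExtremes(lfc)
  expect_equal(ext$min_lfc, c(0.7, -1, 1))
  expect_equal(ext$max_lfc, c(0.7, 2, 1))
  expect_equal(ext$n_sites, c(1L, 3L, 2L))
  # adding a site can only widen the envelope
  withr_seed(9, {
    for (i in 1:20) {
      vals <- rnorm(5)
      base <- data.frame(feature_id = "f", normalized_lfc = vals)
      grown <- rbind(base,
                     data.frame(feature_id = "f",
                                normalized_lfc = rnorm(1)))
      e0 <- utrExtremes(base); e1 <- utrExtremes(grown)
      expect_lte(e1$min_lfc, e0$min_lfc)
      expect_gte(e1$max_lfc, e0$max_lfc)
    }
  })
})

test_that("KS statistic equals the hand-computed ECDF sup-distance", {
  # identical samples -> D = 0
  same <- ksClassCompare(list(a = c(1, 2, 3), b = c(1, 2, 3)), "a", "b")
  expect_equal(same$D, 0)
  # fully separated -> D = 1
  sep <- ksClassCompare(list(a = c(0, 1, 2), b = c(10, 11, 12)),
                        "a", "b")
  expect_equal(sep$D, 1)
  # hand ECDF computation: sup difference is 0.25
  k <- ksClassCompare(list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5)),
                      "a", "b")
  expect_equal(k$D, 0.25)
  # independent oracle: explicit sup over the pooled support
  ecdfSup <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(vapply(g, function(v) mean(x <= v) - mean(y <= v),
                   numeric(1))))
  }
  withr_seed(13, {
    for (i in 1:20) {
      x <- rnorm(15); y <- rnorm(20, 0.5)
      kk <- ksClassCompare(list(x = x, y = y), "x", "y")
      expect_equal(kk$D, ecdfSup(x, y))
    }
  })
  expect_error(ksClassCompare(list(a = 1, b = c(1, 2)), "a", "b"),
               "fewer than 2")
  # returned ECDFs are valid step supports
  expect_equal(k$ecdf$a$ecdf, (1:4) / 4)
})

test_that("repertoire correlation follows Spearman with average ranks", {
  # engineered tallies: family f_i's 8mer site occurs a known number of
  # times in region 1 and in a permuted count in region 2, with one
  # covering site per region; patterns are mutually dissimilar so no
  # cross-family matches arise
  pats <- c(A = "UUCGAUCA", B = "CCAUAGGA", C = "GGAACGCA",
            D = "AUGCUUGA")
  # miRNAs whose seedPatterns()[["8mer"]] equals each pattern:
  # miRNA nt 2-8 is the reverse complement of the pattern's first 7 nt
  revCompRna <- function(s) paste(rev(strsplit(chartr("ACGU", "UGCA", s),
                                               "")[[1]]), collapse = "")
  mirnas <- vapply(pats, function(p)
    paste0("A", revCompRna(substr(p, 1, 7)), "AAAAAAAAAAAAAA"),
    character(1))
  stopifnot(vapply(names(pats), function(f)
    seedPatterns(mirnas[[f]])[["8mer"]] == pats[[f]], logical(1)))
  counts1 <- c(A = 1, B = 2, C = 3, D = 4)
  counts2 <- c(A = 1, B = 3, C = 2, D = 4)
  spacer <- strrep("G", 12)
  mkRegion <- function(counts) paste(unlist(mapply(function(p, k)
    rep(paste0(p, spacer), k), pats, counts)),
    collapse = "")
  seqStr <- paste0(mkRegion(counts1), strrep("G", 50), mkRegion(counts2))
  hf <- HostFeatureSet("u", nchar(seqStr),
                       sequences = c(u = seqStr))
  len1 <- sum(counts1) * 20
  g1 <- makeSites(hf, "u", 0, len1, site_id = "g1")
  g2 <- makeSites(hf, "u", len1 + 50, nchar(seqStr), site_id = "g2")
  r <- seedRepertoireCorrelation(g1, g2, mirnas, hf)
  expect_true(r$rho_defined)
  expect_equal(r$rho, cor(counts1, counts2, method = "spearman"))
  expect_equal(r$rho, 0.8)
  # identical groups give rho 1; reversed ranks give -1
  r1 <- seedRepertoireCorrelation(g1, g1, mirnas, hf)
  expect_equal(r1$rho, 1)
  counts3 <- c(A = 4, B = 3, C = 2, D = 1)
  seqStr2 <- paste0(mkRegion(counts1), strrep("G", 50), mkRegion(counts3))
  hf2 <- HostFeatureSet("u", nchar(seqStr2), sequences = c(u = seqStr2))
  h1 <- makeSites(hf2, "u", 0, len1, site_id = "h1")
  h2 <- makeSites(hf2, "u", len1 + 50, nchar(seqStr2), site_id = "h2")
  expect_equal(seedRepertoireCorrelation(h1, h2, mirnas, hf2)$rho, -1)
})
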