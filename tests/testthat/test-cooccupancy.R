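# Overlap counting, within-UTR randomization nulls, density profiles.

test_that("overlap uses half-open intervals and >= 1 shared nt", {
  hf <- makeFeatures(2, len = 100)
  a <- makeSites(hf, "utr01", 10, 30, site_id = "a1")
  b1 <- makeSites(hf, "utr01", 29, 40, site_id = "b1", protein = "B")
  b2 <- makeSites(hf, "utr01", 30, 40, site_id = "b2", protein = "B")
  expect_equal(nrow(overlapSites(a, b1)$pairs), 1L)  # 1-nt intersection
  expect_equal(nrow(overlapSites(a, b2)$pairs), 0L)  # abutting
  # same interval on a different feature never overlaps
  b3 <- makeSites(hf, "utr02", 10, 30, site_id = "b3", protein = "B")
  expect_equal(nrow(overlapSites(a, b3)$pairs), 0L)
})

test_that("overlap counting equals the brute-force oracle", {
  hf <- makeFeatures(5, len = 120)
  for (rep in 1:10) {
    a <- randomSites(hf, 20, protein = "A", seed = rep)
    b <- randomSites(hf, 20, protein = "B", seed = rep + 100)
    got <- overlapSites(a, b)
    want <- bruteOverlap(a, b)
    expect_equal(got$n_a_overlapping, want$n_a)
    expect_equal(got$n_b_overlapping, want$n_b)
    gotKeys <- sort(paste(got$pairs$site_a, got$pairs$site_b))
    wantKeys <- sort(paste(want$pairs[, 1], want$pairs[, 2]))
    expect_equal(gotKeys, wantKeys)
  }
})

test_that("UTR co-occupancy Venn counts match set algebra", {
  hf <- makeFeatures(10, len = 50)
  a <- makeSites(hf, c("utr01", "utr02", "utr03"), c(0, 0, 0),
                 c(10, 10, 10), protein = "A",
                 site_id = paste0("a", 1:3))
  b <- makeSites(hf, c("utr02", "utr04"), c(20, 0), c(30, 10),
                 protein = "B", site_id = paste0("b", 1:2))
  cc <- utrCooccupancy(list(A = a, B = b), hf)
  expect_equal(sum(cc$venn), nFeatures(hf))
  expect_equal(unname(cc$venn[c("A", "A+B", "B", "none")]),
               c(2L, 1L, 1L, 6L))
  # brute-force membership oracle
  expect_equal(unname(cc$membership[, "A"]),
               featureIds(hf) %in% c("utr01", "utr02", "utr03"))
  expect_equal(unname(cc$membership[, "B"]),
               featureIds(hf) %in% c("utr02", "utr04"))
  # site outside the universe is an error
  expect_error(utrCooccupancy(list(A = a), hf[1]), "outside the universe")
})

test_that("within-host randomization is uniform, seeded, width-safe", {
  hf <- makeFeatures(1, len = 10)
  # width == host length: single valid start
  full <- makeSites(hf, "utr01", 0, 10)
  r <- randomizeWithinHost(full, seed = 1)
  expect_equal(siteStarts(r), 0L)
  # determinism
  s3 <- makeSites(hf, "utr01", 2, 5)
  expect_equal(siteStarts(randomizeWithinHost(s3, seed = 7)),
               siteStarts(randomizeWithinHost(s3, seed = 7)))
  # empirical uniformity over the 8 valid starts of a width-3 site
  many <- makeSites(hf, rep("utr01", 1e4), rep(2, 1e4), rep(5, 1e4),
                    site_id = sprintf("s%05d", 1:1e4))
  starts <- siteStarts(randomizeWithinHost(many, seed = 3))
  expect_setequal(unique(starts), 0:7)
  chi <- suppressWarnings(chisq.test(tabulate(starts + 1L, 8)))
  expect_gt(chi$p.value, 1e-3)
  # a site wider than its host cannot even be constructed
  hf2 <- HostFeatureSet("s", 4L)
  expect_error(BindingSiteSet("s", 0, 5, protein = "A", features = hf2),
               "exceeds")
})

test_that("overlap z-score flags a saturated null and recovers exact p", {
  hf <- makeFeatures(1, len = 10)
  a <- makeSites(hf, "utr01", 0, 3, site_id = "a1")
  bFull <- makeSites(hf, "utr01", 0, 10, site_id = "b1", protein = "B")
  oz <- overlapZscore(a, bFull, which = "a", n = 20, seed = 1)
  expect_equal(oz$null_sd, 0)
  expect_false(oz$z_defined)
  expect_true(is.na(oz$z))

  # exact null: width-3 site on a 10-nt host vs b = [5, 8):
  # 5 of the 8 equiprobable placements overlap, P = 5/8
  b <- makeSites(hf, "utr01", 5, 8, site_id = "b1", protein = "B")
  oz2 <- overlapZscore(a, b, which = "a", n = 2000, seed = 2)
  expect_lt(abs(oz2$null_mean - 5 / 8), 4 * sqrt(5 / 8 * 3 / 8 / 2000))
  expect_equal(oz2$observed, 0L)  # [0,3) does not reach [5,8)
  expect_error(overlapZscore(makeSites(hf, character(), integer(),
                                       integer()), b),
               "empty")
})

test_that("density profile localizes planted offsets and trivial cases", {
  hf <- makeFeatures(3, len = 400)
  refs <- makeSites(hf, featureIds(hf), c(100, 150, 200),
                    c(120, 170, 220), site_id = paste0("r", 1:3))
  # no queries -> all-zero observed profile
  noq <- data.frame(feature_id = character(), position = integer())
  d0 <- densityProfile(refs, noq, window = 100, bin = 10, n = 5, seed = 1)
  expect_true(all(d0$observed == 0))
  # a single query centered on the single reference -> all mass at 0
  one <- makeSites(hf, "utr01", 100, 120, site_id = "q1", protein = "Q")
  d1 <- densityProfile(refs[1], one, window = 100, bin = 10, n = 5,
                       seed = 1)
  expect_equal(sum(d1$observed), 1)
  expect_equal(d1$observed[d1$offset == 5], 1)  # offset 0 in bin [0,10)
  # queries planted 20 nt 3' of every reference center
  q20 <- data.frame(feature_id = featureIds(hf),
                    position = c(109 + 20 - 3, 159 + 20 - 3,
                                 209 + 20 - 3), width = 8)
  d2 <- densityProfile(refs, q20, window = 100, bin = 10, n = 100,
                       seed = 5)
  peak <- which.max(d2$observed)
  expect_equal(d2$offset[peak], 25)  # bin [20, 30)
  expect_gt(d2$observed[peak],
            d2$null_mean[peak] + 3 * d2$null_sd[peak])
  expect_error(densityProfile(refs, one, window = 95, bin = 10),
               "multiple")
  expect_error(densityProfile(refs[integer()], one), "no reference")
})

test_that("stratification by overlap matches the brute-force oracle", {
  hf <- makeFeatures(4, len = 150)
  a <- randomSites(hf, 25, protein = "A", seed = 21)
  # no b sites -> everything non-overlapping
  noneB <- makeSites(hf, character(), integer(), integer(), protein = "B")
  expect_true(all(stratifySitesByOverlap(a, noneB) == "non_overlapping"))
  # b covering every host -> everything overlapping
  allB <- makeSites(hf, featureIds(hf), rep(0, 4), rep(150, 4),
                    protein = "B", site_id = paste0("c", 1:4))
  expect_true(all(stratifySitesByOverlap(a, allB) == "overlapping"))
  # mixed fixture vs brute force
  b <- randomSites(hf, 15, protein = "B", seed = 22)
  lab <- stratifySitesByOverlap(a, b)
  want <- bruteOverlap(a, b)
  expect_setequal(names(lab)[lab == "overlapping"],
                  unique(want$pairs[, 1]))
})
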