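# Generator: determinism, ground-truth bookkeeping, planted elements,
# background motif rates, generative-model expectations, round-trips.

test_that("UTR simulation is deterministic and respects the config", {
  cfg <- simConfig(n_utrs = 5, utr_length = c(300, 300))
  hf <- simulateUtrs(cfg, seed = 4)
  expect_equal(nFeatures(hf), 5L)
  expect_true(all(featureLengths(hf) == 300))
  hf2 <- simulateUtrs(cfg, seed = 4)
  expect_identical(as.character(featureSequences(hf)),
                   as.character(featureSequences(hf2)))
  expect_false(identical(as.character(featureSequences(hf)),
                         as.character(featureSequences(simulateUtrs(cfg,
                                                                    seed = 5)))))
  expect_equal(nFeatures(simulateUtrs(simConfig(n_utrs = 0))), 0L)
  expect_error(simulateUtrs(simConfig(utr_length = c(500, 400))),
               "degenerate")
})

test_that("planted motifs are recovered exactly; random plants avoid
           collisions", {
  hf <- makeFeatures(3, len = 200, seqs = TRUE, seed = 2)
  plants <- data.frame(
    feature_id = c("utr01", "utr01", "utr02"),
    position = c(10, 100, 50),
    pattern = c("UGUACAUA", "UGUAGAUA", "UGUAAAUA"))
  pm <- plantMotifs(hf, plants)
  hits <- scanPumMotifs(pm$features)
  key <- paste(hits$feature_id, hits$position)
  expect_true(all(paste(pm$plants$feature_id,
                        pm$plants$position) %in% key))
  # random placement: all realized, none colliding
  rnd <- data.frame(feature_id = rep("utr03", 10),
                    position = NA,
                    pattern = "UGUACAUA")
  pm2 <- plantMotifs(hf, rnd, seed = 8)
  expect_equal(nrow(pm2$plants), 10L)
  pos <- sort(pm2$plants$position)
  expect_true(all(diff(pos) >= 8))
  # out-of-range fixed plants are skipped, not planted
  off <- data.frame(feature_id = "utr01", position = 195,
                    pattern = "UGUACAUA")
  expect_equal(nrow(plantMotifs(hf, off)$plants), 0L)
})

test_that("background perfect-motif rate matches the closed form", {
  # uniform composition: P(window is UGUA[ACGU]AUA) = 4 / 4^8, so the
  # expected number of perfect hits is (L - 7) * 4^-7 per UTR
  cfg <- simConfig(n_utrs = 300, utr_length = c(1000, 1000))
  hf <- simulateUtrs(cfg, seed = 10)
  hits <- scanPumMotifs(hf)
  lambda <- 300 * (1000 - 7) * 4^-7
  expect_gt(nrow(hits), qpois(1e-5, lambda))
  expect_lt(nrow(hits), qpois(1 - 1e-5, lambda))
})

test_that("ground-truth fractions are exact and consistent with sites", {
  cfg <- simConfig(n_utrs = 40, fraction_cobound = 0.5,
                   fraction_overlapping = 0.5)
  sim <- simulateExperiment(cfg, seed = 3)
  tu <- sim$truth$utrs
  expect_equal(sum(tu$pum2_bound), round(0.5 * 40))
  expect_equal(sum(tu$pum1_bound), round(0.5 * 40))
  ts <- sim$truth$sites
  # exactly one cooperative and one antagonistic AGO2 site per co-bound
  # UTR, before any noise
  ago <- ts[ts$protein == "AGO2", ]
  coopPerUtr <- table(factor(ago$feature_id[ago$class == "cooperative"],
                             levels = tu$feature_id[tu$pum2_bound]))
  expect_true(all(coopPerUtr == 1))
  # per-UTR overlapping-site count honors the fraction deterministically
  p2 <- ts[ts$protein == "PUM2", ]
  overPerUtr <- tapply(p2$ago2_overlap, p2$feature_id, sum)
  expect_true(all(overPerUtr == round(0.5 * cfg$n_pum_per_utr)))
  # the recorded overlap flags agree with interval arithmetic
  strat <- stratifySitesByOverlap(sim$sites$PUM2, sim$sites$AGO2)
  expect_equal(unname(strat[p2$site_id] == "overlapping"),
               p2$ago2_overlap)
  # same seed -> identical count tables
  sim2 <- simulateExperiment(cfg, seed = 3)
  expect_identical(siteCounts(sim$sites$AGO2),
                   siteCounts(sim2$sites$AGO2))
})

test_that("planted coupling effects have the designed magnitudes", {
  # null model: no coupling, no transcript-level effects
  cfg0 <- simConfig(n_utrs = 150,
                    coupling = c(cooperative = 0, antagonistic = 0),
                    mrna_effect = 0)
  sim0 <- simulateExperiment(cfg0, seed = 21)
  l0 <- normalizeLfc(computeLfc(sim0$sites$AGO2, sim0$designs$AGO2,
                                "control", "PUMKD"),
                     sim0$features, "PUMKD")
  cls0 <- stats::setNames(sim0$truth$sites$class,
                          sim0$truth$sites$site_id)[l0$site_id]
  for (cl in unique(cls0)) {
    v <- l0$normalized_lfc[cls0 == cl]
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
  }
  # planted effect of 1 log2 unit is recovered (up to pseudocount
  # shrinkage and Monte-Carlo error)
  sim1 <- simulateExperiment(simConfig(n_utrs = 300), seed = 22)
  l1 <- normalizeLfc(computeLfc(sim1$sites$AGO2, sim1$designs$AGO2,
                                "control", "PUMKD"),
                     sim1$features, "PUMKD")
  cls1 <- stats::setNames(sim1$truth$sites$class,
                          sim1$truth$sites$site_id)[l1$site_id]
  # band covers pseudocount shrinkage (< 0.07 at these depths) plus
  # three standard errors of the Monte-Carlo mean
  expect_lt(abs(mean(l1$normalized_lfc[cls1 == "cooperative"]) + 1), 0.15)
  expect_lt(abs(mean(l1$normalized_lfc[cls1 == "antagonistic"]) - 1), 0.15)
  expect_lt(abs(mean(l1$normalized_lfc[cls1 == "independent"])), 0.1)
})

test_that("emitted files round-trip through the standard readers", {
  sim <- simulateExperiment(simConfig(n_utrs = 15), seed = 6)
  dir <- withr::local_tempdir()
  writeHostFeatures(sim$features, file.path(dir, "u.tsv"),
                    file.path(dir, "u.fa"))
  write.table(mrnaLfc(sim$features), file.path(dir, "m.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeSites(sim$sites$PUM2, file.path(dir, "s.tsv"))
  hf <- readHostFeatures(file.path(dir, "u.tsv"), file.path(dir, "u.fa"))
  mrnaLfc(hf) <- readMrnaLfc(file.path(dir, "m.tsv"))
  expect_equal(featureLengths(hf), featureLengths(sim$features))
  expect_identical(as.character(featureSequences(hf)),
                   as.character(featureSequences(sim$features)))
  back <- readSites(file.path(dir, "s.tsv"), hf)
  ord <- match(siteIds(sim$sites$PUM2), siteIds(back))
  expect_equal(siteStarts(back)[ord], siteStarts(sim$sites$PUM2))
  expect_equal(unname(siteCounts(back)[ord, ]),
               unname(siteCounts(sim$sites$PUM2)))
})
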