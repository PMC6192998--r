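## Synthetic-data generator: host UTRs, motif-planted sequences, site
## sets with known cooperative/antagonistic coupling, negative-binomial
## count matrices and mRNA LFC tables, with full ground truth.
##
## The generative model mirrors a reciprocal-perturbation CLIP design:
## AGO2 CLIP under control vs PUM knockdown (cooperative AGO2 sites on
## co-bound UTRs lose signal, antagonistic sites gain), and PUM CLIP in
## wildtype vs DICER-deficient cells (PUM sites overlapping AGO2 lose
## signal). Transcript-level mRNA changes are generated separately and
## contaminate the raw site counts, so mRNA normalization is genuinely
## exercised.

.DEFAULT_MIRNAS <- c(
  "let-7a" = "UGAGGUAGUAGGUUGUAUAGUU",
  "miR-17" = "CAAAGUGCUUACAGUGCAGGUAG",
  "miR-21" = "UAGCUUAUCAGACUGAUGUUGA",
  "miR-25" = "CAUUGCACUUGUCUCGGUCUGA"
)

#' Configuration for the synthetic CLIP experiment generator
#'
#' Defaults describe a desk-scale but realistic 3'UTR universe: 600
#' UTRs of 500-1500 nt, 3 AGO2 sites per UTR, 2 sites per bound PUM
#' paralog, CLIP peak widths of 30-50 nt, half of the UTRs co-bound,
#' half of the PUM sites overlapping AGO2, a planted coupling effect of
#' 1 log2 unit, negative-binomial counts with mean 50 and dispersion
#' size 10 over 3 replicates per condition.
#'
#' @param n_utrs number of host UTRs.
#' @param utr_length length range (min, max) in nt, sampled uniformly.
#' @param n_ago2_per_utr AGO2 sites per UTR (placed in disjoint
#'   segments).
#' @param n_pum_per_utr sites per PUM paralog on each UTR it binds.
#' @param site_width CLIP peak width range (min, max) in nt.
#' @param fraction_cobound fraction of UTRs bound by each PUM paralog
#'   (assigned deterministically: exactly `round(fraction * n_utrs)`
#'   UTRs per paralog).
#' @param fraction_overlapping fraction of each UTR's PUM sites placed
#'   overlapping an AGO2 site (deterministic count per UTR).
#' @param coupling named vector of planted log2 effect sizes for
#'   `cooperative` and `antagonistic` site classes.
#' @param nb_mu,nb_size negative-binomial mean and dispersion (size) of
#'   collapsed read counts per site and sample.
#' @param site_strength_sdlog log-normal spread of per-site baseline
#'   strength around `nb_mu`.
#' @param n_replicates biological replicates per condition.
#' @param mrna_sd SD of transcript-level mRNA log2 fold change noise.
#' @param mrna_effect mean mRNA stabilization (log2) of PUM2-bound
#'   transcripts upon PUM knockdown.
#' @param overlap_nt shared nucleotides for overlapping site pairs.
#' @param mirnas named character vector of miRNA sequences whose seed
#'   complements are planted under AGO2 sites (default: four abundant
#'   human miRNAs).
#' @param plant_motifs plant PUM motifs at PUM sites and seed
#'   complements at AGO2 sites in the generated sequences.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(n_utrs = 600L,
                      utr_length = c(500L, 1500L),
                      n_ago2_per_utr = 3L,
                      n_pum_per_utr = 2L,
                      site_width = c(30L, 50L),
                      fraction_cobound = 0.5,
                      fraction_overlapping = 0.5,
                      coupling = c(cooperative = 1, antagonistic = 1),
                      nb_mu = 50,
                      nb_size = 10,
                      site_strength_sdlog = 0.5,
                      n_replicates = 3L,
                      mrna_sd = 0.2,
                      mrna_effect = 0.4,
                      overlap_nt = 10L,
                      mirnas = .DEFAULT_MIRNAS,
                      plant_motifs = TRUE) {
  cfg <- list(n_utrs = as.integer(n_utrs), utr_length = utr_length,
              n_ago2_per_utr = as.integer(n_ago2_per_utr),
              n_pum_per_utr = as.integer(n_pum_per_utr),
              site_width = site_width,
              fraction_cobound = fraction_cobound,
              fraction_overlapping = fraction_overlapping,
              coupling = coupling, nb_mu = nb_mu, nb_size = nb_size,
              site_strength_sdlog = site_strength_sdlog,
              n_replicates = as.integer(n_replicates),
              mrna_sd = mrna_sd, mrna_effect = mrna_effect,
              overlap_nt = as.integer(overlap_nt), mirnas = mirnas,
              plant_motifs = plant_motifs)
  stopifnot(cfg$n_utrs >= 0,
            cfg$fraction_cobound >= 0, cfg$fraction_cobound <= 1,
            cfg$fraction_overlapping >= 0, cfg$fraction_overlapping <= 1,
            cfg$nb_mu > 0, cfg$nb_size > 0,
            all(cfg$site_width >= 1), cfg$n_replicates >= 1)
  if (!all(c("cooperative", "antagonistic") %in% names(cfg$coupling)))
    stop("coupling must name cooperative and antagonistic effects")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate host UTRs with uniform-composition random sequences
#'
#' Sequence composition is i.i.d. uniform over A/C/G/U, so background
#' motif rates are closed-form (a given 8-mer pattern with one free
#' position occurs at rate `4 * (L - 7) / 4^8` per UTR).
#'
#' @param config a [simConfig()].
#' @param seed optional integer seed; the same seed gives
#'   byte-identical sequences.
#' @return A [HostFeatureSet] with sequences attached.
#' @export
simulateUtrs <- function(config = simConfig(), seed = NULL) {
  lo <- config$utr_length[1L]; hi <- config$utr_length[2L]
  if (lo < 1 || hi < lo) stop("degenerate UTR length range")
  withSeed(seed, {
    n <- config$n_utrs
    if (n == 0L) return(HostFeatureSet())
    lens <- lo + .runifInt0(rep(hi - lo + 1L, n))
    ids <- sprintf("utr%04d", seq_len(n))
    seqs <- vapply(lens, function(L)
      paste(c("A", "C", "G", "T")[1L + .runifInt0(rep(4L, L))],
            collapse = ""), character(1L))
    HostFeatureSet(ids, lens, sequences = stats::setNames(seqs, ids))
  })
}

## TRUE if interval [s, e) intersects any of [starts, ends).
.hitsAny <- function(s, e, starts, ends) {
  length(starts) > 0L && any(s < ends & e > starts)
}

#' Plant sequence elements into host features
#'
#' Overwrites host sequence at the requested positions with the given
#' patterns. Rows with `position = NA` are placed uniformly at random
#' among positions that do not collide with previously planted
#' elements (up to 100 redraws, then an error). Fixed-position
#' duplicates (same feature, position and pattern) are merged;
#' fixed-position plants that would collide with an earlier plant or
#' run off the host are skipped and excluded from the returned table.
#'
#' @param features a [HostFeatureSet] with sequences.
#' @param plants `data.frame` with columns `feature_id`, `position`
#'   (0-based or `NA`), `pattern` (RNA or DNA alphabet) and optionally
#'   extra annotation columns carried through.
#' @param seed optional integer seed for random placements.
#' @return List with `features` (modified set) and `plants` (realized
#'   table of planted elements with final positions).
#' @export
plantMotifs <- function(features, plants, seed = NULL) {
  seqs <- featureSequences(features)
  if (is.null(seqs)) stop("features carry no sequences")
  plants <- as.data.frame(plants)
  plants$pattern <- .asDnaChar(plants$pattern)
  withSeed(seed, {
    seqChar <- stats::setNames(as.character(seqs), names(seqs))
    placedS <- placedE <- split(integer(), character())
    realized <- logical(nrow(plants))
    ord <- order(is.na(plants$position))  # fixed positions first
    for (i in ord) {
      id <- plants$feature_id[i]
      pat <- plants$pattern[i]
      w <- nchar(pat)
      L <- nchar(seqChar[[id]])
      ps <- placedS[[id]] %||% integer()
      pe <- placedE[[id]] %||% integer()
      pos <- plants$position[i]
      if (is.na(pos)) {
        ok <- FALSE
        for (try in seq_len(100L)) {
          cand <- .runifInt0(L - w + 1L)
          if (!.hitsAny(cand, cand + w, ps, pe)) {
            pos <- cand; ok <- TRUE; break
          }
        }
        if (!ok)
          stop("could not place a random element on ", id,
               " without collision after 100 tries")
      } else {
        if (pos < 0 || pos + w > L) next  # does not fit: skip
        dup <- any(ps == pos & pe == pos + w)
        if (dup) {
          prev <- substr(seqChar[[id]], pos + 1L, pos + w)
          if (identical(prev, pat)) { realized[i] <- TRUE }
          next
        }
        if (.hitsAny(pos, pos + w, ps, pe)) next  # collision: skip
      }
      substr(seqChar[[id]], pos + 1L, pos + w) <- pat
      placedS[[id]] <- c(ps, pos)
      placedE[[id]] <- c(pe, pos + w)
      plants$position[i] <- pos
      realized[i] <- TRUE
    }
    newSeqs <- Biostrings::DNAStringSet(seqChar)
    hf <- features
    hf@sequences <- newSeqs
    validObject(hf)
    list(features = hf,
         plants = plants[realized & !is.na(plants$position), ,
                         drop = FALSE])
  })
}

## Sample one site width from the configured range.
.drawWidth <- function(cfg, n = 1L) {
  cfg$site_width[1L] +
    .runifInt0(rep(cfg$site_width[2L] - cfg$site_width[1L] + 1L, n))
}

#' Simulate binding sites, count matrices and mRNA LFC tables
#'
#' Places AGO2 sites on every UTR (one per equal-length segment, so
#' sites of the same protein never overlap), PUM1/PUM2 sites on
#' deterministic fractions of UTRs, with a deterministic fraction of
#' each UTR's PUM sites overlapping an AGO2 site by `overlap_nt`
#' nucleotides and the rest placed avoiding AGO2 and previously placed
#' PUM sites. Site classes are assigned before any noise:
#' on PUM2-co-bound UTRs the first AGO2 site is `cooperative`
#' (mean count multiplied by `2^-delta` upon PUM knockdown) and the
#' second `antagonistic` (`2^+delta`); PUM sites overlapping AGO2 are
#' `cooperative` upon DICER loss. Counts are negative-binomial around
#' log-normal per-site baselines; perturbed-condition means are
#' additionally multiplied by `2^(mRNA LFC)` of the host transcript, so
#' raw site LFCs are contaminated by transcript-level changes and must
#' be corrected with [normalizeLfc()].
#'
#' @param features a [HostFeatureSet] from [simulateUtrs()].
#' @param config a [simConfig()].
#' @param seed optional integer seed.
#' @return List with `sites` (named list of [BindingSiteSet]:
#'   AGO2, PUM1, PUM2), `designs` (matching [sampleDesign()] tables;
#'   AGO2 has conditions `control`/`PUMKD`, the PUMs `WT`/`DICERKO`),
#'   `features` (input features with the mRNA LFC table attached),
#'   and `truth` (list of `utrs` and `sites` ground-truth tables).
#' @export
simulateSitesAndCounts <- function(features, config = simConfig(),
                                   seed = NULL) {
  withSeed(seed, {
    n <- nFeatures(features)
    if (n == 0L) stop("no host features to simulate on")
    ids <- featureIds(features)
    Ls <- unname(featureLengths(features))
    nA <- config$n_ago2_per_utr
    seg <- Ls %/% nA
    if (any(seg < config$site_width[2L]))
      stop("UTRs too short for ", nA, " non-overlapping AGO2 sites")

    ## -- bound-UTR assignment (deterministic counts) --
    nBound <- round(config$fraction_cobound * n)
    pum1Utr <- sort(sample.int(n, nBound))
    pum2Utr <- sort(sample.int(n, nBound))

    ## -- AGO2 placement: one site per segment --
    agoFeat <- rep(seq_len(n), each = nA)
    segIdx <- rep(seq_len(nA), n)
    agoW <- .drawWidth(config, n * nA)
    segLo <- (segIdx - 1L) * seg[agoFeat]
    agoStart <- segLo + .runifInt0(seg[agoFeat] - agoW + 1L)
    agoEnd <- agoStart + agoW
    agoClass <- rep("independent", n * nA)
    onCobound <- agoFeat %in% pum2Utr
    agoClass[onCobound & segIdx == 1L] <- "cooperative"
    if (nA >= 2L) agoClass[onCobound & segIdx == 2L] <- "antagonistic"

    ## -- PUM placement --
    placePum <- function(boundUtr, protein) {
      k <- config$n_pum_per_utr
      nOver <- round(config$fraction_overlapping * k)
      feat <- integer(); st <- integer(); en <- integer()
      overFlag <- logical(); cls <- character()
      for (u in boundUtr) {
        L <- Ls[u]
        agoIdx <- which(agoFeat == u)
        aS <- agoStart[agoIdx]; aE <- agoEnd[agoIdx]
        if (nOver > length(agoIdx))
          stop("more overlapping PUM sites requested than AGO2 sites")
        anchors <- if (nOver > 0L)
          agoIdx[sample.int(length(agoIdx), nOver)] else integer()
        ## occupied intervals grow as this UTR's PUM sites are placed
        occS <- aS; occE <- aE
        for (j in seq_len(k)) {
          w <- .drawWidth(config)
          if (j <= nOver) {
            aI <- anchors[j]
            s <- agoEnd[aI] - config$overlap_nt
            if (s + w > L) s <- agoStart[aI] + config$overlap_nt - w
            if (s < 0 || s + w > L)
              stop("cannot place overlapping PUM site on ", ids[u])
            isOver <- TRUE
          } else {
            s <- NA_integer_
            for (try in seq_len(200L)) {
              cand <- .runifInt0(L - w + 1L)
              if (!.hitsAny(cand, cand + w, occS, occE)) { s <- cand; break }
            }
            if (is.na(s))
              stop("cannot place non-overlapping PUM site on ", ids[u],
                   " after 200 tries")
            isOver <- FALSE
          }
          feat <- c(feat, u); st <- c(st, s); en <- c(en, s + w)
          overFlag <- c(overFlag, isOver)
          cls <- c(cls, if (isOver) "cooperative" else "independent")
          occS <- c(occS, s); occE <- c(occE, s + w)
        }
      }
      list(feat = feat, start = st, end = en, over = overFlag,
           class = cls, protein = protein)
    }
    pum1 <- placePum(pum1Utr, "PUM1")
    pum2 <- placePum(pum2Utr, "PUM2")

    ## -- mRNA log fold changes (transcript level) --
    pumkdLfc <- rnorm(n, 0, config$mrna_sd) +
      config$mrna_effect * (seq_len(n) %in% pum2Utr)
    dicerLfc <- rnorm(n, 0, config$mrna_sd)
    mrna <- rbind(
      data.frame(feature_id = ids, condition = "PUMKD", lfc = pumkdLfc,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = ids, condition = "DICERKO", lfc = dicerLfc,
                 stringsAsFactors = FALSE)
    )
    mrnaLfc(features) <- mrna

    ## -- counts --
    delta <- config$coupling
    effectOf <- function(cls) {
      ifelse(cls == "cooperative", -delta[["cooperative"]],
             ifelse(cls == "antagonistic", delta[["antagonistic"]], 0))
    }
    nbCounts <- function(mu, nrep) {
      vapply(seq_len(nrep),
             function(j) rnbinom(length(mu), mu = mu,
                                 size = config$nb_size),
             numeric(length(mu)))
    }
    makeSet <- function(feat, st, en, cls, protein, mrnaShift,
                        condLabels) {
      m <- length(feat)
      mu0 <- rlnorm(m, log(config$nb_mu), config$site_strength_sdlog)
      muP <- mu0 * 2^(effectOf(cls) + mrnaShift[feat])
      ctrl <- nbCounts(mu0, config$n_replicates)
      pert <- nbCounts(muP, config$n_replicates)
      counts <- cbind(ctrl, pert)
      samples <- c(sprintf("%s_%s_%d", protein, condLabels[1L],
                           seq_len(config$n_replicates)),
                   sprintf("%s_%s_%d", protein, condLabels[2L],
                           seq_len(config$n_replicates)))
      colnames(counts) <- samples
      siteId <- sprintf("%s_%05d", protein, seq_len(m))
      set <- BindingSiteSet(ids[feat], st, en, protein = protein,
                            site_id = siteId, counts = counts,
                            features = features)
      ## equal nominal depth across samples: CPM scaling is exercised
      ## without introducing composition bias between conditions
      design <- sampleDesign(samples,
                             rep(condLabels, each = config$n_replicates),
                             librarySize = rep(1e6, length(samples)))
      list(set = set, design = design, site_id = siteId)
    }
    ago <- makeSet(agoFeat, agoStart, agoEnd, agoClass, "AGO2",
                   pumkdLfc, c("control", "PUMKD"))
    p1 <- makeSet(pum1$feat, pum1$start, pum1$end, pum1$class, "PUM1",
                  dicerLfc, c("WT", "DICERKO"))
    p2 <- makeSet(pum2$feat, pum2$start, pum2$end, pum2$class, "PUM2",
                  dicerLfc, c("WT", "DICERKO"))

    truthSites <- rbind(
      data.frame(site_id = ago$site_id, protein = "AGO2",
                 feature_id = ids[agoFeat], class = agoClass,
                 ago2_overlap = NA, stringsAsFactors = FALSE),
      data.frame(site_id = p1$site_id, protein = "PUM1",
                 feature_id = ids[pum1$feat], class = pum1$class,
                 ago2_overlap = pum1$over, stringsAsFactors = FALSE),
      data.frame(site_id = p2$site_id, protein = "PUM2",
                 feature_id = ids[pum2$feat], class = pum2$class,
                 ago2_overlap = pum2$over, stringsAsFactors = FALSE)
    )
    truthUtrs <- data.frame(
      feature_id = ids,
      ago2_bound = TRUE,
      pum1_bound = seq_len(n) %in% pum1Utr,
      pum2_bound = seq_len(n) %in% pum2Utr,
      mrna_lfc_pumkd = pumkdLfc,
      mrna_lfc_dicerko = dicerLfc,
      stringsAsFactors = FALSE
    )
    list(sites = list(AGO2 = ago$set, PUM1 = p1$set, PUM2 = p2$set),
         designs = list(AGO2 = ago$design, PUM1 = p1$design,
                        PUM2 = p2$design),
         features = features,
         truth = list(utrs = truthUtrs, sites = truthSites))
  })
}

## Plant table anchored on simulated sites: a perfect PUM motif 2 nt
## into each PUM site (shared-position plants of the two paralogs
## merge) and one miRNA seed complement centered in each AGO2 site,
## cycling through the configured families so the planted repertoire is
## balanced.
.sitePlants <- function(sim, config) {
  sitesToDf <- function(s) as.data.frame(s)
  pum <- rbind(sitesToDf(sim$sites$PUM1)[, 1:5],
               sitesToDf(sim$sites$PUM2)[, 1:5])
  pumPos <- pum$start + 2L
  pumPat <- paste0("UGUA", c("A", "C", "G", "U")[1L +
                     .runifInt0(rep(4L, nrow(pum)))], "AUA")
  ago <- sitesToDf(sim$sites$AGO2)[, 1:5]
  agoCenter <- ago$start + (ago$end - ago$start - 1L) %/% 2L
  fams <- vapply(config$mirnas, function(m)
    seedPatterns(m)[["8mer"]], character(1L))
  ## skewed family usage (geometric abundance profile), independent of
  ## any overlap status: the seed repertoire is shared across site
  ## populations, as for abundant cellular miRNAs
  wts <- 2^-(seq_along(fams) - 1L)
  famIdx <- sample.int(length(fams), nrow(ago), replace = TRUE,
                       prob = wts / sum(wts))
  rbind(
    data.frame(feature_id = pum$feature_id, position = pumPos,
               pattern = pumPat, element = "pum_motif",
               family = NA_character_, anchor_site = pum$site_id,
               stringsAsFactors = FALSE),
    data.frame(feature_id = ago$feature_id,
               position = agoCenter - 3L,
               pattern = unname(fams[famIdx]), element = "seed",
               family = names(config$mirnas)[famIdx],
               anchor_site = ago$site_id, stringsAsFactors = FALSE)
  )
}

#' Simulate a complete CLIP co-occupancy experiment
#'
#' Runs [simulateUtrs()], [simulateSitesAndCounts()] and (unless
#' disabled) plants PUM motifs at PUM sites and miRNA seed complements
#' at AGO2 site centers via [plantMotifs()]. Deterministic for a given
#' seed.
#'
#' @param config a [simConfig()].
#' @param seed optional integer seed.
#' @return List with `features` (sequences planted, mRNA LFCs
#'   attached), `sites`, `designs`, `truth` (with the realized `plants`
#'   table added) and `config`.
#' @export
simulateExperiment <- function(config = simConfig(), seed = NULL) {
  withSeed(seed, {
    hf <- simulateUtrs(config)
    sim <- simulateSitesAndCounts(hf, config)
    ## carry mRNA LFC annotations on the sequence-bearing object
    hf <- sim$features
    plants <- NULL
    if (config$plant_motifs) {
      pm <- plantMotifs(hf, .sitePlants(sim, config))
      hf <- pm$features
      plants <- pm$plants
    }
    sim$features <- hf
    sim$truth$plants <- plants
    sim$config <- config
    sim
  })
}
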