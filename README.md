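# clipcoreg

Co-occupancy and differential binding analysis of RNA-binding protein
(RBP) CLIP-seq sites on 3'UTRs.

## The problem

RBPs and miRNA-guided Argonaute (AGO2) complexes bind defined 3'UTR
sites and can interact on shared transcripts — *cooperatively* (losing
one partner weakens the other's binding) or *antagonistically* (one
partner shields a site from the other's repression). Detecting such
interactions transcriptome-wide requires comparing quantitative CLIP
binding profiles between perturbation conditions while controlling for
transcript-abundance changes and for chance co-localization.
`clipcoreg` is for computational biologists analysing binding-site
tables from quantitative CLIP experiments run under reciprocal
perturbations (e.g. AGO2 CLIP under Pumilio knockdown; Pumilio CLIP in
DICER-deficient cells).

## What it computes

With sites of protein *A* and *B* on a universe of UTRs:

* **Co-occupancy**: Venn counts of UTRs bound by any protein
  combination, and site-level overlap (≥ 1 shared nt, half-open
  intervals) scored against a within-UTR randomization null —
  each site repositioned uniformly among its `L − w + 1` valid starts
  over *n* = 100 control experiments —
  as `z = (obs − μ_null) / σ_null`.
* **Positional density**: binned center-to-center offset profiles of
  query elements (sites, PUM motifs, miRNA seed complements) around
  reference sites, with a permutation mean ± 1 SD envelope.
* **Motif/seed scanning**: the Pumilio element `UGUAnAUA` with
  degenerate classes (`UGUAnnUA`, `UGUAnAnA`, `UGUAnAUn`), and
  canonical miRNA seed-complement types (`8mer`, `7mer-m8`,
  `7mer-A1`) with longest-match precedence.
* **Differential binding**: per-site CPM signal averaged over
  replicates; `LFC = log2((s_pert + 1)/(s_ctrl + 1))`, normalized by
  subtracting the transcript's mRNA-level log2 fold change
  (`LFC_norm = LFC − LFC_mRNA`); per-UTR extreme sites (min/max
  normalized LFC); two-sample Kolmogorov–Smirnov comparisons of
  transcript classes; Spearman correlation of miRNA seed repertoires
  between site populations.
* **Reporter statistics**: technical-replicate CV filtering
  (omit when CV > 50%), WT/mutant luciferase activity ratios, paired
  t-tests (WT vs mutant) and Welch t-tests (ratios between cell
  conditions) on log2 ratios.
* **Synthetic data**: a generator that plants cooperative and
  antagonistic coupling, motifs and seed sites with full ground truth,
  so every stage of the pipeline is testable end to end
  (`simulateExperiment()`, `runPipeline()`).

## Worked example

```r
library(clipcoreg)

# a synthetic reciprocal-perturbation experiment with known coupling
sim <- simulateExperiment(simConfig(n_utrs = 200), seed = 7)

# is AGO2-PUM2 site overlap more frequent than chance?
overlapZscore(sim$sites$AGO2, sim$sites$PUM2, which = "a",
              n = 100, seed = 7)
#> Overlap: observed 100, null 51.03 +/- 5.99 (100 randomizations of set a)
#>   z = 8.17
```

100 of the 600 AGO2 sites overlap a PUM2 site, versus 51 ± 6 expected
when AGO2 sites are repositioned within their own UTRs — an excess of
8 null standard deviations, i.e. strong site-level co-localization.

```r
# AGO2 binding change upon PUM knockdown, corrected for mRNA changes
agoLfc <- normalizeLfc(
  computeLfc(sim$sites$AGO2, sim$designs$AGO2, "control", "PUMKD"),
  sim$features, "PUMKD")
ext <- utrExtremes(agoLfc)
head(ext, 3)
#>   feature_id    min_lfc   max_lfc n_sites
#> 1    utr0001 -0.4608396 0.6207477       3
#> 2    utr0002 -0.5814120 0.5207005       3
#> 3    utr0003 -0.7441731 0.6292242       3

# do co-bound UTRs lose AGO2 binding where PUM2 is present?
mem <- utrCooccupancy(sim$sites, sim$features)$membership
cb <- rownames(mem)[mem[, "PUM2"]]
ao <- rownames(mem)[!mem[, "PUM2"]]
ksClassCompare(list(cobound  = ext$min_lfc[ext$feature_id %in% cb],
                    ago2_only = ext$min_lfc[ext$feature_id %in% ao]),
               "cobound", "ago2_only")
#> KS comparison cobound (n=100) vs ago2_only (n=100): D = 0.7500, p = 0
```

The minimal normalized LFC per UTR is strongly left-shifted on
PUM2-co-bound UTRs (KS D = 0.75, p below double precision): the
planted cooperative AGO2 sites lose binding when PUM2 is depleted,
exactly the signature the statistics are designed to detect.

`runPipeline(simConfig(), outDir, seed)` runs every stage end to end
(file emission, re-ingest, filtering, Venn, z-score, density, LFC, KS
reports, repertoire correlation) and writes tab-delimited tables plus
`summary.json`.

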