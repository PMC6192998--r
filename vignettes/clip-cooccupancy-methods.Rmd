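---
title: "Methods: co-occupancy and differential binding analysis of RBP CLIP sites"
author: "clipcoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy and differential binding analysis of RBP CLIP sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipcoreg)
```

## The scientific setting

RNA-binding proteins (RBPs) and miRNA-loaded Argonaute complexes bind
defined sites in mRNA 3'UTRs and jointly determine transcript fate.
Beyond their individual effects, pairs of regulators can interact on
the same transcript: *cooperatively*, where the loss of one partner
weakens the other's binding, or *antagonistically*, where one partner
shields a site from the other's repressive machinery. `clipcoreg`
implements the statistical machinery for detecting such interactions
from quantitative CLIP-seq binding-site data collected under reciprocal
perturbations — for example Argonaute-2 (AGO2) CLIP under Pumilio
(PUM1/PUM2) knockdown, and PUM CLIP in DICER-deficient cells where
miRNA-guided AGO targeting is abolished.

The package operates entirely in transcript-relative coordinates:
binding sites live on *host features* (3'UTRs by default), 0-based and
half-open, 5'→3' on the mature mRNA. All randomization-based null
models reposition sites *within* their own host, never across
transcripts, because every question asked here — does co-occupancy on
the same UTR change binding? are two site sets closer than chance? —
is conditional on the transcript being bound at all.

## Data model

Two S4 containers carry the data:

* `HostFeatureSet` — features with lengths, optional sequences
  (T/U interchangeable, upper-cased on ingest), and a long-format
  table of transcript-level mRNA log2 fold changes (LFCs) per
  perturbation condition, supplied externally.
* `BindingSiteSet` — CLIP peaks as a `GRanges` keyed by feature id
  with host lengths as seqlengths, plus a matrix of per-sample
  PCR-collapsed read counts. Validity rules enforce within-host
  coordinates, positive widths, unique site ids and non-negative
  integer counts.

Sites spanning annotation-category boundaries are outside the model:
a site must lie entirely within one host feature. Genomic BED input is
accepted only as a means of deriving features (`readHostFeatures`),
and the site readers expose a `zeroBased` switch because peak callers
disagree on coordinate conventions; nothing downstream ever guesses.

Site sets are filtered by total collapsed read count with an inclusive
cutoff that defaults to the number of samples in the set — on average
at least one independent ligation event per sample.

## Co-occupancy statistics

**Overlap** is defined as ≥ 1 shared nucleotide under half-open
arithmetic; abutting sites do not overlap. No minimum-overlap fraction
is imposed: CLIP peak boundaries are soft, and the permissive rule is
the one whose null model is cleanly defined.

**Randomization null.** `randomizeWithinHost()` repositions each site
independently and uniformly among its `length − width + 1` valid
starts, preserving widths and counts. Randomized sites may overlap
each other — rejection sampling would bias the null on short UTRs
where dense sites leave few non-overlapping configurations.
`overlapZscore()` counts the sites of one set having at least one
partner in the other, repeats the count in `n = 100` control
randomizations (the count chosen to keep the null SD estimate stable
while remaining cheap), and reports
`z = (observed − null mean) / null SD`. A saturated null (SD = 0,
e.g. the fixed set covers its hosts) yields a flagged, undefined z
rather than an infinity. Which of the two sets is randomized is an
explicit argument, not a hidden convention.

**Density profiles.** `densityProfile()` bins signed center-to-center
offsets (positive = query 3' of the reference; centers round half-down
for even widths, an arbitrary but fixed tie-break) of query elements
around reference sites, normalized per reference site, and surrounds
the observed curve with a mean ± 1 SD envelope from within-host
randomizations of the query set. Defaults are a ± 500 nt window in
10 nt bins, both configurable; the profile drops offsets at exactly
+window (half-open binning).

## Motif and seed scanning

The Pumilio recognition element is the 8-mer `UGUAnAUA` (position 5
free). Scanning tests every window on the sense strand only — 3'UTR
regulation acts on single-stranded mature mRNA. Degenerate classes
relax one additional 3'-half position (`UGUAnnUA`, `UGUAnAnA`,
`UGUAnAUn`); because `UGUAnnUA` subsumes the other two, each window
reports at most one class with precedence
`PERFECT > UGUAnnUA > UGUAnAnA > UGUAnAUn`. `n` matches A/C/G/U but
not the ambiguity letter N; windows containing N are skipped.
The scanner is hand-written character-vector code; the test suite
checks it against an independent regular-expression oracle on
thousands of random sequences.

miRNA seed-complement sites follow the canonical typing: `7mer-m8` is
the reverse complement of miRNA nucleotides 2–8, `7mer-A1` the reverse
complement of nucleotides 2–7 followed by A, and `8mer` the `7mer-m8`
pattern followed by A. At a given locus only the longest matching type
is reported (`8mer > 7mer-m8 > 7mer-A1`), and families are
deduplicated by seed. 6mer and non-canonical sites are deliberately
not implemented: the package analyses site density and repertoires,
not target efficacy.

## Differential binding

Per-site signal is counts-per-million by sample library size, averaged
across a condition's replicates; the log2 fold change between
conditions is computed once from the condition means rather than
averaged over per-replicate LFCs, which is more stable at low counts.
A pseudocount of 1 CPM on both sides of the ratio keeps zero-count
sites finite and shrinks noisy low-signal LFCs toward zero; the
shrinkage is below 0.07 log2 units at the count depths simulated here.

CLIP signal confounds binding with transcript abundance, so site LFCs
are corrected by subtracting the transcript's externally measured mRNA
LFC in log2 space (`normalized = raw − mRNA`). Subtraction of log fold
changes — rather than rescaling counts before the ratio — is the
default because the mRNA measurement arrives as a per-transcript log2
value, and subtraction is exact for a multiplicative abundance effect.
Sites on transcripts missing from the mRNA table are excluded loudly
(message plus an `"excluded"` attribute), never silently.

Because only a minority of sites on a UTR are expected to interact,
the per-UTR *extreme* sites (minimal and maximal normalized LFC)
are the candidates examined for interaction signatures. Transcript
classes (co-bound vs bound by one protein only, defined from observed
site sets over an explicit universe) are compared by two-sided
two-sample Kolmogorov–Smirnov tests with asymptotic p-values and no
multiple-testing correction — each figure-level comparison is a single
planned test. ECDF supports are returned for cumulative-distribution
plots.

The miRNA repertoire comparison tallies seed-complement occurrences
per family within two site populations (window 0) and reports the
Spearman rank correlation with average-rank tie handling; a constant
tally vector yields a flagged, undefined correlation.

## Reporter-assay statistics

Dual-luciferase measurements (renilla normalized to firefly within
each well) are filtered by technical-replicate coefficient of
variation with a strict `CV > 0.5` omission rule — a CV of exactly 50%
is kept. A biological replicate survives only if both paired
constructs pass. The wildtype/mutant activity ratio per replicate is
the ratio of technical means; values below 1 indicate a repressive
site. Within a condition, WT vs mutant is a two-tailed paired t-test;
between conditions, WT/mut ratios are compared by two-tailed Welch
t-tests. Both tests run on log2-transformed values by default because
ratios are multiplicative; the raw scale is available behind
`logRatios = FALSE`. An all-zero difference vector (identical WT and
mutant) is degenerate and reported as p = 1 with a flag. Significance
is assessed at 0.05.

## The synthetic-data generator

`simulateExperiment()` produces a complete, fully ground-truthed test
bed emulating the reciprocal-perturbation design:

* **UTRs**: 600 features of 500–1500 nt with i.i.d. uniform base
  composition, so background motif rates are closed-form
  (`(L − 7)/4^7` expected perfect PUM motifs per UTR) and scanner
  recovery is exactly testable.
* **Sites**: 3 AGO2 sites per UTR placed in disjoint equal segments
  (same-protein sites never overlap); each PUM paralog binds a
  deterministic half of the UTRs with 2 sites each, of which exactly
  half overlap a randomly chosen AGO2 site by 10 nt and the rest are
  placed avoiding AGO2. Peak widths are 30–50 nt, typical of CLIP
  clusters. Class fractions are assigned deterministically before any
  noise, so ground-truth frequencies match the configuration exactly.
* **Coupling**: on PUM2-co-bound UTRs one AGO2 site is cooperative
  (mean count × 2^−1 upon PUM knockdown) and one antagonistic
  (× 2^+1); PUM sites overlapping AGO2 are cooperative upon DICER
  loss. An effect of 1 log2 unit with ≥ 200 UTRs per class is the
  regime in which the class-level KS comparisons are expected to
  resolve clearly.
* **Counts**: negative-binomial with dispersion size 10 (clearly
  over-dispersed relative to Poisson, as collapsed CLIP ligation
  counts are) around log-normal per-site baselines (median 50,
  sdlog 0.5) across 3 replicates per condition. All libraries have
  equal nominal depth (10^6), so CPM scaling is exercised without
  introducing composition bias between conditions and planted effects
  are recovered on their stated scale.
* **mRNA contamination**: transcript-level LFCs are drawn separately
  (noise SD 0.2; PUM2-bound transcripts gain +0.4 upon PUM knockdown,
  reflecting release from PUM-mediated decay) and multiply the
  perturbed-condition count means — so raw site LFCs are genuinely
  contaminated and the normalization step does real work.
* **Sequence planting**: a perfect PUM motif is written 2 nt into each
  PUM site and one miRNA seed 8mer at each AGO2 site center, the
  family drawn from a fixed geometric abundance profile over four
  well-known abundant miRNAs (let-7a, miR-17, miR-21, miR-25) shared
  across site populations — which is what makes the repertoire
  correlation between overlapping and non-overlapping AGO2 sites high
  by construction. Deterministically anchored plants that would
  collide (rare geometric corner cases) are skipped and excluded from
  the ground-truth table; random plants redraw up to a bounded retry
  count.

What the generator does **not** emulate: dinucleotide or GC
composition structure, crosslink-induced mutation signatures, UMI
artifacts, peak-calling uncertainty, shared-motif competition between
the PUM paralogs, or transcript expression differences affecting site
detectability. Passing tests therefore demonstrate that the statistics
recover planted structure under a clean generative model — not that
any particular biological dataset will show these effects.

## Numerical choices and degenerate inputs

* RNG: every stochastic function takes a single integer seed and
  restores the caller's RNG state; `NULL` draws from the ambient
  stream so composite workflows (`runPipeline`,
  `simulateExperiment`) are reproducible from one top-level seed.
* Uniform integer draws use `floor(runif(n) * k)` with clipping, exact
  for all host lengths used here.
* KS tests use the asymptotic p-value uniformly (tied values warn in
  `stats::ks.test`; the warning is suppressed since site LFCs are
  continuous and ties arise only in degenerate fixtures).
* Zero-variance t-test inputs are flagged degenerate: all-zero
  differences give p = 1, constant non-zero differences p = 0.
* Empty inputs: empty site files read to empty sets; empty feature
  files to empty universes; density profiles require a non-empty
  reference set; overlap z-scores require both sets non-empty.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at its
default scale (600 UTRs, 1800 AGO2 + 2 × 600 PUM sites) for
class-comparison checks; scanner–oracle agreement uses 1000 random
200-nt sequences; null-calibration checks use 500 replicate
experiments of 100 randomizations each on a 20-host fixture; density
envelope calibration uses 15 independent uniform query draws with
100-randomization envelopes. These sizes were chosen so every
statistical tolerance is dominated by the documented Monte-Carlo error
rather than by fixture size.

## Known limitations

* The within-host null conditions on observed site widths and counts;
  it does not model GC- or length-matched backgrounds (explicitly out
  of scope).
* mRNA normalization trusts the external mRNA LFC table; measurement
  error in that table propagates 1:1 into normalized site LFCs.
* The repertoire correlation is only as informative as the supplied
  miRNA list; with few families the Spearman statistic is coarse.
* De novo motif discovery is not implemented; scanning is limited to
  the consensus/degenerate PUM element and canonical seed types.
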