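---
title: "Methods: linking RBP binding to aberrant splicing in ALS models"
author: "clipsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking RBP binding to aberrant splicing in ALS models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

ALS motor neurons accumulate insoluble RNA-binding proteins (RBPs) such as
NOVA1, NOVA2 and RBFOX2. When an RBP is sequestered, its position-dependent
control of alternative splicing degrades, and the direction of the
resulting splicing changes depends on *where* the protein binds relative to
the affected cassette exon (the "RNA map": binding in the upstream intron
versus the alternative exon versus the downstream intron predicts opposite
inclusion outcomes). `clipsplice` implements the downstream inference chain
that connects these observations:

1. a **proteomic insolubility screen** with an exhaustive shuffled-label
   null (module `insolubility`),
2. **cassette-exon table handling** for rMATS-dialect junction-count
   output: coverage filtering, significance calling, canonical event keys,
   cross-dataset joins (module `as_events`),
3. **CLIP peak handling**: thresholds, sharing, a simplified region
   annotator and k-mer Z-scores (module `clip_peaks`),
4. **strand-aware positional enrichment** of peaks at splicing events
   (module `splice_enrichment`),
5. **k-means signature clustering** of cross-dataset delta-PSI profiles
   into gain/loss-of-function patterns (module `signature_clustering`),
6. **single-neuron fluorescence quantification** and the NOVA1/STMN2
   expression analysis (module `tissue_quant`),
7. seeded **synthetic-data generators** with planted, recoverable
   structure for every input (module `synthetic_data`).

The repository is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers over the package functions and
write their tables under `results/`; all computation lives in `R/` where the
tests and `scripts/acceptance.R` exercise it.

## Statistical core

**Exact Mann-Whitney U.** Pairwise comparisons use the two-sided
Mann-Whitney U test. For small samples the null distribution of U is
enumerated over all `choose(n1+n2, n1)` group assignments of the pooled
midranks, which handles ties exactly; the two-sided P is twice the smaller
tail, capped at 1. This reproduces the printed anchor values for forced
complete separation: P = 2/70 ≈ 0.0286 at 4 vs 4 and P = 2/10 = 0.2000 at
2 vs 3 — the smallest attainable two-sided P at those sample sizes. The
exact path is taken when the combined n ≤ 12 or the assignment count is at
most 10^6; beyond that a tie-corrected normal approximation with
continuity correction is used, and every result carries a `method` tag.

**Hypergeometric enrichment.** For a region R, with N coverage-passed
background events of which K carry ≥ 1 peak in R, and n selected
(significant, direction-filtered) events of which k carry a peak, the
enrichment P value is the upper tail P(X ≥ k), X ~ Hypergeometric(N, K, n),
and fold enrichment is (k/n)/(K/N). The tail includes the observed count.
`stats::phyper` supplies the stable tail; Fisher's exact test (conditional
two-sided, with the *sample* odds ratio ad/bc rather than the conditional
MLE) handles 2×2 overlap questions; Kruskal-Wallis and Welch's t come from
base R. The per-protein Welch test of the insolubility screen is a
vectorized reimplementation of the same statistic (validated against
`t.test` to 10^-10) because the shuffle null runs it 400 × 1000 times.

## Conventions that matter

**Coordinates** are 0-based half-open throughout (rMATS `exonStart_0base`,
BED). **Overlap** always means: same strand, at least one shared base.

**Sign of delta-PSI.** Group 1 is the control condition and group 2 the
target, so negative delta-PSI (IncLevelDifference) means the exon is
*included* in the target condition, positive means *excluded*. Significant
events have |dPSI| > 0.1, so direction is always defined.

**Genomic-left flanks vs transcript orientation.** rMATS "upstream" and
"downstream" flank columns are genomic-left and genomic-right regardless
of strand. `event_regions()` restores transcript orientation: on the minus
strand the transcript-level upstream exon/intron are the genomically right
ones, with coordinates unchanged. This is the single most consequential
convention in the package and is pinned by a mirror-invariance test:
reflecting every coordinate (x → L−x) and flipping every strand leaves
every enrichment result identical.

**Event keys.** Two rMATS runs annotate the same junction with different
flank extents, so the canonical key uses only the four junction-defining
coordinates (chromosome, strand, left-flank end, alternative-exon
boundaries, right-flank start) and deliberately excludes flank outer
boundaries. Duplicate keys within one table keep the row with the larger
total junction support (deterministic, logged).

**Thresholds.** Coverage requires IJC+SJC ≥ 10 in *every* sample
(inclusive); significance requires FDR < 0.05 and |dPSI| > 0.1 (both
strict); peak significance requires log2(FC) > 5 and −log10(P) > 5 for
TDP-43 and > 3/> 3 for NOVA1/NOVA2/RBFOX2 (strict). The insolubility
fold-change cutoff is ≥ 1.5 (inclusive): the source methods say "greater
than 1.5" while the results say "≥ 1.5"; we implement the inclusive form
and expose `fc_strict` to flip it. The choice never matters for continuous
fold changes.

**Coverage definition.** "Covered with at least 10 counts in each sample"
is read as the per-replicate total junction evidence IJC + SJC ≥ 10 — the
total support for the event in that sample — rather than requiring each
junction class separately; the alternative would conflate low coverage
with extreme PSI.

## Design choices where the design was open

* **Missing values in the delta-PSI matrix** are imputed with 0 ("no
  change") before k-means; the imputation mask is kept so cluster medians
  can exclude imputed entries (used when ≥ 50% of a cluster's entries are
  observed). Zero-imputation is conservative: it shrinks absent events
  toward the uninformative center rather than inventing signal.
* **Signature rule.** Cluster medians with |median| ≥ 0.025 count as
  changes. LOF: all ALS medians share a sign, the knock-out median agrees,
  the over-expression median opposes. GOF is the mirror. The source
  describes these patterns qualitatively; the 0.025 magnitude is our
  formalization and is configurable.
* **k-means determinism.** The published configuration (k = 8, random
  init, n_init = 10, max_iter = 300, seed = 42) is the default. Note that
  restart-based k-means finds the global optimum only up to
  initialization: permuting input rows changes which rows seed the
  restarts, so partition-level invariance holds reliably only with many
  restarts (the test suite uses n_init = 100 for that property). With the
  default seed the pipeline is bit-deterministic.
* **Shuffle null.** The screen's specificity control enumerates every
  balanced mixed split (3 target + 3 control per side for 6 vs 6; 400
  splits) rather than sampling "iterations"; exhaustive enumeration is
  cheap and removes Monte-Carlo noise. A guard drops any split that
  reproduces the true labeling; among balanced mixed splits none can, so
  all 400 are informative.
* **k-mer background.** The Z-score compares foreground k-mer frequencies
  against empirical frequencies of user-supplied background sequences
  (one-sample binomial approximation; background k-mers never observed get
  pseudo-frequency 1/(N_bg + 4^k)). The original background construction
  is unpublished; supplying the background explicitly keeps the choice
  visible.
* **Region annotation priority** is CDS > 3'UTR > 5'UTR > noncoding exon >
  intron > intergenic, ties broken by longest overlap; the external
  annotator's exact ordering is unpublished, so the priority is a
  configurable argument.
* **Tubulin normalizer.** The beta-III-tubulin reference is the MFI of the
  *lipofuscin-free soma* — the nucleus is deliberately *included* (only
  lipofuscin is subtracted), matching the stated normalizer. Negative
  computed cytoplasmic MFIs (measurement noise) clamp to 0 with a flag.
* **Nested ANOVA / mixed models** used for postmortem group comparisons
  are replaced by patient-level aggregation (per-patient medians) plus
  exact nonparametric tests — an exact sign-flip permutation test on the
  paired per-patient medians for the matched TDP-43 comparison. This
  changes P values but not directions, and avoids parametric assumptions
  the imaging data do not support.
* **Multi-dataset expression pooling** uses control-anchored z-scores per
  dataset (z = (x − mean_ctrl)/sd_ctrl); the NOVA1–STMN2 correlation is
  computed on z-scores whenever the table spans more than one dataset,
  since raw values from different platforms are not rank-comparable after
  pooling.

## What the synthetic data emulate — and what they do not

Each generator plants structure that the corresponding pipeline stage must
recover, and retains a truth table:

* `gen_rmats`: per-replicate PSI ~ Beta around group means (concentration
  100), junction counts binomial at Poisson depth (default 100) with
  inclusion/skipping form lengths 98/49, P from a two-sample location test
  on per-replicate PSI, FDR by Benjamini-Hochberg, a configurable fraction
  of events with planted |dPSI| effects (default 0.2 at 0.3).
* `gen_splicing_family`: seven datasets (four ALS anchors, SPG11, NOVA1
  over-expression and knock-out) over one shared coordinate set, with
  eight planted cluster patterns including the LOF pattern (exclusion in
  ALS and knock-out, inclusion under over-expression) at |dPSI| 0.25.
* `gen_peaks`: background peaks uniform over junction spans (rate 0.1 per
  event), planted peaks inside a chosen transcript-oriented sub-region of
  chosen events (rate 0.6), scores strictly above the significance
  thresholds, strands inherited from events.
* `gen_lfq`: Gaussian log2 intensities (baseline N(20, 2), sample noise
  SD 0.5), 50 of 1000 proteins with +2 log2 effect in the target group,
  2% zero-inflation for non-detection; 6 vs 6 samples as in the screen.
* `gen_mn_cohort`: compartment MFIs drawn per channel and the soma MFI
  assembled from the exact area-weighted conservation identity; lognormal
  per-patient technical factor (SD 0.5) on all channels; per-neuron shared
  staining factor (SD 0.08); channel variability SD 0.25 for NOVA1/TDP-43
  and 0.08 for beta-III-tubulin (its uniform structural expression is
  precisely why it works as a normalizer); planted effects follow the
  disease pattern (nuclear NOVA1 × 0.7 in TDP-43-lost neurons, cytoplasmic
  NOVA1 × 1.5 in retained sALS neurons, nuclear TDP-43 × 0.3 when lost).
* `gen_expression`: control-anchored NOVA1/STMN2 with a Gaussian-copula
  correlation (0.7) in the disease group only and a planted STMN2-low
  subgroup near z = −3.
* `gen_sequences`: uniform-composition background and foreground with one
  planted motif occurrence per sequence ("TCAT" echoing the NOVA YCAY
  preference; "GCATG" the RBFOX motif).

The generators model *statistical* structure, not biology: the splicing P
values come from a location test rather than a splicing likelihood model
(the pipeline only consumes table columns); peaks are placed uniformly
within regions rather than at motif positions; LFQ intensities have no
correlation structure across proteins; neurons are exchangeable within a
patient. Passing tests therefore demonstrate that the inference chain
recovers planted effects under controlled noise — not that it would be
well-calibrated against every pathology of real data (batch structure,
heavy-tailed intensities, segmentation errors).

## Numerical and calibration notes

* Problem sizes in the tests are chosen to keep the full suite within a
  few minutes: 300–800 events per synthetic dataset, 100-seed recovery
  loops, 1000-rep type-I calibrations. Each scale is stated in the test
  that uses it.
* Hypergeometric P values over the 10 (region × direction) cells are
  discrete and correlated; under a uniform-peak null the *minimum* cell is
  below 0.05 in roughly a quarter of runs purely from multiplicity, so
  null calibration is asserted at the 10^-4 level (no cell below 10^-4 in
  ≥ 90% of null runs), the same level used for the per-cluster maps.
* A 95% interval excludes 5% of realizations by construction, so the
  shuffle-null coverage test allows the binomially expected number of
  misses over its seeds instead of demanding 100% coverage.
* Degenerate inputs are contracts, not surprises: empty significant sets,
  zero-variance proteins (P = 1), zero-length introns (span dropped),
  abutting exons, zero lipofuscin area (two-term MFI formula), constant
  expression (error), groups below minimum size (error).

## Known limitations

* The simplified region annotator assigns one class per peak by fixed
  priority; the external tool it replaces may order classes differently.
* `proximal_window_enrichment` exposes the window size as a free
  parameter; the original sub-window sizes are unpublished.
* The cluster-signature classifier is one formalization of qualitative
  labels; clusters near the 0.025 magnitude boundary can flip label under
  resampling.
* Junction-span intersection is used for the whole-event analyses
  (the span between the outer flank boundaries), which includes flanking
  exons and both introns; analyses needing finer resolution should use the
  per-region profile.
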