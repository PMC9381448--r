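# clipsplice

Tools for the downstream inference chain that links RNA-binding-protein
(RBP) insolubility to aberrant alternative splicing in ALS motor-neuron
models: a label-free proteomics insolubility screen with an exhaustive
shuffled-label null, rMATS-dialect cassette-exon filtering and
cross-dataset comparison, strand-aware positional enrichment of CLIP peaks
at splicing events, k-mer motif Z-scores, k-means clustering of
multi-dataset ΔPSI profiles into NOVA1 gain/loss-of-function signatures,
and single-neuron immunofluorescence quantification — all exercisable on
seeded synthetic data with planted, recoverable structure.

## Who this is for

Groups analyzing cassette-exon (skipped-exon) rMATS output together with
eCLIP peak files who want reproducible, tested implementations of the
standard downstream steps: which events are covered and significant, where
an RBP binds relative to the exons it regulates, whether disease splicing
mimics RBP over-expression or depletion, and whether imaging or expression
readouts support the mechanism.

## The statistics at the core

**Positional enrichment (RNA map).** Each cassette event decomposes into
five transcript-oriented sub-regions (upstream exon, upstream intron,
alternative exon, downstream intron, downstream exon). With N background
events (all that pass the ≥ 10-counts-per-sample coverage filter), K of
which carry ≥ 1 significant peak in region R, and n selected events
(FDR < 0.05, |ΔPSI| > 0.1, optionally split by direction: ΔPSI < 0 =
included in the target condition, ΔPSI > 0 = excluded), k of which carry a
peak, the enrichment P value is the hypergeometric upper tail

    P = P(X ≥ k),  X ~ Hypergeom(N, K, n),   fold = (k/n) / (K/N).

rMATS reports genomic-left/right flanks, so on the minus strand the
transcript-level "upstream" region is the genomically right one; the
package restores orientation and pins the convention with a
mirror-invariance test.

**Insolubility screen.** Per protein, fold change =
mean(LFQ+1)_target / mean(LFQ+1)_control, significance by two-sided
Welch's t on log2(LFQ+1); a hit needs P < 0.05 and fold ≥ 1.5. Specificity
comes from enumerating all 400 balanced mixed label splits (3+3 vs 3+3)
and re-running the identical screen on each.

**Exact small-sample tests.** Two-sided Mann-Whitney U by full enumeration
with midranks (P = 2/70 ≈ 0.0286 for 4 vs 4 complete separation), exact
Fisher 2×2 with the sample odds ratio, Kruskal-Wallis with pairwise
rank-sum follow-up, Spearman correlation.

## Worked example

The numbered scripts under `analysis/` run the whole chain on a simulated
workspace (`Rscript analysis/01_simulate.R` through
`analysis/06_tissue.R`). A condensed version:

```r
library(clipsplice)

# simulate a 7-dataset splicing family with a planted LOF cluster
fam <- gen_splicing_family(20260923)
cov <- lapply(fam$datasets, coverage_filter)
am  <- assemble_matrix(cov, anchors = paste0("ALS", 1:4))
km  <- run_kmeans(am$matrix, k = 8, n_init = 10, seed = 42)
md  <- cluster_medians(am$matrix, km$labels, am$imputed)
meds <- md[md$cluster == 4, ]
classify_signature(setNames(meds$median_dpsi, meds$dataset),
                   paste0("ALS", 1:4), "NOVA1_OE", "NOVA1_KO")
#> [1] "LOF"
```

Running the drivers prints, among others:

```
Observed 48 insoluble-enriched proteins (of 1000).
Shuffled-label null over 400 mixed splits: mean 9.3 hits; observed/null = 5.2-fold.
Strongest overlap: ALS3 vs ALS4 (OR = 201.0, Fisher P = 3.7e-87, rho = 0.58).
Top 4-mer: TCAT (z = 101.0).
  cluster 4 (n=40): LOF
Strongest binding enrichment: cluster 4 at the upstream_intron (fold 7.2, P = 3.5e-21).
Matched NOVA1 nucleus MFI by TDP-43 status: higher_when_retained (n=9 patients, P = 0.00391).
NOVA1-STMN2 Spearman in ALS: rho = 0.84 (P = 4.4e-14).
```

Reading: the planted insoluble proteins stand ~5-fold above the shuffled
null; the disease datasets share splicing changes; the NOVA motif ranks
first among 4-mers; one k-means cluster shows exon exclusion in all ALS
datasets and in NOVA1 knock-out but inclusion under over-expression (a
loss-of-function signature) and concentrates NOVA1 binding in the upstream
intron; nuclear NOVA1 drops in neurons that lost nuclear TDP-43; and NOVA1
correlates with STMN2 only in disease samples.

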