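#!/usr/bin/env Rscript
# Builds the demo workspace: a miniature of the study's dataset roster.
# Four "ALS" cassette-exon tables, one SPG11-HSP table, NOVA1
# over-expression and knock-out tables (all sharing event coordinates so
# they join by key), two NOVA1 eCLIP peak replicates, an insoluble-fraction
# LFQ matrix, a postmortem motor-neuron imaging cohort, and NOVA1/STMN2
# expression tables. Everything is seeded and regenerable.

suppressMessages(library(clipsplice))
seed <- 20260923
dir.create("results/simdata", recursive = TRUE, showWarnings = FALSE)

message("Simulating the splicing dataset family ...")
fam <- gen_splicing_family(seed, n_per_cluster = 40, n_null = 120)
for (nm in names(fam$datasets)) {
  write_rmats(fam$datasets[[nm]],
              file.path("results/simdata", paste0(nm, ".SE.MATS.JC.txt")))
}
readr::write_tsv(fam$truth, "results/simdata/splicing_truth.tsv")

message("Planting NOVA1 peaks in the upstream introns of LOF events ...")
cov1 <- coverage_filter(fam$datasets$ALS1)
lof_keys <- fam$truth$event_key[fam$truth$planted_cluster == 1]
for (rep in 1:2) {
  gp <- gen_peaks(cov1, seed + rep,
                  planted_keys = intersect(lof_keys, cov1$event_key),
                  planted_region = "upstream_intron", plant_rate = 0.6,
                  background_rate = 0.1, rbp = "NOVA1")
  write_peaks(gp$peaks,
              sprintf("results/simdata/NOVA1_rep%d.peaks.bed", rep))
}

message("Simulating the insoluble-fraction LFQ matrix (6 ALS vs 6 Ctrl) ...")
lfq <- gen_lfq(seed)
m <- cbind(protein = rownames(lfq$intensities),
           as.data.frame(lfq$intensities))
readr::write_csv(m, "results/simdata/lfq_insoluble.csv")
readr::write_csv(tibble::tibble(sample = colnames(lfq$intensities),
                                group = lfq$groups),
                 "results/simdata/lfq_groups.csv")
readr::write_csv(lfq$truth, "results/simdata/lfq_truth.csv")

message("Simulating the postmortem motor-neuron cohort (7 Ctrl, 9 sALS) ...")
mn <- gen_mn_cohort(seed)
readr::write_csv(mn, "results/simdata/mn_cohort.csv")

message("Simulating NOVA1/STMN2 expression tables ...")
expr <- gen_expression(seed)
readr::write_csv(expr, "results/simdata/expression.csv")

message("Simulating eCLIP peak sequences for k-mer analysis ...")
sq <- gen_sequences(seed, n_fg = 2000, n_bg = 2000, motif = "TCAT")
write_fasta_seqs(sq$fg, "results/simdata/peaks_fg.fa", "peak")
write_fasta_seqs(sq$bg, "results/simdata/peaks_bg.fa", "bg")

message("Done: results/simdata/")
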