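#!/usr/bin/env Rscript
# RNA-map style positional enrichment: NOVA1 peaks at cassette-exon
# sub-regions, stratified by splicing direction, against all
# coverage-passed events as background; plus k-mer Z-score enrichment of
# peak sequences over background sequences.

suppressMessages(library(clipsplice))
dir.create("results", showWarnings = FALSE)

ev <- index_events(read_rmats("results/simdata/ALS1.SE.MATS.JC.txt"))
cov <- coverage_filter(ev)
sig <- call_significant(cov)

profiles <- list()
for (rep in 1:2) {
  peaks <- read_peaks(sprintf("results/simdata/NOVA1_rep%d.peaks.bed", rep))
  peaks <- threshold_peaks(peaks, default_peak_threshold("NOVA1"))
  pp <- positional_profile(sig, cov, peaks)
  pp$replicate <- rep
  profiles[[rep]] <- pp
}
profile <- dplyr::bind_rows(profiles)
readr::write_tsv(profile, "results/enrichment_profile.tsv")
cells <- profile[profile$direction != "all", ]
best <- cells[which.min(cells$p_hypergeom), ]
message(sprintf(
  "Strongest positional enrichment: %s / %s events (fold %.1f, P = %.2g).",
  best$region, best$direction, best$fold_enrichment, best$p_hypergeom))

# proximal window scan on the upstream intron
win <- proximal_window_enrichment(sig, cov, threshold_peaks(
  read_peaks("results/simdata/NOVA1_rep1.peaks.bed"),
  default_peak_threshold("NOVA1")), "upstream_intron", 250,
  direction = "all")
message(sprintf("Upstream-intron 250 bp proximal window: fold %.1f, P = %.2g.",
                win$fold_enrichment, win$p_hypergeom))

# k-mer preferences of the peak sequences
fg <- read_fasta_seqs("results/simdata/peaks_fg.fa")
bg <- read_fasta_seqs("results/simdata/peaks_bg.fa")
for (k in c(4, 6)) {
  ke <- kmer_enrichment(fg, bg, k)
  readr::write_tsv(ke, sprintf("results/kmer_z_%dmer.tsv", k))
  message(sprintf("Top %d-mer: %s (z = %.1f).", k, ke$kmer[1], ke$z[1]))
}
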