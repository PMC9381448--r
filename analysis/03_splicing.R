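#!/usr/bin/env Rscript
# Cassette-exon analysis: parse the rMATS-dialect tables, apply the
# >= 10-counts-per-sample coverage filter, call significant events
# (FDR < 0.05, |dPSI| > 0.1), and compare datasets pairwise: Fisher
# overlap of significance calls and Spearman correlation of dPSI on the
# joined coverage-passed background.

suppressMessages(library(clipsplice))
dir.create("results", showWarnings = FALSE)

ds_names <- c(paste0("ALS", 1:4), "SPG11", "NOVA1_OE", "NOVA1_KO")
tables <- lapply(ds_names, function(nm)
  index_events(read_rmats(
    file.path("results/simdata", paste0(nm, ".SE.MATS.JC.txt")))))
names(tables) <- ds_names

cov <- lapply(tables, coverage_filter)
sig <- lapply(cov, call_significant)
counts <- tibble::tibble(
  dataset = ds_names,
  parsed = vapply(tables, nrow, integer(1)),
  coverage_passed = vapply(cov, nrow, integer(1)),
  significant = vapply(sig, nrow, integer(1)))
readr::write_tsv(counts, "results/splicing_counts.tsv")
message("Events per dataset (parsed / covered / significant):")
print(as.data.frame(counts))

for (nm in ds_names)
  write_event_table(sig[[nm]],
                    file.path("results", paste0(nm, ".significant.tsv")))

pairs <- t(utils::combn(ds_names, 2))
rows <- lapply(seq_len(nrow(pairs)), function(i) {
  a <- pairs[i, 1]; b <- pairs[i, 2]
  j <- join_datasets(cov[[a]], cov[[b]])
  ov <- overlap_test(j, j$event_key %in% sig[[a]]$event_key,
                     j$event_key %in% sig[[b]]$event_key)
  co <- dpsi_correlation(j)
  tibble::tibble(dataset_a = a, dataset_b = b, n_joined = nrow(j),
                 n_sig_both = ov$n_both, odds_ratio = ov$odds_ratio,
                 p_fisher = ov$p_fisher, spearman_rho = co$rho,
                 spearman_p = co$p)
})
pairwise <- dplyr::bind_rows(rows)
readr::write_tsv(pairwise, "results/splicing_pairwise.tsv")
best <- pairwise[which.min(pairwise$p_fisher), ]
message(sprintf(
  "Strongest overlap: %s vs %s (OR = %.1f, Fisher P = %.2g, rho = %.2f).",
  best$dataset_a, best$dataset_b, best$odds_ratio, best$p_fisher,
  best$spearman_rho))
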