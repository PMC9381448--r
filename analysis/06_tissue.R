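#!/usr/bin/env Rscript
# Postmortem tissue analysis: lipofuscin-corrected cytoplasmic MFI,
# soma-size filter, within-patient matched TDP-43 comparison,
# beta-III-tubulin normalization with its variance-reduction readout, and
# the NOVA1-STMN2 z-score analysis with the STMN2-low subgroup.

suppressMessages(library(clipsplice))
dir.create("results", showWarnings = FALSE)

mn <- readr::read_csv("results/simdata/mn_cohort.csv",
                      show_col_types = FALSE)
mn <- soma_filter(mn)
message(sprintf("%d motor neurons pass the 1000 um^2 soma filter.",
                nrow(mn)))

aug <- mn
for (ch in c("NOVA1", "TDP43")) {
  aug[[paste0("mfi_cytoplasm_", ch)]] <- mfi_cytoplasm(mn, ch)$mfi_cytoplasm
  for (comp in c("nucleus", "cytoplasm"))
    aug[[paste0("norm_", comp, "_", ch)]] <-
      tubulin_normalize(mn, ch, comp)
}
readr::write_csv(aug, "results/mn_quantified.csv")

sals <- mn[mn$cohort == "sALS", ]
tests <- list()
for (comp in c("nucleus", "cytoplasm")) {
  mt <- matched_tdp43_comparison(sals, "NOVA1", comp)
  message(sprintf(
    "Matched NOVA1 %s MFI by TDP-43 status: %s (n=%d patients, P = %.3g).",
    comp, mt$direction, mt$n_patients, mt$p_two_sided))
  tests[[paste0("matched_", comp)]] <-
    list(direction = mt$direction, n_patients = mt$n_patients,
         p = mt$p_two_sided)
}

ctrl <- mn[mn$cohort == "Ctrl", ]
for (comp in c("nucleus", "cytoplasm")) {
  red <- interindividual_variance_reduction(ctrl, "NOVA1", comp)
  message(sprintf(
    "Tubulin normalization reduces Ctrl inter-individual variance (%s NOVA1) by %.0f%%.",
    comp, red))
  tests[[paste0("variance_reduction_", comp, "_pct")]] <- red
}

expr <- readr::read_csv("results/simdata/expression.csv",
                        show_col_types = FALSE)
z <- stmn2_grouping(expression_zscores(expr))
readr::write_csv(z, "results/expression_zscores.csv")
message(sprintf("%d of %d ALS samples fall in the STMN2-low group (z < -2).",
                sum(z$stmn2_class == "low"), sum(z$group == "ALS")))
for (grp in c("ALS", "Ctrl")) {
  co <- nova1_stmn2_correlation(z, grp)
  message(sprintf("NOVA1-STMN2 Spearman in %s: rho = %.2f (P = %.2g).",
                  grp, co$rho, co$p))
  tests[[paste0("nova1_stmn2_", tolower(grp))]] <-
    list(rho = co$rho, p = co$p)
}
three <- nova1_stmn2_correlation(z, "ALS", three_group = TRUE)
tests$three_group_kruskal_p <- three$kruskal$p_two_sided
jsonlite::write_json(tests, "results/tissue_tests.json",
                     auto_unbox = TRUE, digits = NA)
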