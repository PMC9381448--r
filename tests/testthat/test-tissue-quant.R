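mn_record <- function(mfi_soma = 10, area_soma = 2000, mfi_nuc = 20,
                      area_nuc = 500, mfi_lip = 30, area_lip = 100,
                      patient = "P1", cohort = "sALS",
                      status = "nuclear_retained") {
  tibble::tibble(
    patient_id = patient, cohort = cohort, tdp43_status = status,
    area_soma = area_soma, area_nucleus = area_nuc,
    area_lipofuscin = area_lip,
    mfi_soma_NOVA1 = mfi_soma, mfi_nucleus_NOVA1 = mfi_nuc,
    mfi_lipofuscin_NOVA1 = mfi_lip,
    mfi_soma_TDP43 = mfi_soma, mfi_nucleus_TDP43 = mfi_nuc,
    mfi_lipofuscin_TDP43 = mfi_lip,
    mfi_soma_TUBB3 = mfi_soma, mfi_nucleus_TUBB3 = mfi_nuc,
    mfi_lipofuscin_TUBB3 = mfi_lip
  )
}

test_that("cytoplasmic MFI follows the area-weighted correction formula", {
  # (10*2000 - 20*500 - 30*100) / 1400 = 5
  r <- mfi_cytoplasm(mn_record(), "NOVA1")
  expect_equal(r$mfi_cytoplasm, 5.0)
  expect_false(r$clamped)

  # uniform intensity c everywhere stays c, any areas
  u <- mn_record(mfi_soma = 7, mfi_nuc = 7, mfi_lip = 7)
  expect_equal(mfi_cytoplasm(u, "NOVA1")$mfi_cytoplasm, 7)

  # no lipofuscin reduces to the two-term formula
  nolip <- mn_record(area_lip = 0, mfi_lip = 0)
  expect_equal(mfi_cytoplasm(nolip, "NOVA1")$mfi_cytoplasm,
               (10 * 2000 - 20 * 500) / 1500)

  # negative result clamps to zero with a flag
  neg <- mn_record(mfi_soma = 5, mfi_nuc = 30)
  r2 <- mfi_cytoplasm(neg, "NOVA1")
  expect_equal(r2$mfi_cytoplasm, 0)
  expect_true(r2$clamped)

  expect_error(mfi_cytoplasm(mn_record(area_nuc = 1950, area_lip = 100),
                             "NOVA1"), "cytoplasmic area")
})

test_that("the conservation identity holds exactly on generated cohorts", {
  mn <- gen_mn_cohort(61, n_ctrl = 3, n_sals = 3, neurons_per_patient = 10)
  for (ch in c("NOVA1", "TDP43", "TUBB3")) {
    cyt <- mfi_cytoplasm(mn, ch)
    a_cyt <- mn$area_soma - mn$area_nucleus - mn$area_lipofuscin
    recon <- (cyt$mfi_cytoplasm * a_cyt +
                mn[[paste0("mfi_nucleus_", ch)]] * mn$area_nucleus +
                mn[[paste0("mfi_lipofuscin_", ch)]] * mn$area_lipofuscin) /
      mn$area_soma
    expect_equal(recon, mn[[paste0("mfi_soma_", ch)]], tolerance = 1e-12)
    expect_false(any(cyt$clamped))
  }
})

test_that("soma filter is strictly greater-than", {
  ev <- dplyr::bind_rows(
    mn_record(area_soma = 1000),
    mn_record(area_soma = 1000.1),
    mn_record(area_soma = 999)
  )
  expect_equal(soma_filter(ev)$area_soma, 1000.1)
  expect_equal(nrow(soma_filter(ev[0, ])), 0)
})

test_that("tubulin normalization is scale-invariant and removes patient factors", {
  rec <- mn_record()
  # channel = tubulin over its own lipofuscin-free soma reference -> the
  # reference reproduces itself
  ref <- tubulin_reference(rec)
  expect_equal(ref, (10 * 2000 - 30 * 100) / 1900)

  # multiplying all MFIs of a record by a scalar leaves the value unchanged
  rec2 <- rec
  for (col in grep("^mfi_", names(rec2), value = TRUE))
    rec2[[col]] <- rec2[[col]] * 3.7
  for (comp in c("nucleus", "soma", "cytoplasm")) {
    expect_equal(tubulin_normalize(rec2, "NOVA1", comp),
                 tubulin_normalize(rec, "NOVA1", comp), tolerance = 1e-12)
  }

  zero <- mn_record(mfi_soma = 0, mfi_lip = 0)
  expect_error(tubulin_normalize(zero, "NOVA1", "nucleus"), "zero tubulin")
})

test_that("variance reduction is large with planted patient factors and near zero without", {
  for (s in 1:3) {
    mn <- soma_filter(gen_mn_cohort(s, n_ctrl = 7, n_sals = 0,
                                    neurons_per_patient = 20, tech_sd = 0.5))
    expect_gte(interindividual_variance_reduction(mn, "NOVA1", "cytoplasm"),
               50)
    expect_gte(interindividual_variance_reduction(mn, "NOVA1", "nucleus"),
               50)
  }
  for (s in 1:3) {
    mn <- soma_filter(gen_mn_cohort(s, n_ctrl = 40, n_sals = 0,
                                    neurons_per_patient = 20, tech_sd = 0))
    red <- interindividual_variance_reduction(mn, "NOVA1", "cytoplasm")
    expect_lt(abs(red), 15)
  }
  one <- dplyr::bind_rows(lapply(1:3, function(i) {
    r <- mn_record(patient = paste0("P", i))
    dplyr::bind_rows(r, r, r)
  }))
  # three patients with identical neurons: raw inter-patient variance is 0
  expect_error(interindividual_variance_reduction(one, "NOVA1", "nucleus"),
               "zero raw")
  expect_error(
    interindividual_variance_reduction(mn_record(), "NOVA1", "nucleus"),
    ">= 3 patients")
})

test_that("matched TDP-43 comparison pairs per-patient medians with an exact sign-flip test", {
  # identical status groups in every patient -> P = 1
  same <- dplyr::bind_rows(lapply(1:4, function(i) dplyr::bind_rows(
    mn_record(patient = paste0("P", i), status = "nuclear_retained"),
    mn_record(patient = paste0("P", i), status = "nuclear_lost"))))
  r <- matched_tdp43_comparison(same, "NOVA1", "nucleus")
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$direction, "none")

  expect_error(matched_tdp43_comparison(same[1:2, ], "NOVA1", "nucleus"),
               ">= 3 patients")

  # planted 30% nuclear NOVA1 deficit: direction recovered with P < 0.05
  # in nearly every seeded cohort of 6 patients x 20 neurons
  hits <- vapply(1:10, function(s) {
    mn <- soma_filter(gen_mn_cohort(s, n_ctrl = 0, n_sals = 6,
                                    neurons_per_patient = 20, tech_sd = 0.3,
                                    nuc_nova1_down = 0.7,
                                    lost_fraction_range = c(0.4, 0.6)))
    mt <- matched_tdp43_comparison(mn, "NOVA1", "nucleus")
    mt$direction == "higher_when_retained" && mt$p_two_sided < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("expression z-scores are control-anchored per dataset with strict STMN2-low cutoff", {
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:6), dataset = "D1",
    group = c("Ctrl", "Ctrl", "Ctrl", "ALS", "ALS", "ALS"),
    nova1 = c(8, 10, 12, 10, 10, 10),
    stmn2 = c(8, 10, 12, 10, 4, 6))
  z <- expression_zscores(tab)
  expect_equal(z$z_stmn2[4], 0)          # equals the control mean
  expect_equal(z$z_stmn2[5], -3)         # (4 - 10) / 2
  g <- stmn2_grouping(z)
  expect_equal(g$stmn2_class[5], "low")
  expect_equal(g$stmn2_class[6], "regular")   # z = -2 exactly: strict "<"
  expect_equal(g$stmn2_class[4], "regular")
  expect_true(all(g$stmn2_class[g$group == "Ctrl"] == "regular"))

  const <- tab; const$stmn2[1:3] <- 5
  expect_error(expression_zscores(const), "zero control SD")
  few <- tab[c(1, 4:6), ]
  expect_error(expression_zscores(few), "< 2 control samples")
})

test_that("NOVA1-STMN2 correlation is disease-specific on planted tables", {
  ok <- vapply(1:10, function(s) {
    ex <- stmn2_grouping(expression_zscores(
      gen_expression(s, n_ctrl = 30, n_als = 40, rho = 0.7)))
    a <- nova1_stmn2_correlation(ex, "ALS")
    c0 <- nova1_stmn2_correlation(ex, "Ctrl")
    a$rho > 0.4 && a$p < 0.05 && abs(c0$rho) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.9)

  ex <- stmn2_grouping(expression_zscores(gen_expression(62)))
  r <- nova1_stmn2_correlation(ex, "ALS", three_group = TRUE)
  expect_true(all(c("kruskal", "pairwise") %in% names(r)))
  expect_lt(r$kruskal$p_two_sided, 0.05)   # the planted low group differs
  expect_true("ALS_low" %in% rownames(r$pairwise))

  mono <- tibble::tibble(sample_id = paste0("s", 1:5), dataset = "D",
                         group = "ALS", nova1 = 1:5, stmn2 = (1:5)^3)
  expect_equal(nova1_stmn2_correlation(mono, "ALS")$rho, 1)
  const <- mono; const$nova1 <- 1
  expect_error(nova1_stmn2_correlation(const, "ALS"), "constant")
  expect_error(nova1_stmn2_correlation(mono[1:2, ], "ALS"), ">= 3")
})
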