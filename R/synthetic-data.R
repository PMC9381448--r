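#' @title Seeded synthetic-data generators
#' @description Generators for every pipeline input, each with planted and
#'   therefore recoverable structure: rMATS-dialect cassette-exon tables
#'   with delta-PSI effects and Benjamini-Hochberg FDR structure, CLIP
#'   peaks planted into chosen sub-regions of chosen events, LFQ matrices
#'   with planted insoluble proteins, motor-neuron cohorts with
#'   patient-level technical scaling and TDP-43-status-dependent effects,
#'   NOVA1/STMN2 expression tables with disease-only correlation and an
#'   STMN2-low subgroup, and FASTA sequence sets with planted motifs.
#'
#'   Every generator takes a single seed; sub-streams are derived by a
#'   fixed tag-hash rule so components are independently reproducible.
#'   Generator P values come from a simple two-sample location test on
#'   per-replicate PSI, not from a splicing likelihood model: the pipeline
#'   only consumes the table columns, so generator fidelity matters for
#'   calibration, not for inference.
#' @name synthetic_data
NULL

#' Derive a reproducible child seed from a parent seed and a tag
#' @param seed integer parent seed.
#' @param tag character stream tag.
#' @return integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) %% 1e6 * 2011 + h * 7919) %% 2147483629 + 1)
}

# per-replicate PSI estimate from junction counts, rMATS-style
.psi_from_counts <- function(ijc, sjc, inc_len, skip_len) {
  num <- ijc / inc_len
  den <- num + sjc / skip_len
  ifelse(den == 0, NA_real_, num / den)
}

.gen_event_coords <- function(n_events) {
  chrom <- paste0("chr", sample(1:4, n_events, replace = TRUE))
  strand <- sample(c("+", "-"), n_events, replace = TRUE)
  up_len <- sample(80:300, n_events, replace = TRUE)
  in1_len <- sample(300:1500, n_events, replace = TRUE)
  alt_len <- sample(50:250, n_events, replace = TRUE)
  in2_len <- sample(300:1500, n_events, replace = TRUE)
  dn_len <- sample(80:300, n_events, replace = TRUE)
  # non-overlapping layout per chromosome
  total <- up_len + in1_len + alt_len + in2_len + dn_len + 500
  start <- integer(n_events)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1000, total[i][-length(i)]))
  }
  tibble::tibble(
    event_id = paste0("E", seq_len(n_events)),
    gene_id = paste0("G", seq_len(n_events)),
    gene_symbol = paste0("SYM", seq_len(n_events)),
    chrom = chrom, strand = strand,
    left_flank_start = as.integer(start),
    left_flank_end = as.integer(start + up_len),
    alt_exon_start = as.integer(start + up_len + in1_len),
    alt_exon_end = as.integer(start + up_len + in1_len + alt_len),
    right_flank_start = as.integer(start + up_len + in1_len + alt_len +
                                     in2_len),
    right_flank_end = as.integer(start + up_len + in1_len + alt_len +
                                   in2_len + dn_len)
  )
}

# simulate one dataset (counts, PSI estimates, P, FDR) on fixed coordinates
.sim_dataset <- function(coords, psi1, psi2, n_rep = 4, depth = 100,
                         concentration = 100) {
  n_events <- nrow(coords)
  inc_len <- 98L; skip_len <- 49L
  draw_group <- function(psi_mean) {
    replicate(n_rep, {
      p <- stats::rbeta(n_events, psi_mean * concentration,
                        (1 - psi_mean) * concentration)
      n <- stats::rpois(n_events, depth)
      r <- p * inc_len / (p * inc_len + (1 - p) * skip_len)
      ijc <- stats::rbinom(n_events, n, r)
      cbind(ijc, n - ijc)
    }, simplify = FALSE)
  }
  g1 <- draw_group(psi1); g2 <- draw_group(psi2)
  get_counts <- function(g, col) {
    lapply(seq_len(n_events), function(i)
      vapply(g, function(rep) as.integer(rep[i, col]), integer(1)))
  }
  ijc1 <- get_counts(g1, 1); sjc1 <- get_counts(g1, 2)
  ijc2 <- get_counts(g2, 1); sjc2 <- get_counts(g2, 2)
  lev1 <- lapply(seq_len(n_events), function(i)
    .psi_from_counts(ijc1[[i]], sjc1[[i]], inc_len, skip_len))
  lev2 <- lapply(seq_len(n_events), function(i)
    .psi_from_counts(ijc2[[i]], sjc2[[i]], inc_len, skip_len))
  pv <- vapply(seq_len(n_events), function(i) {
    a <- lev1[[i]][!is.na(lev1[[i]])]; b <- lev2[[i]][!is.na(lev2[[i]])]
    if (length(a) < 2 || length(b) < 2) return(1)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 1e-6)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  dpsi <- vapply(seq_len(n_events), function(i)
    mean(lev1[[i]], na.rm = TRUE) - mean(lev2[[i]], na.rm = TRUE),
    numeric(1))
  events <- dplyr::bind_cols(coords, tibble::tibble(
    ijc_g1 = ijc1, sjc_g1 = sjc1, ijc_g2 = ijc2, sjc_g2 = sjc2,
    inc_form_len = inc_len, skip_form_len = skip_len,
    p_value = pv, fdr = stats::p.adjust(pv, "BH"),
    inc_level_g1 = lev1, inc_level_g2 = lev2,
    inc_level_difference = dpsi))
  index_events(events)
}

#' Generate a synthetic rMATS-dialect cassette-exon dataset
#'
#' Events are laid out non-overlapping along synthetic chromosomes with
#' random strands. Per-replicate PSI is drawn from a Beta around the group
#' mean; junction counts are binomial at a Poisson read depth with the
#' inclusion/skipping form lengths accounted for; the P value is a Welch
#' test on per-replicate PSI and FDR is Benjamini-Hochberg. A configured
#' fraction of events carries a planted delta-PSI effect with random
#' direction (negative observed delta-PSI = inclusion in the target
#' condition, matching the rMATS -b1 control / -b2 target convention).
#'
#' @param seed integer seed.
#' @param n_events number of events (>= 1).
#' @param n_rep replicates per group.
#' @param depth mean junction read depth per replicate.
#' @param effect_fraction fraction of events with a planted effect.
#' @param effect_size absolute planted delta-PSI.
#' @param concentration Beta concentration of replicate PSI around the
#'   group mean (larger = less dispersion).
#' @return list: `events` (internal event tibble, indexed), `truth`
#'   (event_key, is_effect, true_dpsi, direction).
#' @export
gen_rmats <- function(seed, n_events = 400, n_rep = 4, depth = 100,
                      effect_fraction = 0.2, effect_size = 0.3,
                      concentration = 100) {
  stopifnot(n_events >= 1, effect_fraction >= 0, effect_fraction <= 1)
  set.seed(derive_seed(seed, "rmats"))
  coords <- .gen_event_coords(n_events)
  psi1 <- stats::runif(n_events, 0.15, 0.85)
  is_effect <- stats::runif(n_events) < effect_fraction
  dir_up <- stats::runif(n_events) < 0.5   # TRUE: higher PSI in target
  shift <- ifelse(is_effect, ifelse(dir_up, effect_size, -effect_size), 0)
  psi2 <- pmin(pmax(psi1 + shift, 0.02), 0.98)
  events <- .sim_dataset(coords, psi1, psi2, n_rep, depth, concentration)
  truth <- tibble::tibble(
    event_key = events$event_key, is_effect = is_effect,
    true_dpsi = psi1 - psi2,
    direction = ifelse(is_effect, ifelse(dir_up, "included", "excluded"),
                       "none")
  )
  list(events = events, truth = truth)
}

#' Generate a correlated multi-dataset splicing family with planted
#' cluster signatures
#'
#' One master set of event coordinates is shared by every dataset (four
#' disease "ALS" datasets, one unrelated-disease "SPG11" dataset, a NOVA1
#' over-expression and a knock-out dataset), so events join across
#' datasets by key. Events are partitioned into planted clusters, each
#' with a per-dataset true delta-PSI pattern; the first cluster carries
#' the loss-of-function pattern (exclusion in all ALS datasets and in the
#' knock-out, inclusion under over-expression), the second the mirrored
#' gain-of-function pattern, and the remainder dataset-specific, null and
#' mixed patterns. The rMATS sign convention applies: positive observed
#' delta-PSI = exclusion in the target condition.
#'
#' @param seed integer seed.
#' @param n_per_cluster events per planted cluster.
#' @param n_null additional events with no change anywhere.
#' @param effect absolute true delta-PSI of planted changes.
#' @param n_rep,depth,concentration as in [gen_rmats()].
#' @return list: `datasets` (named list of event tibbles: ALS1..ALS4,
#'   SPG11, NOVA1_OE, NOVA1_KO), `truth` (event_key, planted_cluster with
#'   0 = null), `patterns` (cluster x dataset matrix of true delta-PSI).
#' @export
gen_splicing_family <- function(seed, n_per_cluster = 40, n_null = 120,
                                effect = 0.25, n_rep = 4, depth = 100,
                                concentration = 100) {
  set.seed(derive_seed(seed, "family"))
  ds_names <- c(paste0("ALS", 1:4), "SPG11", "NOVA1_OE", "NOVA1_KO")
  e <- effect
  patterns <- rbind(  # rows = planted clusters, cols = datasets
    LOF = c(e, e, e, e, 0, -e, e),
    GOF = c(e, e, e, e, 0, e, -e),
    ds_specific = c(e, -e, e, -e, 0, 0, 0),
    als_only = c(-e, -e, -e, -e, 0, 0, 0),
    als1_spg = c(e, 0, 0, 0, e, 0, 0),
    als2_ko = c(0, e, 0, 0, 0, 0, e),
    als34_oe = c(0, 0, -e, -e, 0, -e, 0),
    broad_inc = c(-e, -e, -e, -e, -e, -e, -e)
  )
  colnames(patterns) <- ds_names
  n_clusters <- nrow(patterns)
  n_events <- n_clusters * n_per_cluster + n_null
  cluster <- c(rep(seq_len(n_clusters), each = n_per_cluster),
               rep(0L, n_null))
  cluster <- sample(cluster)
  coords <- .gen_event_coords(n_events)
  psi1 <- stats::runif(n_events, 0.2, 0.8)
  datasets <- list()
  for (ds in ds_names) {
    delta <- ifelse(cluster == 0, 0, patterns[pmax(cluster, 1), ds])
    psi2 <- pmin(pmax(psi1 - delta, 0.02), 0.98)  # dpsi_obs ~ psi1 - psi2
    datasets[[ds]] <- .sim_dataset(coords, psi1, psi2, n_rep, depth,
                                   concentration)
  }
  list(datasets = datasets,
       truth = tibble::tibble(event_key = datasets[[1]]$event_key,
                              planted_cluster = cluster),
       patterns = patterns)
}

#' Write an internal event table in the rMATS SE.MATS.JC.txt dialect
#'
#' Inverse of [read_rmats()]: writing then reading reproduces the event
#' table (including the canonical key set) exactly.
#'
#' @param events internal event tibble.
#' @param path output TSV path.
#' @export
write_rmats <- function(events, path) {
  fmt_counts <- function(col) vapply(events[[col]], function(v)
    paste(v, collapse = ","), character(1))
  fmt_levels <- function(col) vapply(events[[col]], function(v)
    paste(ifelse(is.na(v), "NA", format(round(v, 9), trim = TRUE,
                                        scientific = FALSE)),
          collapse = ","), character(1))
  out <- tibble::tibble(
    ID = events$event_id, GeneID = events$gene_id,
    geneSymbol = events$gene_symbol, chr = events$chrom,
    strand = events$strand,
    exonStart_0base = events$alt_exon_start, exonEnd = events$alt_exon_end,
    upstreamES = events$left_flank_start, upstreamEE = events$left_flank_end,
    downstreamES = events$right_flank_start,
    downstreamEE = events$right_flank_end,
    IJC_SAMPLE_1 = fmt_counts("ijc_g1"), SJC_SAMPLE_1 = fmt_counts("sjc_g1"),
    IJC_SAMPLE_2 = fmt_counts("ijc_g2"), SJC_SAMPLE_2 = fmt_counts("sjc_g2"),
    IncFormLen = events$inc_form_len, SkipFormLen = events$skip_form_len,
    PValue = events$p_value, FDR = events$fdr,
    IncLevel1 = fmt_levels("inc_level_g1"),
    IncLevel2 = fmt_levels("inc_level_g2"),
    IncLevelDifference = events$inc_level_difference
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Generate CLIP peaks with planted positional structure
#'
#' Background peaks fall uniformly inside the junction span of randomly
#' chosen events; planted peaks fall inside a named transcript-oriented
#' sub-region of a named subset of events. Enrichment scores are drawn
#' strictly above the significance thresholds so thresholding keeps every
#' generated peak; peaks inherit the strand of their event.
#'
#' @param events indexed event tibble with coordinates.
#' @param seed integer seed.
#' @param planted_keys event keys to receive planted peaks.
#' @param planted_region transcript-oriented region label for the plants.
#' @param plant_rate probability a planted-set event receives a peak.
#' @param background_rate probability any event receives a background peak.
#' @param rbp peak name column value.
#' @param score_base minimum log2 fold-change / -log10 P (exclusive).
#' @return list: `peaks` (tibble), `truth` (event_key, planted).
#' @export
gen_peaks <- function(events, seed, planted_keys = character(),
                      planted_region = "upstream_intron", plant_rate = 0.6,
                      background_rate = 0.1, rbp = "NOVA1",
                      score_base = 3) {
  if (!"event_key" %in% names(events)) events <- index_events(events)
  if (!planted_region %in% .region_labels)
    stop("gen_peaks: unknown region label: ", planted_region)
  set.seed(derive_seed(seed, paste0("peaks_", rbp)))
  regions <- event_regions(events)
  place_peak <- function(reg_row, width_range = c(20L, 60L)) {
    w <- sample(seq(width_range[1], width_range[2]), 1)
    w <- min(w, reg_row$end - reg_row$start)
    s <- reg_row$start + sample.int(reg_row$end - w - reg_row$start + 1, 1) - 1L
    tibble::tibble(chrom = reg_row$chrom, start = s, end = s + w,
                   rbp = rbp, score = 0, strand = reg_row$strand,
                   log2_fc = score_base + stats::runif(1, 0.1, 3),
                   neg_log10_p = score_base + stats::runif(1, 0.1, 5))
  }
  peaks <- list()
  bg_events <- events$event_key[stats::runif(nrow(events)) < background_rate]
  for (key in bg_events) {
    reg <- regions[regions$event_key == key &
                   regions$label == "junction_span", , drop = FALSE]
    peaks[[length(peaks) + 1]] <- place_peak(reg[1, ])
  }
  planted_hit <- planted_keys[stats::runif(length(planted_keys)) < plant_rate]
  for (key in planted_hit) {
    reg <- regions[regions$event_key == key &
                   regions$label == planted_region, , drop = FALSE]
    if (nrow(reg) == 0) next                    # zero-length intron dropped
    peaks[[length(peaks) + 1]] <- place_peak(reg[1, ])
  }
  peaks <- if (length(peaks) == 0) empty_peaks() else dplyr::bind_rows(peaks)
  list(peaks = peaks,
       truth = tibble::tibble(event_key = events$event_key,
                              planted = events$event_key %in% planted_hit))
}

#' Generate an LFQ intensity matrix with planted insoluble proteins
#'
#' Log2 intensities are Gaussian per protein with sample-level noise;
#' a planted set of proteins gains `log2_effect` in the target group.
#' A small zero-inflation rate models non-detection.
#'
#' @param seed integer seed.
#' @param n_proteins number of proteins.
#' @param n_per_group samples per group (labels: target "ALS", control
#'   "Ctrl").
#' @param n_effect number of planted hit proteins.
#' @param log2_effect planted log2 intensity gain in the target group.
#' @param noise_sd sample-level log2 noise SD.
#' @param zero_rate probability a measurement is a missing zero.
#' @param base_mean,base_sd protein baseline log2 intensity distribution.
#' @return list: `intensities` (matrix), `groups`, `truth`
#'   (protein, is_effect).
#' @export
gen_lfq <- function(seed, n_proteins = 1000, n_per_group = 6, n_effect = 50,
                    log2_effect = 2, noise_sd = 0.5, zero_rate = 0.02,
                    base_mean = 20, base_sd = 2) {
  stopifnot(n_effect <= n_proteins, zero_rate >= 0, zero_rate < 1)
  set.seed(derive_seed(seed, "lfq"))
  base <- stats::rnorm(n_proteins, base_mean, base_sd)
  n_s <- 2 * n_per_group
  log2m <- matrix(stats::rnorm(n_proteins * n_s, 0, noise_sd),
                  n_proteins, n_s) + base
  is_effect <- c(rep(TRUE, n_effect), rep(FALSE, n_proteins - n_effect))
  is_effect <- sample(is_effect)
  tgt_cols <- seq_len(n_per_group)
  log2m[is_effect, tgt_cols] <- log2m[is_effect, tgt_cols] + log2_effect
  m <- 2^log2m
  m[matrix(stats::runif(length(m)) < zero_rate, nrow(m))] <- 0
  rownames(m) <- paste0("P", seq_len(n_proteins))
  colnames(m) <- c(paste0("ALS_", seq_len(n_per_group)),
                   paste0("Ctrl_", seq_len(n_per_group)))
  list(intensities = m,
       groups = rep(c("ALS", "Ctrl"), each = n_per_group),
       truth = tibble::tibble(protein = rownames(m), is_effect = is_effect))
}

#' Generate a motor-neuron imaging cohort
#'
#' One row per neuron. Compartment MFIs (cytoplasm, nucleus, lipofuscin)
#' are drawn per channel, then the soma MFI is computed from the exact
#' area-weighted conservation identity, so the lipofuscin-corrected
#' cytoplasm recovers the drawn value.
#'
#' Noise structure: (i) a per-patient lognormal technical scale
#' (`tech_sd`) multiplies every MFI of the patient, all channels --
#' postmortem-interval/fixation/storage variability, which tubulin
#' normalization is meant to remove; (ii) a per-neuron shared staining
#' factor (`neuron_shared_sd`) multiplies all channels of one neuron;
#' (iii) channel-compartment biological variability (`channel_sd` for
#' NOVA1/TDP-43, `tubulin_sd` for beta-III-tubulin, whose structural
#' expression is far more uniform -- the property that makes it a usable
#' normalizer). Planted biology: sALS neurons that lost nuclear TDP-43
#' have reduced nuclear NOVA1 (and TDP-43); sALS neurons with retained
#' nuclear TDP-43 have elevated cytoplasmic NOVA1.
#'
#' @param seed integer seed.
#' @param n_ctrl,n_sals patients per cohort.
#' @param neurons_per_patient neurons per patient.
#' @param tech_sd SD of the per-patient lognormal technical factor.
#' @param neuron_shared_sd SD of the per-neuron shared staining factor.
#' @param channel_sd per-compartment lognormal SD for NOVA1 and TDP-43.
#' @param tubulin_sd per-compartment lognormal SD for beta-III-tubulin.
#' @param cyt_nova1_up fold elevation of cytoplasmic NOVA1 in
#'   nuclear-retained sALS neurons.
#' @param nuc_nova1_down fold reduction of nuclear NOVA1 in nuclear-lost
#'   neurons.
#' @param lost_fraction_range range of the per-patient fraction of
#'   nuclear-lost neurons in sALS.
#' @return tibble of neuron records.
#' @export
gen_mn_cohort <- function(seed, n_ctrl = 7, n_sals = 9,
                          neurons_per_patient = 20, tech_sd = 0.5,
                          neuron_shared_sd = 0.08, channel_sd = 0.25,
                          tubulin_sd = 0.08,
                          cyt_nova1_up = 1.5, nuc_nova1_down = 0.7,
                          lost_fraction_range = c(0.3, 0.6)) {
  set.seed(derive_seed(seed, "mn_cohort"))
  base <- list(  # per-channel per-compartment baseline MFIs (a.u.)
    NOVA1 = c(cyt = 40, nuc = 100, lip = 200),
    TDP43 = c(cyt = 30, nuc = 120, lip = 200),
    TUBB3 = c(cyt = 150, nuc = 60, lip = 200)
  )
  patients <- c(sprintf("Ctrl_%d", seq_len(n_ctrl)),
                sprintf("sALS_%d", seq_len(n_sals)))
  cohorts <- rep(c("Ctrl", "sALS"), c(n_ctrl, n_sals))
  n_pat <- length(patients)
  n <- n_pat * neurons_per_patient
  pat_idx <- rep(seq_len(n_pat), each = neurons_per_patient)

  tech <- exp(stats::rnorm(n_pat, 0, tech_sd))[pat_idx]
  lost_frac <- ifelse(cohorts == "sALS",
                      stats::runif(n_pat, lost_fraction_range[1],
                                   lost_fraction_range[2]), 0)[pat_idx]
  status <- ifelse(stats::runif(n) < lost_frac, "nuclear_lost",
                   "nuclear_retained")
  a_soma <- exp(stats::rnorm(n, log(2000), 0.25))
  a_nuc <- a_soma * stats::runif(n, 0.18, 0.32)
  a_lip <- ifelse(stats::runif(n) < 0.8,
                  a_soma * stats::runif(n, 0.02, 0.12), 0)
  shared <- exp(stats::rnorm(n, 0, neuron_shared_sd))
  cohort <- cohorts[pat_idx]

  out <- tibble::tibble(
    patient_id = patients[pat_idx], cohort = cohort, tdp43_status = status,
    area_soma = a_soma, area_nucleus = a_nuc, area_lipofuscin = a_lip)
  a_cyt <- a_soma - a_nuc - a_lip
  for (ch in names(base)) {
    sdev <- if (ch == "TUBB3") tubulin_sd else channel_sd
    cyt <- base[[ch]]["cyt"] * exp(stats::rnorm(n, 0, sdev))
    nuc <- base[[ch]]["nuc"] * exp(stats::rnorm(n, 0, sdev))
    lip <- ifelse(a_lip > 0,
                  base[[ch]]["lip"] * exp(stats::rnorm(n, 0, sdev)), 0)
    if (ch == "NOVA1") {
      nuc <- nuc * ifelse(status == "nuclear_lost", nuc_nova1_down, 1)
      cyt <- cyt * ifelse(cohort == "sALS" & status == "nuclear_retained",
                          cyt_nova1_up, 1)
    }
    if (ch == "TDP43")
      nuc <- nuc * ifelse(status == "nuclear_lost", 0.3, 1)
    f <- tech * shared
    cyt <- cyt * f; nuc <- nuc * f; lip <- lip * f
    out[[paste0("mfi_soma_", ch)]] <-
      (cyt * a_cyt + nuc * a_nuc + lip * a_lip) / a_soma
    out[[paste0("mfi_nucleus_", ch)]] <- nuc
    out[[paste0("mfi_lipofuscin_", ch)]] <- lip
  }
  out
}

#' Generate NOVA1/STMN2 expression tables
#'
#' Controls have independent NOVA1 and STMN2; disease samples share a
#' Gaussian-copula rank correlation `rho`, and a planted fraction of
#' disease samples forms an STMN2-low subgroup (control-anchored z around
#' -3) with correspondingly reduced NOVA1, so the disease-only positive
#' correlation and the low subgroup are both recoverable.
#'
#' @param seed integer seed.
#' @param n_datasets number of datasets (platforms) to emulate.
#' @param n_ctrl,n_als samples per group per dataset.
#' @param rho disease-group latent correlation.
#' @param low_fraction fraction of disease samples in the STMN2-low
#'   subgroup.
#' @return tibble (sample_id, dataset, group, nova1, stmn2).
#' @export
gen_expression <- function(seed, n_datasets = 2, n_ctrl = 15, n_als = 25,
                           rho = 0.7, low_fraction = 0.25) {
  set.seed(derive_seed(seed, "expression"))
  out <- list()
  for (d in seq_len(n_datasets)) {
    mu_n <- stats::runif(1, 8, 15); sd_n <- mu_n * 0.15
    mu_s <- stats::runif(1, 40, 80); sd_s <- mu_s * 0.15
    ctrl <- tibble::tibble(
      sample_id = paste0("DS", d, "_C", seq_len(n_ctrl)),
      dataset = paste0("DS", d), group = "Ctrl",
      nova1 = stats::rnorm(n_ctrl, mu_n, sd_n),
      stmn2 = stats::rnorm(n_ctrl, mu_s, sd_s))
    z2 <- stats::rnorm(n_als)
    low <- stats::runif(n_als) < low_fraction
    z2[low] <- stats::rnorm(sum(low), -3, 0.4)
    z1 <- rho * z2 + sqrt(1 - rho^2) * stats::rnorm(n_als)
    als <- tibble::tibble(
      sample_id = paste0("DS", d, "_A", seq_len(n_als)),
      dataset = paste0("DS", d), group = "ALS",
      nova1 = mu_n + sd_n * z1, stmn2 = mu_s + sd_s * z2)
    out[[d]] <- dplyr::bind_rows(ctrl, als)
  }
  dplyr::bind_rows(out)
}

#' Generate foreground/background sequence sets with a planted motif
#'
#' Background sequences are uniform over A/C/G/T; foreground sequences
#' additionally carry one planted motif occurrence at a random position
#' with probability `plant_rate`. Defaults echo the NOVA (YCAY, here
#' "TCAT") preference; "GCATG" mirrors the RBFOX GCAUG motif.
#'
#' @param seed integer seed.
#' @param n_fg,n_bg numbers of sequences.
#' @param len sequence length.
#' @param motif planted motif (DNA alphabet).
#' @param plant_rate probability a foreground sequence carries the motif.
#' @return list: `fg`, `bg` (character vectors).
#' @export
gen_sequences <- function(seed, n_fg = 500, n_bg = 500, len = 50,
                          motif = "TCAT", plant_rate = 1) {
  set.seed(derive_seed(seed, "sequences"))
  rand_seq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
  fg <- rand_seq(n_fg); bg <- rand_seq(n_bg)
  k <- nchar(motif)
  plant <- stats::runif(n_fg) < plant_rate
  pos <- sample(seq_len(len - k + 1), n_fg, replace = TRUE)
  for (i in which(plant)) {
    substr(fg[i], pos[i], pos[i] + k - 1) <- motif
  }
  list(fg = fg, bg = bg)
}

#' Write sequences as FASTA
#' @param seqs character vector of sequences.
#' @param path output path.
#' @param prefix record-name prefix.
#' @export
write_fasta_seqs <- function(seqs, path, prefix = "seq") {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- paste0(prefix, seq_along(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
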