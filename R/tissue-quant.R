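#' @title Single-neuron fluorescence quantification and expression z-scores
#' @description Quantification of per-neuron immunofluorescence in
#'   postmortem spinal cord: lipofuscin-corrected cytoplasmic mean
#'   fluorescence intensity (MFI), a soma-area filter, beta-III-tubulin
#'   normalization to remove patient-level technical variability, matched
#'   within-patient comparison of neurons by nuclear TDP-43 status, and
#'   the NOVA1/STMN2 expression analysis on control-anchored z-scores with
#'   an STMN2-low subgroup (z < -2).
#'
#'   A neuron record (one row) carries: patient_id, cohort (Ctrl/sALS),
#'   tdp43_status (nuclear_retained/nuclear_lost), compartment areas
#'   (area_soma, area_nucleus, area_lipofuscin, in um^2) and per-channel
#'   MFIs `mfi_<compartment>_<channel>` for channels NOVA1, TDP43, TUBB3.
#' @name tissue_quant
NULL

#' Lipofuscin-corrected cytoplasmic MFI
#'
#' MFI_cytoplasm = (MFI_soma * area_soma - MFI_nucleus * area_nucleus -
#' MFI_lipofuscin * area_lipofuscin) / area_cytoplasm, with
#' area_cytoplasm = area_soma - area_nucleus - area_lipofuscin (the
#' lipofuscin-free cytoplasm). Negative results (measurement noise) are
#' clamped to 0 and flagged.
#'
#' @param records neuron tibble.
#' @param channel "NOVA1", "TDP43" or "TUBB3".
#' @return tibble (mfi_cytoplasm, clamped).
#' @export
mfi_cytoplasm <- function(records, channel) {
  a_cyt <- records$area_soma - records$area_nucleus - records$area_lipofuscin
  if (any(a_cyt <= 0))
    stop("mfi_cytoplasm: non-positive cytoplasmic area in ",
         sum(a_cyt <= 0), " record(s)")
  soma <- records[[paste0("mfi_soma_", channel)]]
  nuc <- records[[paste0("mfi_nucleus_", channel)]]
  lip <- records[[paste0("mfi_lipofuscin_", channel)]]
  lip[records$area_lipofuscin == 0] <- 0
  raw <- (soma * records$area_soma - nuc * records$area_nucleus -
            lip * records$area_lipofuscin) / a_cyt
  tibble::tibble(mfi_cytoplasm = pmax(raw, 0), clamped = raw < 0)
}

#' Keep neurons with soma area strictly above a minimum
#'
#' @param records neuron tibble.
#' @param min_area strict lower bound in um^2 (default 1000).
#' @export
soma_filter <- function(records, min_area = 1000) {
  records[records$area_soma > min_area, , drop = FALSE]
}

#' beta-III-tubulin MFI of the lipofuscin-free soma
#'
#' Denominator of the tubulin normalization:
#' (MFI_soma_TUBB3 * area_soma - MFI_lipofuscin_TUBB3 * area_lipofuscin) /
#' (area_soma - area_lipofuscin). Note the nucleus is *included* here (the
#' normalizer subtracts only lipofuscin).
#'
#' @param records neuron tibble.
#' @export
tubulin_reference <- function(records) {
  lip <- records$mfi_lipofuscin_TUBB3
  lip[records$area_lipofuscin == 0] <- 0
  denom_area <- records$area_soma - records$area_lipofuscin
  (records$mfi_soma_TUBB3 * records$area_soma -
     lip * records$area_lipofuscin) / denom_area
}

#' Tubulin-normalized MFI of a channel in a compartment
#'
#' Divides the channel's compartment MFI by the beta-III-tubulin MFI of
#' the lipofuscin-free soma, removing multiplicative patient-level
#' technical factors (postmortem interval, fixation, storage).
#'
#' @param records neuron tibble.
#' @param channel "NOVA1" or "TDP43".
#' @param compartment "nucleus", "soma", or "cytoplasm"
#'   (lipofuscin-corrected, via [mfi_cytoplasm()]).
#' @export
tubulin_normalize <- function(records, channel,
                              compartment = c("nucleus", "soma",
                                              "cytoplasm")) {
  compartment <- match.arg(compartment)
  ref <- tubulin_reference(records)
  if (any(ref == 0)) stop("tubulin_normalize: zero tubulin reference MFI")
  num <- switch(compartment,
                nucleus = records[[paste0("mfi_nucleus_", channel)]],
                soma = records[[paste0("mfi_soma_", channel)]],
                cytoplasm = mfi_cytoplasm(records, channel)$mfi_cytoplasm)
  num / ref
}

#' Inter-individual variance reduction achieved by tubulin normalization
#'
#' Computes per-patient means of the raw and the tubulin-normalized MFI
#' (per-patient neuron means, then variance across patients, each scaled
#' by its squared grand mean so the comparison is scale-free), and reports
#' 100 * (1 - var_normalized / var_raw) as a percentage.
#'
#' @param records neuron tibble (>= 3 patients with >= 3 neurons each).
#' @param channel,compartment as in [tubulin_normalize()].
#' @return percentage (positive = normalization reduced variance).
#' @export
interindividual_variance_reduction <- function(records, channel,
                                               compartment = "cytoplasm") {
  counts <- table(records$patient_id)
  if (length(counts) < 3 || any(counts < 3))
    stop("interindividual_variance_reduction: need >= 3 patients with >= 3 neurons each")
  raw <- switch(compartment,
                nucleus = records[[paste0("mfi_nucleus_", channel)]],
                soma = records[[paste0("mfi_soma_", channel)]],
                cytoplasm = mfi_cytoplasm(records, channel)$mfi_cytoplasm)
  norm <- tubulin_normalize(records, channel, compartment)
  per_patient <- function(v) tapply(v, records$patient_id, mean)
  rel_var <- function(v) {
    pm <- per_patient(v)
    g <- mean(pm)
    if (g == 0) stop("interindividual_variance_reduction: zero grand mean")
    stats::var(pm) / g^2
  }
  v_raw <- rel_var(raw)
  if (v_raw == 0)
    stop("interindividual_variance_reduction: zero raw inter-patient variance")
  100 * (1 - rel_var(norm) / v_raw)
}

#' Matched within-patient comparison by nuclear TDP-43 status
#'
#' For each patient with neurons in both TDP-43 classes, takes the median
#' raw MFI per class, then tests the paired per-patient medians with an
#' exact two-sided sign-flip permutation test on the mean paired
#' difference (retained minus lost).
#'
#' @param records neurons of one cohort.
#' @param channel,compartment measurement to compare.
#' @return list: per-patient tibble, `n_patients`, `mean_difference`,
#'   `direction` ("higher_when_retained"/"higher_when_lost"/"none"),
#'   `p_two_sided`.
#' @export
matched_tdp43_comparison <- function(records, channel,
                                     compartment = "nucleus") {
  value <- switch(compartment,
                  nucleus = records[[paste0("mfi_nucleus_", channel)]],
                  soma = records[[paste0("mfi_soma_", channel)]],
                  cytoplasm = mfi_cytoplasm(records, channel)$mfi_cytoplasm)
  d <- tibble::tibble(patient_id = records$patient_id,
                      status = records$tdp43_status, value = value)
  med <- dplyr::summarise(
    dplyr::group_by(d, .data$patient_id, .data$status),
    median_mfi = stats::median(.data$value), .groups = "drop")
  wide <- dplyr::inner_join(
    dplyr::filter(med, .data$status == "nuclear_retained"),
    dplyr::filter(med, .data$status == "nuclear_lost"),
    by = "patient_id", suffix = c("_retained", "_lost"))
  if (nrow(wide) < 3)
    stop("matched_tdp43_comparison: need >= 3 patients with both TDP-43 classes")
  diffs <- wide$median_mfi_retained - wide$median_mfi_lost
  obs <- mean(diffs)
  n <- length(diffs)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- as.vector(signs %*% diffs) / n
  p <- mean(abs(perm) >= abs(obs) - 1e-12)
  direction <- if (obs > 0) "higher_when_retained"
  else if (obs < 0) "higher_when_lost" else "none"
  list(per_patient = wide, n_patients = n, mean_difference = obs,
       direction = direction, p_two_sided = p)
}

#' Control-anchored expression z-scores per dataset
#'
#' z = (value - mean_ctrl) / sd_ctrl, computed within each dataset from
#' that dataset's control samples, so samples from different platforms can
#' be pooled.
#'
#' @param records tibble with columns sample_id, dataset, group
#'   ("Ctrl"/"ALS"), nova1, stmn2.
#' @return input tibble with z_nova1 and z_stmn2 added.
#' @export
expression_zscores <- function(records) {
  out <- lapply(split(records, records$dataset), function(d) {
    ctrl <- d[d$group == "Ctrl", , drop = FALSE]
    if (nrow(ctrl) < 2)
      stop("expression_zscores: dataset '", d$dataset[1],
           "' has < 2 control samples")
    for (g in c("nova1", "stmn2")) {
      mu <- mean(ctrl[[g]]); sdev <- stats::sd(ctrl[[g]])
      if (sdev == 0)
        stop("expression_zscores: zero control SD for ", g, " in dataset '",
             d$dataset[1], "'")
      d[[paste0("z_", g)]] <- (d[[g]] - mu) / sdev
    }
    d
  })
  dplyr::bind_rows(out)
}

#' Assign the STMN2-low subgroup
#'
#' ALS samples with STMN2 z-score strictly below the cutoff (-2) are
#' classed "low"; everything else, and every control, is "regular".
#'
#' @param records output of [expression_zscores()].
#' @param cutoff z-score cutoff (default -2, strict "<").
#' @return input with an `stmn2_class` column.
#' @export
stmn2_grouping <- function(records, cutoff = -2) {
  records$stmn2_class <- ifelse(
    records$group != "Ctrl" & records$z_stmn2 < cutoff, "low", "regular")
  records
}

#' NOVA1-STMN2 correlation within one group
#'
#' Spearman correlation of NOVA1 and STMN2 within the named group;
#' optionally the three-group Kruskal-Wallis plus pairwise rank-sum
#' comparison of NOVA1 z-scores across Ctrl / ALS STMN2-regular / ALS
#' STMN2-low. When the table spans several datasets the correlation is
#' computed on the control-anchored z-scores (raw values from different
#' platforms are not comparable and pooling them would distort the
#' ranks); a single-dataset table without z columns uses raw values.
#'
#' @param records z-scored (and, for `three_group`, STMN2-classed)
#'   expression tibble.
#' @param group group to correlate within ("ALS" or "Ctrl").
#' @param three_group also run the three-group comparison.
#' @return list with `rho`, `p`, and optionally `kruskal`, `pairwise`.
#' @export
nova1_stmn2_correlation <- function(records, group, three_group = FALSE) {
  d <- records[records$group == group, , drop = FALSE]
  if (nrow(d) < 3)
    stop("nova1_stmn2_correlation: need >= 3 records in group '", group, "'")
  multi <- length(unique(records$dataset)) > 1
  if (multi && !all(c("z_nova1", "z_stmn2") %in% names(records)))
    stop("nova1_stmn2_correlation: multi-dataset table requires z-scores; run expression_zscores() first")
  ct <- if (multi) spearman_test(d$z_nova1, d$z_stmn2)
        else spearman_test(d$nova1, d$stmn2)
  out <- list(rho = ct$rho, p = ct$p_two_sided)
  if (three_group) {
    if (!"stmn2_class" %in% names(records))
      records <- stmn2_grouping(records)
    cls <- ifelse(records$group == "Ctrl", "Ctrl",
                  paste0("ALS_", records$stmn2_class))
    groups <- split(records$z_nova1, cls)
    out$kruskal <- kruskal_wallis(groups)
    out$pairwise <- pairwise_ranksum(groups)
  }
  out
}
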