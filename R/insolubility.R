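#' @title Proteomic insolubility enrichment screen
#' @description Label-free quantification (LFQ) screen for proteins
#'   enriched in the detergent-insoluble fraction of disease samples.
#'   Per protein: fold change = mean(LFQ + 1)_target / mean(LFQ + 1)_control
#'   (the +1 pseudocount handles non-detected zeros), significance by a
#'   two-sided Welch t test on log2(LFQ + 1). A hit requires P < 0.05 and
#'   fold change >= 1.5 under the defaults. The specificity control is an
#'   exhaustive shuffled-label null: every balanced mixed split (half of
#'   each group on each side) is re-screened and the observed hit count is
#'   compared to the null distribution of hit counts.
#' @name insolubility
NULL

# vectorized per-row Welch on log2(x + 1); zero variance in both groups -> P 1
.welch_rows <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  l1 <- log2(m1 + 1); l2 <- log2(m2 + 1)
  mu1 <- rowMeans(l1); mu2 <- rowMeans(l2)
  v1 <- rowSums((l1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((l2 - mu2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- v1 == 0 & v2 == 0
  p[degenerate] <- 1
  t[degenerate] <- 0
  list(t = t, p = p)
}

#' Run the insolubility screen on an LFQ matrix
#'
#' @param intensities numeric matrix, rows = proteins, columns = samples,
#'   non-negative (0 = not detected).
#' @param groups character/factor of length ncol with exactly two levels.
#' @param target_label level treated as the target (numerator) group; by
#'   default the second level in sorted order is a poor guess, so pass it
#'   explicitly (e.g. "ALS").
#' @param fc_min fold-change cutoff (inclusive >=, default 1.5).
#' @param p_max Welch P cutoff (strict <, default 0.05).
#' @param fc_strict set TRUE for a strict ">" fold-change comparison.
#' @return tibble (protein, fold_change, log2_fc, p_welch, neg_log10_p,
#'   is_hit).
#' @export
insolubility_screen <- function(intensities, groups, target_label,
                                fc_min = 1.5, p_max = 0.05,
                                fc_strict = FALSE) {
  m <- as.matrix(intensities)
  if (any(m < 0)) stop("insolubility_screen: negative intensities")
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("insolubility_screen: one group label per sample required")
  lv <- unique(groups)
  if (length(lv) != 2) stop("insolubility_screen: exactly two groups required")
  if (missing(target_label)) target_label <- lv[1]
  if (!target_label %in% lv)
    stop("insolubility_screen: unknown target label")
  tgt <- m[, groups == target_label, drop = FALSE]
  ctl <- m[, groups != target_label, drop = FALSE]
  if (ncol(tgt) < 2 || ncol(ctl) < 2)
    stop("insolubility_screen: each group needs >= 2 samples")
  fc <- rowMeans(tgt + 1) / rowMeans(ctl + 1)
  w <- .welch_rows(tgt, ctl)
  fc_pass <- if (fc_strict) fc > fc_min else fc >= fc_min
  tibble::tibble(
    protein = rownames(m) %||% as.character(seq_len(nrow(m))),
    fold_change = unname(fc), log2_fc = unname(log2(fc)),
    p_welch = unname(w$p),
    neg_log10_p = unname(-log10(pmax(w$p, .Machine$double.xmin))),
    is_hit = unname(w$p < p_max & fc_pass)
  )
}

#' Exhaustive shuffled-label null for the insolubility screen
#'
#' Enumerates every balanced mixed split: half of the target samples plus
#' half of the controls form the pseudo-target group, the remaining halves
#' the pseudo-control group (for 6 vs 6 input: C(6,3) * C(6,3) = 400
#' splits). Any split whose pseudo-target set coincides with the true
#' target or true control group is excluded as label-faithful (such splits
#' cannot occur among balanced mixed splits, so all 400 are informative
#' for 6 vs 6). The identical screen runs on each split.
#'
#' @inheritParams insolubility_screen
#' @return list: `null_hits` (per-split hit counts), `mean_null`,
#'   `observed_hits`, `fold_observed_over_null`, `n_splits`.
#' @export
shuffle_null <- function(intensities, groups, target_label,
                         fc_min = 1.5, p_max = 0.05, fc_strict = FALSE) {
  m <- as.matrix(intensities)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("shuffle_null: exactly two groups required")
  if (missing(target_label)) target_label <- lv[1]
  idx_t <- which(groups == target_label)
  idx_c <- which(groups != target_label)
  if (length(idx_t) %% 2 != 0 || length(idx_c) %% 2 != 0)
    stop("shuffle_null: group sizes must be evenly splittable")
  ht <- length(idx_t) / 2; hc <- length(idx_c) / 2
  ct <- utils::combn(idx_t, ht, simplify = FALSE)
  cc <- utils::combn(idx_c, hc, simplify = FALSE)

  obs <- sum(insolubility_screen(m, groups, target_label, fc_min, p_max,
                                 fc_strict)$is_hit)
  true_t <- sort(idx_t); true_c <- sort(idx_c)
  null_hits <- integer(0)
  for (st in ct) for (sc in cc) {
    side_a <- sort(c(st, sc))
    if (identical(side_a, true_t) || identical(side_a, true_c)) next
    side_b <- setdiff(seq_along(groups), side_a)
    fc <- rowMeans(m[, side_a, drop = FALSE] + 1) /
      rowMeans(m[, side_b, drop = FALSE] + 1)
    w <- .welch_rows(m[, side_a, drop = FALSE], m[, side_b, drop = FALSE])
    fc_pass <- if (fc_strict) fc > fc_min else fc >= fc_min
    null_hits <- c(null_hits, sum(w$p < p_max & fc_pass))
  }
  mean_null <- mean(null_hits)
  list(null_hits = null_hits, mean_null = mean_null, observed_hits = obs,
       fold_observed_over_null = if (mean_null == 0) Inf else obs / mean_null,
       n_splits = length(null_hits))
}

#' Write screen results as a volcano-plot-ready TSV
#' @param hits output of [insolubility_screen()].
#' @param path output TSV path.
#' @export
write_screen_table <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
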