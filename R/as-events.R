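#' @title rMATS-dialect cassette-exon tables
#' @description Parsing, coverage filtering, significance calling, canonical
#'   event indexing and cross-dataset comparison of skipped-exon (SE)
#'   junction-count tables in the rMATS 4.1.0 `SE.MATS.JC.txt` dialect.
#'
#'   Events are held in a tibble with one row per cassette exon. Junction
#'   counts and inclusion levels are list-columns (one value per replicate).
#'   All coordinates are 0-based half-open, matching `exonStart_0base` and
#'   BED. `left_flank_*` / `right_flank_*` are the *genomically* left and
#'   right flanking exons (rMATS "upstream"/"downstream" columns are
#'   genomic-left/right regardless of strand; transcript orientation is
#'   restored later by [event_regions()]).
#'
#'   Sign convention (from the order of the rMATS `-b1`/`-b2` groups):
#'   group 1 is the control condition and group 2 the target, so a
#'   *negative* delta-PSI means the exon is *included* in the target
#'   condition and a positive delta-PSI means it is *excluded*.
#' @name as_events
NULL

.rmats_required_cols <- c(
  "ID", "GeneID", "geneSymbol", "chr", "strand",
  "exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
  "downstreamES", "downstreamEE",
  "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
  "IncFormLen", "SkipFormLen", "PValue", "FDR",
  "IncLevel1", "IncLevel2", "IncLevelDifference"
)

.parse_count_list <- function(s, col, ids) {
  out <- lapply(strsplit(s, ",", fixed = TRUE), function(v) {
    suppressWarnings(as.integer(trimws(v)))
  })
  bad <- vapply(out, function(v) length(v) == 0 || anyNA(v) || any(v < 0),
                logical(1))
  if (any(bad))
    stop(sprintf("non-numeric or negative %s counts in row(s): %s",
                 col, paste(ids[bad], collapse = ", ")))
  out
}

.parse_level_list <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[v %in% c("NA", "nan", "")] <- NA
    suppressWarnings(as.numeric(v))
  })
}

#' Read an rMATS-dialect SE junction-count table
#'
#' @param path TSV file with the rMATS 4.1.0 `SE.MATS.JC.txt` header.
#' @return tibble of events (one per row) with list-columns `ijc_g1`,
#'   `sjc_g1`, `ijc_g2`, `sjc_g2`, `inc_level_g1`, `inc_level_g2`.
#' @export
read_rmats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(.rmats_required_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("rMATS table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) return(empty_events())
  bad_strand <- !raw$strand %in% c("+", "-")
  if (any(bad_strand))
    stop("invalid strand (must be '+' or '-') in row(s): ",
         paste(which(bad_strand), collapse = ", "))
  ev <- tibble::tibble(
    event_id = raw$ID,
    gene_id = raw$GeneID,
    gene_symbol = raw$geneSymbol,
    chrom = raw$chr,
    strand = raw$strand,
    alt_exon_start = as.integer(raw$exonStart_0base),
    alt_exon_end = as.integer(raw$exonEnd),
    left_flank_start = as.integer(raw$upstreamES),
    left_flank_end = as.integer(raw$upstreamEE),
    right_flank_start = as.integer(raw$downstreamES),
    right_flank_end = as.integer(raw$downstreamEE),
    ijc_g1 = .parse_count_list(raw$IJC_SAMPLE_1, "IJC_SAMPLE_1", raw$ID),
    sjc_g1 = .parse_count_list(raw$SJC_SAMPLE_1, "SJC_SAMPLE_1", raw$ID),
    ijc_g2 = .parse_count_list(raw$IJC_SAMPLE_2, "IJC_SAMPLE_2", raw$ID),
    sjc_g2 = .parse_count_list(raw$SJC_SAMPLE_2, "SJC_SAMPLE_2", raw$ID),
    inc_form_len = as.integer(raw$IncFormLen),
    skip_form_len = as.integer(raw$SkipFormLen),
    p_value = as.numeric(raw$PValue),
    fdr = as.numeric(raw$FDR),
    inc_level_g1 = .parse_level_list(raw$IncLevel1),
    inc_level_g2 = .parse_level_list(raw$IncLevel2),
    inc_level_difference = as.numeric(raw$IncLevelDifference)
  )
  bad_order <- with(ev, !(left_flank_end <= alt_exon_start &
                          alt_exon_start < alt_exon_end &
                          alt_exon_end <= right_flank_start))
  if (any(bad_order))
    stop("exon ordering violated (need left_flank_end <= alt_exon_start < ",
         "alt_exon_end <= right_flank_start) in row(s): ",
         paste(ev$event_id[bad_order], collapse = ", "))
  if (any(abs(ev$inc_level_difference) > 1 + 1e-9, na.rm = TRUE))
    stop("|IncLevelDifference| > 1 in table")
  ev
}

#' An empty event table with the full column set
#' @export
empty_events <- function() {
  tibble::tibble(
    event_id = character(), gene_id = character(), gene_symbol = character(),
    chrom = character(), strand = character(),
    alt_exon_start = integer(), alt_exon_end = integer(),
    left_flank_start = integer(), left_flank_end = integer(),
    right_flank_start = integer(), right_flank_end = integer(),
    ijc_g1 = list(), sjc_g1 = list(), ijc_g2 = list(), sjc_g2 = list(),
    inc_form_len = integer(), skip_form_len = integer(),
    p_value = numeric(), fdr = numeric(),
    inc_level_g1 = list(), inc_level_g2 = list(),
    inc_level_difference = numeric()
  )
}

# per-replicate total junction support (IJC + SJC), both groups concatenated
.sample_totals <- function(events) {
  Map(function(i1, s1, i2, s2) c(i1 + s1, i2 + s2),
      events$ijc_g1, events$sjc_g1, events$ijc_g2, events$sjc_g2)
}

#' Coverage filter: keep events supported in every sample
#'
#' Retains events whose total junction support (IJC + SJC for that
#' replicate) is at least `min_reads` in *every* sample of both groups.
#' The boundary is inclusive ("at least 10 counts").
#'
#' @param events event tibble.
#' @param min_reads minimum per-sample junction support (default 10).
#' @export
coverage_filter <- function(events, min_reads = 10) {
  stopifnot(min_reads >= 0)
  if (nrow(events) == 0) return(events)
  keep <- vapply(.sample_totals(events), function(v) all(v >= min_reads),
                 logical(1))
  events[keep, , drop = FALSE]
}

#' Call differentially spliced events
#'
#' Significant means FDR strictly below `fdr_max` *and* |delta-PSI|
#' strictly above `min_abs_dpsi` ("below 0.05", "more than 0.1").
#'
#' @param events coverage-filtered event tibble.
#' @param fdr_max FDR threshold (strict, default 0.05).
#' @param min_abs_dpsi |delta-PSI| threshold (strict, default 0.1).
#' @export
call_significant <- function(events, fdr_max = 0.05, min_abs_dpsi = 0.1) {
  if (nrow(events) == 0) return(events)
  keep <- !is.na(events$fdr) & events$fdr < fdr_max &
    !is.na(events$inc_level_difference) &
    abs(events$inc_level_difference) > min_abs_dpsi
  events[keep, , drop = FALSE]
}

#' Direction of a significant splicing change in the target condition
#'
#' Negative delta-PSI = exon included in the target condition; positive =
#' excluded. Only meaningful for significant events (|dPSI| > 0 there).
#'
#' @param dpsi numeric delta-PSI values.
#' @return character vector, "included" or "excluded".
#' @export
splicing_direction <- function(dpsi) {
  ifelse(dpsi < 0, "included", "excluded")
}

#' Canonical event key identifying a splice junction across rMATS runs
#'
#' Built from the four junction-defining coordinates (chrom, strand,
#' left-flank donor end, alternative exon boundaries, right-flank acceptor
#' start). Flank *outer* boundaries are deliberately excluded so the same
#' junction annotated with different flank extents still matches.
#'
#' @param events event tibble.
#' @return character vector of keys.
#' @export
event_key <- function(events) {
  paste(events$chrom, events$strand, events$left_flank_end,
        events$alt_exon_start, events$alt_exon_end,
        events$right_flank_start, sep = ":")
}

#' Add the canonical key and resolve duplicates
#'
#' Duplicate keys within a table are resolved deterministically by keeping
#' the row with the larger total junction support (sum of all IJC + SJC);
#' remaining ties keep the first occurrence. A warning reports how many
#' rows were dropped.
#'
#' @param events event tibble.
#' @export
index_events <- function(events) {
  events$event_key <- event_key(events)
  if (nrow(events) <= 1) return(events)
  support <- vapply(.sample_totals(events), sum, numeric(1))
  ord <- order(events$event_key, -support)
  ev <- events[ord, , drop = FALSE]
  dup <- duplicated(ev$event_key)
  if (any(dup)) {
    warning(sprintf("index_events: dropped %d duplicate-key row(s), keeping the row with larger junction support", sum(dup)))
    ev <- ev[!dup, , drop = FALSE]
  }
  ev[order(match(ev$event_key, events$event_key)), , drop = FALSE]
}

#' Inner-join two event tables on the canonical event key
#'
#' Both inputs should already be coverage-filtered; the join retains only
#' junctions detected (and covered) in both datasets. delta-PSI and FDR
#' from the two tables are carried as `*_a` / `*_b` columns.
#'
#' @param a,b event tibbles.
#' @return tibble with one row per shared key.
#' @export
join_datasets <- function(a, b) {
  if (!"event_key" %in% names(a)) a <- index_events(a)
  if (!"event_key" %in% names(b)) b <- index_events(b)
  ja <- tibble::tibble(event_key = a$event_key,
                       dpsi_a = a$inc_level_difference, fdr_a = a$fdr)
  jb <- tibble::tibble(event_key = b$event_key,
                       dpsi_b = b$inc_level_difference, fdr_b = b$fdr)
  dplyr::inner_join(ja, jb, by = "event_key")
}

#' Fisher overlap of significance calls on a joined background
#'
#' 2x2 table over the joined events (significant in both / in a only / in
#' b only / in neither) with the conditional exact two-sided P and the
#' sample odds ratio (n_both * n_neither) / (n_a_only * n_b_only).
#'
#' @param joined output of [join_datasets()].
#' @param sig_a,sig_b logical flags over the joined rows.
#' @return list with counts, `odds_ratio`, `or_infinite`, `p_fisher`.
#' @export
overlap_test <- function(joined, sig_a, sig_b) {
  stopifnot(length(sig_a) == nrow(joined), length(sig_b) == nrow(joined))
  n_both <- sum(sig_a & sig_b)
  n_a_only <- sum(sig_a & !sig_b)
  n_b_only <- sum(!sig_a & sig_b)
  n_neither <- sum(!sig_a & !sig_b)
  m <- matrix(c(n_both, n_a_only, n_b_only, n_neither), 2, 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  denom <- n_a_only * n_b_only
  or_inf <- denom == 0
  list(n_both = n_both, n_a_only = n_a_only, n_b_only = n_b_only,
       n_neither = n_neither,
       odds_ratio = if (or_inf) Inf else (n_both * n_neither) / denom,
       or_infinite = or_inf, p_fisher = p)
}

#' Spearman correlation of delta-PSI across two joined datasets
#'
#' @param joined output of [join_datasets()] with >= 3 rows.
#' @return list with `rho` and `p`.
#' @export
dpsi_correlation <- function(joined) {
  if (nrow(joined) < 3)
    stop("dpsi_correlation: need >= 3 joined events")
  res <- spearman_test(joined$dpsi_a, joined$dpsi_b)
  list(rho = res$rho, p = res$p_two_sided)
}

#' Write events as a filtered/flagged TSV with the canonical key column
#'
#' @param events event tibble (indexed or not).
#' @param path output TSV path.
#' @export
write_event_table <- function(events, path) {
  if (!"event_key" %in% names(events)) events <- index_events(events)
  flat <- events
  for (col in c("ijc_g1", "sjc_g1", "ijc_g2", "sjc_g2",
                "inc_level_g1", "inc_level_g2")) {
    flat[[col]] <- vapply(flat[[col]], function(v)
      paste(ifelse(is.na(v), "NA", format(v, trim = TRUE, digits = 15)),
            collapse = ","), character(1))
  }
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
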