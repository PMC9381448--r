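#' @title Positional enrichment of CLIP peaks at cassette-exon events
#' @description Decomposes each cassette-exon event into five
#'   transcript-oriented sub-regions (upstream exon, upstream intron,
#'   alternative exon, downstream intron, downstream exon) plus the full
#'   junction span, and tests whether significantly changed events carry
#'   peaks in a given region more often than expected, by a hypergeometric
#'   upper-tail test against all coverage-passed events as background.
#'
#'   The event table stores *genomic-left/right* flanks (the rMATS
#'   "upstream"/"downstream" columns are genomic, not transcript-oriented);
#'   on the minus strand the transcript-level upstream region is the
#'   genomically right one, so labels swap here while genomic coordinates
#'   stay fixed.
#' @name splice_enrichment
NULL

.region_labels <- c("upstream_exon", "upstream_intron", "alternative_exon",
                    "downstream_intron", "downstream_exon", "junction_span")

#' Transcript-oriented sub-regions of cassette-exon events
#'
#' For each event, emits up to six spans: the two flanking exons, the two
#' introns, the alternative exon, and the junction span (genomic-left
#' flank start to genomic-right flank end). Zero-length introns (abutting
#' exons) are dropped rather than emitted empty. `upstream` / `downstream`
#' are in transcript orientation: on "+" the upstream exon is the
#' genomically left flank; on "-" it is the right flank.
#'
#' @param events event tibble (one or more rows).
#' @return tibble with columns event_key, label, chrom, start, end, strand.
#' @export
event_regions <- function(events) {
  if (!"event_key" %in% names(events)) events <- index_events(events)
  bad <- with(events, !(left_flank_end <= alt_exon_start &
                        alt_exon_start < alt_exon_end &
                        alt_exon_end <= right_flank_start))
  if (any(bad))
    stop("event_regions: exon ordering violated for event(s): ",
         paste(events$event_key[bad], collapse = ", "))
  plus <- events$strand == "+"
  span <- function(label, start, end) {
    tibble::tibble(event_key = events$event_key, label = label,
                   chrom = events$chrom, start = start, end = end,
                   strand = events$strand)
  }
  out <- dplyr::bind_rows(
    span(ifelse(plus, "upstream_exon", "downstream_exon"),
         events$left_flank_start, events$left_flank_end),
    span(ifelse(plus, "upstream_intron", "downstream_intron"),
         events$left_flank_end, events$alt_exon_start),
    span("alternative_exon", events$alt_exon_start, events$alt_exon_end),
    span(ifelse(plus, "downstream_intron", "upstream_intron"),
         events$alt_exon_end, events$right_flank_start),
    span(ifelse(plus, "downstream_exon", "upstream_exon"),
         events$right_flank_start, events$right_flank_end),
    span("junction_span", events$left_flank_start, events$right_flank_end)
  )
  out[out$start < out$end, , drop = FALSE]
}

#' @keywords internal
.regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = regions$strand
  )
}

#' Events carrying at least one peak in a named region
#'
#' An event qualifies when any thresholded peak overlaps the named
#' sub-region by >= 1 bp on the same strand; the event is counted once
#' regardless of how many peaks hit it (`bedtools intersect -u`
#' semantics).
#'
#' @param events event tibble.
#' @param peaks thresholded peak tibble.
#' @param region_label one of upstream_exon, upstream_intron,
#'   alternative_exon, downstream_intron, downstream_exon, junction_span.
#' @param regions optional precomputed [event_regions()] table for
#'   `events` (saves recomputation in profile loops).
#' @return character vector of qualifying event keys.
#' @export
events_with_peak <- function(events, peaks, region_label, regions = NULL) {
  if (!region_label %in% .region_labels)
    stop("events_with_peak: unknown region label: ", region_label)
  if (!"event_key" %in% names(events)) events <- index_events(events)
  if (nrow(peaks) == 0 || nrow(events) == 0) return(character())
  if (is.null(regions)) regions <- event_regions(events)
  reg <- regions[regions$label == region_label &
                 regions$event_key %in% events$event_key, , drop = FALSE]
  if (nrow(reg) == 0) return(character())
  hit <- IRanges::overlapsAny(.regions_to_granges(reg),
                              peaks_to_granges(peaks),
                              minoverlap = 1L, ignore.strand = FALSE)
  unique(reg$event_key[hit])
}

#' Hypergeometric enrichment of peaks at selected events in one region
#'
#' With N = background events (all coverage-passed), K = background events
#' carrying >= 1 peak in the region, n = selected (significant, optionally
#' direction-filtered) events and k = selected events carrying a peak, the
#' P value is the upper tail P(X >= k) of Hypergeometric(N, K, n), and
#' fold enrichment is (k/n) / (K/N). The tail includes the observed count.
#'
#' @param sig_events significant events (must be a subset of the
#'   background keys).
#' @param background_events all coverage-passed events.
#' @param peaks thresholded peaks.
#' @param region_label region to score.
#' @param direction "all", "included" (delta-PSI < 0 in the target
#'   condition) or "excluded" (delta-PSI > 0).
#' @param bg_regions optional precomputed regions for the background.
#' @return list: region, direction, n/k background and selected counts,
#'   fold_enrichment (NA with `fold_undefined = TRUE` when K = 0),
#'   p_hypergeom.
#' @export
region_enrichment <- function(sig_events, background_events, peaks,
                              region_label,
                              direction = c("all", "included", "excluded"),
                              bg_regions = NULL) {
  direction <- match.arg(direction)
  if (!"event_key" %in% names(background_events))
    background_events <- index_events(background_events)
  if (!"event_key" %in% names(sig_events)) sig_events <- index_events(sig_events)
  if (!all(sig_events$event_key %in% background_events$event_key))
    stop("region_enrichment: significant events must be a subset of the background")
  sel <- sig_events
  if (direction == "included") {
    sel <- sel[sel$inc_level_difference < 0, , drop = FALSE]
  } else if (direction == "excluded") {
    sel <- sel[sel$inc_level_difference > 0, , drop = FALSE]
  }
  if (nrow(sel) == 0)
    stop("region_enrichment: no selected events for direction '", direction, "'")
  if (is.null(bg_regions)) bg_regions <- event_regions(background_events)
  bg_hit <- events_with_peak(background_events, peaks, region_label,
                             regions = bg_regions)
  n_background <- nrow(background_events)
  k_background <- length(bg_hit)
  n_selected <- nrow(sel)
  k_selected <- sum(sel$event_key %in% bg_hit)
  fold_undefined <- k_background == 0
  fold <- if (fold_undefined) NA_real_ else
    (k_selected / n_selected) / (k_background / n_background)
  list(region = region_label, direction = direction,
       n_background = n_background, k_background = k_background,
       n_selected = n_selected, k_selected = k_selected,
       fold_enrichment = fold, fold_undefined = fold_undefined,
       p_hypergeom = hypergeom_sf(n_background, k_background,
                                  n_selected, k_selected))
}

#' Positional enrichment profile across all sub-regions and directions
#'
#' The RNA-map style readout: an enrichment row for each of the five
#' sub-regions crossed with {included, excluded}, plus the junction span
#' over all significant events.
#'
#' @inheritParams region_enrichment
#' @return tibble with one row per (region, direction) cell.
#' @export
positional_profile <- function(sig_events, background_events, peaks) {
  if (!"event_key" %in% names(background_events))
    background_events <- index_events(background_events)
  if (!"event_key" %in% names(sig_events)) sig_events <- index_events(sig_events)
  if (nrow(sig_events) == 0)
    stop("positional_profile: empty significant event set")
  bg_regions <- event_regions(background_events)
  cells <- rbind(
    expand.grid(region = setdiff(.region_labels, "junction_span"),
                direction = c("included", "excluded"),
                stringsAsFactors = FALSE),
    data.frame(region = "junction_span", direction = "all")
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- region_enrichment(sig_events, background_events, peaks,
                           cells$region[i], cells$direction[i],
                           bg_regions = bg_regions)
    tibble::as_tibble(r[c("region", "direction", "n_background",
                          "k_background", "n_selected", "k_selected",
                          "fold_enrichment", "fold_undefined",
                          "p_hypergeom")])
  })
  dplyr::bind_rows(rows)
}

#' Enrichment in a proximal intron window adjacent to the alternative exon
#'
#' Restricts an intron region to its `window_bp` closest to the
#' alternative exon (transcript-oriented: the 3' end of the upstream
#' intron, the 5' end of the downstream intron) and recomputes the
#' enrichment there. `anchor = "far"` anchors the window at the opposite
#' (flank-side) end instead.
#'
#' @inheritParams region_enrichment
#' @param region_label "upstream_intron" or "downstream_intron".
#' @param window_bp window width in bases (> 0).
#' @param anchor "alt_exon" (default) or "far".
#' @export
proximal_window_enrichment <- function(sig_events, background_events, peaks,
                                       region_label, window_bp,
                                       direction = c("all", "included",
                                                     "excluded"),
                                       anchor = c("alt_exon", "far")) {
  direction <- match.arg(direction); anchor <- match.arg(anchor)
  if (!region_label %in% c("upstream_intron", "downstream_intron"))
    stop("proximal_window_enrichment: region must be an intron")
  if (window_bp <= 0) stop("proximal_window_enrichment: window_bp must be > 0")
  if (!"event_key" %in% names(background_events))
    background_events <- index_events(background_events)
  if (!"event_key" %in% names(sig_events)) sig_events <- index_events(sig_events)
  bg_regions <- event_regions(background_events)
  reg <- bg_regions[bg_regions$label == region_label, , drop = FALSE]
  # which genomic end of this intron touches the alternative exon?
  # upstream intron on "+" and downstream intron on "-" end at the alt exon
  # (alt-exon side = genomic right end); the mirrored cases start there.
  alt_at_right <- (reg$label == "upstream_intron" & reg$strand == "+") |
    (reg$label == "downstream_intron" & reg$strand == "-")
  if (anchor == "far") alt_at_right <- !alt_at_right
  w <- pmin(window_bp, reg$end - reg$start)
  reg$start <- ifelse(alt_at_right, reg$end - w, reg$start)
  reg$end <- ifelse(alt_at_right, reg$end, reg$start + w)
  bg_regions <- dplyr::bind_rows(
    bg_regions[bg_regions$label != region_label, , drop = FALSE], reg)
  region_enrichment(sig_events, background_events, peaks, region_label,
                    direction, bg_regions = bg_regions)
}

#' Export per-event region spans as BED6
#' @param regions output of [event_regions()].
#' @param path output BED path.
#' @export
write_region_bed <- function(regions, path) {
  bed <- tibble::tibble(chrom = regions$chrom, start = regions$start,
                        end = regions$end,
                        name = paste(regions$event_key, regions$label,
                                     sep = "|"),
                        score = 0L, strand = regions$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
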