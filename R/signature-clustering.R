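#' @title Multi-dataset delta-PSI clustering and GOF/LOF signatures
#' @description Assembles events significant in at least one anchor
#'   dataset into a delta-PSI matrix across all datasets, clusters the
#'   rows by k-means (defaults mirroring the published configuration:
#'   k = 8, random init, n_init = 10, max_iter = 300, seed = 42),
#'   summarizes clusters by per-dataset median delta-PSI, classifies each
#'   cluster as a NOVA1 gain-of-function (GOF) or loss-of-function (LOF)
#'   signature from the sign pattern across disease, over-expression and
#'   knock-out datasets, and localizes per-cluster peak enrichment along
#'   the event sub-regions.
#' @name signature_clustering
NULL

#' Assemble the cross-dataset delta-PSI matrix
#'
#' Rows are the union of events significant (per [call_significant()]
#' thresholds) in at least one anchor dataset; columns are datasets.
#' A cell holds the event's delta-PSI where the event passed coverage in
#' that dataset, otherwise 0 (imputed "no change"); the imputation mask is
#' retained so medians can exclude imputed values.
#'
#' @param datasets named list of coverage-filtered, indexed event tibbles.
#' @param anchors names of the datasets whose significant events define
#'   the row set.
#' @param fdr_max,min_abs_dpsi significance thresholds for the anchors.
#' @return list with `matrix` (rows = event keys, cols = datasets),
#'   `imputed` (logical mask, TRUE where the value was imputed 0).
#' @export
assemble_matrix <- function(datasets, anchors, fdr_max = 0.05,
                            min_abs_dpsi = 0.1) {
  stopifnot(is.list(datasets), length(datasets) >= 2)
  if (length(anchors) == 0 || !all(anchors %in% names(datasets)))
    stop("assemble_matrix: anchors must name datasets")
  datasets <- lapply(datasets, function(d)
    if ("event_key" %in% names(d)) d else index_events(d))
  sig_keys <- unique(unlist(lapply(datasets[anchors], function(d)
    call_significant(d, fdr_max, min_abs_dpsi)$event_key)))
  if (length(sig_keys) == 0)
    stop("assemble_matrix: no significant events in any anchor dataset")
  m <- matrix(0, nrow = length(sig_keys), ncol = length(datasets),
              dimnames = list(sig_keys, names(datasets)))
  imputed <- matrix(TRUE, nrow = length(sig_keys), ncol = length(datasets),
                    dimnames = dimnames(m))
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    idx <- match(sig_keys, d$event_key)
    found <- !is.na(idx) & !is.na(d$inc_level_difference[pmax(idx, 1)])
    m[found, nm] <- d$inc_level_difference[idx[found]]
    imputed[found, nm] <- FALSE
  }
  list(matrix = m, imputed = imputed)
}

#' k-means clustering of the delta-PSI matrix
#'
#' Random initialization (centers sampled from the rows), `n_init`
#' restarts keeping the lowest within-cluster sum of squares, Euclidean
#' distance. Deterministic for a fixed seed.
#'
#' @param matrix numeric matrix without missing values.
#' @param k number of clusters (default 8).
#' @param n_init restarts (default 10).
#' @param max_iter iteration cap (default 300).
#' @param seed RNG seed (default 42).
#' @return list with `labels` (named cluster ids, 0-based), `centers`,
#'   `tot_withinss`.
#' @export
run_kmeans <- function(matrix, k = 8, n_init = 10, max_iter = 300,
                       seed = 42) {
  if (k > nrow(matrix)) stop("run_kmeans: k exceeds number of rows")
  if (anyNA(matrix)) stop("run_kmeans: matrix contains missing values")
  set.seed(seed)
  km <- stats::kmeans(matrix, centers = k, nstart = n_init,
                      iter.max = max_iter)
  list(labels = stats::setNames(km$cluster - 1L, rownames(matrix)),
       centers = km$centers, tot_withinss = km$tot.withinss)
}

#' Per-cluster per-dataset median delta-PSI
#'
#' Medians are taken over non-imputed entries when at least half of the
#' cluster's entries in that dataset are observed; otherwise over all
#' entries, with `imputed_flag` set.
#'
#' @param matrix delta-PSI matrix.
#' @param labels cluster labels (from [run_kmeans()]).
#' @param imputed logical imputation mask (optional).
#' @return tibble (cluster, dataset, median_dpsi, n_events, imputed_flag).
#' @export
cluster_medians <- function(matrix, labels, imputed = NULL) {
  stopifnot(length(labels) == nrow(matrix))
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(matrix), ncol(matrix),
                      dimnames = dimnames(matrix))
  rows <- list()
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    for (ds in colnames(matrix)) {
      v <- matrix[in_cl, ds]
      obs <- !imputed[in_cl, ds]
      use_obs <- mean(obs) >= 0.5
      med <- stats::median(if (use_obs) v[obs] else v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = cl, dataset = ds, median_dpsi = med,
        n_events = sum(in_cl), imputed_flag = !use_obs)
    }
  }
  dplyr::bind_rows(rows)
}

#' Classify a cluster's median pattern as a NOVA1 GOF/LOF signature
#'
#' LOF: all disease (ALS) medians share one sign with magnitude >=
#' `min_magnitude`, the knock-out median has the same sign and the
#' over-expression median the opposite sign (both with magnitude >=
#' `min_magnitude`) -- disease mimics loss of the protein. GOF is the
#' mirrored pattern (disease agrees with over-expression, opposes
#' knock-out). `dataset_specific`: ALS medians disagree in sign but at
#' least one exceeds the magnitude. `no_change`: every named median is
#' below magnitude. `mixed`: anything else.
#'
#' @param medians named numeric vector of per-dataset medians for one
#'   cluster.
#' @param als_cols names of the disease datasets.
#' @param oe_col over-expression dataset name.
#' @param ko_col knock-out dataset name.
#' @param min_magnitude minimum |median| to count as a change
#'   (default 0.025).
#' @return one of "LOF", "GOF", "dataset_specific", "no_change", "mixed".
#' @export
classify_signature <- function(medians, als_cols, oe_col, ko_col,
                               min_magnitude = 0.025) {
  need <- c(als_cols, oe_col, ko_col)
  if (!all(need %in% names(medians)))
    stop("classify_signature: missing median column(s): ",
         paste(setdiff(need, names(medians)), collapse = ", "))
  als <- medians[als_cols]; oe <- medians[[oe_col]]; ko <- medians[[ko_col]]
  big <- function(v) abs(v) >= min_magnitude
  if (all(!big(c(als, oe, ko)))) return("no_change")
  als_sign <- unique(sign(als[big(als)]))
  als_agree <- all(big(als)) && length(unique(sign(als))) == 1
  if (als_agree) {
    s <- sign(als[[1]])
    if (big(ko) && big(oe) && sign(ko) == s && sign(oe) == -s) return("LOF")
    if (big(ko) && big(oe) && sign(oe) == s && sign(ko) == -s) return("GOF")
    return("mixed")
  }
  if (length(unique(sign(als))) > 1 && any(big(als)))
    return("dataset_specific")
  "mixed"
}

#' Per-cluster positional peak enrichment
#'
#' For each cluster, tests every event sub-region for peak enrichment of
#' the cluster's events against all coverage-passed events of the anchor
#' datasets (the same hypergeometric machinery as
#' [region_enrichment()]).
#'
#' @param labels cluster labels named by event key.
#' @param background_events coverage-passed events resolvable to
#'   coordinates, containing (at least) every clustered event.
#' @param peaks thresholded peak tibble.
#' @return tibble (cluster, region, counts, fold, p); clusters whose
#'   events are absent from the background are flagged with NA rows.
#' @export
cluster_positional_enrichment <- function(labels, background_events, peaks) {
  if (!"event_key" %in% names(background_events))
    background_events <- index_events(background_events)
  bg_regions <- event_regions(background_events)
  region_labels <- setdiff(.region_labels, "junction_span")
  hit_sets <- lapply(region_labels, function(rl)
    events_with_peak(background_events, peaks, rl, regions = bg_regions))
  names(hit_sets) <- region_labels
  n_bg <- nrow(background_events)
  rows <- list()
  for (cl in sort(unique(labels))) {
    keys <- names(labels)[labels == cl]
    keys <- keys[keys %in% background_events$event_key]
    for (rl in region_labels) {
      if (length(keys) == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster = cl, region = rl, n_background = n_bg,
          k_background = length(hit_sets[[rl]]), n_selected = 0L,
          k_selected = 0L, fold_enrichment = NA_real_,
          p_hypergeom = NA_real_, empty_cluster = TRUE)
        next
      }
      k_bg <- length(hit_sets[[rl]])
      k_sel <- sum(keys %in% hit_sets[[rl]])
      fold <- if (k_bg == 0) NA_real_ else
        (k_sel / length(keys)) / (k_bg / n_bg)
      rows[[length(rows) + 1]] <- tibble::tibble(
        cluster = cl, region = rl, n_background = n_bg, k_background = k_bg,
        n_selected = length(keys), k_selected = k_sel,
        fold_enrichment = fold,
        p_hypergeom = hypergeom_sf(n_bg, k_bg, length(keys), k_sel),
        empty_cluster = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}
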