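#' @title Shared statistical primitives
#' @description Exact and approximate tests used throughout the pipeline:
#'   exact Mann-Whitney U, hypergeometric upper tail, Fisher's exact 2x2,
#'   Kruskal-Wallis with pairwise rank-sum follow-up, Welch's t on
#'   log2-transformed intensities, and Spearman correlation. Every test
#'   returns a `test_result` list with fields `statistic`, `p_two_sided`
#'   and a `method` tag ("exact" or "normal-approximation") so downstream
#'   tables record which path produced each P value.
#' @name stats_core
NULL

new_test_result <- function(statistic, p_two_sided, method, ...) {
  stopifnot(p_two_sided > 0, p_two_sided <= 1 + 1e-12)
  structure(
    list(statistic = unname(statistic),
         p_two_sided = min(unname(p_two_sided), 1),
         method = method, ...),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result: statistic = %.6g, two-sided P = %.6g (%s)\n",
              x$statistic, x$p_two_sided, x$method))
  invisible(x)
}

# Enumeration is exact when the permutation set is small enough to walk.
.mw_enumerable <- function(n1, n2, limit = 1e6) {
  (n1 + n2) <= 12 || choose(n1 + n2, n1) <= limit
}

#' Exact two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic for `x` (number of (x, y) pairs
#' with x > y, counting ties as 1/2) and a two-sided P value. For small
#' samples (combined n <= 12, or whenever the full set of
#' choose(n1+n2, n1) group assignments is at most `enum_limit`) the null
#' distribution of U is enumerated exactly over all assignments of the
#' pooled midranks, which handles ties correctly. Larger samples use the
#' normal approximation with tie correction and continuity correction.
#' The two-sided P is twice the smaller tail, capped at 1, matching the
#' convention under which 4-vs-4 complete separation gives P = 2/70.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param enum_limit maximum number of assignments to enumerate exactly.
#' @return a `test_result` with `statistic` = U for `x`.
#' @export
mann_whitney_exact <- function(x, y, enum_limit = 1e6) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney_exact: both samples must be non-empty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("mann_whitney_exact: NA values not allowed")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (.mw_enumerable(n1, n2, enum_limit)) {
    idx <- utils::combn(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_low <- mean(u_all <= u_obs + eps)
    p_high <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_low, p_high))
    return(new_test_result(u_obs, p, "exact"))
  }

  # normal approximation with tie correction (as in the large-sample U test)
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(new_test_result(u_obs, 1, "normal-approximation"))
  mu <- n1 * n2 / 2
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  new_test_result(u_obs, max(p, .Machine$double.xmin), "normal-approximation")
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Probability of drawing at least `k` marked items when `n` items are
#' drawn without replacement from a population of `N` containing `K`
#' marked items. Computed through the stable distribution function in
#' log-capable form (valid for N up to at least 1e6).
#'
#' @param N population size; `K` marked items; `n` draws; `k` observed marked.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_sf <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(K, n))
    stop("hypergeom_sf: require 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher's exact test on a 2x2 table with sample odds ratio
#'
#' Two-sided conditional exact P (sum of tables, at fixed margins, whose
#' probability does not exceed the observed table's) together with the
#' sample odds ratio (a*d)/(b*c) -- deliberately the plug-in estimate, not
#' the conditional MLE. A zero in the OR denominator yields an infinite
#' odds ratio with `or_infinite = TRUE`; the P value is still computed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `test_result` with extra fields `odds_ratio`, `or_infinite`.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stop("fisher_exact_2x2: need a 2x2 table of non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("fisher_exact_2x2: a margin of the table is zero")
  p <- stats::fisher.test(m)$p.value
  denom <- m[1, 2] * m[2, 1]
  or_inf <- denom == 0
  or <- if (or_inf) Inf else (m[1, 1] * m[2, 2]) / denom
  new_test_result(statistic = or, p_two_sided = p, method = "exact",
                  odds_ratio = or, or_infinite = or_inf)
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with its chi-squared P value.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return a `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis: need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(values == values[1]))
    return(new_test_result(0, 1, "normal-approximation"))
  kt <- stats::kruskal.test(values, g)
  new_test_result(unname(kt$statistic), max(kt$p.value, .Machine$double.xmin),
                  "normal-approximation")
}

#' Pairwise two-sided rank-sum tests between all group pairs
#'
#' Mann-Whitney U on every pair of groups; no multiplicity adjustment by
#' default (optional Bonferroni), following a Kruskal-Wallis omnibus test.
#'
#' @param groups named list of numeric vectors.
#' @param adjust "none" or "bonferroni".
#' @return matrix of two-sided P values (diagonal NA).
#' @export
pairwise_ranksum <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2)
    stop("pairwise_ranksum: need >= 2 groups")
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pij <- mann_whitney_exact(groups[[i]], groups[[j]])$p_two_sided
    if (adjust == "bonferroni") pij <- min(1, pij * n_pairs)
    p[i, j] <- p[j, i] <- pij
  }
  p
}

#' Welch's t test on log2(x + 1) transformed values
#'
#' The insolubility screen's significance test: a two-sided Welch (unequal
#' variance) t test on log2(value + pseudocount). Degenerate input with
#' zero variance in both groups gives P = 1.
#'
#' @param x,y numeric vectors (length >= 2 each) of non-negative raw values.
#' @param pseudocount added before the log transform (default 1).
#' @return a `test_result` with the t statistic.
#' @export
welch_t_log <- function(x, y, pseudocount = 1) {
  if (length(x) < 2 || length(y) < 2)
    stop("welch_t_log: need >= 2 values per group")
  lx <- log2(x + pseudocount); ly <- log2(y + pseudocount)
  v1 <- stats::var(lx); v2 <- stats::var(ly)
  if (v1 == 0 && v2 == 0)
    return(new_test_result(0, 1, "normal-approximation"))
  tt <- stats::t.test(lx, ly, var.equal = FALSE)
  new_test_result(unname(tt$statistic), max(tt$p.value, .Machine$double.xmin),
                  "normal-approximation")
}

#' Spearman rank correlation with two-sided P
#'
#' Exact P (via the null permutation distribution of the rank statistic)
#' for n <= 9 without ties, t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a `test_result` with `statistic` = rho and a `rho` field.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_test: length mismatch")
  if (length(x) < 3) stop("spearman_test: need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_test: constant input, rho undefined")
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  new_test_result(unname(ct$estimate),
                  max(ct$p.value, .Machine$double.xmin),
                  if (exact) "exact" else "normal-approximation",
                  rho = unname(ct$estimate))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
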