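# hand-built fixtures and independent oracles shared across test files

make_event <- function(id = "E1", chrom = "chr1", strand = "+",
                       lfs = 100, lfe = 200, aes = 300, aee = 400,
                       rfs = 500, rfe = 600,
                       ijc1 = c(20L, 20L), sjc1 = c(10L, 10L),
                       ijc2 = c(20L, 20L), sjc2 = c(10L, 10L),
                       p = 0.5, fdr = 0.5, dpsi = 0) {
  tibble::tibble(
    event_id = id, gene_id = paste0("G_", id), gene_symbol = paste0("S_", id),
    chrom = chrom, strand = strand,
    alt_exon_start = as.integer(aes), alt_exon_end = as.integer(aee),
    left_flank_start = as.integer(lfs), left_flank_end = as.integer(lfe),
    right_flank_start = as.integer(rfs), right_flank_end = as.integer(rfe),
    ijc_g1 = list(ijc1), sjc_g1 = list(sjc1),
    ijc_g2 = list(ijc2), sjc_g2 = list(sjc2),
    inc_form_len = 98L, skip_form_len = 49L,
    p_value = p, fdr = fdr,
    inc_level_g1 = list(c(0.5, 0.5)), inc_level_g2 = list(c(0.5, 0.5)),
    inc_level_difference = dpsi
  )
}

make_peak <- function(chrom = "chr1", start = 0, end = 10, strand = "+",
                      rbp = "NOVA1", log2_fc = 4, neg_log10_p = 4) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), rbp = rbp, score = 0,
                 strand = strand, log2_fc = log2_fc,
                 neg_log10_p = neg_log10_p)
}

# naive O(n*m) same-strand >=1 bp half-open overlap scan
naive_overlap_any <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(s$chrom == q$chrom[i] & s$strand == q$strand[i] &
          s$start < q$end[i] & q$start[i] < s$end)
  }, logical(1))
}

# upper-tail hypergeometric by direct combinatorial sum
oracle_hyper_sf <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# conditional two-sided Fisher P by table enumeration at fixed margins
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- choose(c1, a_range) * choose(N - c1, r1 - a_range) / choose(N, r1)
  p_obs <- probs[a_range == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney P via enumeration of group assignments,
# computing U by direct pair counting (independent of the rank-sum route)
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
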