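test_that("rMATS reader parses counts, handles empty tables and rejects bad rows", {
  g <- gen_rmats(101, n_events = 30)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_rmats(g$events, tf)
  ev <- read_rmats(tf)
  expect_equal(nrow(ev), 30)
  expect_identical(ev$ijc_g1, g$events$ijc_g1)
  expect_identical(ev$sjc_g2, g$events$sjc_g2)
  expect_equal(ev$inc_level_difference, g$events$inc_level_difference,
               tolerance = 1e-8)
  # write-then-read reproduces the identical key set
  expect_setequal(event_key(ev), g$events$event_key)

  # header-only file -> empty list
  header <- readLines(tf, n = 1)
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(header, tf2)
  expect_equal(nrow(read_rmats(tf2)), 0)

  # missing mandatory column is named in the error
  tab <- readr::read_tsv(tf, show_col_types = FALSE)
  tf3 <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(tab[, setdiff(names(tab), "FDR")], tf3)
  expect_error(read_rmats(tf3), "FDR")

  # invalid strand is rejected with the row identified
  tab$strand[3] <- "."
  tf4 <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(tab, tf4)
  expect_error(read_rmats(tf4), "strand")

  # non-numeric count names the column
  tab <- readr::read_tsv(tf, show_col_types = FALSE)
  tab$IJC_SAMPLE_1[2] <- "12,oops"
  tf5 <- withr::local_tempfile(fileext = ".txt")
  readr::write_tsv(tab, tf5)
  expect_error(read_rmats(tf5), "IJC_SAMPLE_1")
})

test_that("coverage filter is inclusive at the boundary, per sample, and monotone", {
  ev <- dplyr::bind_rows(
    make_event("ok", ijc1 = c(6L, 6L), sjc1 = c(4L, 4L),
               ijc2 = c(5L, 5L), sjc2 = c(5L, 5L)),       # all totals 10
    make_event("low", ijc1 = c(6L, 5L), sjc1 = c(4L, 4L),
               ijc2 = c(9L, 9L), sjc2 = c(9L, 9L))        # one sample at 9
  )
  kept <- coverage_filter(ev, 10)
  expect_equal(kept$event_id, "ok")
  expect_equal(coverage_filter(ev, 0)$event_id, ev$event_id)

  # idempotent and monotone in min_reads
  g <- gen_rmats(102, n_events = 100, depth = 30)$events
  f10 <- coverage_filter(g, 10)
  expect_identical(coverage_filter(f10, 10), f10)
  for (thr in c(0, 5, 15, 25)) {
    expect_true(all(coverage_filter(g, thr + 5)$event_key %in%
                      coverage_filter(g, thr)$event_key))
  }
})

test_that("significance calling uses strict thresholds on FDR and |dPSI|", {
  ev <- dplyr::bind_rows(
    make_event("sig", fdr = 0.04, dpsi = -0.15),
    make_event("fdr_at_boundary", fdr = 0.05, dpsi = 0.5),
    make_event("dpsi_at_boundary", fdr = 0.001, dpsi = 0.10)
  )
  sig <- call_significant(ev)
  expect_equal(sig$event_id, "sig")
  expect_equal(splicing_direction(sig$inc_level_difference), "included")

  # significant set shrinks as thresholds tighten
  g <- coverage_filter(gen_rmats(103, n_events = 200)$events)
  s1 <- call_significant(g, 0.05, 0.1)
  expect_true(all(call_significant(g, 0.01, 0.1)$event_key %in% s1$event_key))
  expect_true(all(call_significant(g, 0.05, 0.2)$event_key %in% s1$event_key))
  expect_true(all(s1$event_key %in% g$event_key))
})

test_that("event keys identify junctions, ignore flank outer bounds, and deduplicate by support", {
  a <- make_event("a", rfe = 600)
  b <- make_event("b", rfe = 650)             # flank outer boundary differs
  expect_equal(event_key(a), event_key(b))
  c2 <- make_event("c", strand = "-")
  expect_false(event_key(a) == event_key(c2))

  # duplicate keys: the row with larger total junction support wins
  dup <- dplyr::bind_rows(
    make_event("weak", ijc1 = c(5L, 5L), sjc1 = c(5L, 5L)),
    make_event("strong", ijc1 = c(50L, 50L), sjc1 = c(50L, 50L))
  )
  expect_warning(res <- index_events(dup), "duplicate")
  expect_equal(res$event_id, "strong")
})

test_that("dataset joins are key-based, symmetric in cardinality, and carry both dPSI columns", {
  fam <- gen_splicing_family(104, n_per_cluster = 10, n_null = 20)
  a <- coverage_filter(fam$datasets$ALS1)
  b <- coverage_filter(fam$datasets$ALS2)
  j <- join_datasets(a, b)
  expect_true(all(c("dpsi_a", "dpsi_b", "fdr_a", "fdr_b") %in% names(j)))
  expect_equal(nrow(j), length(intersect(a$event_key, b$event_key)))
  expect_lte(nrow(j), min(nrow(a), nrow(b)))
  expect_equal(nrow(j), nrow(join_datasets(b, a)))

  # disjoint keys -> empty join; a subset of b -> |a|
  a2 <- a[1:5, ]
  expect_equal(nrow(join_datasets(a2, a)), 5)
  b2 <- b
  b2$chrom <- paste0(b2$chrom, "_other")
  b2$event_key <- NULL
  expect_equal(nrow(join_datasets(a, b2)), 0)
})

test_that("overlap test builds the 2x2 table with sample OR and exact P", {
  joined <- tibble::tibble(event_key = as.character(1:8),
                           dpsi_a = 0, dpsi_b = 0, fdr_a = 1, fdr_b = 1)
  sig_a <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  sig_b <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  r <- overlap_test(joined, sig_a, sig_b)
  expect_equal(r$n_both, 3); expect_equal(r$n_a_only, 1)
  expect_equal(r$n_b_only, 1); expect_equal(r$n_neither, 3)
  expect_equal(r$odds_ratio, 9)
  expect_equal(r$p_fisher, 34 / 70, tolerance = 1e-12)

  # independence-structured table
  j2 <- tibble::tibble(event_key = as.character(1:100), dpsi_a = 0,
                       dpsi_b = 0, fdr_a = 1, fdr_b = 1)
  fa <- rep(c(TRUE, FALSE), each = 50)
  fb <- rep(c(TRUE, FALSE), times = 50)
  r2 <- overlap_test(j2, fa, fb)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_fisher, 1)

  # zero cell in the OR denominator
  r3 <- overlap_test(joined, sig_a, sig_a)
  expect_true(r3$or_infinite)
  expect_true(is.finite(r3$p_fisher))
})

test_that("delta-PSI correlation recovers planted monotone association", {
  j <- tibble::tibble(event_key = as.character(1:5),
                      dpsi_a = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      dpsi_b = c(0.1, 0.2, 0.3, 0.4, 0.5),
                      fdr_a = 0, fdr_b = 0)
  expect_equal(dpsi_correlation(j)$rho, 1)
  j$dpsi_b <- rev(j$dpsi_b)
  expect_equal(dpsi_correlation(j)$rho, -1)
  expect_error(dpsi_correlation(j[1:2, ]), ">= 3")

  # bivariate monotone noise: Gaussian copula with known rank correlation
  set.seed(105)
  n <- 200; rho <- 0.8
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  jj <- tibble::tibble(event_key = as.character(1:n), dpsi_a = z1,
                       dpsi_b = z2, fdr_a = 0, fdr_b = 0)
  rho_rank <- 6 / pi * asin(rho / 2)      # analytic Spearman of the copula
  expect_lt(abs(dpsi_correlation(jj)$rho - rho_rank), 0.1)
})
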