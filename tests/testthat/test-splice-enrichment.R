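test_that("event regions are transcript-oriented with the minus-strand label swap", {
  plus <- event_regions(index_events(make_event("p")))
  get <- function(r, lab) unlist(r[r$label == lab, c("start", "end")])
  expect_equal(unname(get(plus, "upstream_exon")), c(100, 200))
  expect_equal(unname(get(plus, "upstream_intron")), c(200, 300))
  expect_equal(unname(get(plus, "alternative_exon")), c(300, 400))
  expect_equal(unname(get(plus, "downstream_intron")), c(400, 500))
  expect_equal(unname(get(plus, "downstream_exon")), c(500, 600))
  expect_equal(unname(get(plus, "junction_span")), c(100, 600))

  # same genomic coordinates on "-": upstream labels move to the right side
  minus <- event_regions(index_events(make_event("m", strand = "-")))
  expect_equal(unname(get(minus, "upstream_intron")), c(400, 500))
  expect_equal(unname(get(minus, "downstream_intron")), c(200, 300))
  expect_equal(unname(get(minus, "upstream_exon")), c(500, 600))

  # abutting exons: the zero-length intron is dropped
  ab <- event_regions(index_events(make_event("ab", lfe = 300)))
  expect_false("upstream_intron" %in% ab$label)
  expect_equal(nrow(ab), 5)
})

test_that("events_with_peak uses -u semantics and matches a naive scan", {
  ev <- index_events(dplyr::bind_rows(
    make_event("e1"),
    make_event("e2", lfs = 2000, lfe = 2100, aes = 2300, aee = 2400,
               rfs = 2600, rfe = 2700)
  ))
  # one peak inside e1's junction span only
  p <- make_peak(start = 320, end = 340)
  expect_equal(events_with_peak(ev, p, "junction_span"), ev$event_key[1])
  expect_equal(events_with_peak(ev, p, "alternative_exon"), ev$event_key[1])
  # many peaks on one event still count it once
  p3 <- dplyr::bind_rows(p, make_peak(start = 350, end = 360))
  expect_equal(length(events_with_peak(ev, p3, "alternative_exon")), 1)
  expect_equal(events_with_peak(ev, empty_peaks(), "junction_span"),
               character(0))
  expect_error(events_with_peak(ev, p, "promoter"), "unknown region")

  # a peak spanning two events' introns returns both events
  ev2 <- index_events(dplyr::bind_rows(
    make_event("a"),
    make_event("b", lfs = 420, lfe = 450, aes = 460, aee = 470,
               rfs = 480, rfe = 490)
  ))
  wide <- make_peak(start = 410, end = 465)
  hit <- events_with_peak(ev2, wide, "downstream_intron")
  expect_equal(sort(hit), sort(ev2$event_key[1:1]))
  hit_b <- events_with_peak(ev2, wide, "upstream_intron")
  expect_true(ev2$event_key[2] %in% hit_b)

  # random events/peaks against the naive all-pairs oracle
  set.seed(31)
  g <- coverage_filter(gen_rmats(31, n_events = 60)$events)
  gp <- gen_peaks(g, 31, planted_keys = g$event_key[1:20],
                  planted_region = "alternative_exon", plant_rate = 0.5,
                  background_rate = 0.3)
  regions <- event_regions(g)
  for (lab in c("upstream_intron", "alternative_exon", "junction_span")) {
    reg <- regions[regions$label == lab, ]
    naive <- unique(reg$event_key[naive_overlap_any(reg, gp$peaks)])
    expect_setequal(events_with_peak(g, gp$peaks, lab), naive)
  }
})

test_that("region enrichment reproduces enumerated hypergeometric examples", {
  ev <- index_events(dplyr::bind_rows(lapply(1:10, function(i)
    make_event(paste0("e", i), lfs = i * 3000, lfe = i * 3000 + 100,
               aes = i * 3000 + 300, aee = i * 3000 + 400,
               rfs = i * 3000 + 600, rfe = i * 3000 + 700,
               fdr = ifelse(i <= 5, 0.01, 0.9),
               dpsi = ifelse(i <= 5, 0.5, 0)))))
  sig <- call_significant(ev)
  expect_equal(nrow(sig), 5)
  # peaks in the alt exon of events 1..4: N=10, K=4, n=5, k=4
  pk <- dplyr::bind_rows(lapply(1:4, function(i)
    make_peak(start = i * 3000 + 310, end = i * 3000 + 330)))
  r <- region_enrichment(sig, ev, pk, "alternative_exon", "all")
  expect_equal(r$p_hypergeom, 6 / 252, tolerance = 1e-12)
  expect_equal(r$fold_enrichment, 2.0)
  expect_equal(r$k_selected, 4)

  # no peaks at all -> k = 0 -> P = 1, fold undefined
  r0 <- region_enrichment(sig, ev, empty_peaks(), "alternative_exon", "all")
  expect_equal(r0$p_hypergeom, 1)
  expect_true(r0$fold_undefined)

  # direction filter with no qualifying events errors
  expect_error(region_enrichment(sig, ev, pk, "alternative_exon", "included"),
               "no selected events")
})

test_that("enrichment is invariant under coordinate mirroring with strand flip", {
  g <- coverage_filter(gen_rmats(32, n_events = 80)$events)
  sig <- call_significant(g)
  gp <- gen_peaks(g, 32, planted_keys = sig$event_key,
                  planted_region = "upstream_intron", plant_rate = 0.7,
                  background_rate = 0.15)
  pp1 <- positional_profile(sig, g, gp$peaks)

  L <- max(g$right_flank_end) + max(gp$peaks$end) + 10
  mirror_events <- function(ev) {
    out <- ev
    out$left_flank_start <- L - ev$right_flank_end
    out$left_flank_end <- L - ev$right_flank_start
    out$alt_exon_start <- L - ev$alt_exon_end
    out$alt_exon_end <- L - ev$alt_exon_start
    out$right_flank_start <- L - ev$left_flank_end
    out$right_flank_end <- L - ev$left_flank_start
    out$strand <- ifelse(ev$strand == "+", "-", "+")
    out$event_key <- NULL
    index_events(out)
  }
  mirror_peaks <- function(p) {
    out <- p
    out$start <- L - p$end
    out$end <- L - p$start
    out$strand <- ifelse(p$strand == "+", "-", "+")
    out
  }
  gm <- mirror_events(g)
  sigm <- mirror_events(sig)
  pp2 <- positional_profile(sigm, gm, mirror_peaks(gp$peaks))
  expect_equal(pp1$k_selected, pp2$k_selected)
  expect_equal(pp1$k_background, pp2$k_background)
  expect_equal(pp1$p_hypergeom, pp2$p_hypergeom, tolerance = 1e-12)
})

test_that("positional profile recovers a planted region x direction cell", {
  g <- coverage_filter(gen_rmats(33, n_events = 300,
                                 effect_fraction = 0.25)$events)
  sig <- call_significant(g)
  inc <- sig[sig$inc_level_difference < 0, ]
  gp <- gen_peaks(g, 33, planted_keys = inc$event_key,
                  planted_region = "downstream_intron", plant_rate = 0.6,
                  background_rate = 0.1)
  pp <- positional_profile(sig, g, gp$peaks)
  cells <- pp[pp$direction != "all", ]
  best <- cells[which.min(cells$p_hypergeom), ]
  expect_equal(best$region, "downstream_intron")
  expect_equal(best$direction, "included")
  expect_error(positional_profile(sig[0, ], g, gp$peaks), "empty significant")
})

test_that("proximal intron windows localize near-exon binding", {
  g <- coverage_filter(gen_rmats(34, n_events = 250,
                                 effect_fraction = 0.3)$events)
  sig <- call_significant(g)

  # plant peaks within 100 bp of the alt-exon end of the upstream intron:
  # emulate by planting into a window-restricted region copy
  regions <- event_regions(g)
  up <- regions[regions$label == "upstream_intron" &
                regions$event_key %in% sig$event_key, ]
  alt_right <- up$strand == "+"
  w <- pmin(100, up$end - up$start)
  ps <- ifelse(alt_right, up$end - w, up$start)
  set.seed(34)
  sel <- runif(nrow(up)) < 0.7
  pk <- tibble::tibble(chrom = up$chrom[sel],
                       start = as.integer(ps[sel]),
                       end = as.integer(ps[sel] + pmin(30, w[sel])),
                       rbp = "NOVA1", score = 0, strand = up$strand[sel],
                       log2_fc = 5, neg_log10_p = 5)
  near <- proximal_window_enrichment(sig, g, pk, "upstream_intron", 250,
                                     direction = "all")
  far <- proximal_window_enrichment(sig, g, pk, "upstream_intron", 250,
                                    direction = "all", anchor = "far")
  expect_lt(near$p_hypergeom, 1e-6)
  expect_gt(far$p_hypergeom, near$p_hypergeom)

  # a window at least as long as every intron reduces to the full result
  full <- region_enrichment(sig, g, pk, "upstream_intron", "all")
  wide <- proximal_window_enrichment(sig, g, pk, "upstream_intron", 10^7,
                                     direction = "all")
  expect_equal(wide$p_hypergeom, full$p_hypergeom)
  expect_equal(wide$k_selected, full$k_selected)
  expect_error(proximal_window_enrichment(sig, g, pk, "upstream_intron", 0),
               "window_bp")
  expect_error(proximal_window_enrichment(sig, g, pk, "alternative_exon", 10),
               "intron")
})
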