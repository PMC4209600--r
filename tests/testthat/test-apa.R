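test_that("fit_breakpoint recovers constructed step positions", {
  f <- fit_breakpoint(c(5, 5, 5, 1, 1, 1), minseg = 1)
  expect_equal(f$breakpoint, 3L)
  expect_equal(f$proximal_mean, 5)
  expect_equal(f$distal_mean, 1)
  expect_false(f$flat)

  expect_equal(fit_breakpoint(c(10, 10, 2, 2, 2, 2), minseg = 2)$breakpoint, 2L)

  flat <- fit_breakpoint(rep(4, 6), minseg = 1)
  expect_true(flat$flat)
  expect_equal(flat$breakpoint, 1L)  # reported at minseg for flat tracks

  short <- fit_breakpoint(c(1, 2, 3), minseg = 2)
  expect_true(short$qc_fail)
  expect_true(is.na(short$breakpoint))
})

test_that("fit_breakpoint ties break to the smallest index", {
  # symmetric track: k = 2 and k = 4 give equal RSS; first minimum wins
  f <- fit_breakpoint(c(1, 1, 5, 1, 1, 1), minseg = 1)
  b <- brute_breakpoint(c(1, 1, 5, 1, 1, 1), 1)
  expect_equal(f$breakpoint, b$k)
})

test_that("fit_breakpoint equals exhaustive RSS minimisation on random tracks", {
  set.seed(21)
  for (i in 1:150) {
    L <- sample(10:200, 1)
    minseg <- sample(1:4, 1)
    cov <- rpois(L, sample(c(2, 20, 80), 1))
    f <- fit_breakpoint(cov, minseg = minseg)
    b <- brute_breakpoint(cov, minseg)
    if (!f$flat) {
      expect_equal(f$breakpoint, b$k, label = sprintf("track %d", i))
      expect_equal(f$rss, b$rss, tolerance = 1e-9)
    }
  }
})

test_that("raw-scale breakpoint is invariant to positive scaling of the track", {
  set.seed(5)
  for (i in 1:30) {
    cov <- c(rpois(60, 40), rpois(60, 6))
    f1 <- fit_breakpoint(cov, minseg = 5, transform = "raw")
    f2 <- fit_breakpoint(cov * 3.7, minseg = 5, transform = "raw")
    expect_equal(f1$breakpoint, f2$breakpoint)
  }
})

test_that("distal usage index matches hand computations", {
  expect_equal(distal_usage_index(c(5, 5, 5, 1, 1, 1), 3, pseudocount = 0), 0.2)
  expect_equal(distal_usage_index(rep(7, 10), 4, pseudocount = 0), 1)
  expect_equal(distal_usage_index(c(2, 2, 0, 0), 2, pseudocount = 0.5), 0.2)
  expect_error(distal_usage_index(c(1, 2, 3), 3), "segment")
})

test_that("shortening calls combine the DUI ratio, coverage floor and seed position", {
  set.seed(31)
  L <- 300
  sites_distal <- data.frame(transcript_id = "tx", start = 150L, end = 158L,
                             site_type = "8mer")
  sites_prox <- data.frame(transcript_id = "tx", start = 10L, end = 18L,
                           site_type = "8mer")
  uniform <- rpois(L, 20)
  stepped <- c(rpois(100, 20), rpois(L - 100, 2))

  same <- call_shortening(uniform, uniform, sites_distal)
  expect_false(same$shortened)
  expect_false(same$seed_lost)
  expect_equal(same$dui_ratio, 1)

  lost <- call_shortening(rpois(L, 20), stepped, sites_distal)
  expect_true(lost$shortened)
  expect_true(lost$seed_lost)
  expect_true(lost$dui_ratio <= 0.5)

  kept <- call_shortening(rpois(L, 20), stepped, sites_prox)
  expect_true(kept$shortened)
  expect_false(kept$seed_lost)

  expect_error(call_shortening(rpois(10, 5), rpois(11, 5), NULL,
                               transcript_id = "txX"), "txX")
})

test_that("insufficient coverage yields a QC failure, not a call", {
  set.seed(12)
  low <- rpois(300, 0.2)
  ok <- rpois(300, 20)
  res <- call_shortening(low, ok, NULL)
  expect_true(res$qc_fail)
  expect_true(is.na(res$shortened))
  res2 <- call_shortening(ok, low, NULL)
  expect_true(res2$qc_fail)
})

test_that("a vector track already lacking distal coverage is annotated lost_in_both", {
  set.seed(8)
  both_lost_v <- c(rpois(100, 30), rpois(200, 0.5))
  both_lost_m <- c(rpois(100, 30), rpois(200, 0.2))
  res <- call_shortening(both_lost_v, both_lost_m, NULL)
  expect_true(res$lost_in_both)
  uniform <- rpois(300, 30)
  expect_false(call_shortening(uniform, uniform, NULL)$lost_in_both)
})

test_that("seed_lost implies shortened on simulated screens", {
  cfg <- sim_config(n_genes = 60, seed = 77)
  sim <- simulate_screen(cfg)
  motifs <- derive_seed_motifs(mir155())
  sites <- scan_utr_set(sim$utrs, motifs)
  calls <- call_shortening_set(sim$tracks_vector, sim$tracks_mir155, sites)
  ok <- !is.na(calls$seed_lost)
  expect_true(all(!calls$seed_lost[ok] | calls$shortened[ok]))
})

test_that("seed escape fraction weights isoforms by expression", {
  iso <- data.frame(isoform_id = c("v1", "v2", "v4"),
                    expression = c(3, 0, 1),
                    contains_seed_utr = c(TRUE, TRUE, FALSE))
  expect_equal(seed_escape_fraction(iso), 0.25)
  iso$contains_seed_utr <- TRUE
  expect_equal(seed_escape_fraction(iso), 0)
  iso$contains_seed_utr <- FALSE
  expect_equal(seed_escape_fraction(iso), 1)
  iso$expression <- 0
  expect_error(seed_escape_fraction(iso), "undefined")
})
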