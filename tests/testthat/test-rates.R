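test_that("sector frequencies and confidence limits match binomial theory", {
  f1 <- sector_frequency(197, 39417)
  expect_equal(f1$estimate, 5.0e-3, tolerance = 0.01)
  expect_equal(f1$lo, 4.4e-3, tolerance = 0.03)
  expect_equal(f1$hi, 5.7e-3, tolerance = 0.03)
  expect_equal(sector_frequency(118, 36403)$estimate, 3.2e-3,
               tolerance = 0.015)

  f0 <- sector_frequency(0, 1000)
  expect_equal(f0$estimate, 0)
  expect_equal(f0$lo, 0, tolerance = 1e-9)

  cp <- sector_frequency(197, 39417, ci_method = "clopper-pearson")
  expect_lt(cp$lo, f1$estimate)
  expect_error(sector_frequency(5, 0), "n_total")
})

test_that("the median-method estimator is monotone and flags zero medians", {
  counts <- simulate_fluctuation_cultures(1e-5, 1e7, 60, seed = 11)
  est <- estimate_rate_median(counts, 1e7)
  expect_lt(abs(est$estimate / 1e-5 - 1), 0.3)
  expect_true(est$lo <= est$estimate && est$estimate <= est$hi)

  est2 <- estimate_rate_median(counts * 2, 1e7)
  expect_gt(est2$estimate, est$estimate)

  z <- estimate_rate_median(rep(0, 20), 1e7)
  expect_match(z$flag, "upper-bound")
  expect_equal(z$estimate, 0)
  expect_gt(z$hi, 0)
  expect_error(estimate_rate_median(c(1, 2), 1e7), "5 cultures")
})

test_that("segregation and viability corrections reproduce the worked arithmetic", {
  expect_equal(crossover_rate_from_sectors(2.8e-2), 5.6e-2)
  expect_equal(crossover_rate_from_sectors(0), 0)

  expect_equal(events_per_genome(4.2e-2 / 2, 1, 0.9), 5.2e-2,
               tolerance = 0.005)
  expect_equal(events_per_genome(7.3e-1 / 2, 1, 0.1), 73)
  expect_equal(events_per_genome(7.3e-1 / 2, 1, 0.1,
                                 include_noncrossover = TRUE), 146)
  # corrections are multiplicative and order-independent
  expect_equal(events_per_genome(0.1, 0.5, 0.8),
               events_per_genome(0.1, 1, 0.8) / 0.5)
  expect_error(events_per_genome(0.1, 0, 0.5), "interval_fraction")

  cc <- correct_co_con_counts(26, 61)
  expect_equal(c(cc$co, cc$con), c(52, 35))
  expect_equal(unlist(correct_co_con_counts(0, 9)[c("co", "con")]),
               c(co = 0, con = 9))
  expect_equal(unlist(correct_co_con_counts(10, 10)[c("co", "con")]),
               c(co = 20, con = 0))
  expect_warning(bad <- correct_co_con_counts(10, 4), "negative")
  expect_match(bad$flag, "negative")
})

test_that("tract-length bootstrap brackets the median and has coverage", {
  one <- tract_length_stats(10, n_boot = 100, seed = 1)
  expect_equal(c(one$median_kb, one$lo, one$hi), c(10, 10, 10))

  x <- rtract_length(200, median_kb = 13)
  ts <- tract_length_stats(x, n_boot = 2000, seed = 2)
  expect_true(ts$lo <= ts$median_kb && ts$median_kb <= ts$hi)
  # order invariance
  ts2 <- tract_length_stats(rev(x), n_boot = 2000, seed = 2)
  expect_equal(ts$median_kb, ts2$median_kb)

  # bootstrap CL covers the true median parameter in >= 93% of repetitions
  withr::with_seed(7, {
    cover <- vapply(1:100, function(i) {
      xi <- rtract_length(200, median_kb = 13)
      ci <- tract_length_stats(xi, n_boot = 500, seed = i)
      ci$lo <= 13 && 13 <= ci$hi
    }, logical(1))
  })
  expect_gte(mean(cover), 0.93)
  expect_error(tract_length_stats(numeric(0)), "no tracts")
})

test_that("G1 fractions and per-isolate means match the published tallies", {
  fr <- fraction_g1_initiated(c(74, 87))
  expect_equal(fr$fraction, 0.85, tolerance = 0.01)
  expect_equal(fraction_g1_initiated(c(55, 73))$fraction, 0.75,
               tolerance = 0.01)
  expect_equal(fraction_g1_initiated(c(0, 10))$fraction, 0)
  expect_error(fraction_g1_initiated(c(0, 0)), "no typed")

  g <- build_genome(genome_config("paper"), seed = 1)
  mk_events <- function(n, n_iso) {
    data.frame(isolate = rep_len(sprintf("i%02d", seq_len(n_iso)), n),
               chrom = rep_len(g$chromosomes$chrom, n), type = "CON",
               loh_kb = 10, cnv_kb = 0)
  }
  s1 <- per_isolate_summary(mk_events(101, 14), g, n_isolates = 14)
  expect_equal(s1$mean_events_per_isolate, 7.2, tolerance = 0.01)
  s2 <- per_isolate_summary(mk_events(347, 30), g, n_isolates = 30)
  expect_equal(s2$mean_events_per_isolate, 11.6, tolerance = 0.01)
  expect_equal(sum(s2$per_chromosome$n_events), 347)
  expect_gt(s2$length_fit$events_per_kb, 0)

  s0 <- per_isolate_summary(mk_events(10, 2)[0, ], g, n_isolates = 5)
  expect_equal(s0$mean_events_per_isolate, 0)
})

test_that("hotspot test flags concentration and passes its null", {
  ints <- data.frame(start_kb = seq(0, 900, 100), end_kb = seq(100, 1000, 100))
  ht <- hotspot_test(rep(55, 20), ints)
  expect_lt(ht$p_adj[1], 1e-6)

  one <- hotspot_test(runif(30, 0, 1000), data.frame(start_kb = 0,
                                                     end_kb = 1000))
  expect_equal(one$p, 1)

  withr::with_seed(21, {
    sig <- vapply(1:100, function(i) {
      any(hotspot_test(runif(100, 0, 1000), ints)$p_adj < 0.05)
    }, logical(1))
  })
  expect_gte(mean(!sig), 0.95)
  expect_error(hotspot_test(numeric(0), ints), "no events")
})

test_that("feature enrichment detects planted overlap and respects empty tracks", {
  g <- build_genome(genome_config("paper"), seed = 1)
  whole <- lapply(seq_len(nrow(g$chromosomes)), function(i) {
    data.frame(chrom = g$chromosomes$chrom[i], start_kb = 0,
               end_kb = g$chromosomes$length_kb[i])
  })
  whole <- do.call(rbind, whole)
  ev <- data.frame(chrom = c("chrI", "chrV"), start_kb = c(10, 50),
                   end_kb = c(20, 60))
  fe <- feature_enrichment(ev, list(all = whole), g, n_perm = 200, seed = 1)
  expect_equal(fe$observed, 2)
  expect_equal(fe$p, 1)

  feat <- g$features$Ty
  withr::with_seed(5, {
    hit <- feat[sample(nrow(feat), 50, replace = TRUE), ]
    ev2 <- data.frame(chrom = hit$chrom, start_kb = hit$start_kb + 0.1,
                      end_kb = hit$start_kb + 0.5)
  })
  fe2 <- feature_enrichment(ev2, list(Ty = feat), g, n_perm = 10000, seed = 2)
  expect_lte(fe2$p, 0.001)
  expect_equal(fe2$direction, "enriched")

  expect_warning(
    fe3 <- feature_enrichment(ev, list(empty = feat[0, ], Ty = feat), g,
                              n_perm = 100, seed = 3),
    "empty track")
  expect_equal(nrow(fe3), 1)
})

test_that("rDNA expectation and zero probability follow the Poisson model", {
  r <- rdna_expectation(105, 0.0762)
  expect_equal(r$expected, 8.0, tolerance = 0.001)
  expect_equal(rdna_expectation(105, 8 / 105)$p_zero, exp(-8))
  expect_lt(rdna_expectation(105, 0.0762)$p_zero, 0.01)
  z <- rdna_expectation(0, 0.1)
  expect_equal(c(z$expected, z$p_zero), c(0, 1))
})

test_that("spectrum comparison is chi-square with symmetric per-class tests", {
  s <- c(30, 10, 50, 20, 25, 15)
  same <- compare_spectra(s, s)
  expect_equal(unname(same$chisq$statistic), 0)
  expect_equal(same$p, 1)

  dis <- compare_spectra(c(100, 0, 0, 0, 0, 0), c(0, 100, 0, 0, 0, 0))
  expect_lt(dis$p, 1e-10)

  a <- c(40, 10, 60, 25, 30, 20); b <- c(10, 35, 20, 30, 15, 25)
  ab <- compare_spectra(a, b); ba <- compare_spectra(b, a)
  expect_equal(ab$per_class$p, ba$per_class$p)
  expect_error(compare_spectra(rep(0, 6), s), "zero-total")
})
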