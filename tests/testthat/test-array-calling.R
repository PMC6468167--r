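test_that("normalization fixes the array mean at 1 and is scale-invariant", {
  g <- small_genome()
  raw <- render_profile(diploid_genotype(g), 0.2, seed = 1)
  raw$ratio_W <- raw$ratio_W * 3.7  # arbitrary scanner gain
  raw$ratio_Y <- raw$ratio_Y * 3.7
  norm <- normalize_profile(raw)
  expect_equal(mean(c(norm$ratio_W, norm$ratio_Y)), 1, tolerance = 1e-9)

  raw2 <- raw
  raw2$ratio_W <- raw$ratio_W * 10; raw2$ratio_Y <- raw$ratio_Y * 10
  expect_equal(normalize_profile(raw2), norm)

  const <- raw; const$ratio_W <- 5; const$ratio_Y <- 5
  cn <- normalize_profile(const)
  expect_true(all(cn$ratio_W == 1) && all(cn$ratio_Y == 1))

  zero <- raw; zero$ratio_W <- 0; zero$ratio_Y <- 0
  expect_error(normalize_profile(zero), "all-zero")
})

test_that("marker states go to the nearest dosage centroid", {
  prof <- data.frame(chrom = "chrA", pos_kb = 1:3,
                     ratio_W = c(1.6, 1.0, 0.3),
                     ratio_Y = c(0.2, 1.0, 1.5))
  calls <- call_marker_states(prof)
  expect_equal(calls$cnW, c(2L, 1L, 0L))
  expect_equal(calls$cnY, c(0L, 1L, 2L))
  expect_true(all(calls$margin > 0))
  expect_error(call_marker_states(prof, centroids = c(1, 0.5)), "increasing")
})

test_that("moving-average smoothing has the prescribed window behaviour", {
  g <- small_genome()
  prof <- render_profile(diploid_genotype(g), 0, seed = 1)
  expect_equal(smooth_profile(prof, 9), prof)      # constant profile
  noisy <- render_profile(diploid_genotype(g), 0.15, seed = 2)
  expect_equal(smooth_profile(noisy, 1), noisy)    # window 1 is identity

  # single outlier 3.0 among 1.0 values: centre of a 9-window is (8*1 + 3)/9
  out <- prof
  i <- 100
  out$ratio_W[i] <- 3.0
  sm <- smooth_profile(out, 9)
  expect_equal(sm$ratio_W[i], (8 * 1 + 3) / 9, tolerance = 1e-12)
  expect_error(smooth_profile(prof, 8), "odd")
})

test_that("segmentation finds maximal runs with correct breakpoint intervals", {
  g <- small_genome()
  prof <- render_profile(diploid_genotype(g), 0, seed = 1)
  calls <- call_marker_states(prof)
  seg <- segment_states(calls, g)
  expect_equal(nrow(seg), 3)                       # one (1,1) run per chromosome
  expect_true(all(seg$cnW == 1 & seg$cnY == 1))

  # a planted transition is reported between the flanking informative markers
  geno <- diploid_genotype(g)
  sel <- geno$chrom == "chrA" & geno$pos_kb >= 500
  geno$cnW[sel] <- 2L; geno$cnY[sel] <- 0L
  calls2 <- call_marker_states(render_profile(geno, 0, seed = 2))
  seg2 <- segment_states(calls2, g)
  sa <- seg2[seg2$chrom == "chrA", ]
  expect_equal(nrow(sa), 2)
  expect_equal(sa$bp_left_lo[2], 499)
  expect_equal(sa$bp_left_hi[2], 500)

  # partition property: segments tile each chromosome's markers exactly once
  for (ch in unique(seg2$chrom)) {
    expect_equal(sum(seg2$n_markers[seg2$chrom == ch]),
                 sum(g$markers$chrom == ch))
  }
})

test_that("short noisy runs are absorbed into the longer (or proximal) flank", {
  g <- small_genome()
  calls <- call_marker_states(render_profile(diploid_genotype(g), 0, seed = 1))
  idx <- which(calls$chrom == "chrA")
  calls$cnW[idx[400]] <- 2L; calls$cnY[idx[400]] <- 0L  # lone miscall
  seg <- segment_states(calls, g, min_markers = 2)
  expect_equal(nrow(seg[seg$chrom == "chrA", ]), 1)
})

test_that("the full pipeline is exact on noiseless data and degrades monotonely", {
  g <- small_genome()
  geno <- diploid_genotype(g)
  sel <- geno$chrom == "chrB" & geno$pos_kb >= 350 & geno$pos_kb <= 380
  geno$cnW[sel] <- 2L; geno$cnY[sel] <- 0L
  res <- call_pipeline(render_profile(geno, 0, seed = 3), g)
  sb <- res$segments[res$segments$chrom == "chrB", ]
  expect_equal(nrow(sb), 3)
  expect_equal(sb$start_kb[2], 350)
  expect_equal(sb$end_kb[2], 380)

  # whole-chromosome (0,2) genotype is called as one chromosome-wide segment
  upd <- diploid_genotype(g)
  on_c <- upd$chrom == "chrC"
  upd$cnW[on_c] <- 0L; upd$cnY[on_c] <- 2L
  resu <- call_pipeline(render_profile(upd, 0, seed = 4), g)
  sc <- resu$segments[resu$segments$chrom == "chrC", ]
  expect_equal(nrow(sc), 1)
  expect_equal(c(sc$cnW, sc$cnY), c(0, 2))

  # monotone noise degradation on a fixed planted cohort
  gp <- build_genome(genome_config("paper"), seed = 1)
  rec <- vapply(c(0.05, 0.2), function(ns) {
    co <- simulate_sector_cohort(gp, 40, noise_sd = ns, seed = 11)
    ev <- classify_cohort(co, gp)
    mean(evaluate_recovery(co$truth, ev, gp)$recovered)
  }, numeric(1))
  expect_gte(rec[1], rec[2])
})

test_that("hybridization ratios are reciprocal at homozygous markers", {
  g <- small_genome()
  geno <- diploid_genotype(g)
  sel <- geno$chrom == "chrA" & geno$pos_kb >= 400
  geno$cnW[sel] <- 2L; geno$cnY[sel] <- 0L
  prof <- render_profile(geno, 0.2, seed = 9)
  expect_gte(mean(prof$ratio_W[sel] > prof$ratio_Y[sel]), 0.99)
})
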