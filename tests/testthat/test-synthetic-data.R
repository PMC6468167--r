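test_that("build_genome honours marker counts, sorting, and determinism", {
  g <- small_genome()
  expect_s3_class(g, "genome_map")
  for (ch in unique(g$markers$chrom)) {
    expect_false(is.unsorted(g$markers$pos_kb[g$markers$chrom == ch],
                             strictly = TRUE))
  }

  cfg <- genome_config("custom",
                       chromosomes = data.frame(chrom = c("c1", "c2"),
                                                length_kb = c(1000, 1000),
                                                cen_kb = c(400, 400)),
                       n_markers = 200, features = FALSE)
  g2 <- build_genome(cfg, seed = 3)
  expect_equal(nrow(g2$markers), 200)
  g2b <- build_genome(cfg, seed = 3)
  expect_identical(g2$markers, g2b$markers)

  gp <- build_genome(genome_config("paper"), seed = 1)
  expect_equal(nrow(gp$markers), 15000)
  expect_equal(nrow(gp$chromosomes), 16)
  expect_equal(sum(gp$chromosomes$length_kb), 12071, tolerance = 0.01)
  expect_equal(nrow(gp$features$rDNA), 1)

  expect_error(genome_config("custom",
                             chromosomes = data.frame(chrom = "c1",
                                                      length_kb = -5,
                                                      cen_kb = 1)),
               "positive")
})

test_that("planted crossover mechanisms produce the diagnostic LOH patterns", {
  g <- small_genome()
  pl <- plant_event(g, planted_event("G1_DSB_CO", "chrA", 600, donor = "W",
                                     tract_kb = list(a1 = 5, a2 = 15, b2 = 20)),
                    seed = 1)
  d1 <- pl$daughter1; d2 <- pl$daughter2
  pos <- d1$pos_kb
  on_a <- d1$chrom == "chrA"
  # both daughters altered distal of the break; merged tract has 3:1 and 4:0
  distal <- on_a & pos > 640
  expect_true(all(d1$cnW[distal] == 2 & d1$cnY[distal] == 0))
  expect_true(all(d2$cnW[distal] == 0 & d2$cnY[distal] == 2))
  t40 <- on_a & pos >= 595 & pos <= 620  # both daughters homozygous donor
  expect_true(all(d1$cnW[t40] + d2$cnW[t40] == 4))
  t31 <- on_a & pos >= 586 & pos <= 594
  expect_true(all(d1$cnW[t31] + d2$cnW[t31] == 3))

  # BIR: daughter 2 identical to the diploid input at every marker
  plb <- plant_event(g, planted_event("BIR", "chrB", 400, donor = "Y"),
                     seed = 2)
  expect_identical(plb$daughter2, diploid_genotype(g))
  expect_true(any(plb$daughter1$cnY == 2))

  # CON_only: zero markers with reciprocal terminal LOH
  plc <- plant_event(g, planted_event("CON_only", "chrC", 250, donor = "W",
                                      tract_kb = list(a = 10, b = 10)),
                     seed = 3)
  recip <- plc$daughter1$cnW == 2 & plc$daughter2$cnY == 2
  expect_equal(sum(recip), 0)

  expect_error(plant_event(g, planted_event("BIR", "chrA", 5000), seed = 1),
               "outside")
})

test_that("copy number is conserved across daughters for copy-neutral mechanisms", {
  g <- small_genome()
  for (m in c("G1_DSB_CO", "G2_DSB_CO", "BIR", "CON_only", "UPD")) {
    pl <- plant_event(g, planted_event(m, "chrA", 550, donor = "W",
                                       tract_kb = list(a1 = 6, a2 = 14,
                                                       b2 = 12, a = 8, b = 8)),
                      seed = 7)
    tot <- pl$daughter1$cnW + pl$daughter1$cnY +
           pl$daughter2$cnW + pl$daughter2$cnY
    expect_true(all(tot == 4), label = paste("copy conservation for", m))
  }
  # reciprocity distal of the tract for crossover mechanisms
  pl <- plant_event(g, planted_event("G2_DSB_CO", "chrA", 550, donor = "W",
                                     tract_kb = list(a = 8, b = 8)), seed = 8)
  distal <- pl$daughter1$chrom == "chrA" & pl$daughter1$pos_kb > 570
  expect_true(all(pl$daughter1$cnW[distal] == 2 &
                  pl$daughter2$cnY[distal] == 2))
})

test_that("rendered ratios sit on the dosage centroids and reproduce per seed", {
  g <- small_genome()
  geno <- diploid_genotype(g)
  prof <- render_profile(geno, 0, seed = 1)
  expect_true(all(prof$ratio_W == 1.0) && all(prof$ratio_Y == 1.0))

  geno$cnW[1] <- 2L; geno$cnY[1] <- 0L
  prof2 <- render_profile(geno, 0, seed = 1)
  expect_equal(unname(c(prof2$ratio_W[1], prof2$ratio_Y[1])), c(1.5, 0.3))
  expect_equal(dosage_centroid(c(3, 4)), c(1.9, 2.3))

  pa <- render_profile(geno, 0.1, seed = 42)
  pb <- render_profile(geno, 0.1, seed = 42)
  expect_identical(pa, pb)
  expect_error(render_profile(geno, -0.1), "noise_sd")
})

test_that("fluctuation cultures show Luria-Delbruck behaviour", {
  expect_true(all(simulate_fluctuation_cultures(0, 1e6, 20, seed = 1) == 0))
  expect_error(simulate_fluctuation_cultures(1.5, 1e6, 10), "rate")

  counts <- simulate_fluctuation_cultures(1e-5, 1e7, 1000, seed = 2)
  expect_gt(mean(counts), median(counts))  # jackpot skew

  # P(0 resistant colonies) ~ exp(-m) at small m, within 3 binomial SE
  for (m in c(1, 3)) {
    cc <- simulate_fluctuation_cultures(m / 1e6, 1e6, 1000, seed = m)
    p0 <- exp(-m)
    se <- sqrt(p0 * (1 - p0) / 1000)
    expect_lt(abs(mean(cc == 0) - p0), 3 * se)
  }

  est <- estimate_rate_median(counts, 1e7)
  expect_lt(abs(est$estimate / 1e-5 - 1), 0.3)
})

test_that("circular breakage fraction follows 1 - exp(-lambda L)", {
  expect_equal(simulate_circular_breakage(0, 320, 1000, seed = 1), 0)
  f <- simulate_circular_breakage(log(2) / 320, 320, 1e5, seed = 2)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 1e5))
  f1 <- simulate_circular_breakage(1 / 320, 320, 1e4, seed = 3)
  p <- 1 - exp(-1)
  expect_lt(abs(f1 - p), 3 * sqrt(p * (1 - p) / 1e4))
})

test_that("mutation generator is multinomial and deterministic", {
  m1 <- generate_mutations(c(1, 0, 0, 0, 0, 0, 0), 50, seed = 1)
  expect_true(all(m1$class == "C>A"))
  expect_equal(nrow(generate_mutations(rep(1 / 7, 7), 0, seed = 1)), 0)

  mu <- generate_mutations(rep(1 / 7, 7), 600, seed = 5)
  tab <- table(factor(mu$class, levels = c(SUBSTITUTION_CLASSES, "indel")))
  # each of the 7 classes ~ Binomial(600, 1/7): within 4 SD of 600/7
  sd7 <- sqrt(600 * (1 / 7) * (6 / 7))
  expect_true(all(abs(tab - 600 / 7) < 4 * sd7))
  expect_error(generate_mutations(rep(0.2, 7), 10), "probabilities")
})
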