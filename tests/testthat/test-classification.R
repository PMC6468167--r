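test_that("conversion tracts are typed from summed haplotype copies", {
  expect_equal(type_conversion_tract(c(1, 1), c(2, 0)), "3:1")
  expect_equal(type_conversion_tract(c(2, 0), c(2, 0)), "4:0")
  expect_equal(type_conversion_tract(c(1, 1), c(1, 1)), "none")
  expect_equal(type_conversion_tract(c(0, 2), c(1, 1)), "3:1")
  expect_error(type_conversion_tract(c(2, 1), c(1, 1)), "copy-neutral")
})

test_that("the HO-20-22 sector pair yields one CO with a 3:1 then 4:0 tract", {
  fx <- ho2022_pair(noise_sd = 0)
  g <- fx$genome
  red <- call_pipeline(fx$red, g)$segments
  white <- call_pipeline(fx$white, g)$segments

  # published transition intervals, recovered at single-marker resolution
  expect_equal(red$bp_left_lo[2], 1277.206)
  expect_equal(red$bp_left_hi[2], 1278.958)
  expect_equal(white$bp_left_lo[2], 1275.710)
  expect_equal(white$bp_left_hi[2], 1277.206)
  expect_equal(white$bp_left_lo[3], 1289.953)
  expect_equal(white$bp_left_hi[3], 1292.325)

  ev <- classify_sector_pair(sector_pair(red, white, g))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "CO")
  expect_equal(ev$tract_classes, "3:1/4:0")
  expect_equal(ev$phase, "G1")
  expect_equal(ev$donor, "W")
  expect_equal(c(ev$co_bp_lo, ev$co_bp_hi), c(1289.953, 1292.325))
})

test_that("a fully heterozygous pair has no events; BIR gives one BIR and no CO", {
  g <- small_genome()
  het <- het_segments(g)
  expect_equal(nrow(classify_sector_pair(sector_pair(het, het, g))), 0)

  pl <- plant_event(g, planted_event("BIR", "chrB", 400, donor = "W"),
                    seed = 2)
  r <- call_pipeline(render_profile(pl$daughter1, 0, seed = 3), g)$segments
  w <- call_pipeline(render_profile(pl$daughter2, 0, seed = 4), g)$segments
  ev <- classify_sector_pair(sector_pair(r, w, g))
  expect_equal(ev$type, "BIR")
  expect_equal(sum(ev$type == "CO"), 0)
})

test_that("initiation phase follows the 4:0 rule", {
  expect_equal(infer_initiation_phase(list(tract_classes = "3:1/4:0")), "G1")
  expect_equal(infer_initiation_phase(list(tract_classes = "3:1")),
               "G2_or_nick")
  expect_equal(infer_initiation_phase(list(tract_classes = NA_character_)),
               NA_character_)
})

test_that("unsectored classification types UPD, aneuploidy, and CON_CO merging", {
  g <- small_genome()

  upd <- diploid_genotype(g)
  on_b <- upd$chrom == "chrB"
  upd$cnW[on_b] <- 2L; upd$cnY[on_b] <- 0L
  seg <- call_pipeline(render_profile(upd, 0, seed = 1), g)$segments
  ev <- classify_unsectored(seg, g)
  expect_equal(ev$type[ev$chrom == "chrB"], "UPD")

  tri <- diploid_genotype(g)
  on_c <- tri$chrom == "chrC"
  tri$cnW[on_c] <- 2L; tri$cnY[on_c] <- 1L
  seg2 <- call_pipeline(render_profile(tri, 0, seed = 2), g)$segments
  ev2 <- classify_unsectored(seg2, g)
  expect_equal(ev2$type[ev2$chrom == "chrC"], "trisomy")

  # interstitial (2,0) tract 10 kb proximal of a terminal (0,2) LOH merges
  cc <- diploid_genotype(g)
  t1 <- cc$chrom == "chrA" & cc$pos_kb >= 600 & cc$pos_kb <= 630
  cc$cnW[t1] <- 2L; cc$cnY[t1] <- 0L
  t2 <- cc$chrom == "chrA" & cc$pos_kb >= 640
  cc$cnW[t2] <- 0L; cc$cnY[t2] <- 2L
  seg3 <- call_pipeline(render_profile(cc, 0, seed = 3), g)$segments
  ev3 <- classify_unsectored(seg3, g, adjacency_kb = 25)
  expect_equal(ev3$type[ev3$chrom == "chrA"], "CON_CO")

  # symmetric in haplotype labels
  cc2 <- cc
  cc2[t1 | t2, c("cnW", "cnY")] <- cc[t1 | t2, c("cnY", "cnW")]
  seg4 <- call_pipeline(render_profile(cc2, 0, seed = 4), g)$segments
  ev4 <- classify_unsectored(seg4, g, adjacency_kb = 25)
  expect_equal(ev4$type[ev4$chrom == "chrA"], "CON_CO")

  # beyond the adjacency window they remain separate CON + CO_or_BIR
  ev5 <- classify_unsectored(seg3, g, adjacency_kb = 5)
  expect_setequal(ev5$type[ev5$chrom == "chrA"], c("CON", "CO_or_BIR"))
})

test_that("G2 crossover segregation sectors half the colonies", {
  seg <- simulate_co_segregation(10000, seed = 3)
  expect_lt(abs(seg$fraction_sectored - 0.5), 0.02)
  expect_lt(abs(seg$co_per_sectored - 2), 0.08)
})

test_that("sector pairs with mismatched marker sets are rejected", {
  g <- small_genome()
  het <- het_segments(g)
  bad <- het[het$chrom != "chrC", ]
  expect_error(sector_pair(het, bad, g), "different marker sets")
})
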