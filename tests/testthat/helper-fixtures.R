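# Fixtures built in code: a small dense-marker genome for fast unit tests,
# and the HO-20-22-style sectored-colony profile pair with its published
# transition coordinates.

small_genome <- function(marker_step = 1) {
  chroms <- data.frame(chrom = c("chrA", "chrB", "chrC"),
                       length_kb = c(800, 600, 400),
                       cen_kb = c(300, 200, 150))
  markers <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    data.frame(chrom = chroms$chrom[i],
               pos_kb = seq(marker_step, chroms$length_kb[i] - marker_step,
                            by = marker_step))
  }))
  build_genome(genome_config("custom", chromosomes = chroms,
                             markers = markers, features = FALSE))
}

# Chromosome-IV-like map whose markers reproduce the exact published LOH
# transition intervals of sectored colony HO-20-22: red 1277.206-1278.958;
# white 1275.710-1277.206 and 1289.953-1292.325 (kb).
ho2022_genome <- function() {
  chroms <- data.frame(chrom = "chrIV", length_kb = 1532, cen_kb = 450)
  key <- c(1275.710, 1277.206, 1278.958, 1289.953, 1292.325)
  grid <- seq(2, 1530, by = 2)
  grid <- grid[grid < 1274 | grid > 1294]
  inner <- seq(1279.5, 1289.5, by = 1)  # markers inside the 4:0 tract
  markers <- data.frame(chrom = "chrIV", pos_kb = sort(c(grid, key, inner)))
  build_genome(genome_config("custom", chromosomes = chroms,
                             markers = markers, features = FALSE))
}

ho2022_pair <- function(noise_sd = 0, seed = 1L) {
  g <- ho2022_genome()
  red <- diploid_genotype(g)
  white <- diploid_genotype(g)
  pos <- red$pos_kb
  # red sector: het -> homozygous W distal of the single transition
  red$cnW[pos >= 1278.958] <- 2L
  red$cnY[pos >= 1278.958] <- 0L
  # white sector: conversion tract homozygous W, then reciprocal hom Y
  sel_t <- pos >= 1277.206 & pos <= 1289.953
  white$cnW[sel_t] <- 2L; white$cnY[sel_t] <- 0L
  sel_d <- pos >= 1292.325
  white$cnW[sel_d] <- 0L; white$cnY[sel_d] <- 2L
  list(genome = g,
       red = render_profile(red, noise_sd, seed = seed, sample_label = "red"),
       white = render_profile(white, noise_sd, seed = seed + 1L,
                              sample_label = "white"))
}

# segments of an all-heterozygous profile of a genome, via the calling path
het_segments <- function(genome, seed = 1L) {
  prof <- render_profile(diploid_genotype(genome), 0, seed = seed)
  call_pipeline(prof, genome)$segments
}
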