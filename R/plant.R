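#' Mitotic recombination mechanisms that can be planted
#' @export
EVENT_MECHANISMS <- c("G1_DSB_CO", "G2_DSB_CO", "BIR", "CON_only",
                      "interstitial_del", "interstitial_dup",
                      "terminal_del", "terminal_dup",
                      "trisomy", "monosomy", "UPD")

#' Fully heterozygous diploid genotype
#'
#' One (cnW, cnY) = (1, 1) record per marker of the genome.
#' @param genome a `genome_map`.
#' @return data.frame `chrom`, `pos_kb`, `cnW`, `cnY`.
#' @export
diploid_genotype <- function(genome) {
  data.frame(chrom = genome$markers$chrom, pos_kb = genome$markers$pos_kb,
             cnW = 1L, cnY = 1L, stringsAsFactors = FALSE)
}

#' Describe an event to plant
#'
#' @param mechanism one of [EVENT_MECHANISMS].
#' @param chrom chromosome name.
#' @param break_kb break / transition coordinate in kb (ignored for
#'   whole-chromosome mechanisms).
#' @param donor `"W"` or `"Y"`: the haplotype that donates (or is retained /
#'   duplicated) in the altered region.
#' @param tract_kb optional named numeric vector of realized tract extents in
#'   kb; members depend on mechanism (`a1`, `a2`, `b2` for `G1_DSB_CO`; `a`,
#'   `b` for `G2_DSB_CO` and `CON_only`; `len` for interstitial CNVs).
#'   Missing extents are drawn from the tract-length model at plant time.
#' @return list of class `"planted_event"`.
#' @export
planted_event <- function(mechanism, chrom, break_kb = NA_real_,
                          donor = c("W", "Y"), tract_kb = NULL) {
  mechanism <- match.arg(mechanism, EVENT_MECHANISMS)
  donor <- match.arg(donor)
  structure(list(mechanism = mechanism, chrom = chrom,
                 break_kb = break_kb, donor = donor, tract_kb = tract_kb),
            class = "planted_event")
}

#' Conversion-tract length model
#'
#' Log-normal with median 13 kb (the combined crossover-associated
#' conversion-tract median for peroxide-treated cells) and log-sd 1.1, so the
#' 10-90 percentile range is roughly 3-53 kb.
#' @param n number of lengths to draw.
#' @param median_kb median tract length in kb.
#' @param sdlog log-scale standard deviation.
#' @return numeric vector of lengths in kb.
#' @export
rtract_length <- function(n, median_kb = 13, sdlog = 1.1) {
  stats::rlnorm(n, meanlog = log(median_kb), sdlog = sdlog)
}

state_for <- function(donor, kind) {
  # kind: hom (2 copies of donor), opp (2 copies of the other haplotype),
  # del (donor retained, other lost), dup (donor duplicated)
  switch(kind,
    hom = if (donor == "W") c(2L, 0L) else c(0L, 2L),
    opp = if (donor == "W") c(0L, 2L) else c(2L, 0L),
    del = if (donor == "W") c(1L, 0L) else c(0L, 1L),
    dup = if (donor == "W") c(2L, 1L) else c(1L, 2L)
  )
}

#' Plant a recombination / copy-number event into a diploid
#'
#' Produces the two daughter-cell genotypes expected from each mechanism.
#' Crossover mechanisms follow the two chromatid-repair models: a G1 break is
#' replicated into two broken chromatids whose independent repair tracts give
#' a merged 3:1-then-4:0 conversion region next to the reciprocal exchange; a
#' G2 break on a single chromatid gives a pure 3:1 tract. BIR copies the
#' donor homolog to the telomere in one daughter only. Copy-number and
#' aneuploidy mechanisms alter one daughter (UPD is planted reciprocally, as
#' a first-division nondisjunction).
#'
#' @param genome a `genome_map`.
#' @param spec a [planted_event()].
#' @param seed integer seed (used when tract extents must be drawn).
#' @return list with `daughter1`, `daughter2` (genotype data.frames) and
#'   `truth`: one-row data.frame of the realized boundaries (`s1`, `s2`,
#'   `e2`, `s`, `e` in kb where applicable) and the event type expected from
#'   classification.
#' @export
plant_event <- function(genome, spec, seed = 1L) {
  stopifnot(inherits(spec, "planted_event"))
  chrom <- spec$chrom
  L <- chrom_length(genome, chrom)
  if (is.na(L)) abort_config("plant_event: unknown chromosome %s", chrom)
  cen <- chrom_cen(genome, chrom)
  B <- spec$break_kb
  whole_chrom <- spec$mechanism %in% c("trisomy", "monosomy", "UPD")
  if (!whole_chrom && (is.na(B) || B <= 0 || B >= L)) {
    abort_config("plant_event: break coordinate outside chromosome")
  }
  d1 <- diploid_genotype(genome)
  d2 <- diploid_genotype(genome)
  on_ch <- d1$chrom == chrom
  pos <- d1$pos_kb
  donor <- spec$donor

  set_state <- function(g, mask, st) {
    g$cnW[mask] <- st[1]; g$cnY[mask] <- st[2]; g
  }
  # distal direction: toward the telomere of the arm carrying the break
  dirp <- if (whole_chrom) TRUE else B >= cen
  distal_mask <- function(x) if (dirp) on_ch & pos >= x else on_ch & pos <= x
  span_mask <- function(lo, hi) on_ch & pos >= lo & pos <= hi
  # tract interval [prox extent a, distal extent b] around x
  tract_iv <- function(x, a, b) {
    if (dirp) c(max(0, x - a), min(L, x + b)) else c(max(0, x - b), min(L, x + a))
  }
  tk <- function(name, default) {
    v <- spec$tract_kb[[name]] %||% NA_real_
    if (is.na(v)) default else v
  }

  truth <- data.frame(mechanism = spec$mechanism, chrom = chrom,
                      donor = donor, break_kb = B, stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, 11), {
    draws <- rtract_length(3)
    switch(spec$mechanism,
      G1_DSB_CO = {
        # proximal tract extents of the two repaired chromatids (a2 > a1) and
        # the distal extent of the non-crossover chromatid's tract
        a <- sort(c(tk("a1", draws[1] / 2), tk("a2", draws[2] / 2)))
        a1 <- a[1]; a2 <- a[2]
        if (a1 == a2) a2 <- a2 + 1
        b2 <- tk("b2", draws[3] / 2)
        t1 <- tract_iv(B, a1, 0); t2 <- tract_iv(B, a2, b2)
        s1 <- if (dirp) t1[1] else t1[2]
        s2 <- if (dirp) t2[1] else t2[2]
        e2 <- if (dirp) t2[2] else t2[1]
        d1 <- set_state(d1, distal_mask(s1), state_for(donor, "hom"))
        d2 <- set_state(d2, span_mask(min(s2, e2), max(s2, e2)),
                        state_for(donor, "hom"))
        d2 <- set_state(d2, distal_mask(e2) & !span_mask(min(s2, e2), max(s2, e2)),
                        state_for(donor, "opp"))
        truth$s1 <- s1; truth$s2 <- s2; truth$e2 <- e2
        truth$type <- "CO"; truth$phase <- "G1"
      },
      G2_DSB_CO = {
        iv <- tract_iv(B, tk("a", draws[1] / 2), tk("b", draws[2] / 2))
        s <- if (dirp) iv[1] else iv[2]
        e <- if (dirp) iv[2] else iv[1]
        d1 <- set_state(d1, distal_mask(s), state_for(donor, "hom"))
        d2 <- set_state(d2, distal_mask(e) & !span_mask(min(s, e), max(s, e)),
                        state_for(donor, "opp"))
        truth$s <- s; truth$e <- e
        truth$type <- "CO"; truth$phase <- "G2_or_nick"
      },
      BIR = {
        d1 <- set_state(d1, distal_mask(B), state_for(donor, "hom"))
        truth$type <- "BIR"; truth$phase <- NA_character_
      },
      CON_only = {
        iv <- tract_iv(B, tk("a", draws[1] / 2), tk("b", draws[2] / 2))
        if (iv[1] <= 0 || iv[2] >= L) {
          abort_config("plant_event: CON_only tract reaches a chromosome end")
        }
        d1 <- set_state(d1, span_mask(iv[1], iv[2]), state_for(donor, "hom"))
        truth$s <- iv[1]; truth$e <- iv[2]
        truth$type <- "CON"; truth$phase <- "G2_or_nick"
      },
      interstitial_del = ,
      interstitial_dup = {
        len <- tk("len", draws[1])
        iv <- tract_iv(B, 0, len)
        if (iv[1] <= 0 || iv[2] >= L) {
          abort_config("plant_event: interstitial CNV reaches a chromosome end")
        }
        kind <- if (spec$mechanism == "interstitial_del") "del" else "dup"
        d1 <- set_state(d1, span_mask(iv[1], iv[2]), state_for(donor, kind))
        truth$s <- iv[1]; truth$e <- iv[2]
        truth$type <- spec$mechanism; truth$phase <- NA_character_
      },
      terminal_del = ,
      terminal_dup = {
        kind <- if (spec$mechanism == "terminal_del") "del" else "dup"
        d1 <- set_state(d1, distal_mask(B), state_for(donor, kind))
        truth$type <- spec$mechanism; truth$phase <- NA_character_
      },
      trisomy = {
        d1 <- set_state(d1, on_ch, state_for(donor, "dup"))
        truth$type <- "trisomy"; truth$phase <- NA_character_
      },
      monosomy = {
        d1 <- set_state(d1, on_ch, state_for(donor, "del"))
        truth$type <- "monosomy"; truth$phase <- NA_character_
      },
      UPD = {
        d1 <- set_state(d1, on_ch, state_for(donor, "hom"))
        d2 <- set_state(d2, on_ch, state_for(donor, "opp"))
        truth$type <- "UPD"; truth$phase <- NA_character_
      }
    )
  })
  list(daughter1 = d1, daughter2 = d2, truth = truth)
}

#' Simulate chromatid segregation after a single G2 crossover
#'
#' After a reciprocal crossover between one chromatid of each homolog, the
#' two recombinant chromatids segregate to opposite daughter cells (yielding
#' reciprocal terminal LOH, a sectored colony) or to the same daughter
#' (yielding two fully heterozygous daughters, no LOH). The two patterns are
#' equally likely, which is why the crossover rate is twice the sectored
#' frequency.
#'
#' @param n_trials number of independent crossovers simulated.
#' @param seed integer seed.
#' @return list: `n_trials`, `n_sectored`, `fraction_sectored`, and
#'   `co_per_sectored` (= n_trials / n_sectored).
#' @export
simulate_co_segregation <- function(n_trials = 10000L, seed = 1L) {
  stopifnot(is_count(n_trials), n_trials >= 1)
  with_seed(derive_seed(seed, 13), {
    # daughter 1 receives the recombinant W chromatid plus one of the two Y
    # sisters; LOH results only when that Y sister is the non-recombinant one
    y_partner <- sample(c("Y_recomb", "Y_parental"), n_trials, replace = TRUE)
    sect <- sum(y_partner == "Y_parental")
    list(n_trials = n_trials, n_sectored = sect,
         fraction_sectored = sect / n_trials,
         co_per_sectored = n_trials / sect)
  })
}
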