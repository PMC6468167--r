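# Cohort-level simulation: many planted events distributed over sector
# pairs, plus the scoring used to evaluate round-trip recovery.

#' Simulate a cohort of sector pairs with planted events
#'
#' Distributes `n_events` planted events over sector pairs (at most
#' `events_per_pair` per pair, each on its own chromosome) and renders the
#' red/white profiles. Tract extents are drawn from the tract-length model
#' but floored so every diagnostic sub-region spans at least one typical
#' inter-marker gap; breaks are placed on arms long enough to leave a
#' marker-bearing segment on each side.
#'
#' @param genome a `genome_map`.
#' @param n_events number of events to plant.
#' @param noise_sd profile noise SD.
#' @param seed integer seed.
#' @param mechanisms mechanisms to cycle through (default all).
#' @param events_per_pair events per sector pair (default 8).
#' @return list: `pairs` (list of `list(red, white)` profiles) and `truth`
#'   (data.frame with pair index and realized event boundaries).
#' @export
simulate_sector_cohort <- function(genome, n_events, noise_sd = 0.1,
                                   seed = 1L, mechanisms = EVENT_MECHANISMS,
                                   events_per_pair = 8L) {
  chroms <- genome$chromosomes
  arm_ok <- function(ch) {
    L <- chroms$length_kb[chroms$chrom == ch]
    cen <- chroms$cen_kb[chroms$chrom == ch]
    # usable break windows on each arm, leaving 80 kb of flank
    right <- c(cen + 40, L - 80)
    left <- c(80, cen - 40)
    list(right = if (right[2] > right[1]) right else NULL,
         left = if (left[2] > left[1]) left else NULL)
  }
  n_pairs <- ceiling(n_events / events_per_pair)
  with_seed(derive_seed(seed, 41), {
    truth <- list(); pairs <- vector("list", n_pairs)
    ev_i <- 0L
    for (p in seq_len(n_pairs)) {
      geno1 <- diploid_genotype(genome)
      geno2 <- diploid_genotype(genome)
      n_here <- min(events_per_pair, n_events - (p - 1L) * events_per_pair)
      use_chr <- sample(chroms$chrom, n_here)
      for (k in seq_len(n_here)) {
        ev_i <- ev_i + 1L
        ch <- use_chr[k]
        m <- mechanisms[((ev_i - 1L) %% length(mechanisms)) + 1L]
        arms <- arm_ok(ch)
        win <- if (!is.null(arms$right) &&
                   (is.null(arms$left) || stats::runif(1) < 0.5)) {
          arms$right
        } else arms$left %||% arms$right
        brk <- stats::runif(1, win[1], win[2])
        d <- rtract_length(4)
        clamp <- function(x, lo) pmin(pmax(x, lo), 60)
        tracts <- list(a1 = clamp(d[1] / 2, 6), a2 = clamp(d[1] / 2, 6) + 12,
                       b2 = clamp(d[2] / 2, 12), a = clamp(d[3] / 2, 8),
                       b = clamp(d[4] / 2, 8), len = clamp(d[1], 16))
        pl <- plant_event(genome, planted_event(m, ch, brk,
                                                donor = sample(c("W", "Y"), 1),
                                                tract_kb = tracts),
                          seed = derive_seed(seed, 1000L + ev_i))
        sel <- geno1$chrom == ch
        geno1[sel, c("cnW", "cnY")] <- pl$daughter1[sel, c("cnW", "cnY")]
        geno2[sel, c("cnW", "cnY")] <- pl$daughter2[sel, c("cnW", "cnY")]
        tr <- pl$truth
        tr$pair <- p
        truth[[ev_i]] <- tr
      }
      pairs[[p]] <- list(
        red = render_profile(geno1, noise_sd,
                             seed = derive_seed(seed, 2L * p),
                             sample_label = sprintf("pair%03d_red", p)),
        white = render_profile(geno2, noise_sd,
                               seed = derive_seed(seed, 2L * p + 1L),
                               sample_label = sprintf("pair%03d_white", p)))
    }
    cols <- c("pair", "mechanism", "chrom", "donor", "break_kb", "type",
              "phase", "s1", "s2", "e2", "s", "e")
    truth <- do.call(rbind, lapply(truth, function(t) {
      for (cc in setdiff(cols, names(t))) t[[cc]] <- NA_real_
      t[, cols]
    }))
    list(pairs = pairs, truth = truth)
  })
}

#' Call and classify every pair of a simulated cohort
#'
#' @param cohort from [simulate_sector_cohort()].
#' @param genome the `genome_map` used to build the cohort.
#' @param params calling parameters passed to [call_pipeline()].
#' @return list of event data.frames, one per pair.
#' @export
classify_cohort <- function(cohort, genome, params = list()) {
  lapply(seq_along(cohort$pairs), function(p) {
    r <- call_pipeline(cohort$pairs[[p]]$red, genome, params)
    w <- call_pipeline(cohort$pairs[[p]]$white, genome, params)
    classify_sector_pair(sector_pair(r$segments, w$segments, genome),
                         isolate = sprintf("pair%03d", p))
  })
}

# Is coordinate x inside (lo, hi) widened by one inter-marker interval?
within_one_interval <- function(x, lo, hi, pos) {
  i_lo <- findInterval(lo, pos)
  i_hi <- findInterval(hi, pos)
  g_l <- if (i_lo >= 2L) pos[i_lo] - pos[i_lo - 1L] else pos[2L] - pos[1L]
  g_r <- if (i_hi < length(pos)) pos[min(i_hi + 1L, length(pos))] -
           pos[max(i_hi, 1L)] else pos[length(pos)] - pos[length(pos) - 1L]
  x >= lo - g_l & x <= hi + g_r
}

#' Score round-trip recovery of planted events
#'
#' A planted event is recovered when its chromosome carries exactly one
#' classified event of the expected type and the diagnostic breakpoints fall
#' within one inter-marker interval of the planted coordinates.
#'
#' @param truth cohort truth table.
#' @param events_by_pair from [classify_cohort()].
#' @param genome the `genome_map`.
#' @return truth with logical columns `type_ok`, `bp_ok`, `recovered`.
#' @export
evaluate_recovery <- function(truth, events_by_pair, genome) {
  truth$type_ok <- FALSE
  truth$bp_ok <- FALSE
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    ev <- events_by_pair[[tr$pair]]
    ev <- ev[ev$chrom == tr$chrom, , drop = FALSE]
    if (nrow(ev) != 1L || ev$type != tr$type) next
    truth$type_ok[i] <- TRUE
    pos <- genome$markers$pos_kb[genome$markers$chrom == tr$chrom]
    ok <- TRUE
    chk <- function(x, lo, hi) within_one_interval(x, lo, hi, pos)
    if (tr$type == "CO") {
      x <- if (!is.na(tr$e2)) tr$e2 else tr$e  # reciprocity transition
      ok <- chk(x, ev$co_bp_lo, ev$co_bp_hi)
      if (tr$mechanism == "G1_DSB_CO") {
        ok <- ok && grepl("3:1", ev$tract_classes, fixed = TRUE) &&
          grepl("4:0", ev$tract_classes, fixed = TRUE)
      }
    } else if (tr$type == "BIR") {
      edge <- if (abs(ev$start_kb - tr$break_kb) <=
                  abs(ev$end_kb - tr$break_kb)) {
        c(ev$start_kb, ev$start_kb)
      } else c(ev$end_kb, ev$end_kb)
      ok <- chk(tr$break_kb, edge[1], edge[2])
    } else if (tr$type %in% c("CON", "interstitial_del", "interstitial_dup")) {
      ok <- chk(tr$s, ev$start_kb, ev$start_kb) &&
            chk(tr$e, ev$end_kb, ev$end_kb)
    } else if (tr$type %in% c("terminal_del", "terminal_dup")) {
      edge <- if (abs(ev$start_kb - tr$break_kb) <=
                  abs(ev$end_kb - tr$break_kb)) ev$start_kb else ev$end_kb
      ok <- chk(tr$break_kb, edge, edge)
    }
    truth$bp_ok[i] <- isTRUE(ok)
  }
  truth$recovered <- truth$type_ok & truth$bp_ok
  truth
}
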