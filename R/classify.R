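#' Type a conversion tract from the two sector states at a marker
#'
#' Sums the haplotype copies across the red and white sectors: (3,1)/(1,3)
#' is a 3:1 tract marker, (4,0)/(0,4) a 4:0 tract marker, (2,2) is not a
#' tract (either fully heterozygous or the reciprocal crossover region).
#'
#' @param red_state,white_state integer vectors `c(cnW, cnY)`; each must sum
#'   to 2 (copy-neutral). Non-copy-neutral input is routed to CNV logic by
#'   the callers and is an error here.
#' @return `"3:1"`, `"4:0"` or `"none"`.
#' @export
type_conversion_tract <- function(red_state, white_state) {
  if (sum(red_state) != 2L || sum(white_state) != 2L) {
    abort_config("type_conversion_tract: states must be copy-neutral; route CNVs through copy-number logic")
  }
  comb <- red_state + white_state
  if (max(comb) == 4L) "4:0" else if (max(comb) == 3L) "3:1" else "none"
}

#' Pair the red and white sector segment calls of one colony
#'
#' @param red,white segment data.frames (from [segment_states()] or
#'   [call_pipeline()]) for the two sectors.
#' @param genome the shared `genome_map`.
#' @return list of class `"sector_pair"`.
#' @export
sector_pair <- function(red, white, genome) {
  for (ch in unique(c(red$chrom, white$chrom))) {
    nr <- sum(red$n_markers[red$chrom == ch])
    nw <- sum(white$n_markers[white$chrom == ch])
    if (nr != nw) {
      abort_config("sector_pair: sectors cover different marker sets on %s", ch)
    }
  }
  structure(list(red = red, white = white, genome = genome),
            class = "sector_pair")
}

# Expand a segment table back to per-marker (cnW, cnY) aligned to the genome.
states_at_markers <- function(segments, genome) {
  m <- genome$markers
  cnW <- integer(nrow(m)); cnY <- integer(nrow(m))
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) abort_config("states_at_markers: no segments for %s", ch)
    k <- findInterval(m$pos_kb[idx], seg$start_kb)
    k[k < 1L] <- 1L
    cnW[idx] <- seg$cnW[k]; cnY[idx] <- seg$cnY[k]
  }
  data.frame(chrom = m$chrom, pos_kb = m$pos_kb, cnW = cnW, cnY = cnY,
             stringsAsFactors = FALSE)
}

new_event <- function(isolate, chrom, type, donor = NA_character_,
                      phase = NA_character_, tract_classes = NA_character_,
                      has_40 = NA, tract_len_kb = NA_real_,
                      tract_intervals = NA_character_,
                      co_bp_lo = NA_real_, co_bp_hi = NA_real_,
                      start_kb = NA_real_, end_kb = NA_real_,
                      loh_kb = 0, cnv_kb = 0, n_markers = NA_integer_,
                      flag = NA_character_) {
  data.frame(isolate = isolate, chrom = chrom, type = type, donor = donor,
             phase = phase, tract_classes = tract_classes, has_40 = has_40,
             tract_len_kb = tract_len_kb, tract_intervals = tract_intervals,
             co_bp_lo = co_bp_lo, co_bp_hi = co_bp_hi,
             start_kb = start_kb, end_kb = end_kb, loh_kb = loh_kb,
             cnv_kb = cnv_kb, n_markers = n_markers, flag = flag,
             stringsAsFactors = FALSE)
}

#' Infer the cell-cycle phase of the initiating lesion
#'
#' A conversion tract containing a 4:0 region implies a double-strand break
#' on an unreplicated (G1) chromosome whose two replicated broken chromatids
#' were repaired independently; a tract that is entirely 3:1 is consistent
#' with a break (or nick) on a single replicated chromatid.
#'
#' @param event one event row (or list) carrying `tract_classes`.
#' @return `"G1"`, `"G2_or_nick"` or `NA`.
#' @export
infer_initiation_phase <- function(event) {
  tc <- event$tract_classes
  if (is.null(tc) || is.na(tc) || !nzchar(tc)) return(NA_character_)
  if (grepl("4:0", tc, fixed = TRUE)) "G1" else "G2_or_nick"
}

# helpers for one chromosome's marker-level pair classification -------------

marker_pair_class <- function(r, w) {
  # r, w: n x 2 integer matrices of (cnW, cnY)
  sr <- r[, 1] + r[, 2]; sw <- w[, 1] + w[, 2]
  cls <- rep("BASE", nrow(r))
  cnv <- sr != 2L | sw != 2L
  comb_max <- pmax(r[, 1] + w[, 1], r[, 2] + w[, 2])
  r_hom <- r[, 1] == 2L | r[, 2] == 2L
  w_hom <- w[, 1] == 2L | w[, 2] == 2L
  cls[comb_max == 3L] <- "T31"
  cls[comb_max == 4L] <- "T40"
  cls[r_hom & w_hom & comb_max == 2L] <- "RECIP"
  cls[cnv] <- "CNV"
  cls
}

tract_group_info <- function(runs, group_idx, pos, L) {
  # runs: rle-style list; group_idx: indices of consecutive T31/T40 runs
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  i0 <- starts[group_idx[1]]; i1 <- ends[group_idx[length(group_idx)]]
  n <- length(pos)
  bp_l <- c(if (i0 > 1L) pos[i0 - 1L] else 0, pos[i0])
  bp_r <- c(pos[i1], if (i1 < n) pos[i1 + 1L] else L)
  ivs <- vapply(group_idx, function(k) {
    sprintf("%.3f-%.3f=%s", pos[starts[k]], pos[ends[k]],
            sub("T31", "3:1", sub("T40", "4:0", runs$values[k])))
  }, character(1))
  classes <- sub("T31", "3:1", sub("T40", "4:0", runs$values[group_idx]))
  list(start_kb = pos[i0], end_kb = pos[i1],
       tract_len_kb = mean(bp_r) - mean(bp_l),
       tract_intervals = paste(ivs, collapse = ";"),
       tract_classes = paste(unique(classes), collapse = "/"),
       has_40 = any(classes == "4:0"),
       n_markers = i1 - i0 + 1L)
}

hap_name <- function(is_w) if (is_w) "W" else "Y"

#' Classify the events of a red/white sector pair
#'
#' Per chromosome: whole-chromosome dosage changes are typed as
#' trisomy/monosomy; a reciprocal whole-chromosome homozygosity pattern as
#' uniparental disomy (UPD); reciprocal terminal LOH (one sector homozygous
#' W, the other homozygous Y, distal of a point) as a crossover (CO) with
#' any adjacent contiguous 3:1/4:0 region attached as its conversion tract;
#' copy-neutral terminal LOH in one sector only as BIR; interstitial
#' 3:1/4:0 tracts as conversions (CON); copy-number segments as
#' deletions/duplications. Events on distinct chromosomes, or separated by a
#' return to the heterozygous baseline, are independent.
#'
#' @param pair a [sector_pair()].
#' @param isolate label stored on the events.
#' @param ploidy_fraction fraction of a chromosome's markers that must be
#'   aberrant to call a whole-chromosome event (default 0.9).
#' @return data.frame of classified events (possibly 0 rows).
#' @export
classify_sector_pair <- function(pair, isolate = "colony",
                                 ploidy_fraction = 0.9) {
  stopifnot(inherits(pair, "sector_pair"))
  genome <- pair$genome
  red <- states_at_markers(pair$red, genome)
  white <- states_at_markers(pair$white, genome)
  out <- list()
  for (ch in unique(genome$markers$chrom)) {
    idx <- which(genome$markers$chrom == ch)
    pos <- genome$markers$pos_kb[idx]
    L <- chrom_length(genome, ch)
    r <- cbind(red$cnW[idx], red$cnY[idx])
    w <- cbind(white$cnW[idx], white$cnY[idx])
    out[[ch]] <- classify_pair_chrom(r, w, pos, ch, L, isolate,
                                     ploidy_fraction)
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

classify_pair_chrom <- function(r, w, pos, ch, L, isolate, ploidy_fraction) {
  n <- length(pos)
  sr <- r[, 1] + r[, 2]; sw <- w[, 1] + w[, 2]
  cls <- marker_pair_class(r, w)
  events <- list()

  # whole-chromosome dosage / UPD
  for (sec in list(list(s = sr, m = r, lab = "red"),
                   list(s = sw, m = w, lab = "white"))) {
    if (mean(sec$s == 3L) >= ploidy_fraction) {
      donor <- hap_name(stats::median(sec$m[, 1]) == 2L)
      return(new_event(isolate, ch, "trisomy", donor, start_kb = pos[1],
                       end_kb = pos[n], cnv_kb = L, n_markers = n,
                       flag = sec$lab))
    }
    if (mean(sec$s == 1L) >= ploidy_fraction) {
      donor <- hap_name(stats::median(sec$m[, 1]) == 1L)
      return(new_event(isolate, ch, "monosomy", donor, start_kb = pos[1],
                       end_kb = pos[n], cnv_kb = L, n_markers = n,
                       flag = sec$lab))
    }
  }
  if (mean(cls == "RECIP") >= ploidy_fraction) {
    return(new_event(isolate, ch, "UPD", hap_name(r[1, 1] == 2L),
                     start_kb = pos[1], end_kb = pos[n], loh_kb = L,
                     n_markers = n))
  }

  runs <- rle(cls)
  k <- length(runs$lengths)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  consumed <- logical(k)

  # copy-number runs
  for (i in which(runs$values == "CNV")) {
    j <- starts[i]
    sec <- if (sr[j] != 2L) list(m = r, s = sr, lab = "red")
           else list(m = w, s = sw, lab = "white")
    kind <- if (sec$s[j] < 2L) "del" else "dup"
    terminal <- i == 1L || i == k
    type <- paste0(if (terminal) "terminal_" else "interstitial_", kind)
    donor <- hap_name(sec$m[j, 1] >= sec$m[j, 2])
    span <- pos[ends[i]] - pos[starts[i]]
    events[[length(events) + 1L]] <-
      new_event(isolate, ch, type, donor, start_kb = pos[starts[i]],
                end_kb = pos[ends[i]], cnv_kb = span,
                n_markers = runs$lengths[i], flag = sec$lab)
    consumed[i] <- TRUE
  }

  # crossovers: reciprocal terminal LOH at either chromosome end
  for (end_side in c("right", "left")) {
    i <- if (end_side == "right") k else 1L
    if (consumed[i] || runs$values[i] != "RECIP") next
    step <- if (end_side == "right") -1L else 1L
    grp <- integer(0)
    jj <- i + step
    while (jj >= 1L && jj <= k && runs$values[jj] %in% c("T31", "T40")) {
      grp <- c(jj, grp)
      jj <- jj + step
    }
    ti <- if (length(grp)) tract_group_info(runs, sort(grp), pos, L) else NULL
    first_recip <- if (end_side == "right") starts[i] else ends[i]
    bp <- if (end_side == "right") {
      c(if (first_recip > 1L) pos[first_recip - 1L] else 0, pos[first_recip])
    } else {
      c(pos[first_recip], if (first_recip < n) pos[first_recip + 1L] else L)
    }
    donor <- if (!is.null(ti)) {
      tm <- starts[sort(grp)[1]]:ends[sort(grp)[length(grp)]]
      hap_name(sum(r[tm, 1] + w[tm, 1]) >= sum(r[tm, 2] + w[tm, 2]))
    } else NA_character_
    span0 <- if (!is.null(ti)) ti$start_kb else pos[first_recip]
    loh_span <- if (end_side == "right") L - span0 else span0
    ev <- new_event(isolate, ch, "CO", donor,
                    tract_classes = if (!is.null(ti)) ti$tract_classes else NA_character_,
                    has_40 = if (!is.null(ti)) ti$has_40 else NA,
                    tract_len_kb = if (!is.null(ti)) ti$tract_len_kb else NA_real_,
                    tract_intervals = if (!is.null(ti)) ti$tract_intervals else NA_character_,
                    co_bp_lo = min(bp), co_bp_hi = max(bp),
                    start_kb = if (end_side == "right") span0 else pos[starts[i]],
                    end_kb = if (end_side == "right") pos[ends[i]] else
                      (if (!is.null(ti)) ti$end_kb else pos[ends[i]]),
                    loh_kb = loh_span,
                    n_markers = sum(runs$lengths[c(i, grp)]))
    ev$phase <- infer_initiation_phase(ev)
    events[[length(events) + 1L]] <- ev
    consumed[c(i, grp)] <- TRUE
  }

  # remaining tract runs: terminal -> BIR, interstitial -> CON
  i <- 1L
  while (i <= k) {
    if (consumed[i] || !(runs$values[i] %in% c("T31", "T40"))) { i <- i + 1L; next }
    grp <- i
    while (grp[length(grp)] + 1L <= k &&
           runs$values[grp[length(grp)] + 1L] %in% c("T31", "T40") &&
           !consumed[grp[length(grp)] + 1L]) {
      grp <- c(grp, grp[length(grp)] + 1L)
    }
    ti <- tract_group_info(runs, grp, pos, L)
    tm <- starts[grp[1]]:ends[grp[length(grp)]]
    donor <- hap_name(sum(r[tm, 1] + w[tm, 1]) >= sum(r[tm, 2] + w[tm, 2]))
    terminal <- grp[1] == 1L || grp[length(grp)] == k
    if (terminal) {
      loh_span <- if (grp[length(grp)] == k) L - ti$start_kb else ti$end_kb
      ev <- new_event(isolate, ch, "BIR", donor, start_kb = ti$start_kb,
                      end_kb = ti$end_kb, loh_kb = loh_span,
                      n_markers = ti$n_markers)
    } else {
      ev <- new_event(isolate, ch, "CON", donor,
                      tract_classes = ti$tract_classes, has_40 = ti$has_40,
                      tract_len_kb = ti$tract_len_kb,
                      tract_intervals = ti$tract_intervals,
                      start_kb = ti$start_kb, end_kb = ti$end_kb,
                      loh_kb = ti$tract_len_kb, n_markers = ti$n_markers)
      ev$phase <- infer_initiation_phase(ev)
    }
    events[[length(events) + 1L]] <- ev
    consumed[grp] <- TRUE
    i <- grp[length(grp)] + 1L
  }
  if (length(events)) do.call(rbind, events) else new_event(isolate, ch, "none")[0, ]
}

#' Classify the events of a single unsectored isolate
#'
#' Interstitial copy-neutral LOH is a conversion (CON); LOH running to a
#' telomere is a crossover or BIR (CO_or_BIR, indistinguishable without
#' sectors); an interstitial LOH tract from one homolog within
#' `adjacency_kb` of a terminal LOH from the opposite homolog is merged into
#' a single CON_CO event (a crossover with its 4:0-type conversion tract);
#' copy-number segments become deletions/duplications (terminal vs
#' interstitial by telomere contact); whole-chromosome dosage 3 or 1 is
#' trisomy or monosomy, and copy-neutral whole-chromosome homozygosity
#' spanning the centromere is UPD.
#'
#' @param segments segment data.frame of one isolate.
#' @param genome `genome_map`.
#' @param adjacency_kb maximum gap for CON_CO merging (default 25 kb).
#' @param isolate label stored on the events.
#' @param ploidy_fraction fraction of markers required for whole-chromosome
#'   calls (default 0.9).
#' @param short_terminal_markers terminal LOH events spanning fewer markers
#'   than this are flagged `"short_terminal"` (default 5).
#' @return data.frame of classified events.
#' @export
classify_unsectored <- function(segments, genome, adjacency_kb = 25,
                                isolate = "isolate", ploidy_fraction = 0.9,
                                short_terminal_markers = 5L) {
  if (length(unique(segments$isolate %||% "x")) > 1L) {
    abort_config("classify_unsectored: segments from multiple isolates")
  }
  events <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    L <- chrom_length(genome, ch)
    cen <- chrom_cen(genome, ch)
    n_tot <- sum(seg$n_markers)
    s <- seg$cnW + seg$cnY
    hom <- s == 2L & (seg$cnW == 2L | seg$cnY == 2L)

    # whole-chromosome calls
    big <- which(seg$n_markers >= ploidy_fraction * n_tot)
    if (length(big) == 1L) {
      b <- big
      spans_cen <- seg$start_kb[b] <= cen && seg$end_kb[b] >= cen
      if (s[b] == 3L) {
        events[[length(events) + 1L]] <- new_event(
          isolate, ch, "trisomy", hap_name(seg$cnW[b] == 2L),
          start_kb = seg$start_kb[b], end_kb = seg$end_kb[b], cnv_kb = L,
          n_markers = seg$n_markers[b])
        next
      }
      if (s[b] == 1L) {
        events[[length(events) + 1L]] <- new_event(
          isolate, ch, "monosomy", hap_name(seg$cnW[b] == 1L),
          start_kb = seg$start_kb[b], end_kb = seg$end_kb[b], cnv_kb = L,
          n_markers = seg$n_markers[b])
        next
      }
      if (hom[b] && spans_cen) {
        events[[length(events) + 1L]] <- new_event(
          isolate, ch, "UPD", hap_name(seg$cnW[b] == 2L),
          start_kb = seg$start_kb[b], end_kb = seg$end_kb[b], loh_kb = L,
          n_markers = seg$n_markers[b])
        next
      }
    }

    nseg <- nrow(seg)
    terminal <- seq_len(nseg) == 1L | seq_len(nseg) == nseg
    used <- logical(nseg)

    # copy-number events
    for (i in which(s != 2L)) {
      kind <- if (s[i] < 2L) "del" else "dup"
      type <- paste0(if (terminal[i]) "terminal_" else "interstitial_", kind)
      donor <- hap_name(seg$cnW[i] >= seg$cnY[i])
      events[[length(events) + 1L]] <- new_event(
        isolate, ch, type, donor, start_kb = seg$start_kb[i],
        end_kb = seg$end_kb[i], cnv_kb = seg$end_kb[i] - seg$start_kb[i],
        n_markers = seg$n_markers[i])
      used[i] <- TRUE
    }

    term_loh <- which(hom & terminal & !used)
    int_loh <- which(hom & !terminal & !used)

    for (i in term_loh) {
      donor_t <- hap_name(seg$cnW[i] == 2L)
      loh_span <- if (i == nseg) L - seg$start_kb[i] else seg$end_kb[i]
      # CON_CO merge: nearby interstitial LOH of the opposite haplotype
      partner <- int_loh[!used[int_loh]]
      if (length(partner)) {
        opp <- vapply(partner, function(j) hap_name(seg$cnW[j] == 2L) != donor_t,
                      logical(1))
        gap <- vapply(partner, function(j) {
          max(0, max(seg$start_kb[i] - seg$end_kb[j],
                     seg$start_kb[j] - seg$end_kb[i]))
        }, numeric(1))
        cand <- partner[opp & gap <= adjacency_kb]
      } else cand <- integer(0)
      if (length(cand)) {
        j <- cand[which.min(abs(seg$start_kb[cand] - seg$start_kb[i]))]
        events[[length(events) + 1L]] <- new_event(
          isolate, ch, "CON_CO", donor_t, phase = "G1",
          tract_classes = "4:0-type",
          start_kb = min(seg$start_kb[c(i, j)]),
          end_kb = max(seg$end_kb[c(i, j)]),
          tract_len_kb = (mean(c(seg$bp_right_lo[j], seg$bp_right_hi[j])) -
                          mean(c(seg$bp_left_lo[j], seg$bp_left_hi[j]))),
          loh_kb = loh_span + seg$end_kb[j] - seg$start_kb[j],
          n_markers = sum(seg$n_markers[c(i, j)]))
        used[c(i, j)] <- TRUE
      } else {
        flg <- if (seg$n_markers[i] < short_terminal_markers) "short_terminal"
               else NA_character_
        events[[length(events) + 1L]] <- new_event(
          isolate, ch, "CO_or_BIR", donor_t, start_kb = seg$start_kb[i],
          end_kb = seg$end_kb[i], loh_kb = loh_span,
          n_markers = seg$n_markers[i], flag = flg)
        used[i] <- TRUE
      }
    }

    for (j in int_loh[!used[int_loh]]) {
      events[[length(events) + 1L]] <- new_event(
        isolate, ch, "CON", hap_name(seg$cnW[j] == 2L),
        start_kb = seg$start_kb[j], end_kb = seg$end_kb[j],
        tract_len_kb = (mean(c(seg$bp_right_lo[j], seg$bp_right_hi[j])) -
                        mean(c(seg$bp_left_lo[j], seg$bp_left_hi[j]))),
        loh_kb = seg$end_kb[j] - seg$start_kb[j],
        n_markers = seg$n_markers[j])
      used[j] <- TRUE
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else new_event("x", "x", "none")[0, ]
  rownames(ev) <- NULL
  ev
}
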