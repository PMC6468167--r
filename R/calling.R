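#' Normalize a raw hybridization profile
#'
#' Divides every allele-specific ratio by the mean over all allele
#' oligonucleotides on the array, so the normalized profile has mean 1. The
#' result is invariant to overall scaling of the raw intensities.
#'
#' @param raw data.frame `chrom`, `pos_kb`, `ratio_W`, `ratio_Y` of raw
#'   intensity ratios (>= 0, not all zero).
#' @return `snp_profile` with mean(c(ratio_W, ratio_Y)) == 1.
#' @export
normalize_profile <- function(raw) {
  if (nrow(raw) < 1L) abort_config("normalize_profile: empty profile")
  v <- c(raw$ratio_W, raw$ratio_Y)
  if (any(v < 0)) abort_config("normalize_profile: negative intensities")
  m <- mean(v)
  if (m == 0) abort_config("normalize_profile: all-zero profile")
  out <- raw
  out$ratio_W <- raw$ratio_W / m
  out$ratio_Y <- raw$ratio_Y / m
  class(out) <- c("snp_profile", "data.frame")
  out
}

#' Call per-marker allele copy numbers
#'
#' Assigns each allele's ratio to the copy number with the nearest dosage
#' centroid, independently for the two parental alleles. The decision
#' boundaries implied by the 0.3 / 1.0 / 1.5 anchors are their midpoints
#' (0.65, 1.25, then +0.4 steps for higher dosage).
#'
#' @param profile a `snp_profile`.
#' @param centroids numeric vector of centroids for copies `0:(k-1)`;
#'   strictly increasing. Default [dosage_centroid()] for 0..6 copies.
#' @return data.frame `chrom`, `pos_kb`, `cnW`, `cnY`, `margin` where
#'   `margin` is the smaller of the two alleles' distances between best and
#'   second-best centroid assignment.
#' @export
call_marker_states <- function(profile, centroids = dosage_centroid(0:6)) {
  if (any(diff(centroids) <= 0)) {
    abort_config("call_marker_states: centroids must be strictly increasing")
  }
  near <- function(x) {
    d <- abs(outer(x, centroids, "-"))
    best <- max.col(-d, ties.method = "first")
    dbest <- d[cbind(seq_along(x), best)]
    d[cbind(seq_along(x), best)] <- Inf
    second <- apply(d, 1L, min)
    list(cn = best - 1L, margin = second - dbest)
  }
  w <- near(profile$ratio_W)
  y <- near(profile$ratio_Y)
  data.frame(chrom = profile$chrom, pos_kb = profile$pos_kb,
             cnW = w$cn, cnY = y$cn, margin = pmin(w$margin, y$margin),
             stringsAsFactors = FALSE)
}

#' Smooth a profile with a centered moving-average window
#'
#' A window of `window` SNPs is moved one SNP at a time along each
#' chromosome; chromosome ends use the truncated window. Output length
#' equals input length.
#'
#' @param profile a `snp_profile`.
#' @param window odd window size in SNPs (default 9).
#' @return smoothed `snp_profile`.
#' @export
smooth_profile <- function(profile, window = 9L) {
  if (window %% 2 == 0 || window < 1) {
    abort_config("smooth_profile: window must be odd and >= 1")
  }
  half <- (window - 1L) / 2L
  run_mean <- function(x) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out <- profile
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch)
    out$ratio_W[idx] <- run_mean(profile$ratio_W[idx])
    out$ratio_Y[idx] <- run_mean(profile$ratio_Y[idx])
  }
  out
}

state_id <- function(cnW, cnY) paste(cnW, cnY, sep = ":")

# Absorb runs shorter than min_markers into the flank with the longer
# adjacent run; ties go to the centromere-proximal flank. Operates on the
# per-marker state-id vector; returns the stabilized vector.
absorb_short_runs <- function(sid, pos, cen, min_markers) {
  if (min_markers <= 1L) return(sid)
  repeat {
    r <- rle(sid)
    k <- length(r$lengths)
    if (k <= 1L) break
    short <- which(r$lengths < min_markers)
    if (length(short) == 0L) break
    # handle the shortest run first for stability
    i <- short[order(r$lengths[short], short)][1L]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    if (i == 1L) {
      take <- r$values[2L]
    } else if (i == k) {
      take <- r$values[k - 1L]
    } else {
      ll <- r$lengths[i - 1L]; rl <- r$lengths[i + 1L]
      if (ll > rl) take <- r$values[i - 1L]
      else if (rl > ll) take <- r$values[i + 1L]
      else {
        mid <- mean(pos[starts[i]:ends[i]])
        # proximal flank: the one on the centromere side of the run
        take <- if (mid > cen) r$values[i - 1L] else r$values[i + 1L]
      }
    }
    sid[starts[i]:ends[i]] <- take
    if (length(rle(sid)$lengths) >= k) break  # safety: no progress
  }
  sid
}

# Build the segment table for one chromosome from a per-marker state vector.
segments_from_states <- function(sid, cnW, cnY, pos, chrom, chrom_len) {
  r <- rle(sid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(pos)
  data.frame(
    chrom = chrom,
    cnW = cnW[starts], cnY = cnY[starts],
    start_kb = pos[starts], end_kb = pos[ends],
    bp_left_lo = ifelse(starts == 1L, 0, pos[pmax(starts - 1L, 1L)]),
    bp_left_hi = pos[starts],
    bp_right_lo = pos[ends],
    bp_right_hi = ifelse(ends == n, chrom_len, pos[pmin(ends + 1L, n)]),
    n_markers = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Segment per-marker state calls into maximal runs
#'
#' Finds maximal runs of identical (cnW, cnY) state on each chromosome.
#' Runs shorter than `min_markers` are absorbed into the flanking state with
#' the longer adjacent run (ties to the centromere-proximal flank).
#' Breakpoint intervals span from the last marker of the previous state to
#' the first marker of the segment (chromosome ends use coordinate 0 and the
#' chromosome length).
#'
#' @param calls data.frame from [call_marker_states()].
#' @param genome a `genome_map` the calls are aligned to.
#' @param min_markers minimum run length retained (default 2).
#' @return data.frame of segments: `chrom`, `cnW`, `cnY`, `start_kb`,
#'   `end_kb`, `bp_left_lo`, `bp_left_hi`, `bp_right_lo`, `bp_right_hi`,
#'   `n_markers`.
#' @export
segment_states <- function(calls, genome, min_markers = 2L) {
  out <- lapply(unique(calls$chrom), function(ch) {
    idx <- which(calls$chrom == ch)
    if (length(idx) == 0L) return(NULL)
    pos <- calls$pos_kb[idx]
    sid <- state_id(calls$cnW[idx], calls$cnY[idx])
    sid <- absorb_short_runs(sid, pos, chrom_cen(genome, ch), min_markers)
    cn <- do.call(rbind, strsplit(sid, ":", fixed = TRUE))
    segments_from_states(sid, as.integer(cn[, 1]), as.integer(cn[, 2]),
                         pos, ch, chrom_length(genome, ch))
  })
  do.call(rbind, out)
}

# Refine one detection boundary at single-marker resolution: choose the cut
# within +/- window unsmoothed markers minimizing disagreement with the two
# flanking detection states.
refine_cut <- function(ucall_sid, cut, left_state, right_state, lo, hi) {
  cand <- seq.int(lo, hi + 1L)
  costs <- vapply(cand, function(c0) {
    left <- if (c0 > lo) sum(ucall_sid[lo:(c0 - 1L)] != left_state) else 0L
    right <- if (c0 <= hi) sum(ucall_sid[c0:hi] != right_state) else 0L
    left + right
  }, integer(1))
  cand[which.min(costs)]
}

#' Full calling pipeline: normalize, smooth, call, segment, refine
#'
#' Transitions are detected on a smoothed track (moving average of `window`
#' SNPs) and each breakpoint is then refined at single-SNP resolution by
#' re-examining the unsmoothed per-marker calls within `window` markers of
#' the detected boundary. Reported breakpoints therefore always come from
#' unsmoothed calls. Detection suppresses runs shorter than about half a
#' window; the final segmentation enforces `min_markers`.
#'
#' @param raw raw profile data.frame (`chrom`, `pos_kb`, `ratio_W`,
#'   `ratio_Y`).
#' @param genome `genome_map`.
#' @param params list: `window` (odd, default 9), `min_markers` (default 2),
#'   `centroids` (default [dosage_centroid()] of 0..6), `normalize`
#'   (default TRUE).
#' @return list with `profile` (normalized), `calls` (unsmoothed per-marker
#'   states), `segments`.
#' @export
call_pipeline <- function(raw, genome, params = list()) {
  window <- as.integer(params$window %||% 9L)
  min_markers <- as.integer(params$min_markers %||% 2L)
  centroids <- params$centroids %||% dosage_centroid(0:6)
  prof <- if (isTRUE(params$normalize %||% TRUE)) normalize_profile(raw) else raw
  ucalls <- call_marker_states(prof, centroids)
  scalls <- call_marker_states(smooth_profile(prof, window), centroids)
  detect_min <- max(min_markers, (window + 1L) %/% 2L)

  seg_list <- lapply(unique(prof$chrom), function(ch) {
    idx <- which(prof$chrom == ch)
    pos <- prof$pos_kb[idx]
    n <- length(idx)
    cen <- chrom_cen(genome, ch)
    usid <- state_id(ucalls$cnW[idx], ucalls$cnY[idx])
    ssid <- state_id(scalls$cnW[idx], scalls$cnY[idx])
    dsid <- absorb_short_runs(ssid, pos, cen, detect_min)
    r <- rle(dsid)
    if (length(r$lengths) > 1L) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cuts <- starts[-1L]
      for (b in seq_along(cuts)) {
        lo <- max(starts[b], cuts[b] - window)
        hi <- min(ends[b + 1L], cuts[b] + window - 1L)
        cuts[b] <- refine_cut(usid, cuts[b], r$values[b], r$values[b + 1L],
                              lo, hi)
      }
      cuts <- pmin(pmax(cuts, seq_along(cuts) + 1L), n)
      cuts <- cummax(cuts)  # keep boundaries ordered
      fin <- rep(r$values, times = diff(c(1L, cuts, n + 1L)))
    } else {
      fin <- dsid
    }
    fin <- absorb_short_runs(fin, pos, cen, min_markers)
    cn <- do.call(rbind, strsplit(fin, ":", fixed = TRUE))
    segments_from_states(fin, as.integer(cn[, 1]), as.integer(cn[, 2]),
                         pos, ch, chrom_length(genome, ch))
  })
  list(profile = prof, calls = ucalls, segments = do.call(rbind, seg_list))
}
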