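new_rate_estimate <- function(estimate, lo, hi, method, corrections = character(),
                              flag = NA_character_) {
  structure(list(estimate = estimate, lo = lo, hi = hi, method = method,
                 corrections = corrections, flag = flag),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g (95%% CL %.4g-%.4g)%s\n", x$method, x$estimate,
              x$lo, x$hi,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  if (length(x$corrections)) {
    cat("  corrections:", paste(x$corrections, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sectored-colony frequency with binomial confidence limits
#'
#' The frequency of red/white sectored colonies: sectored divided by total,
#' with a Wilson score 95% interval by default (Clopper-Pearson exact on
#' request).
#'
#' @param n_sectored,n_total counts, `0 <= n_sectored <= n_total`,
#'   `n_total > 0`.
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @return a `rate_estimate` (frequency per colony).
#' @export
sector_frequency <- function(n_sectored, n_total,
                             ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  if (!is_count(n_sectored) || !is_count(n_total) || n_total == 0 ||
      n_sectored > n_total) {
    abort_config("sector_frequency: need 0 <= n_sectored <= n_total, n_total > 0")
  }
  ci <- if (ci_method == "wilson") {
    stats::prop.test(n_sectored, n_total, correct = FALSE)$conf.int
  } else {
    stats::binom.test(n_sectored, n_total)$conf.int
  }
  new_rate_estimate(n_sectored / n_total, ci[1], ci[2],
                    method = paste0("binomial-frequency (", ci_method, ")"))
}

#' Luria-Delbruck rate by the method of the median (Lea-Coulson)
#'
#' Solves the Lea-Coulson median equation `r/m - ln(m) = 1.24` for the
#' expected number of events per culture `m`, where `r` is the median
#' resistant-colony count; the rate is `m / n_final_cells`. Confidence
#' limits transform the order-statistic 95% interval of the median count
#' through the same equation. A zero median yields an upper-bound-only
#' estimate (from the zero-culture likelihood), flagged.
#'
#' @param counts per-culture resistant-colony counts (>= 5 cultures).
#' @param n_final_cells final cells per culture.
#' @return a `rate_estimate` (events per cell division).
#' @export
estimate_rate_median <- function(counts, n_final_cells) {
  if (length(counts) < 5L) {
    abort_config("estimate_rate_median: need at least 5 cultures")
  }
  if (n_final_cells <= 0) {
    abort_config("estimate_rate_median: n_final_cells must be positive")
  }
  lc_m <- function(r) {
    if (r <= 0) return(NA_real_)
    stats::uniroot(function(m) r / m - log(m) - 1.24,
                   lower = 1e-9, upper = max(10 * r, 100),
                   tol = 1e-8, extendInt = "downX")$root
  }
  med <- stats::median(counts)
  n <- length(counts)
  if (med == 0) {
    m_hi <- -log(0.05) / n  # all-zero-compatible upper bound on m
    return(new_rate_estimate(0, 0, m_hi / n_final_cells,
                             method = "median-method",
                             flag = "upper-bound-only (median zero)"))
  }
  # order-statistic 95% CI for the median count, then transform
  ranks <- stats::qbinom(c(0.025, 0.975), n, 0.5)
  srt <- sort(counts)
  r_lo <- srt[max(1L, ranks[1])]
  r_hi <- srt[min(n, ranks[2] + 1L)]
  m_hat <- lc_m(med)
  m_lo <- if (r_lo > 0) lc_m(r_lo) else 0
  new_rate_estimate(m_hat / n_final_cells, m_lo / n_final_cells,
                    lc_m(r_hi) / n_final_cells, method = "median-method")
}

#' Crossover rate from the sectored-colony frequency
#'
#' Only half of the chromatid segregation patterns after a mitotic crossover
#' yield reciprocal LOH (a sectored colony), so the crossover rate is twice
#' the sectored frequency.
#'
#' @param freq sectored-colony frequency (>= 0).
#' @return crossover rate.
#' @export
crossover_rate_from_sectors <- function(freq) {
  stopifnot(freq >= 0)
  2 * freq
}

#' Recombination events per genome with assay corrections
#'
#' Starting from a sectored-colony frequency measured over an assay interval
#' covering `interval_fraction` of the genome: the segregation correction
#' doubles the frequency, the interval correction scales it to the whole
#' genome, and the viability correction divides by `viability^2` (a sectored
#' colony requires two viable daughters). With `include_noncrossover`, the
#' total is doubled again because conversions unassociated with crossovers
#' are about as frequent as crossovers.
#'
#' @param freq sectored-colony frequency.
#' @param interval_fraction fraction of the genome assayed (0 < f <= 1).
#' @param viability fraction of treated cells that remain viable
#'   (0 < v <= 1).
#' @param include_noncrossover double the total to count non-crossover
#'   conversions?
#' @return events per genome per cell division.
#' @export
events_per_genome <- function(freq, interval_fraction = 1, viability = 1,
                              include_noncrossover = FALSE) {
  if (interval_fraction <= 0 || interval_fraction > 1) {
    abort_config("events_per_genome: interval_fraction must be in (0, 1]")
  }
  if (viability <= 0 || viability > 1) {
    abort_config("events_per_genome: viability must be in (0, 1]")
  }
  x <- (2 * freq / interval_fraction) / viability^2
  if (isTRUE(include_noncrossover)) x <- 2 * x
  x
}

#' Segregation correction of observed crossover / conversion counts
#'
#' Half of the crossovers are invisible (their segregation pattern gives no
#' reciprocal LOH) and instead appear as conversions unassociated with
#' crossovers. The observed crossover count is therefore doubled and the
#' same number subtracted from the observed conversions.
#'
#' @param n_co observed crossovers.
#' @param n_con observed conversions unassociated with crossovers.
#' @return list `co` (= 2 n_co), `con` (= n_con - n_co), and `flag`
#'   (non-NA when the corrected conversion count is negative).
#' @export
correct_co_con_counts <- function(n_co, n_con) {
  stopifnot(is_count(n_co), is_count(n_con))
  out <- list(co = 2 * n_co, con = n_con - n_co, flag = NA_character_)
  if (n_con < n_co) {
    out$flag <- "negative-corrected-conversions"
    warning("correct_co_con_counts: corrected conversion count is negative",
            call. = FALSE)
  }
  out
}

#' Median conversion-tract length with bootstrap confidence limits
#'
#' Tract length is the distance between the midpoints of the two flanking
#' breakpoint intervals (column `tract_len_kb` of an event table). The 95%
#' CL is a percentile bootstrap of the median.
#'
#' @param events event data.frame with `tract_len_kb` (or a numeric vector
#'   of lengths).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @return list `median_kb`, `lo`, `hi`, `n`.
#' @export
tract_length_stats <- function(events, n_boot = 10000L, seed = 1L) {
  x <- if (is.data.frame(events)) events$tract_len_kb else events
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort_config("tract_length_stats: no tracts")
  med <- stats::median(x)
  if (length(x) == 1L) {
    return(list(median_kb = med, lo = med, hi = med, n = 1L))
  }
  with_seed(derive_seed(seed, 31), {
    boots <- vapply(seq_len(n_boot), function(i) {
      stats::median(sample(x, length(x), replace = TRUE))
    }, numeric(1))
    ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    list(median_kb = med, lo = min(ci[1], med), hi = max(ci[2], med),
         n = length(x))
  })
}

#' Fraction of conversion events initiated in G1
#'
#' The fraction of typed conversion tracts that contain a 4:0 region
#' (diagnostic of a DSB on an unreplicated chromosome), with a Wilson 95%
#' interval.
#'
#' @param events event data.frame with logical `has_40` (NA rows are
#'   untyped and excluded), or a list `c(n_40, n_total)`.
#' @return list `fraction`, `n_40`, `n_total`, `lo`, `hi`.
#' @export
fraction_g1_initiated <- function(events) {
  if (is.data.frame(events)) {
    h <- events$has_40[!is.na(events$has_40)]
    n40 <- sum(h); ntot <- length(h)
  } else {
    n40 <- events[1]; ntot <- events[2]
  }
  if (ntot == 0) abort_config("fraction_g1_initiated: no typed conversions")
  ci <- stats::prop.test(n40, ntot, correct = FALSE)$conf.int
  list(fraction = n40 / ntot, n_40 = n40, n_total = ntot,
       lo = ci[1], hi = ci[2])
}

#' Per-isolate and per-chromosome event summaries
#'
#' @param events event data.frame with `isolate`, `chrom`, `type`, `loh_kb`,
#'   `cnv_kb`.
#' @param genome `genome_map`.
#' @param n_isolates total isolates examined (defaults to the number of
#'   distinct labels; supply explicitly when some isolates had no events).
#' @return list: `per_isolate` (counts by category, kb under LOH/CNV),
#'   `mean_events_per_isolate`, `per_chromosome` (event totals), and
#'   `length_fit` (slope of events per kb and a Poisson dispersion test of
#'   proportionality to chromosome length).
#' @export
per_isolate_summary <- function(events, genome, n_isolates = NULL) {
  n_isolates <- n_isolates %||% max(1L, length(unique(events$isolate)))
  cat4 <- function(type) {
    ifelse(type == "CON", "CON",
      ifelse(type %in% c("CO", "CO_or_BIR", "BIR", "CON_CO"), "CO/BIR",
        ifelse(type %in% c("trisomy", "monosomy", "UPD"), "PLOIDY", "DEL/DUP")))
  }
  if (nrow(events)) {
    events$category <- cat4(events$type)
    per_iso <- do.call(rbind, lapply(split(events, events$isolate), function(e) {
      data.frame(isolate = e$isolate[1], n_events = nrow(e),
                 n_con = sum(e$category == "CON"),
                 n_co_bir = sum(e$category == "CO/BIR"),
                 n_del_dup = sum(e$category == "DEL/DUP"),
                 n_ploidy = sum(e$category == "PLOIDY"),
                 loh_kb = sum(e$loh_kb, na.rm = TRUE),
                 cnv_kb = sum(e$cnv_kb, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(per_iso) <- NULL
  } else {
    per_iso <- data.frame(isolate = character(), n_events = integer(),
                          n_con = integer(), n_co_bir = integer(),
                          n_del_dup = integer(), n_ploidy = integer(),
                          loh_kb = numeric(), cnv_kb = numeric())
  }
  chroms <- genome$chromosomes
  per_chr <- data.frame(chrom = chroms$chrom, length_kb = chroms$length_kb,
                        n_events = vapply(chroms$chrom, function(ch) {
                          sum(events$chrom == ch)
                        }, integer(1)), stringsAsFactors = FALSE)
  fit <- NULL
  if (sum(per_chr$n_events) > 0) {
    slope <- sum(per_chr$n_events) / sum(per_chr$length_kb)
    expected <- slope * per_chr$length_kb
    chi2 <- sum((per_chr$n_events - expected)^2 / expected)
    fit <- list(events_per_kb = slope, chi2 = chi2,
                df = nrow(per_chr) - 1L,
                p_dispersion = stats::pchisq(chi2, nrow(per_chr) - 1L,
                                             lower.tail = FALSE))
  }
  list(per_isolate = per_iso,
       mean_events_per_isolate = nrow(events) / n_isolates,
       per_chromosome = per_chr, length_fit = fit)
}

#' Per-interval recombination hotspot test
#'
#' Binomial test of each interval's observed event share against its
#' expected share (marker count or length weights), Bonferroni-adjusted.
#'
#' @param event_pos numeric positions of events (or an event data.frame with
#'   `start_kb` used as position).
#' @param intervals data.frame `start_kb`, `end_kb` tiling the assayed
#'   region.
#' @param weights positive expected weights per interval (default: interval
#'   lengths).
#' @return data.frame with observed counts, expected, raw and adjusted p.
#' @export
hotspot_test <- function(event_pos, intervals, weights = NULL) {
  if (is.data.frame(event_pos)) event_pos <- event_pos$start_kb
  n <- length(event_pos)
  if (n == 0L) abort_config("hotspot_test: no events")
  weights <- weights %||% (intervals$end_kb - intervals$start_kb)
  if (any(weights <= 0)) abort_config("hotspot_test: weights must be positive")
  pexp <- weights / sum(weights)
  obs <- vapply(seq_len(nrow(intervals)), function(i) {
    sum(event_pos >= intervals$start_kb[i] & event_pos < intervals$end_kb[i])
  }, integer(1))
  praw <- vapply(seq_along(obs), function(i) {
    stats::binom.test(obs[i], n, pexp[i])$p.value
  }, numeric(1))
  data.frame(intervals, observed = obs, expected = n * pexp, p = praw,
             p_adj = stats::p.adjust(praw, "bonferroni"))
}

#' Feature enrichment / depletion by tract permutation
#'
#' Compares the number of event tracts overlapping each feature track with a
#' null built by re-placing every tract uniformly on its own chromosome,
#' preserving its length. Two-sided empirical p-values with the add-one
#' correction, Bonferroni-adjusted across tracks.
#'
#' @param events event data.frame with `chrom`, `start_kb`, `end_kb`.
#' @param features named list of feature data.frames (`chrom`, `start_kb`,
#'   `end_kb`), e.g. `genome$features`.
#' @param genome `genome_map`.
#' @param n_perm permutations (>= 1000 recommended for reported p-values).
#' @param seed integer seed.
#' @return data.frame: feature, observed overlap count, null mean, p, p_adj.
#' @export
feature_enrichment <- function(events, features, genome, n_perm = 10000L,
                               seed = 1L) {
  stopifnot(nrow(events) > 0)
  ev_chr <- events$chrom
  ev_len <- events$end_kb - events$start_kb
  chr_len <- genome$chromosomes$length_kb[match(ev_chr, genome$chromosomes$chrom)]
  nev <- nrow(events)

  # merged, sorted feature intervals per chromosome for O(log n) overlap
  prep <- function(f) {
    lapply(split(f[, c("start_kb", "end_kb")], f$chrom), function(d) {
      d <- d[order(d$start_kb), ]
      s <- d$start_kb; e <- d$end_kb
      keep_s <- s[1]; merged_s <- c(); merged_e <- c(); cur_e <- e[1]
      for (i in seq_along(s)[-1]) {
        if (s[i] <= cur_e) cur_e <- max(cur_e, e[i])
        else { merged_s <- c(merged_s, keep_s); merged_e <- c(merged_e, cur_e)
               keep_s <- s[i]; cur_e <- e[i] }
      }
      list(s = c(merged_s, keep_s), e = c(merged_e, cur_e))
    })
  }
  overlap_count <- function(tree, chr, s, e) {
    hits <- logical(length(s))
    for (ch in unique(chr)) {
      iv <- tree[[ch]]
      idx <- which(chr == ch)
      if (is.null(iv)) next
      k <- findInterval(s[idx], iv$s)
      ov <- (k >= 1L & iv$e[pmax(k, 1L)] >= s[idx]) |
            (k < length(iv$s) & iv$s[k + 1L] <= e[idx])
      hits[idx] <- ov
    }
    sum(hits)
  }

  with_seed(derive_seed(seed, 37), {
    rows <- lapply(names(features), function(nm) {
      f <- features[[nm]]
      if (is.null(f) || nrow(f) == 0L) {
        warning(sprintf("feature_enrichment: empty track '%s' skipped", nm),
                call. = FALSE)
        return(NULL)
      }
      tree <- prep(f)
      obs <- overlap_count(tree, ev_chr, events$start_kb, events$end_kb)
      null <- vapply(seq_len(n_perm), function(p) {
        ns <- stats::runif(nev, 0, pmax(0.001, chr_len - ev_len))
        overlap_count(tree, ev_chr, ns, ns + ev_len)
      }, numeric(1))
      mu <- mean(null)
      # symmetric-deviation two-sided empirical p with add-one correction
      p2 <- (1 + sum(abs(null - mu) >= abs(obs - mu))) / (1 + n_perm)
      data.frame(feature = nm, observed = obs, null_mean = mu,
                 p = min(1, p2),
                 direction = if (obs >= mean(null)) "enriched" else "depleted",
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$p_adj <- pmin(1, out$p * nrow(out))
    out
  })
}

#' Expected rDNA events and the Poisson probability of seeing none
#'
#' @param n_terminal number of terminal LOH events observed genome-wide.
#' @param rdna_fraction fraction of the genome that is rDNA.
#' @return list `expected` (= n * fraction) and `p_zero` (= exp(-expected)).
#' @export
rdna_expectation <- function(n_terminal, rdna_fraction) {
  if (rdna_fraction < 0 || rdna_fraction > 1) {
    abort_config("rdna_expectation: rdna_fraction must be in [0, 1]")
  }
  expected <- n_terminal * rdna_fraction
  list(expected = expected, p_zero = exp(-expected))
}

#' Compare two mutation spectra
#'
#' Chi-square test of the six substitution-class proportions, plus per-class
#' two-sided tests comparing each class's share between the two spectra
#' (two-proportion chi-square, symmetric in the spectrum order).
#'
#' @param s1,s2 numeric vectors of six substitution-class counts (named by
#'   [SUBSTITUTION_CLASSES] or positional).
#' @return list `chisq` (htest), `p`, `per_class` data.frame.
#' @export
compare_spectra <- function(s1, s2) {
  s1 <- as.numeric(s1)[1:6]; s2 <- as.numeric(s2)[1:6]
  if (sum(s1) == 0 || sum(s2) == 0) {
    abort_config("compare_spectra: zero-total spectrum")
  }
  tab <- rbind(s1, s2)
  keep <- colSums(tab) > 0
  ch <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))
  per <- do.call(rbind, lapply(1:6, function(i) {
    pv <- if (s1[i] + s2[i] == 0 || s1[i] + s2[i] == sum(s1) + sum(s2)) 1 else
      suppressWarnings(stats::prop.test(c(s1[i], s2[i]),
                                        c(sum(s1), sum(s2)))$p.value)
    data.frame(class = SUBSTITUTION_CLASSES[i], s1 = s1[i], s2 = s2[i],
               share1 = s1[i] / sum(s1), share2 = s2[i] / sum(s2), p = pv,
               stringsAsFactors = FALSE)
  }))
  list(chisq = ch, p = ch$p.value, per_class = per)
}
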