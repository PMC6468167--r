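#' Simulate Luria-Delbruck fluctuation cultures
#'
#' Each culture grows from a single sensitive cell to `n_final_cells` cells
#' by binary divisions occurring one at a time in exchangeable random order;
#' each of the `n_final_cells - 1` divisions produces, with probability
#' `rate`, one mutant daughter whose lineage then grows stochastically with
#' the rest of the culture (a mutant clone founded when the population has
#' `n` cells reaches a geometric size with mean `n_final_cells / n`). This
#' is the growth law underlying the Lea-Coulson distribution, so counts
#' show the classic jackpot skew (mean far above median) and
#' `P(0) = exp(-m)` with `m = rate * n_final_cells` (to within 1/n).
#'
#' @param rate per-division event probability (0 <= rate <= 1).
#' @param n_final_cells final population size per culture (>= 2).
#' @param n_cultures number of parallel cultures.
#' @param seed integer seed.
#' @return numeric vector of resistant-colony counts, one per culture.
#' @export
simulate_fluctuation_cultures <- function(rate, n_final_cells, n_cultures,
                                          seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    abort_config("simulate_fluctuation_cultures: rate must be in [0, 1]")
  }
  if (n_final_cells < 2) {
    abort_config("simulate_fluctuation_cultures: n_final_cells must be >= 2")
  }
  stopifnot(is_count(n_cultures), n_cultures >= 1)
  N <- round(n_final_cells)
  with_seed(derive_seed(seed, 23), {
    counts <- numeric(n_cultures)
    for (i in seq_len(n_cultures)) {
      n_mut_events <- stats::rbinom(1L, size = N - 1L, prob = rate)
      if (n_mut_events == 0L) { counts[i] <- 0; next }
      # population size just after each founding division, uniform over the
      # growth history; clone then grows to a geometric size with mean N/n
      n_at <- sample.int(N - 1L, n_mut_events, replace = TRUE) + 1L
      sizes <- stats::rgeom(n_mut_events, prob = n_at / N) + 1
      counts[i] <- min(sum(sizes), N)
    }
    counts
  })
}

#' Simulate breakage of a circular chromosome
#'
#' Each of `n_molecules` circles receives Poisson(breaks_per_kb * circle_kb)
#' double-strand breaks; any break linearizes the molecule.
#'
#' @param breaks_per_kb break rate per kb (>= 0).
#' @param circle_kb circle size in kb (> 0).
#' @param n_molecules number of molecules (> 0).
#' @param seed integer seed.
#' @return fraction of molecules with at least one break.
#' @export
simulate_circular_breakage <- function(breaks_per_kb, circle_kb, n_molecules,
                                       seed = 1L) {
  if (breaks_per_kb < 0 || circle_kb <= 0 || n_molecules <= 0) {
    abort_config("simulate_circular_breakage: arguments must be positive (rate >= 0)")
  }
  lambda <- breaks_per_kb * circle_kb
  with_seed(derive_seed(seed, 29), {
    mean(stats::rpois(n_molecules, lambda) >= 1L)
  })
}
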