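#' Fraction of circular reporter molecules linearized
#'
#' From a Southern-quantified gel lane: the linear-III signal normalized to
#' the linear chromosome II loading control, divided by that ratio at
#' complete linearization. Without a calibration lane, complete
#' linearization is taken as `signal_linear_III + signal_well` (all circular
#' molecules broken), so `f = linIII / (linIII + well)`.
#'
#' @param lane list/data.frame row with `sig_well`, `sig_linIII`,
#'   `sig_chrII` (all >= 0, `sig_chrII > 0`).
#' @param calibration optional lane at complete linearization providing the
#'   reference linIII/chrII ratio.
#' @return fraction broken, clamped to `[0, 1)`.
#' @export
fraction_broken <- function(lane, calibration = NULL) {
  if (lane$sig_chrII <= 0 || lane$sig_well < 0 || lane$sig_linIII < 0) {
    abort_config("fraction_broken: signals must be >= 0 with sig_chrII > 0")
  }
  ratio <- lane$sig_linIII / lane$sig_chrII
  cal <- if (!is.null(calibration)) {
    calibration$sig_linIII / calibration$sig_chrII
  } else {
    (lane$sig_linIII + lane$sig_well) / lane$sig_chrII
  }
  if (cal <= 0) return(0)
  f <- ratio / cal
  if (f >= 1 + 1e-6) abort_config("fraction_broken: saturated lane (f >= 1)")
  min(max(f, 0), 1 - 1e-12)
}

#' DSBs per genome from the linearized fraction
#'
#' Single-hit Poisson model: breaks fall on the circle as Poisson with mean
#' `lambda * circle_kb`, so the intact fraction is `exp(-lambda * L)`.
#' Background breakage (untreated lane) is subtracted on the lambda scale:
#' `lambda = (-ln(1 - f) + ln(1 - f_background)) / circle_kb`, and the
#' genome-wide expectation is `lambda * genome_kb`.
#'
#' @param f fraction of circles linearized (0 <= f < 1).
#' @param circle_kb circle size in kb (default 320, the linear III band).
#' @param genome_kb genome size in kb (default 12070, haploid).
#' @param f_background linearized fraction in the untreated control.
#' @return expected DSBs per genome.
#' @export
dsbs_per_genome <- function(f, circle_kb = 320, genome_kb = 12070,
                            f_background = 0) {
  if (circle_kb <= 0 || genome_kb <= 0) {
    abort_config("dsbs_per_genome: lengths must be positive")
  }
  if (f >= 1) abort_config("dsbs_per_genome: f = 1 gives an infinite estimate")
  if (f_background < 0 || f_background > f) {
    abort_config("dsbs_per_genome: need 0 <= f_background <= f < 1")
  }
  lambda <- (-log(1 - f) + log(1 - f_background)) / circle_kb
  lambda * genome_kb
}

#' Quantify a table of gel lanes
#'
#' @param lanes data.frame with `lane`, `dose_mM`, `sig_well`, `sig_linIII`,
#'   `sig_chrII`.
#' @param circle_kb,genome_kb reporter and genome sizes in kb.
#' @param background_lane optional lane label used as the untreated
#'   background; its estimated `f` is subtracted from all lanes.
#' @return the input with `f` and `dsbs_per_genome` columns appended.
#' @export
quantify_lanes <- function(lanes, circle_kb = 320, genome_kb = 12070,
                           background_lane = NULL) {
  f <- vapply(seq_len(nrow(lanes)), function(i) {
    fraction_broken(lanes[i, ])
  }, numeric(1))
  f_bg <- 0
  if (!is.null(background_lane)) {
    i <- match(background_lane, lanes$lane)
    if (is.na(i)) abort_config("quantify_lanes: unknown background lane")
    f_bg <- f[i]
  }
  lanes$f <- f
  lanes$dsbs_per_genome <- vapply(f, function(fi) {
    dsbs_per_genome(max(fi, f_bg), circle_kb, genome_kb, f_background = f_bg)
  }, numeric(1))
  lanes
}
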