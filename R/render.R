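#' Hybridization-ratio centroid for a copy number
#'
#' Normalized two-colour hybridization ratios cluster near 0.3, 1.0 and 1.5
#' for 0, 1 and 2 copies of an allele; for 3 or more copies the dosage
#' response is extrapolated linearly with a sub-linear slope of 0.4 per extra
#' copy.
#'
#' @param cn integer copy number(s), >= 0.
#' @return numeric centroid ratio(s).
#' @export
dosage_centroid <- function(cn) {
  stopifnot(all(cn >= 0))
  out <- ifelse(cn == 0, 0.3, ifelse(cn == 1, 1.0, 1.5 + 0.4 * (cn - 2)))
  as.numeric(out)
}

#' Render a SNP-array profile from a genotype
#'
#' Draws, for every marker, a normalized hybridization ratio for each
#' parental allele from Normal(centroid(cn), noise_sd), truncated at 0.
#'
#' @param genotype data.frame `chrom`, `pos_kb`, `cnW`, `cnY` (from
#'   [diploid_genotype()] / [plant_event()]).
#' @param noise_sd standard deviation of the ratio noise (>= 0).
#' @param seed integer seed; profiles are bitwise-reproducible per seed.
#' @param sample_label label stored on the profile.
#' @return A `snp_profile`: data.frame `chrom`, `pos_kb`, `ratio_W`,
#'   `ratio_Y` with attribute `sample`.
#' @export
render_profile <- function(genotype, noise_sd = 0.1, seed = 1L,
                           sample_label = "sample") {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort_config("render_profile: noise_sd must be a single value >= 0")
  }
  n <- nrow(genotype)
  with_seed(derive_seed(seed, 17), {
    rw <- pmax(0, dosage_centroid(genotype$cnW) + stats::rnorm(n, 0, noise_sd))
    ry <- pmax(0, dosage_centroid(genotype$cnY) + stats::rnorm(n, 0, noise_sd))
    prof <- data.frame(chrom = genotype$chrom, pos_kb = genotype$pos_kb,
                       ratio_W = rw, ratio_Y = ry, stringsAsFactors = FALSE)
    attr(prof, "sample") <- sample_label
    class(prof) <- c("snp_profile", "data.frame")
    prof
  })
}

#' The six pyrimidine-strand substitution classes
#' @export
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Generate a synthetic mutation set
#'
#' Draws `n` mutation records with classes (six substitution classes plus
#' small in/dels) multinomially distributed.
#'
#' @param class_probs numeric vector of 7 probabilities (six substitutions,
#'   then indel) summing to 1.
#' @param n number of mutations.
#' @param seed integer seed.
#' @return data.frame `class`, `is_indel`.
#' @export
generate_mutations <- function(class_probs, n, seed = 1L) {
  if (length(class_probs) != 7L || any(class_probs < 0) ||
      abs(sum(class_probs) - 1) > 1e-8) {
    abort_config("generate_mutations: class_probs must be 7 probabilities summing to 1")
  }
  stopifnot(is_count(n))
  labels <- c(SUBSTITUTION_CLASSES, "indel")
  if (n == 0L) {
    return(data.frame(class = character(), is_indel = logical()))
  }
  with_seed(derive_seed(seed, 19), {
    cls <- sample(labels, n, replace = TRUE, prob = class_probs)
    data.frame(class = cls, is_indel = cls == "indel",
               stringsAsFactors = FALSE)
  })
}
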