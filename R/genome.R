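#' Reference chromosome sizes for the "paper" genome preset
#'
#' The 16 Saccharomyces cerevisiae chromosomes with approximate lengths and
#' centromere positions in kb (haploid total ~12,070 kb). Used by
#' [build_genome()] when `config = genome_config(preset = "paper")`.
#'
#' @return data.frame with columns `chrom`, `length_kb`, `cen_kb`.
#' @export
yeast_chromosomes <- function() {
  data.frame(
    chrom = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
              "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
              "chrXIV", "chrXV", "chrXVI"),
    length_kb = c(230, 813, 317, 1532, 577, 270, 1091, 563, 440, 746, 667,
                  1078, 924, 784, 1091, 948),
    cen_kb = c(151, 238, 114, 450, 152, 149, 497, 106, 356, 436, 440, 151,
               268, 628, 327, 556),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic genome
#'
#' @param preset `"paper"` for the 16-chromosome ~12 Mb hybrid diploid layout
#'   with 15,000 genome-wide heterozygous SNPs, or `"custom"`.
#' @param chromosomes for `"custom"`: data.frame with `chrom`, `length_kb`,
#'   `cen_kb`.
#' @param n_markers total number of heterozygous markers to place (allocated
#'   to chromosomes proportionally to length).
#' @param markers optional explicit marker table (`chrom`, `pos_kb`);
#'   overrides `n_markers`.
#' @param features logical; generate the synthetic annotation tracks (Ty,
#'   LTR, tRNA, G4, tandem_repeat, high_GC, rDNA)?
#' @return A list of class `"genome_config"`.
#' @export
genome_config <- function(preset = c("paper", "custom"), chromosomes = NULL,
                          n_markers = NULL, markers = NULL, features = TRUE) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    chromosomes <- chromosomes %||% yeast_chromosomes()
    n_markers <- n_markers %||% 15000L
  }
  if (is.null(chromosomes)) {
    abort_config("genome_config: 'custom' preset requires a chromosome table")
  }
  if (!all(c("chrom", "length_kb", "cen_kb") %in% names(chromosomes))) {
    abort_config("genome_config: chromosome table needs chrom, length_kb, cen_kb")
  }
  if (any(chromosomes$length_kb <= 0)) {
    abort_config("genome_config: chromosome lengths must be positive")
  }
  if (any(chromosomes$cen_kb <= 0 | chromosomes$cen_kb >= chromosomes$length_kb)) {
    abort_config("genome_config: centromeres must lie inside their chromosome")
  }
  if (is.null(markers)) {
    if (is.null(n_markers) || n_markers <= 0) {
      abort_config("genome_config: n_markers must be a positive count")
    }
  }
  structure(list(preset = preset, chromosomes = chromosomes,
                 n_markers = n_markers, markers = markers,
                 features = isTRUE(features)),
            class = "genome_config")
}

#' Build a synthetic hybrid-diploid genome map
#'
#' Places heterozygous SNP markers along each chromosome (uniformly at random,
#' sorted, deduplicated to a 1 bp grid) and, for the `"paper"` preset,
#' synthesizes annotation tracks including a single rDNA interval on
#' chromosome XII.
#'
#' @param config a [genome_config()].
#' @param seed integer seed; the map is deterministic given `config` + `seed`.
#' @return An object of class `"genome_map"`: list with `chromosomes`
#'   (chrom, length_kb, cen_kb), `markers` (chrom, pos_kb; strictly increasing
#'   within chromosome), and `features` (named list of data.frames with
#'   chrom, start_kb, end_kb, label).
#' @export
build_genome <- function(config = genome_config(), seed = 1L) {
  if (!inherits(config, "genome_config")) config <- do.call(genome_config, config)
  chroms <- config$chromosomes
  markers <- config$markers
  with_seed(seed, {
    if (is.null(markers)) {
      n <- as.integer(config$n_markers)
      # allocate counts proportionally to length, largest-remainder rounding
      w <- chroms$length_kb / sum(chroms$length_kb)
      n_per <- floor(w * n)
      rem <- n - sum(n_per)
      if (rem > 0) {
        extra <- order(w * n - n_per, decreasing = TRUE)[seq_len(rem)]
        n_per[extra] <- n_per[extra] + 1L
      }
      markers <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
        # uniform placement on a 1 bp grid, at least 1 bp from the ends
        pos <- sort(sample.int(chroms$length_kb[i] * 1000 - 2, n_per[i])) / 1000
        data.frame(chrom = chroms$chrom[i], pos_kb = pos,
                   stringsAsFactors = FALSE)
      }))
    } else {
      markers <- markers[order(match(markers$chrom, chroms$chrom),
                               markers$pos_kb), , drop = FALSE]
    }
    rownames(markers) <- NULL
    features <- if (config$features) synth_feature_tracks(chroms) else list()
    g <- structure(list(chromosomes = chroms, markers = markers,
                        features = features), class = "genome_map")
    validate_genome(g)
    g
  })
}

# Synthetic annotation tracks emulating the density and size of the real
# elements; the rDNA is one interval on chrXII.
synth_feature_tracks <- function(chroms) {
  mk <- function(n_per_mb, len_kb) {
    do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
      L <- chroms$length_kb[i]
      n <- max(0L, round(n_per_mb * L / 1000))
      if (n == 0L) return(NULL)
      start <- sort(runif(n, 1, max(2, L - len_kb - 1)))
      data.frame(chrom = chroms$chrom[i], start_kb = start,
                 end_kb = pmin(L, start + len_kb), stringsAsFactors = FALSE)
    }))
  }
  lab <- function(df, label) {
    if (is.null(df) || nrow(df) == 0L) {
      return(data.frame(chrom = character(), start_kb = numeric(),
                        end_kb = numeric(), label = character()))
    }
    df$label <- paste0(label, seq_len(nrow(df)))
    df
  }
  rdna <- data.frame(chrom = "chrXII", start_kb = 451, end_kb = 468,
                     label = "RDN1", stringsAsFactors = FALSE)
  if (!"chrXII" %in% chroms$chrom || max(chroms$length_kb[chroms$chrom == "chrXII"]) < 468) {
    rdna <- rdna[0, , drop = FALSE]
  }
  list(
    Ty            = lab(mk(4, 6), "Ty"),
    LTR           = lab(mk(30, 0.35), "LTR"),
    tRNA          = lab(mk(25, 0.08), "tRNA"),
    G4            = lab(mk(40, 0.03), "G4"),
    tandem_repeat = lab(mk(8, 2), "TR"),
    high_GC       = lab(mk(10, 5), "GC"),
    rDNA          = rdna
  )
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosomes, %.0f kb, %d markers, %d feature tracks\n",
              nrow(x$chromosomes), sum(x$chromosomes$length_kb),
              nrow(x$markers), length(x$features)))
  invisible(x)
}

validate_genome <- function(g) {
  stopifnot(inherits(g, "genome_map"))
  m <- g$markers
  for (ch in unique(m$chrom)) {
    pos <- m$pos_kb[m$chrom == ch]
    if (any(diff(pos) <= 0)) {
      abort_config("genome_map: marker positions not strictly increasing on %s", ch)
    }
    L <- g$chromosomes$length_kb[g$chromosomes$chrom == ch]
    if (length(L) != 1L) abort_config("genome_map: marker on unknown chromosome %s", ch)
    if (any(pos <= 0 | pos >= L)) {
      abort_config("genome_map: marker outside chromosome bounds on %s", ch)
    }
  }
  for (nm in names(g$features)) {
    f <- g$features[[nm]]
    if (nrow(f) == 0L) next
    L <- g$chromosomes$length_kb[match(f$chrom, g$chromosomes$chrom)]
    if (anyNA(L) || any(f$start_kb < 0 | f$end_kb > L | f$end_kb <= f$start_kb)) {
      abort_config("genome_map: feature track '%s' has out-of-bounds intervals", nm)
    }
  }
  if (!is.null(g$features$rDNA) && nrow(g$features$rDNA) > 1L) {
    abort_config("genome_map: rDNA track must be a single interval")
  }
  invisible(g)
}

# marker index helpers
chrom_markers <- function(genome, chrom) {
  genome$markers[genome$markers$chrom == chrom, , drop = FALSE]
}

chrom_length <- function(genome, chrom) {
  genome$chromosomes$length_kb[match(chrom, genome$chromosomes$chrom)]
}

chrom_cen <- function(genome, chrom) {
  genome$chromosomes$cen_kb[match(chrom, genome$chromosomes$chrom)]
}
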