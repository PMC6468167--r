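# TSV / BED input-output for pipeline stage products. All stage outputs are
# plain tab-separated text with a '#'-prefixed header comment recording the
# tool version and seed, so runs are auditable and diffable.

output_header <- function(seed = NA) {
  sprintf("# oxloh %s | seed=%s | %s",
          as.character(utils::packageVersion("oxloh")),
          ifelse(is.na(seed), "NA", format(seed)),
          format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

write_tsv_commented <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.table(format(df, digits = 7, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, required = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      abort_config("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
    }
  }
  df
}

#' Write / read a SNP profile TSV
#'
#' Columns `chrom`, `pos_kb`, `ratio_W`, `ratio_Y`; positions must be sorted
#' within chromosome. Round trip is lossless to 6 significant digits.
#'
#' @param profile a `snp_profile`.
#' @param path file path.
#' @param seed seed recorded in the header comment.
#' @return `read_profile_tsv` returns a `snp_profile`.
#' @export
write_profile_tsv <- function(profile, path, seed = NA) {
  write_tsv_commented(profile, path, seed)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read_tsv_commented(path, c("chrom", "pos_kb", "ratio_W", "ratio_Y"))
  if (nrow(df) == 0L) abort_config("%s: empty profile", path)
  for (ch in unique(df$chrom)) {
    if (is.unsorted(df$pos_kb[df$chrom == ch], strictly = TRUE)) {
      abort_config("%s: positions not strictly increasing on %s", path, ch)
    }
  }
  class(df) <- c("snp_profile", "data.frame")
  df
}

#' Write / read a segment TSV
#' @param segments segment data.frame from [segment_states()].
#' @param path file path.
#' @param seed seed recorded in the header comment.
#' @export
write_segments_tsv <- function(segments, path, seed = NA) {
  write_tsv_commented(segments, path, seed)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  read_tsv_commented(path, c("chrom", "cnW", "cnY", "start_kb", "end_kb",
                             "bp_left_lo", "bp_left_hi", "bp_right_lo",
                             "bp_right_hi", "n_markers"))
}

#' Write / read an event TSV
#' @param events event data.frame from the classifiers.
#' @param path file path.
#' @param seed seed recorded in the header comment.
#' @export
write_events_tsv <- function(events, path, seed = NA) {
  write_tsv_commented(events, path, seed)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  read_tsv_commented(path, c("isolate", "chrom", "type"))
}

#' Write / read a genome map as TSV files
#'
#' Writes `<stem>.chromosomes.tsv`, `<stem>.markers.tsv` and, per feature
#' track, `<stem>.features.tsv`.
#' @param genome a `genome_map`.
#' @param stem path stem.
#' @export
write_genome_tsv <- function(genome, stem) {
  write_tsv_commented(genome$chromosomes, paste0(stem, ".chromosomes.tsv"))
  write_tsv_commented(genome$markers, paste0(stem, ".markers.tsv"))
  feats <- do.call(rbind, lapply(names(genome$features), function(nm) {
    f <- genome$features[[nm]]
    if (nrow(f) == 0L) return(NULL)
    data.frame(track = nm, f, stringsAsFactors = FALSE)
  }))
  if (!is.null(feats)) {
    write_tsv_commented(feats, paste0(stem, ".features.tsv"))
  }
  invisible(stem)
}

#' @rdname write_genome_tsv
#' @export
read_genome_tsv <- function(stem) {
  chroms <- read_tsv_commented(paste0(stem, ".chromosomes.tsv"),
                               c("chrom", "length_kb", "cen_kb"))
  markers <- read_tsv_commented(paste0(stem, ".markers.tsv"),
                                c("chrom", "pos_kb"))
  fpath <- paste0(stem, ".features.tsv")
  features <- list()
  if (file.exists(fpath)) {
    f <- read_tsv_commented(fpath, c("track", "chrom", "start_kb", "end_kb"))
    features <- lapply(split(f, f$track), function(d) {
      d$track <- NULL; rownames(d) <- NULL; d
    })
  }
  g <- structure(list(chromosomes = chroms, markers = markers,
                      features = features), class = "genome_map")
  validate_genome(g)
  g
}

#' Read feature intervals from a BED-dialect file
#'
#' 4+ column BED: 0-based half-open bp intervals, converted to the internal
#' 1-based closed kb convention (`start_kb = (start + 1) / 1000`,
#' `end_kb = end / 1000`); the conversions are inverse bijections.
#'
#' @param path BED file path.
#' @param genome optional `genome_map`; intervals are validated against its
#'   chromosome bounds.
#' @return data.frame `chrom`, `start_kb`, `end_kb`, `label`.
#' @export
read_features_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    warning(sprintf("%s: empty feature file", path), call. = FALSE)
    return(data.frame(chrom = character(), start_kb = numeric(),
                      end_kb = numeric(), label = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort_config("%s: BED needs at least 3 columns (line %d)", path,
                 which(lengths(parts) < 3L)[1])
  }
  start_bp <- as.numeric(vapply(parts, `[`, "", 2L))
  end_bp <- as.numeric(vapply(parts, `[`, "", 3L))
  bad <- which(!(end_bp > start_bp))
  if (length(bad)) {
    abort_config("%s: end <= start at line %d", path, bad[1])
  }
  df <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start_kb = (start_bp + 1) / 1000,
    end_kb = end_bp / 1000,
    label = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else ".", ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    L <- genome$chromosomes$length_kb[match(df$chrom, genome$chromosomes$chrom)]
    if (anyNA(L)) abort_config("%s: unknown chromosome %s", path,
                               df$chrom[which(is.na(L))[1]])
    if (any(df$end_kb > L)) {
      abort_config("%s: interval exceeds chromosome length at line %d", path,
                   which(df$end_kb > L)[1])
    }
  }
  df
}

#' Write feature intervals as BED
#' @param features data.frame `chrom`, `start_kb`, `end_kb`, `label`.
#' @param path output path.
#' @export
write_features_bed <- function(features, path) {
  bed <- data.frame(chrom = features$chrom,
                    start = round(features$start_kb * 1000) - 1,
                    end = round(features$end_kb * 1000),
                    name = features$label %||% ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
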