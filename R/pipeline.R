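#' Load a pipeline configuration
#'
#' YAML key-value file with sections `genome` (preset, n_markers),
#' `simulate` (n_pairs, events_per_pair, noise_sd, mechanisms), `call`
#' (window, min_markers), `classify` (adjacency_kb), `stats` (n_boot,
#' n_perm), plus top-level `seed` and `out_dir`. Any referenced input file
#' must exist at load time.
#'
#' @param path YAML config file, or a list of the same structure.
#' @return list of class `"pipeline_config"` with defaults filled in.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort_config("pipeline_config: no such file: %s", path)
    c(yaml::read_yaml(path), list(.path = path))
  } else as.list(path)
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "oxloh_out"
  cfg$genome <- utils::modifyList(list(preset = "paper", n_markers = 15000L),
                                  cfg$genome %||% list())
  cfg$simulate <- utils::modifyList(
    list(n_pairs = 4L, events_per_pair = 4L, noise_sd = 0.1,
         mechanisms = EVENT_MECHANISMS), cfg$simulate %||% list())
  cfg$call <- utils::modifyList(list(window = 9L, min_markers = 2L),
                                cfg$call %||% list())
  cfg$classify <- utils::modifyList(list(adjacency_kb = 25), cfg$classify %||% list())
  cfg$stats <- utils::modifyList(list(n_boot = 10000L, n_perm = 10000L),
                                 cfg$stats %||% list())
  for (f in c(cfg$dsb$lanes_file)) {
    if (!is.null(f) && !file.exists(f)) {
      abort_config("pipeline_config: referenced file missing: %s", f)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

log_msg <- function(log_con, ...) {
  msg <- sprintf(...)
  message("[oxloh] ", msg)
  if (!is.null(log_con)) writeLines(paste(format(Sys.time()), msg), log_con)
}

#' Run pipeline stages
#'
#' Stages: `simulate` (genome + planted sector pairs + rendered profiles +
#' truth table + manifest), `call` (profiles to segments), `classify`
#' (segment pairs to events), `stats` (event summaries), `dsbquant` (gel
#' lane table to DSBs/genome), or `all`. All stage products are TSVs under
#' `out_dir`; identical config + seed reproduce byte-identical event tables.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @param subcommand one of `"simulate"`, `"call"`, `"classify"`, `"stats"`,
#'   `"dsbquant"`, `"all"`.
#' @return invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config, subcommand = c("all", "simulate", "call",
                                                "classify", "stats",
                                                "dsbquant")) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "a")
  on.exit(close(log_con))
  cfg_hash <- if (!is.null(config$.path)) unname(tools::md5sum(config$.path))
              else "inline"
  log_msg(log_con, "oxloh %s | stage=%s | seed=%d | config=%s",
          as.character(utils::packageVersion("oxloh")), subcommand,
          as.integer(seed), cfg_hash)
  paths <- list(log = log_path)
  stages <- if (subcommand == "all") {
    c("simulate", "call", "classify", "stats")
  } else subcommand

  gpath <- file.path(config$out_dir, "genome")
  manifest_path <- file.path(config$out_dir, "manifest.tsv")

  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = with_seed(derive_seed(seed, 97), {
        g <- build_genome(genome_config(preset = config$genome$preset,
                                        n_markers = config$genome$n_markers),
                          seed = seed)
        write_genome_tsv(g, gpath)
        mech <- config$simulate$mechanisms
        rows <- list(); truths <- list()
        for (p in seq_len(config$simulate$n_pairs)) {
          geno1 <- diploid_genotype(g); geno2 <- diploid_genotype(g)
          chroms <- sample(g$chromosomes$chrom,
                           config$simulate$events_per_pair)
          for (ei in seq_along(chroms)) {
            ch <- chroms[ei]
            m <- mech[((p + ei) %% length(mech)) + 1L]
            L <- chrom_length(g, ch); cen <- chrom_cen(g, ch)
            brk <- stats::runif(1, cen + 0.1 * L, 0.95 * L)
            pl <- plant_event(g, planted_event(m, ch, brk,
                                               donor = sample(c("W", "Y"), 1)),
                              seed = derive_seed(seed, p * 100 + ei))
            sel <- geno1$chrom == ch
            geno1[sel, c("cnW", "cnY")] <- pl$daughter1[sel, c("cnW", "cnY")]
            geno2[sel, c("cnW", "cnY")] <- pl$daughter2[sel, c("cnW", "cnY")]
            truths[[length(truths) + 1L]] <- cbind(pair = p, pl$truth)
          }
          red_path <- file.path(config$out_dir, sprintf("pair%02d_red.tsv", p))
          white_path <- file.path(config$out_dir, sprintf("pair%02d_white.tsv", p))
          write_profile_tsv(render_profile(geno1, config$simulate$noise_sd,
                                           seed = derive_seed(seed, 2 * p),
                                           sample_label = sprintf("pair%02d_red", p)),
                            red_path, seed)
          write_profile_tsv(render_profile(geno2, config$simulate$noise_sd,
                                           seed = derive_seed(seed, 2 * p + 1),
                                           sample_label = sprintf("pair%02d_white", p)),
                            white_path, seed)
          rows[[p]] <- data.frame(red_profile = basename(red_path),
                                  white_profile = basename(white_path))
        }
        write_tsv_commented(do.call(rbind, rows), manifest_path, seed)
        truth_df <- do.call(rbind, lapply(truths, function(t) {
          t[setdiff(c("pair", "mechanism", "chrom", "donor", "break_kb",
                      "type", "phase"), names(t))] <- NA
          t[, c("pair", "mechanism", "chrom", "donor", "break_kb", "type",
                "phase")]
        }))
        write_tsv_commented(truth_df,
                            file.path(config$out_dir, "truth.tsv"), seed)
        paths$manifest <- manifest_path
        log_msg(log_con, "simulate: %d sector pairs written",
                config$simulate$n_pairs)
      }),
      call = {
        if (!file.exists(manifest_path)) {
          abort_config("stage 'call': missing manifest (run 'simulate' first)")
        }
        g <- read_genome_tsv(gpath)
        man <- read_tsv_commented(manifest_path,
                                  c("red_profile", "white_profile"))
        for (f in c(man$red_profile, man$white_profile)) {
          prof <- read_profile_tsv(file.path(config$out_dir, f))
          res <- call_pipeline(prof, g, config$call)
          out <- file.path(config$out_dir, sub("\\.tsv$", ".segments.tsv", f))
          write_segments_tsv(res$segments, out, seed)
        }
        log_msg(log_con, "call: %d profiles segmented", 2L * nrow(man))
      },
      classify = {
        if (!file.exists(manifest_path) ||
            !file.exists(paste0(gpath, ".chromosomes.tsv"))) {
          abort_config("stage 'classify': missing inputs (run 'simulate' and 'call' first)")
        }
        g <- read_genome_tsv(gpath)
        man_seg <- file.path(config$out_dir,
                             sub("\\.tsv$", ".segments.tsv",
                                 read_tsv_commented(manifest_path,
                                                    c("red_profile",
                                                      "white_profile"))$red_profile))
        if (!all(file.exists(man_seg))) {
          abort_config("stage 'classify': missing segment files (run 'call' first)")
        }
        man <- read_tsv_commented(manifest_path, c("red_profile", "white_profile"))
        evs <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
          red <- read_segments_tsv(file.path(config$out_dir,
                      sub("\\.tsv$", ".segments.tsv", man$red_profile[i])))
          white <- read_segments_tsv(file.path(config$out_dir,
                      sub("\\.tsv$", ".segments.tsv", man$white_profile[i])))
          classify_sector_pair(sector_pair(red, white, g),
                               isolate = sprintf("pair%02d", i))
        }))
        paths$events <- file.path(config$out_dir, "events.tsv")
        write_events_tsv(evs, paths$events, seed)
        log_msg(log_con, "classify: %d events from %d pairs", nrow(evs),
                nrow(man))
      },
      stats = {
        epath <- file.path(config$out_dir, "events.tsv")
        if (!file.exists(epath)) {
          abort_config("stage 'stats': missing events.tsv (run 'classify' first)")
        }
        g <- read_genome_tsv(gpath)
        evs <- read_events_tsv(epath)
        summ <- per_isolate_summary(evs, g)
        write_tsv_commented(summ$per_isolate,
                            file.path(config$out_dir, "per_isolate.tsv"), seed)
        write_tsv_commented(summ$per_chromosome,
                            file.path(config$out_dir, "per_chromosome.tsv"),
                            seed)
        tl <- evs$tract_len_kb[!is.na(evs$tract_len_kb)]
        if (length(tl)) {
          ts <- tract_length_stats(tl, n_boot = config$stats$n_boot,
                                   seed = seed)
          write_tsv_commented(data.frame(median_kb = ts$median_kb,
                                         lo = ts$lo, hi = ts$hi, n = ts$n),
                              file.path(config$out_dir, "tract_lengths.tsv"),
                              seed)
        }
        log_msg(log_con, "stats: summaries written")
      },
      dsbquant = {
        lf <- config$dsb$lanes_file
        if (is.null(lf)) abort_config("stage 'dsbquant': no dsb$lanes_file configured")
        lanes <- read_tsv_commented(lf, c("lane", "dose_mM", "sig_well",
                                          "sig_linIII", "sig_chrII"))
        out <- quantify_lanes(lanes,
                              circle_kb = config$dsb$circle_kb %||% 320,
                              genome_kb = config$dsb$genome_kb %||% 12070,
                              background_lane = config$dsb$background_lane)
        paths$dsb <- file.path(config$out_dir, "dsb_quant.tsv")
        write_tsv_commented(out, paths$dsb, seed)
        log_msg(log_con, "dsbquant: %d lanes quantified", nrow(out))
      }
    ), error = function(e) {
      log_msg(log_con, "stage '%s' failed: %s", stage, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  invisible(paths)
}
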