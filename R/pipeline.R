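#' Pipeline configuration
#'
#' Bundles all stage parameters of the end-to-end analysis. Input is either
#' a [session_config()] (synthetic session) or a directory of trajectory
#' TSV files written by [write_trajectory_tsv()].
#'
#' @param session a [session_config()], or `NULL` when `input_dir` is given.
#' @param input_dir directory of trajectory TSV files, or `NULL`.
#' @param out_dir output directory for the report bundle, or `NULL` to only
#'   return results in memory.
#' @param target_rate_hz sampling rate of the conditioned signals; inputs
#'   at 15 x this rate go through the two-stage decimator.
#' @param decimation_stages integer factors of the decimator.
#' @param butter_cutoff_hz,butter_order zero-delay Butterworth parameters.
#' @param threshold onset/offset fraction of peak velocity.
#' @param velocity_floor minimal span peak velocity, mm/s.
#' @param amplitude_floor_fraction non-targeted movement exclusion floor.
#' @param subsample_n speed-curvature samples per movement.
#' @param amplitude_delimiters `"zero"` or `"threshold"` window for the
#'   amplitude path integral.
#' @param seed integer seed overriding the session's.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(session = session_config(),
                            input_dir = NULL,
                            out_dir = NULL,
                            target_rate_hz = 1250 / 15,
                            decimation_stages = c(5L, 3L),
                            butter_cutoff_hz = 25, butter_order = 4,
                            threshold = 0.20, velocity_floor = 1,
                            amplitude_floor_fraction = 0.2,
                            subsample_n = 5,
                            amplitude_delimiters = "zero",
                            seed = NULL) {
  if (is.null(session) && is.null(input_dir))
    stop("either a session config or an input directory is required")
  if (!is.null(seed) && !is.null(session)) session$seed <- as.integer(seed)
  structure(list(session = session, input_dir = input_dir, out_dir = out_dir,
                 target_rate_hz = target_rate_hz,
                 decimation_stages = decimation_stages,
                 butter_cutoff_hz = butter_cutoff_hz,
                 butter_order = butter_order,
                 threshold = threshold, velocity_floor = velocity_floor,
                 amplitude_floor_fraction = amplitude_floor_fraction,
                 subsample_n = subsample_n,
                 amplitude_delimiters = amplitude_delimiters),
            class = "pipeline_config")
}

#' Condition one raw recording
#'
#' The conditioning chain: two-stage FIR decimation down to the target
#' rate (skipped when the input is already there), per-frame rigid
#' head-motion correction from the reference sensors (skipped when fewer
#' than three are present), and the zero-delay Butterworth lowpass.
#'
#' @param rec a raw [trajectory_recording()].
#' @param cfg a [pipeline_config()].
#' @return conditioned [trajectory_recording()].
#' @export
preprocess_recording <- function(rec, cfg = pipeline_config()) {
  if (rec$sample_rate > 1.5 * cfg$target_rate_hz)
    rec <- decimate_two_stage(rec, stages = cfg$decimation_stages)
  if (length(rec_sensors(rec, "reference")) >= 3)
    rec <- correct_head_and_align(rec)
  lowpass_zero_delay(rec, cutoff = cfg$butter_cutoff_hz,
                     order = cfg$butter_order)
}

#' Analyze one conditioned recording
#'
#' Spline representation of the (first) tongue sensor, principal-component
#' segmentation into closing/opening movements, amplitude-floor filtering,
#' kinematic triples and speed-curvature subsamples, and the trial's phase
#' density with its regime score.
#'
#' @param rec conditioned [trajectory_recording()].
#' @param cfg a [pipeline_config()].
#' @param truth optional ground truth entry for delimiter-based filtering.
#' @return list with `segments`, `triples`, `samples`, `phase`,
#'   `regime`, `pm`, `smooth` plus the trial `metadata`.
#' @export
analyze_recording <- function(rec, cfg = pipeline_config(), truth = NULL) {
  tongue <- setdiff(names(rec$channels), rec_sensors(rec, "reference"))[1]
  if (is.na(tongue)) stop("no tongue sensor in recording")
  smooth <- fit_quintic_spline(rec, sensors = tongue)
  pm <- principal_motion(smooth)
  segs <- segment_movements(pm, threshold = cfg$threshold,
                            velocity_floor = cfg$velocity_floor)
  segs <- filter_targeted(segs, floor_fraction = cfg$amplitude_floor_fraction,
                          truth = truth)
  md <- rec$metadata
  lab <- data.frame(speaker = md$speaker %||% "S1",
                    sequence = md$sequence %||% "ta",
                    rate_bpm = md$rate_bpm %||% NA_real_,
                    trial = md$trial %||% 1L,
                    sensor = tongue)
  triples <- samples <- NULL
  if (nrow(segs)) {
    triples <- cbind(kinematic_triples(segs, smooth,
                                       amplitude_delimiters = cfg$amplitude_delimiters),
                     lab, row.names = NULL)
    samples <- cbind(subsample_movements(segs, smooth, n = cfg$subsample_n),
                     lab, row.names = NULL)
  }
  pd <- phase_density(pm)
  list(metadata = md, segments = segs, triples = triples, samples = samples,
       phase = pd, regime = regime_score(pd), pm = pm, smooth = smooth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates generation (or loading), conditioning, segmentation,
#' kinematic and power-law analysis and phase portraits over a whole
#' session, and optionally writes the report bundle (CSV tables, phase
#' density TSVs, a machine-readable `summary.json` and a run log). Fully
#' deterministic for a given configuration and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly when writing) a list with `triples`, `samples`,
#'   `segments_per_trial`, `c_factors`, `pv_amplitude`, `global_fits`,
#'   `by_rate`, `comparison_2d`, `regimes`, `counts`, `log`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  log_lines <- character(0)
  logf <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  if (!is.null(cfg$input_dir)) {
    files <- sort(list.files(cfg$input_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(files)) stop("no trajectory files found in ", cfg$input_dir)
    recordings <- lapply(files, read_trajectory_tsv)
    names(recordings) <- sub("\\.tsv$", "", basename(files))
    truth <- stats::setNames(vector("list", length(recordings)),
                             names(recordings))
    logf("loaded %d trajectory files from %s", length(files), cfg$input_dir)
  } else {
    sess <- generate_session(cfg$session)
    recordings <- sess$recordings
    truth <- sess$truth
    logf("generated %d synthetic trials (seed %d)", length(recordings),
         cfg$session$seed)
  }
  results <- vector("list", length(recordings))
  names(results) <- names(recordings)
  for (id in names(recordings)) {
    res <- tryCatch({
      cond <- preprocess_recording(recordings[[id]], cfg)
      analyze_recording(cond, cfg, truth = truth[[id]])
    }, error = function(e)
      stop("pipeline stage failed for trial ", id, ": ",
           conditionMessage(e), call. = FALSE))
    results[[id]] <- res
    logf("trial %s: %d movements retained, %d samples (%d degenerate), regime score %.2f",
         id, nrow(res$segments),
         if (is.null(res$samples)) 0L else nrow(res$samples),
         if (is.null(res$samples)) 0L else sum(res$samples$degenerate),
         res$regime$score)
  }
  triples <- do.call(rbind, lapply(results, `[[`, "triples"))
  samples <- do.call(rbind, lapply(results, `[[`, "samples"))
  rownames(triples) <- rownames(samples) <- NULL
  c_factors <- pv_amp <- global_fits <- by_rate <- cmp2d <- NULL
  if (!is.null(triples) && nrow(triples)) {
    c_factors <- fit_c_factor(triples, by = c("sequence", "direction"))
    pv_amp <- suppressMessages(
      fit_peak_velocity_amplitude(triples,
                                  by = c("sequence", "direction", "rate_bpm")))
  }
  if (!is.null(samples) && nrow(samples)) {
    global_fits <- rate_direction_tables(samples,
                                         by = c("sequence", "direction"))
    by_rate <- rate_direction_tables(samples)
    cmp2d <- project_midsagittal(samples)
  }
  regimes <- do.call(rbind, lapply(names(results), function(id) {
    md <- results[[id]]$metadata
    data.frame(trial_id = id, sequence = md$sequence %||% NA,
               rate_bpm = md$rate_bpm %||% NA_real_,
               score = results[[id]]$regime$score,
               indeterminate = results[[id]]$regime$indeterminate)
  }))
  counts <- list(
    trials = length(results),
    movements = if (is.null(triples)) 0L else nrow(triples),
    closing = if (is.null(triples)) 0L else sum(triples$direction == "closing"),
    opening = if (is.null(triples)) 0L else sum(triples$direction == "opening"),
    samples = if (is.null(samples)) 0L else nrow(samples),
    degenerate_samples = if (is.null(samples)) 0L else sum(samples$degenerate))
  logf("totals: %d movements (%d closing, %d opening), %d speed-curvature pairs",
       counts$movements, counts$closing, counts$opening, counts$samples)
  bundle <- list(triples = triples, samples = samples,
                 c_factors = c_factors, pv_amplitude = pv_amp,
                 global_fits = global_fits, by_rate = by_rate,
                 comparison_2d = cmp2d, regimes = regimes,
                 counts = counts, results = results, log = log_lines)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir, results)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir, results) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(bundle$triples, "triples.csv")
  wcsv(bundle$samples, "speed_curvature_samples.csv")
  wcsv(bundle$c_factors, "c_factors.csv")
  wcsv(bundle$pv_amplitude, "peak_velocity_amplitude.csv")
  wcsv(bundle$global_fits, "powerlaw_global.csv")
  wcsv(bundle$by_rate, "powerlaw_by_rate.csv")
  wcsv(bundle$comparison_2d, "powerlaw_2d_vs_3d.csv")
  wcsv(bundle$regimes, "regime_scores.csv")
  for (id in names(results))
    write_phase_density(results[[id]]$phase,
                        file.path(out_dir, sprintf("phase_%s.tsv", id)))
  summary <- list(counts = bundle$counts,
                  global_fits = bundle$global_fits,
                  by_rate = bundle$by_rate,
                  c_factors = bundle$c_factors,
                  regimes = bundle$regimes)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(bundle$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Thin shell surface over the package functions. Subcommands:
#' `simulate` (write synthetic trials + ground truth JSON),
#' `analyze` (run the analysis on a directory of trajectory TSVs),
#' `all` (synthetic session end to end). Common flags: `--rates 30,570`,
#' `--trials N`, `--syllables N`, `--noise SD`, `--seed N`, `--out DIR`,
#' `--in DIR`. Returns the exit status (0 on success) rather than calling
#' `quit()`, so it is testable; the installed script
#' `inst/cli/artikin` wraps it.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
artikin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: artikin <simulate|analyze|all> [options]",
    "  simulate --out DIR [--rates R1,R2,..] [--trials N] [--syllables N]",
    "           [--noise SD] [--seed N]",
    "  analyze  --in DIR --out DIR",
    "  all      --out DIR [simulate options]", sep = "\n")
  fail <- function(msg) {
    message(msg)
    message(usage)
    invisible(1L)
  }
  if (!length(args)) return(fail("no subcommand given"))
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    a <- rest[i]
    if (!startsWith(a, "--") || i == length(rest))
      return(fail(paste("cannot parse argument:", a)))
    opts[[substring(a, 3)]] <- rest[i + 1L]
    i <- i + 2L
  }
  known <- c("rates", "trials", "syllables", "noise", "seed", "out", "in")
  bad <- setdiff(names(opts), known)
  if (length(bad)) return(fail(paste("unknown flag(s): --",
                                     paste(bad, collapse = ", --"), sep = "")))
  sess <- tryCatch(session_config(
    rates = if (!is.null(opts$rates))
      as.numeric(strsplit(opts$rates, ",")[[1]]) else c(30, 150, 300, 570),
    trials_per_rate = as.integer(opts$trials %||% 1L),
    syllables_per_trial = as.integer(opts$syllables %||% 10L),
    noise_sd = as.numeric(opts$noise %||% 0.05),
    seed = as.integer(opts$seed %||% 1L)), error = function(e) e)
  if (inherits(sess, "error")) return(fail(conditionMessage(sess)))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        if (is.null(opts$out)) return(fail("simulate requires --out DIR"))
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        s <- generate_session(sess)
        for (id in names(s$recordings))
          write_trajectory_tsv(s$recordings[[id]],
                               file.path(opts$out, paste0(id, ".tsv")))
        gt <- lapply(s$truth, function(g) g[setdiff(names(g), "head")])
        jsonlite::write_json(gt, file.path(opts$out, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA)
        message(sprintf("wrote %d trials to %s", length(s$recordings), opts$out))
        0L
      },
      analyze = {
        if (is.null(opts[["in"]]) || is.null(opts$out))
          return(fail("analyze requires --in DIR and --out DIR"))
        run_pipeline(pipeline_config(session = NULL, input_dir = opts[["in"]],
                                     out_dir = opts$out))
        0L
      },
      all = {
        if (is.null(opts$out)) return(fail("all requires --out DIR"))
        run_pipeline(pipeline_config(session = sess, out_dir = opts$out))
        0L
      },
      return(fail(paste("unknown subcommand:", cmd))))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
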