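#' Trajectory recording container
#'
#' A `trajectory_recording` holds uniformly sampled 3D positions (mm) for one
#' or more sensors, together with the sampling rate and trial metadata. It is
#' the common currency of the whole pipeline: the synthetic generator emits
#' it, the preprocessing chain transforms it, and the spline stage consumes
#' it.
#'
#' @param channels named list of numeric matrices, one per sensor, each with
#'   columns `x`, `y`, `z` (mm) and one row per sample. Coordinate
#'   convention: `x` anterior+, `y` superior+, `z` lateral+ (the mid-sagittal
#'   plane is x-y).
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param roles named character vector mapping sensor names to roles
#'   (`"tongue_tip"`, `"tongue_back"`, `"reference"`).
#' @param metadata list of trial metadata; conventional keys are `speaker`,
#'   `sequence` (`"ta"` or `"ka"`) and `rate_bpm`.
#' @return an object of class `trajectory_recording`.
#' @export
trajectory_recording <- function(channels, sample_rate, t0 = 0,
                                 roles = NULL, metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            is.numeric(sample_rate), length(sample_rate) == 1L)
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  n <- unique(vapply(channels, nrow, integer(1)))
  if (length(n) != 1L)
    stop("all channels must have the same number of samples")
  channels <- lapply(channels, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stop("each channel must have 3 columns (x, y, z)")
    colnames(m) <- c("x", "y", "z")
    m
  })
  if (is.null(roles)) {
    roles <- rep("tongue_tip", length(channels))
    names(roles) <- names(channels)
  }
  structure(list(channels = channels, sample_rate = sample_rate, t0 = t0,
                 roles = roles, metadata = metadata),
            class = "trajectory_recording")
}

#' @export
print.trajectory_recording <- function(x, ...) {
  n <- nrow(x$channels[[1]])
  cat(sprintf("<trajectory_recording> %d sensors x %d samples @ %.4g Hz (%.2f s)\n",
              length(x$channels), n, x$sample_rate, n / x$sample_rate))
  cat("  sensors:", paste(sprintf("%s[%s]", names(x$channels), x$roles[names(x$channels)]),
                          collapse = ", "), "\n")
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                                    character(1)),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Sample times of a recording
#' @param rec a [trajectory_recording()].
#' @return numeric vector of sample times (s).
#' @export
rec_times <- function(rec) {
  n <- nrow(rec$channels[[1]])
  rec$t0 + (seq_len(n) - 1L) / rec$sample_rate
}

#' Number of samples in a recording
#' @param rec a [trajectory_recording()].
#' @export
rec_length <- function(rec) nrow(rec$channels[[1]])

#' Sensors of a recording with a given role
#' @param rec a [trajectory_recording()].
#' @param role role string, e.g. `"reference"`.
#' @return character vector of sensor names.
#' @export
rec_sensors <- function(rec, role = NULL) {
  if (is.null(role)) return(names(rec$channels))
  names(rec$roles)[rec$roles == role]
}

#' Write a recording to tab-separated text
#'
#' The format is a plain TSV with `#`-prefixed header lines
#' (`sample_rate_hz`, `t0_s`, and metadata keys), a `# roles:` line, and
#' columns `t`, `<sensor>_x`, `<sensor>_y`, `<sensor>_z` in mm.
#'
#' @param rec a [trajectory_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(rec, path) {
  hdr <- c(sprintf("# sample_rate_hz: %.10g", rec$sample_rate),
           sprintf("# t0_s: %.10g", rec$t0),
           sprintf("# roles: %s", paste(names(rec$roles), rec$roles,
                                        sep = "=", collapse = " ")))
  for (k in names(rec$metadata))
    hdr <- c(hdr, sprintf("# %s: %s", k, paste(format(rec$metadata[[k]]), collapse = " ")))
  cols <- do.call(cbind, lapply(names(rec$channels), function(s) {
    m <- rec$channels[[s]]
    colnames(m) <- paste(s, c("x", "y", "z"), sep = "_")
    m
  }))
  df <- data.frame(t = rec_times(rec), cols, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_trajectory_tsv()]
#' @param path input file path.
#' @return a [trajectory_recording()].
#' @export
read_trajectory_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^# *([^:]+): *(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  sample_rate <- as.numeric(kv[["sample_rate_hz"]])
  t0 <- if (!is.null(kv[["t0_s"]])) as.numeric(kv[["t0_s"]]) else 0
  roles <- NULL
  if (!is.null(kv[["roles"]])) {
    pairs <- strsplit(strsplit(kv[["roles"]], " +")[[1]], "=", fixed = TRUE)
    roles <- vapply(pairs, `[`, character(1), 2L)
    names(roles) <- vapply(pairs, `[`, character(1), 1L)
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", check.names = FALSE)
  sens <- unique(sub("_[xyz]$", "", setdiff(names(df), "t")))
  channels <- lapply(sens, function(s)
    as.matrix(df[, paste(s, c("x", "y", "z"), sep = "_")]))
  names(channels) <- sens
  meta_keys <- setdiff(names(kv), c("sample_rate_hz", "t0_s", "roles"))
  metadata <- lapply(kv[meta_keys], function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  trajectory_recording(channels, sample_rate, t0 = t0,
                       roles = roles[sens], metadata = metadata)
}

#' Convert metronome rate to syllable frequency
#'
#' One consonant-vowel syllable is produced per metronome beat, so the
#' syllable frequency in Hz is `bpm / 60`: 30 bpm is 0.5 Hz and 570 bpm is
#' 9.5 Hz.
#'
#' @param bpm metronome rate(s) in beats per minute.
#' @return frequency in Hz.
#' @export
bpm_to_hz <- function(bpm) {
  if (any(bpm <= 0)) stop("metronome rate must be positive: ",
                          paste(bpm[bpm <= 0], collapse = ", "))
  bpm / 60
}
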