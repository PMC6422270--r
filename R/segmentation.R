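#' Principal component of articulator displacement
#'
#' The movement axis of a trial is the leading eigenvector of the position
#' covariance over the whole trial; the projection of the centered positions
#' onto it (the "score") is the 1D displacement along the movement
#' direction whose velocity drives segmentation. The axis sign is fixed so
#' that closing movements (toward the palate, superior) have positive score
#' velocity: the axis' superior (`y`) component is made non-negative.
#'
#' @param smooth a `smooth_trajectory` (see [fit_quintic_spline()]).
#' @param at sample times used for the covariance; defaults to the original
#'   sampling grid of the fit.
#' @return a `principal_motion` list with `axis` (unit 3-vector), `scores`,
#'   `score_velocity` (both at `at`), `t`, `explained_variance_fraction`,
#'   `center`, and the generating `smooth` object.
#' @export
principal_motion <- function(smooth, at = NULL) {
  if (is.null(at)) {
    n <- round(diff(smooth$t_range) * smooth$sample_rate) + 1L
    at <- seq(smooth$t_range[1], smooth$t_range[2], length.out = n)
  }
  pos <- predict(smooth, at)
  pc <- stats::prcomp(pos, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) < 1e-16 * (1 + mean(pos^2)))
    stop("no motion: zero positional variance")
  axis <- pc$rotation[, 1]
  if (axis[2] < 0 || (axis[2] == 0 && axis[1] < 0)) axis <- -axis
  vel <- predict(smooth, at, deriv = 1) %*% axis
  structure(list(axis = axis, t = at,
                 scores = as.numeric(sweep(pos, 2, pc$center) %*% axis),
                 score_velocity = as.numeric(vel),
                 explained_variance_fraction = ev[1] / sum(ev),
                 center = pc$center, smooth = smooth),
            class = "principal_motion")
}

# continuous score velocity along the principal axis
pm_velocity_fun <- function(pm) {
  force(pm)
  function(t) as.numeric(predict(pm$smooth, t, deriv = 1) %*% pm$axis)
}

#' Segment a trial into closing and opening movements
#'
#' Zero crossings of the principal-component velocity are the primary
#' movement delimiters. Within each inter-zero span the peak score speed is
#' located, and the movement onset (offset) is the earliest (latest)
#' crossing of 20% of that span's peak, so multi-peak velocity profiles
#' yield a single movement spanning the earliest-to-latest crossing.
#' Direction is `"closing"` where the score velocity is positive. Spans
#' whose peak score speed falls below `velocity_floor` are skipped as noise
#' micro-movements.
#'
#' @param pm a [principal_motion()].
#' @param threshold onset/offset threshold as a fraction of the span's peak
#'   velocity.
#' @param velocity_floor minimum span peak score speed, mm/s.
#' @return data.frame of class `movement_segments`, one row per movement,
#'   with zero-velocity delimiters `t_zero_on`/`t_zero_off`,
#'   threshold delimiters `t_on`/`t_off`, `direction`,
#'   `peak_velocity_time`, `peak_score_speed` and `excursion` (score range
#'   within the span, mm).
#' @export
segment_movements <- function(pm, threshold = 0.20, velocity_floor = 1) {
  stopifnot(inherits(pm, "principal_motion"), threshold > 0, threshold < 1)
  vfun <- pm_velocity_fun(pm)
  t <- pm$t
  v <- pm$score_velocity
  s <- sign(v)
  flip <- which(s[-1] * s[-length(s)] < 0)
  zeros <- vapply(flip, function(i)
    stats::uniroot(vfun, c(t[i], t[i + 1L]), tol = 1e-10)$root, numeric(1))
  zeros <- c(if (abs(v[1]) < .Machine$double.eps) t[1], zeros)
  if (length(zeros) < 2) return(empty_segments())
  rows <- list()
  for (k in seq_len(length(zeros) - 1L)) {
    z0 <- zeros[k]; z1 <- zeros[k + 1L]
    grid <- seq(z0, z1, length.out = max(31L, ceiling((z1 - z0) * pm$smooth$sample_rate * 4)))
    vg <- vfun(grid)
    dirsign <- sign(vg[which.max(abs(vg))])
    speed <- dirsign * vg                     # positive within the span
    ipk <- which.max(speed)
    opt <- stats::optimize(function(tt) dirsign * vfun(tt),
                           lower = grid[max(1L, ipk - 1L)],
                           upper = grid[min(length(grid), ipk + 1L)],
                           maximum = TRUE)
    vpk <- opt$objective; tpk <- opt$maximum
    if (vpk < velocity_floor) next
    thr <- threshold * vpk
    f <- function(tt) dirsign * vfun(tt) - thr
    above <- speed >= thr
    i_on <- which(above)[1]
    i_off <- which(above)[sum(above)]
    t_on <- if (i_on > 1L)
      stats::uniroot(f, c(grid[i_on - 1L], grid[i_on]), tol = 1e-10)$root else z0
    t_off <- if (i_off < length(grid))
      stats::uniroot(f, c(grid[i_off], grid[i_off + 1L]), tol = 1e-10)$root else z1
    sc <- predict(pm$smooth, grid) %*% pm$axis
    rows[[length(rows) + 1L]] <- data.frame(
      t_zero_on = z0, t_on = t_on, t_off = t_off, t_zero_off = z1,
      direction = if (dirsign > 0) "closing" else "opening",
      peak_velocity_time = tpk, peak_score_speed = vpk,
      excursion = diff(range(sc)))
  }
  if (!length(rows)) return(empty_segments())
  out <- do.call(rbind, rows)
  out$movement <- seq_len(nrow(out))
  class(out) <- c("movement_segments", "data.frame")
  out
}

empty_segments <- function() {
  out <- data.frame(t_zero_on = numeric(0), t_on = numeric(0),
                    t_off = numeric(0), t_zero_off = numeric(0),
                    direction = character(0), peak_velocity_time = numeric(0),
                    peak_score_speed = numeric(0), excursion = numeric(0),
                    movement = integer(0))
  class(out) <- c("movement_segments", "data.frame")
  out
}

#' Drop non-targeted movements
#'
#' Stand-in for the manual exclusion of movements not involved in forming
#' or releasing a tongue-palate constriction (drifts between syllables,
#' mostly at slow rates): movements whose principal-axis excursion falls
#' below `floor_fraction` of the trial's median excursion are removed. With
#' ground-truth delimiters available, segments are instead kept only if
#' they match a true movement within `match_tol` seconds.
#'
#' @param segments a `movement_segments` data.frame.
#' @param floor_fraction amplitude floor relative to the median excursion.
#' @param truth optional ground-truth list of one trial (from
#'   [generate_session()]) with element `zero_times`.
#' @param match_tol delimiter matching tolerance, s.
#' @return filtered `movement_segments`.
#' @export
filter_targeted <- function(segments, floor_fraction = 0.2, truth = NULL,
                            match_tol = 0.05) {
  if (!nrow(segments)) return(segments)
  if (!is.null(truth)) {
    zt <- truth$zero_times
    keep <- vapply(seq_len(nrow(segments)), function(i) {
      i_on <- which.min(abs(zt - segments$t_zero_on[i]))
      i_off <- which.min(abs(zt - segments$t_zero_off[i]))
      abs(zt[i_on] - segments$t_zero_on[i]) <= match_tol &&
        abs(zt[i_off] - segments$t_zero_off[i]) <= match_tol &&
        i_off == i_on + 1L   # spans exactly one true movement
    }, logical(1))
  } else {
    keep <- segments$excursion >= floor_fraction * stats::median(segments$excursion)
  }
  out <- segments[keep, , drop = FALSE]
  out$movement <- seq_len(nrow(out))
  class(out) <- c("movement_segments", "data.frame")
  out
}

#' Write a movement-segment table to CSV
#' @param segments a `movement_segments` data.frame.
#' @param path output path.
#' @param metadata optional named list prepended as constant columns.
#' @export
write_segments_csv <- function(segments, path, metadata = NULL) {
  df <- as.data.frame(segments)
  if (!is.null(metadata))
    for (k in rev(names(metadata))) df <- cbind(stats::setNames(
      data.frame(rep(metadata[[k]], nrow(df))), k), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
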