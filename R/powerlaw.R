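#' Instantaneous speed and 3D curvature along a trajectory
#'
#' Tangential speed `v = ||rdot||` and curvature
#' `kappa = ||rdot x rddot|| / ||rdot||^3`, the cross-product form of the
#' 3D curve-theory expression. Samples whose speed falls below
#' `speed_floor` are flagged degenerate (curvature is numerically unstable
#' where the velocity and acceleration vectors are nearly linearly
#' dependent), never silently dropped.
#'
#' @param smooth a `smooth_trajectory`.
#' @param t evaluation times within the spline domain.
#' @param speed_floor degeneracy floor on speed, mm/s.
#' @return data.frame with `t`, `v` (mm/s), `kappa` (1/mm), `kappa2d`
#'   (mid-sagittal x-y projection) and logical `degenerate`.
#' @export
speed_and_curvature <- function(smooth, t, speed_floor = 1e-3) {
  d1 <- predict(smooth, t, deriv = 1)
  d2 <- predict(smooth, t, deriv = 2)
  v2 <- rowSums(d1^2)
  v <- sqrt(v2)
  cx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  cy <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  cz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  kappa <- sqrt(cx^2 + cy^2 + cz^2) / pmax(v, .Machine$double.xmin)^3
  v2d <- sqrt(d1[, 1]^2 + d1[, 2]^2)
  kappa2d <- abs(cz) / pmax(v2d, .Machine$double.xmin)^3
  data.frame(t = t, v = v, kappa = kappa, v2d = v2d, kappa2d = kappa2d,
             degenerate = v < speed_floor)
}

#' Subsample a movement for the power-law regression
#'
#' Draws `n` speed-curvature samples at equal time fractions strictly
#' inside the zero-velocity delimiters, at
#' `t_zero_on + i/(n+1) * (t_zero_off - t_zero_on)`, `i = 1..n`. Interior
#' placement keeps the principal-axis velocity (and in practice the
#' tangential speed) away from zero so `log v` is defined, while the
#' zero-delimited window retains the high-curvature transitions between
#' opposite movements that threshold delimiters would cut away.
#'
#' @param seg one row of a `movement_segments` data.frame.
#' @param smooth the trial's `smooth_trajectory`.
#' @param n samples per movement.
#' @param speed_floor degeneracy floor passed to [speed_and_curvature()].
#' @return data.frame of `n` rows with `t`, `v`, `kappa`, `kappa2d`,
#'   `degenerate` and the movement's `direction`.
#' @export
subsample_movement <- function(seg, smooth, n = 5, speed_floor = 1e-3) {
  frac <- seq_len(n) / (n + 1)
  tt <- seg$t_zero_on + frac * (seg$t_zero_off - seg$t_zero_on)
  out <- speed_and_curvature(smooth, tt, speed_floor)
  out$movement <- seg$movement
  out$direction <- seg$direction
  out
}

#' Speed-curvature samples for all movements of a trial
#' @inheritParams subsample_movement
#' @param segments a `movement_segments` data.frame.
#' @return row-bound samples of all movements.
#' @export
subsample_movements <- function(segments, smooth, n = 5, speed_floor = 1e-3) {
  do.call(rbind, lapply(seq_len(nrow(segments)), function(i)
    subsample_movement(segments[i, ], smooth, n, speed_floor)))
}

#' Fit the speed-curvature power law
#'
#' Ordinary least squares of `log10 v` on `log10 kappa`:
#' `log v = log k - beta log kappa`, so the exponent is the negated slope
#' and the velocity gain factor is `10^intercept`. Degenerate samples are
#' excluded from the regression. `beta` and `r2` are invariant to the log
#' base; `k_gain` is reported for base 10, matching the customary printed
#' magnitudes.
#'
#' @param samples data.frame with `v`, `kappa` and optionally `degenerate`,
#'   `kappa2d`.
#' @param use_2d fit the mid-sagittal projection (`kappa2d` and in-plane
#'   speed are used) instead of the full 3D quantities.
#' @param speed_floor floor below which samples count as degenerate when no
#'   `degenerate` column is present.
#' @return one-row data.frame: `beta`, `log_k`, `k_gain`, `r2`, `p`, `n`
#'   (class `power_law_fit`).
#' @export
fit_power_law <- function(samples, use_2d = FALSE, speed_floor = 1e-3) {
  deg <- if (!is.null(samples$degenerate)) samples$degenerate
         else samples$v < speed_floor
  kap <- if (use_2d) samples$kappa2d else samples$kappa
  spd <- if (use_2d && !is.null(samples$v2d)) samples$v2d else samples$v
  keep <- !deg & kap > 0 & spd > 0
  if (sum(keep) < 3)
    stop("need at least 3 non-degenerate samples to fit the power law")
  lv <- log10(spd[keep])
  lk <- log10(kap[keep])
  fit <- stats::lm(lv ~ lk)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  ct <- suppressWarnings(stats::cor.test(lk, lv))
  out <- data.frame(beta = -unname(stats::coef(fit)[2]),
                    log_k = unname(stats::coef(fit)[1]),
                    k_gain = 10^unname(stats::coef(fit)[1]),
                    r2 = r2,
                    p = ct$p.value, n = sum(keep))
  class(out) <- c("power_law_fit", "data.frame")
  out
}

#' Stratified power-law tables
#'
#' Runs [fit_power_law()] separately per stratum (by default sequence x
#' direction x rate), the rate- and direction-specific analysis behind the
#' per-rate exponent/gain trends. Strata with fewer than 3 usable samples
#' are reported as `NA` rows ("n/a" cells), which is data, not an error.
#'
#' @param samples pooled sample data.frame including stratum columns.
#' @param by stratum column names present in `samples`.
#' @param use_2d fit the mid-sagittal 2D projection instead of 3D.
#' @return data.frame with one row per stratum (all combinations present in
#'   the data), columns `beta`, `log_k`, `k_gain`, `r2`, `p`, `n`.
#' @export
rate_direction_tables <- function(samples,
                                  by = c("sequence", "direction", "rate_bpm"),
                                  use_2d = FALSE) {
  by <- intersect(by, names(samples))
  strata <- split(samples, samples[by], drop = FALSE, sep = " | ")
  rows <- lapply(strata, function(d) {
    lab <- if (nrow(d)) unique(d[by])[1, , drop = FALSE] else NULL
    fit <- tryCatch(fit_power_law(d, use_2d = use_2d), error = function(e) NULL)
    if (is.null(fit))
      fit <- data.frame(beta = NA_real_, log_k = NA_real_, k_gain = NA_real_,
                        r2 = NA_real_, p = NA_real_,
                        n = if (nrow(d)) sum(!d$degenerate) else 0L)
    if (is.null(lab)) return(NULL)
    rownames(lab) <- NULL
    cbind(lab, as.data.frame(fit))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Mid-sagittal 2D vs full 3D power-law comparison
#'
#' Refits every stratum with the trajectory intentionally projected onto
#' the mid-sagittal (x-y) plane, reusing the same subsampling times, and
#' pairs the resulting fits with the 3D ones. Lateral components of a few
#' percent are enough to weaken the 2D correlation relative to 3D.
#'
#' @inheritParams rate_direction_tables
#' @return data.frame with per-stratum `beta_3d`, `beta_2d`, `r2_3d`,
#'   `r2_2d` and `r2_diff` (3D minus 2D).
#' @export
project_midsagittal <- function(samples,
                                by = c("sequence", "direction", "rate_bpm")) {
  f3 <- rate_direction_tables(samples, by = by, use_2d = FALSE)
  f2 <- rate_direction_tables(samples, by = by, use_2d = TRUE)
  by <- intersect(by, names(samples))
  key3 <- do.call(paste, c(f3[by], sep = " | "))
  key2 <- do.call(paste, c(f2[by], sep = " | "))
  f2 <- f2[match(key3, key2), ]
  out <- cbind(f3[by],
               data.frame(beta_3d = f3$beta, beta_2d = f2$beta,
                          k_3d = f3$k_gain, k_2d = f2$k_gain,
                          r2_3d = f3$r2, r2_2d = f2$r2,
                          r2_diff = f3$r2 - f2$r2, n = f3$n))
  rownames(out) <- NULL
  out
}
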