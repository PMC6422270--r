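#' Kinematic triple of one movement
#'
#' Duration `T`, amplitude `A` and peak velocity `v*`. Duration is the time
#' between the 20%-peak-velocity onset and offset delimiters; amplitude is
#' the 3D path length of the trajectory, integrated by default over the
#' zero-velocity delimiters so it equals the full figural excursion
#' (switchable to the threshold delimiters); peak velocity is the maximum
#' tangential speed `sqrt(xdot^2 + ydot^2 + zdot^2)` over the movement.
#'
#' @param seg one row of a `movement_segments` data.frame.
#' @param smooth the trial's `smooth_trajectory`.
#' @param amplitude_delimiters `"zero"` (default) or `"threshold"`: window
#'   for the path-length integral.
#' @param duration_delimiters `"threshold"` (default) or `"zero"`: window
#'   defining `T` (and the `v*` search window).
#' @param n_quad quadrature points for the arc-length integral.
#' @return data.frame row with `T`, `A`, `v_peak`, `v_peak_time` and the
#'   delimiters.
#' @export
kinematic_triple <- function(seg, smooth,
                             amplitude_delimiters = c("zero", "threshold"),
                             duration_delimiters = c("threshold", "zero"),
                             n_quad = 200) {
  amplitude_delimiters <- match.arg(amplitude_delimiters)
  duration_delimiters <- match.arg(duration_delimiters)
  dwin <- if (duration_delimiters == "threshold")
    c(seg$t_on, seg$t_off) else c(seg$t_zero_on, seg$t_zero_off)
  Tdur <- diff(dwin)
  if (Tdur <= 0) stop("degenerate segment: non-positive duration")
  awin <- if (amplitude_delimiters == "zero")
    c(seg$t_zero_on, seg$t_zero_off) else c(seg$t_on, seg$t_off)
  A <- arc_length(smooth, awin[1], awin[2], n_quad)
  # tangential speed is searched over the full zero-delimited movement
  grid <- seq(seg$t_zero_on, seg$t_zero_off, length.out = n_quad)
  sp <- tangential_speed(smooth, grid)
  i <- which.max(sp)
  opt <- stats::optimize(function(tt) tangential_speed(smooth, tt),
                         lower = grid[max(1L, i - 1L)],
                         upper = grid[min(n_quad, i + 1L)], maximum = TRUE)
  data.frame(T = Tdur, A = A, v_peak = opt$objective,
             v_peak_time = opt$maximum,
             t_zero_on = seg$t_zero_on, t_on = seg$t_on,
             t_off = seg$t_off, t_zero_off = seg$t_zero_off,
             direction = seg$direction)
}

tangential_speed <- function(smooth, t) {
  d1 <- predict(smooth, t, deriv = 1)
  sqrt(rowSums(d1^2))
}

# arc length by composite Gauss-Legendre (2-point) quadrature
arc_length <- function(smooth, t0, t1, n_quad = 200) {
  edges <- seq(t0, t1, length.out = n_quad + 1L)
  hw <- diff(edges) / 2
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  g <- 1 / sqrt(3)
  sum(hw * (tangential_speed(smooth, mid - g * hw) +
            tangential_speed(smooth, mid + g * hw)))
}

#' Kinematic triples for all movements of a trial
#'
#' @param segments a `movement_segments` data.frame.
#' @param smooth the trial's `smooth_trajectory`.
#' @param ... passed to [kinematic_triple()].
#' @return data.frame with one row per movement (plus `movement` id).
#' @export
kinematic_triples <- function(segments, smooth, ...) {
  out <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i)
    kinematic_triple(segments[i, ], smooth, ...)))
  out$movement <- segments$movement
  out
}

#' Peak-velocity vs amplitude regression per stratum
#'
#' Ordinary least squares of `v_peak` on `A` within each stratum (e.g. each
#' rate x direction cell), reported so rate ordering of the slopes can be
#' examined.
#'
#' @param triples data.frame with columns `v_peak`, `A` and any stratum
#'   columns.
#' @param by character vector of stratum column names (may be empty).
#' @return data.frame with `slope`, `intercept`, `r2`, `n` per stratum;
#'   strata with fewer than 3 movements or zero amplitude variance are
#'   skipped with a message.
#' @export
fit_peak_velocity_amplitude <- function(triples, by = character(0)) {
  strata <- if (length(by)) split(triples, triples[by], drop = TRUE)
            else list(all = triples)
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 3 || stats::var(d$A) == 0) {
      message("skipping stratum ", nm, ": n < 3 or constant amplitude")
      return(NULL)
    }
    fit <- stats::lm(v_peak ~ A, data = d)
    cbind(stratum_frame(d, by),
          data.frame(slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     r2 = suppressWarnings(summary(fit)$r.squared),
                     n = nrow(d)))
  })
  do.call(rbind, rows)
}

#' c factor of the duration relation
#'
#' The ratio of peak velocity to amplitude varies inversely with movement
#' duration, `v*/A = c * pi / T`; `c` is estimated per stratum by
#' no-intercept least squares of `v*/A` on `1/T` and reported in units of
#' pi. For harmonic movements delimited at zero velocity, `c = 1/2`
#' exactly; for critically damped gestures it is bounded just below 1/2.
#' The reported `r2` is the squared Pearson correlation between `v*/A` and
#' `1/T` (comparable across strata, unlike the no-intercept coefficient of
#' determination); a `with_intercept` diagnostic variant is available.
#'
#' @param triples data.frame with `v_peak`, `A`, `T` and stratum columns.
#' @param by character vector of stratum column names.
#' @param with_intercept if `TRUE`, fit `v*/A ~ 1/T` with an intercept
#'   (diagnostic; `c` is then the slope term in units of pi).
#' @return data.frame with `c`, `r2`, `n` per stratum.
#' @export
fit_c_factor <- function(triples, by = character(0), with_intercept = FALSE) {
  strata <- if (length(by)) split(triples, triples[by], drop = TRUE)
            else list(all = triples)
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 3) {
      message("skipping stratum ", nm, ": n < 3")
      return(NULL)
    }
    ratio <- d$v_peak / d$A
    invT <- 1 / d$T
    fit <- if (with_intercept) stats::lm(ratio ~ invT)
           else stats::lm(ratio ~ 0 + invT)
    slope <- unname(stats::coef(fit)[["invT"]])
    r2 <- if (stats::var(invT) > 0) stats::cor(ratio, invT)^2 else NA_real_
    cbind(stratum_frame(d, by),
          data.frame(c = slope / pi, r2 = r2, n = nrow(d)))
  })
  do.call(rbind, rows)
}

stratum_frame <- function(d, by) {
  if (!length(by)) return(data.frame(row.names = 1L))
  out <- unique(d[by])
  rownames(out) <- NULL
  out[1, , drop = FALSE]
}

#' Simulate a critically damped gesture
#'
#' The standard dynamical model of a speech gesture is the damped linear
#' oscillator `xddot = -k (x - target) - b xdot` with critical damping
#' (`zeta = 1`, `b = 2 sqrt(k)`). The solution is evaluated in closed form:
#' for `zeta = 1`, `x(t) = target + (dx0 + (v0 + omega dx0) t) exp(-omega t)`
#' with `omega = sqrt(k)` and `dx0 = x0 - target`. Non-critical damping is
#' accepted (with a warning flagging it as outside the standard model) and
#' solved with the general under/over-damped closed forms.
#'
#' @param k_s stiffness, 1/s^2.
#' @param x0,v0 initial displacement (mm) and velocity (mm/s).
#' @param target equilibrium target, mm.
#' @param zeta damping ratio; 1 for the standard model.
#' @param dt time step, s.
#' @param duration simulated time, s.
#' @return data.frame with `t`, `x`, `v`.
#' @export
simulate_gesture <- function(k_s, x0, v0 = 0, target = 0, zeta = 1,
                             dt = 0.001, duration = 1) {
  stopifnot(k_s > 0, dt > 0, duration > 0)
  om <- sqrt(k_s)
  t <- seq(0, duration, by = dt)
  d0 <- x0 - target
  if (zeta == 1) {
    e <- exp(-om * t)
    x <- target + (d0 + (v0 + om * d0) * t) * e
    v <- (v0 - om * (v0 + om * d0) * t) * e
  } else {
    warning("zeta != 1: outside the standard critically damped gesture model")
    if (zeta < 1) {
      wd <- om * sqrt(1 - zeta^2)
      e <- exp(-zeta * om * t)
      A1 <- d0
      B1 <- (v0 + zeta * om * d0) / wd
      x <- target + e * (A1 * cos(wd * t) + B1 * sin(wd * t))
      v <- e * ((B1 * wd - zeta * om * A1) * cos(wd * t) -
                (A1 * wd + zeta * om * B1) * sin(wd * t))
    } else {
      r1 <- -om * (zeta - sqrt(zeta^2 - 1))
      r2 <- -om * (zeta + sqrt(zeta^2 - 1))
      A1 <- (v0 - r2 * d0) / (r1 - r2)
      B1 <- d0 - A1
      x <- target + A1 * exp(r1 * t) + B1 * exp(r2 * t)
      v <- A1 * r1 * exp(r1 * t) + B1 * r2 * exp(r2 * t)
    }
  }
  data.frame(t = t, x = x, v = v)
}
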