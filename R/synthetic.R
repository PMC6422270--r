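#' Configuration of a synthetic recording session
#'
#' Describes a metronome-driven repetitive-syllable session: eight rates
#' from very slow to very fast, around 30 syllables per trial, at least four
#' trials per rate, sensors digitized at 1250 Hz. Defaults follow that
#' paradigm; deviations are configuration, not code changes.
#'
#' The figural excursion shrinks linearly from `excursion_range[1]` at the
#' slowest configured rate to `excursion_range[2]` at the fastest
#' (15 mm to 10 mm by default), and the traversal timing follows a
#' speed-curvature power law whose exponent interpolates linearly over rate
#' between `beta_range[1]` (slowest) and `beta_range[2]` (fastest). The
#' velocity gain factor is implied by the cycle period, so it rises with
#' rate.
#'
#' @param rates metronome rates in beats per minute.
#' @param syllables_per_trial syllable (cycle) count per trial.
#' @param trials_per_rate number of trials recorded at each rate.
#' @param sequences syllable types to record, subset of `c("ta", "ka")`.
#' @param shape figural template passed to [figural_path()].
#' @param lateral_fraction RMS of the lateral (z) component relative to the
#'   in-plane RMS displacement; the study range is 0.05-0.10.
#' @param noise_sd additive i.i.d. Gaussian sensor noise per axis, mm.
#' @param amplitude_jitter relative amplitude of the slow envelope that
#'   modulates figure size within a trial, emulating token-to-token
#'   variability (0 disables).
#' @param head_motion list with `translation_mm` and `rotation_deg`
#'   amplitudes of the slow rigid head motion (0 for none).
#' @param excursion_range peak-to-peak principal-axis excursion (mm) at the
#'   slowest and fastest configured rate.
#' @param beta_range true power-law exponent at the slowest and fastest
#'   configured rate.
#' @param aspect,bend figural template parameters, see [figural_path()].
#' @param sample_rate digitization rate, Hz.
#' @param seed integer seed; identical seeds give identical sessions.
#' @return a `session_config` list.
#' @export
session_config <- function(rates = c(30, 90, 150, 210, 300, 390, 480, 570),
                           syllables_per_trial = 30,
                           trials_per_rate = 4,
                           sequences = "ta",
                           shape = "bent_loop",
                           lateral_fraction = 0.075,
                           noise_sd = 0.05,
                           amplitude_jitter = 0.05,
                           head_motion = list(translation_mm = 2, rotation_deg = 1.5),
                           excursion_range = c(15, 10),
                           beta_range = c(0.50, 0.33),
                           aspect = 0.6, bend = 0.12,
                           sample_rate = 1250,
                           seed = 1L) {
  if (any(rates <= 0))
    stop("metronome rates must be positive; offending rate(s): ",
         paste(rates[rates <= 0], collapse = ", "))
  stopifnot(syllables_per_trial >= 1, trials_per_rate >= 0,
            lateral_fraction >= 0, lateral_fraction < 1,
            noise_sd >= 0, sample_rate > 0)
  sequences <- match.arg(sequences, c("ta", "ka"), several.ok = TRUE)
  stopifnot(amplitude_jitter >= 0, amplitude_jitter < 0.5)
  structure(list(rates = rates, syllables_per_trial = syllables_per_trial,
                 trials_per_rate = trials_per_rate, sequences = sequences,
                 shape = shape, lateral_fraction = lateral_fraction,
                 noise_sd = noise_sd, amplitude_jitter = amplitude_jitter,
                 head_motion = head_motion,
                 excursion_range = excursion_range, beta_range = beta_range,
                 aspect = aspect, bend = bend, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "session_config")
}

rate_interp <- function(rate, rates, endpoints) {
  lo <- min(rates); hi <- max(rates)
  if (hi == lo) return(endpoints[1])
  endpoints[1] + (endpoints[2] - endpoints[1]) * (rate - lo) / (hi - lo)
}

#' Trace a path under an exact speed-curvature power law
#'
#' Reparameterizes a closed figural path so that the instantaneous
#' tangential speed obeys `v = k * kappa^(-beta)` exactly: along arc length
#' `s`, `dt = ds / (k * kappa(s)^(-beta))`. The constant-angular-velocity
#' parameterization of an ellipse is the special case `beta = 1/3`, and
#' `beta = 0` degenerates to uniform traversal.
#'
#' Exactly one of `k_gain` and `cycle_period` must be given; the other is
#' implied (the cycle time of one loop is `integral(kappa^beta ds) / k`).
#'
#' @param path a [figural_path()] (or template name).
#' @param beta power-law exponent, `>= 0`.
#' @param k_gain velocity gain factor, mm/s * mm^(-beta).
#' @param cycle_period time for one full loop, s.
#' @param n_cycles number of loops to trace.
#' @param sample_rate output sampling rate, Hz.
#' @param phase starting parameter on the loop; the default starts at the
#'   inferior extreme so the trial opens with a closing movement.
#' @param sensor channel name for the output recording.
#' @param fine_n internal reparameterization grid size per cycle.
#' @return a [trajectory_recording()] with one planar (z = 0) channel and an
#'   attribute `"truth"` carrying the exact `beta`, `k_gain`,
#'   `cycle_period`, per-sample path parameter `u`, and the times of
#'   principal-axis extremes (`zero_times`, the true zero-velocity movement
#'   delimiters) with alternating direction labels.
#' @export
generate_power_law_path <- function(path, beta, k_gain = NULL,
                                    cycle_period = NULL, n_cycles = 10,
                                    sample_rate = 1250, phase = -pi / 2,
                                    sensor = "TT", fine_n = 8192) {
  if (is.character(path)) path <- figural_path(path)
  stopifnot(inherits(path, "figural_path"))
  if (beta < 0) stop("beta must be >= 0")
  if (is.null(k_gain) == is.null(cycle_period))
    stop("give exactly one of k_gain or cycle_period")
  uf <- phase + seq(0, 2 * pi, length.out = fine_n + 1L)
  g <- path_geometry(path, uf)
  if (beta > 0 && (max(g$kappa) == 0 ||
                   min(g$kappa) < 1e-9 * max(g$kappa)))
    stop("path curvature vanishes somewhere; speed would be unbounded for beta > 0")
  # dt/du for unit gain, integrated by the trapezoidal rule on the fine grid
  dtdu <- g$ds_du * g$kappa^beta
  du <- diff(uf)
  t_unit <- c(0, cumsum((dtdu[-1] + dtdu[-length(dtdu)]) / 2 * du))
  if (is.null(k_gain)) k_gain <- t_unit[length(t_unit)] / cycle_period
  if (k_gain <= 0) stop("k_gain must be positive")
  tf <- t_unit / k_gain
  t_cycle <- tf[length(tf)]
  u_of_t <- stats::splinefun(tf, uf, method = "hyman")

  n <- max(2L, floor(n_cycles * t_cycle * sample_rate) + 1L)
  t <- (seq_len(n) - 1L) / sample_rate
  tm <- t %% t_cycle
  u <- u_of_t(tm) + 2 * pi * (t %/% t_cycle)
  xy <- path$f(u)
  zc <- if (ncol(xy) >= 3L) xy[, 3] else 0
  ch <- list(cbind(x = xy[, 1], y = xy[, 2], z = zc))
  names(ch) <- sensor
  rec <- trajectory_recording(ch, sample_rate,
                              roles = stats::setNames("tongue_tip", sensor),
                              metadata = list(beta = beta, k_gain = k_gain,
                                              cycle_period = t_cycle))
  # true zero-velocity delimiters: extremes of the principal (y) coordinate.
  # The root grid is offset by a half step so an extreme exactly at the
  # starting phase is detected as an interior sign change.
  mg <- 4096L
  ug <- phase - pi / mg + seq(0, 2 * pi, length.out = mg + 1L)
  dyg <- path$d1(ug)[, 2]
  sg <- sign(dyg)
  idx <- which(sg[-1] * sg[-length(sg)] < 0)
  u_zero <- vapply(idx, function(i) {
    stats::uniroot(function(uu) path$d1(uu)[, 2], c(ug[i], ug[i + 1L]),
                   tol = 1e-12)$root
  }, numeric(1))
  u_zero <- sort(((u_zero - phase) %% (2 * pi)) + phase)
  t_zero_cycle <- vapply(u_zero, function(uz) {
    i <- findInterval(uz, uf)
    i <- min(max(i, 1L), length(uf) - 1L)
    stats::approx(uf[c(i, i + 1L)], tf[c(i, i + 1L)], uz)$y
  }, numeric(1))
  closing_after <- path$d1(u_zero + 1e-5)[, 2] > 0  # next span moves superior
  n_rep <- ceiling(n_cycles) + 1L
  zero_times <- rep(t_zero_cycle, n_rep) + rep(0:(n_rep - 1L),
                                               each = length(t_zero_cycle)) * t_cycle
  dirs <- rep(ifelse(closing_after, "closing", "opening"), n_rep)
  keep <- zero_times <= t[n] + t_cycle / 2
  attr(rec, "truth") <- list(beta = beta, k_gain = k_gain,
                             cycle_period = t_cycle, u = u,
                             zero_times = zero_times[keep],
                             direction_after = dirs[keep])
  rec
}

head_motion_params <- function(hm) {
  if (is.null(hm) || (is.numeric(hm) && all(hm == 0)))
    hm <- list(translation_mm = 0, rotation_deg = 0)
  list(trans_amp = rep_len(hm$translation_mm, 3),
       trans_freq = c(0.19, 0.23, 0.16),
       rot_amp = rep_len(hm$rotation_deg, 3) * pi / 180,
       rot_freq = c(0.13, 0.17, 0.11))
}

#' True rigid head transform of a synthetic trial
#'
#' Reconstructs the rotation matrix and translation applied to all sensors
#' at time `t`, from the parameters stored in a trial's ground truth.
#'
#' @param gt ground-truth entry of one trial from [generate_session()].
#' @param t time, s.
#' @return list with `rotation` (3x3) and `translation` (length 3, mm).
#' @export
true_head_transform <- function(gt, t) {
  p <- gt$head
  ang <- p$rot_amp * sin(2 * pi * p$rot_freq * t + p$rot_phase)
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  list(rotation = Rz %*% Ry %*% Rx,
       translation = p$trans_amp * sin(2 * pi * p$trans_freq * t + p$trans_phase))
}

# fixed head-frame positions (mm) of the three reference sensors
ref_template <- function() {
  rbind(REF_N = c(80, 40, 0),
        REF_L = c(-20, 10, -40),
        REF_R = c(-20, 10, 40))
}

#' Generate a synthetic EMA session with ground truth
#'
#' Produces one [trajectory_recording()] per (sequence, rate, trial) at the
#' configured digitization rate. The tongue sensor traces the figural
#' template under an exact speed-curvature power law at the syllable
#' frequency implied by the metronome rate; a lateral component with the
#' configured RMS fraction makes the trace genuinely three-dimensional;
#' three reference sensors ride on the (rigid) head motion, which also
#' displaces the tongue channel as in a raw recording; i.i.d. Gaussian
#' sensor noise is added last.
#'
#' @param config a [session_config()].
#' @return list with `recordings` (list of recordings, named
#'   `<seq>_<rate>bpm_t<trial>`) and `truth`, a parallel list carrying per
#'   trial the exact law parameters, zero-velocity delimiters, direction
#'   labels and head-motion parameters.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  hmp <- head_motion_params(config$head_motion)
  refs <- ref_template()
  recordings <- list()
  truth <- list()
  for (seqc in config$sequences) {
    sensor <- if (seqc == "ta") "TT" else "TB"
    for (rate in config$rates) {
      extent <- rate_interp(rate, config$rates, config$excursion_range)
      beta <- rate_interp(rate, config$rates, config$beta_range)
      pth <- figural_path(config$shape, extent = extent,
                          aspect = config$aspect, bend = config$bend,
                          lateral = config$lateral_fraction)
      for (trial in seq_len(config$trials_per_rate)) {
        rec <- generate_power_law_path(pth, beta = beta,
                                       cycle_period = 60 / rate,
                                       n_cycles = config$syllables_per_trial,
                                       sample_rate = config$sample_rate,
                                       sensor = sensor)
        tru <- attr(rec, "truth")
        pos <- rec$channels[[1]]
        n <- nrow(pos)
        t <- rec_times(rec)
        # slow multiplicative amplitude envelope: token-to-token size
        # variability around the figural center
        if (config$amplitude_jitter > 0) {
          f_env <- 1 / (3.7 * tru$cycle_period)
          phi_env <- stats::runif(1, 0, 2 * pi)
          env <- 1 + config$amplitude_jitter * sin(2 * pi * f_env * t + phi_env)
          ctr <- colMeans(pos)
          pos <- sweep(sweep(pos, 2, ctr) * env, 2, ctr, `+`)
          # refine true delimiters on the enveloped superior coordinate
          tru$zero_times <- vapply(tru$zero_times, function(zt) {
            win <- which(abs(t - zt) <= tru$cycle_period / 8)
            if (length(win) < 3) return(zt)
            yw <- pos[win, 2]
            t[win[if (stats::median(yw) < pos[which.min(abs(t - zt)), 2])
              which.max(yw) else which.min(yw)]]
          }, numeric(1))
        }
        head <- c(hmp, list(rot_phase = stats::runif(3, 0, 2 * pi),
                            trans_phase = stats::runif(3, 0, 2 * pi)))
        gt1 <- list(sequence = seqc, rate_bpm = rate, trial = trial,
                    sensor = sensor, beta = tru$beta, k_gain = tru$k_gain,
                    cycle_period = tru$cycle_period,
                    zero_times = tru$zero_times,
                    direction_after = tru$direction_after,
                    head = head)
        chans <- c(list(pos),
                   lapply(seq_len(nrow(refs)), function(i)
                     matrix(refs[i, ], n, 3, byrow = TRUE,
                            dimnames = list(NULL, c("x", "y", "z")))))
        names(chans) <- c(sensor, rownames(refs))
        if (any(hmp$trans_amp != 0) || any(hmp$rot_amp != 0)) {
          # vectorized x-y-z Euler rotation, same convention as
          # true_head_transform (R = Rz Ry Rx)
          a1 <- head$rot_amp[1] * sin(2 * pi * head$rot_freq[1] * t + head$rot_phase[1])
          a2 <- head$rot_amp[2] * sin(2 * pi * head$rot_freq[2] * t + head$rot_phase[2])
          a3 <- head$rot_amp[3] * sin(2 * pi * head$rot_freq[3] * t + head$rot_phase[3])
          cx <- cos(a1); sx <- sin(a1); cy <- cos(a2); sy <- sin(a2)
          cz <- cos(a3); sz <- sin(a3)
          tx <- head$trans_amp[1] * sin(2 * pi * head$trans_freq[1] * t + head$trans_phase[1])
          ty <- head$trans_amp[2] * sin(2 * pi * head$trans_freq[2] * t + head$trans_phase[2])
          tz <- head$trans_amp[3] * sin(2 * pi * head$trans_freq[3] * t + head$trans_phase[3])
          chans <- lapply(chans, function(p) {
            px <- p[, 1]; py <- p[, 2]; pz <- p[, 3]
            cbind(
              x = (cz * cy) * px + (cz * sy * sx - sz * cx) * py +
                  (cz * sy * cx + sz * sx) * pz + tx,
              y = (sz * cy) * px + (sz * sy * sx + cz * cx) * py +
                  (sz * sy * cx - cz * sx) * pz + ty,
              z = (-sy) * px + (cy * sx) * py + (cy * cx) * pz + tz)
          })
        }
        if (config$noise_sd > 0)
          chans <- lapply(chans, function(p)
            p + matrix(stats::rnorm(3 * n, sd = config$noise_sd), n, 3))
        id <- sprintf("%s_%03dbpm_t%02d", seqc, rate, trial)
        recordings[[id]] <- trajectory_recording(
          chans, config$sample_rate,
          roles = stats::setNames(c("tongue_tip", "reference", "reference",
                                    "reference"),
                                  names(chans)),
          metadata = list(speaker = "S1", sequence = seqc, rate_bpm = rate,
                          trial = trial))
        truth[[id]] <- gt1
      }
    }
  }
  list(recordings = recordings, truth = truth)
}

#' Generate a one-dimensional control-regime signal
#'
#' Emulates the two candidate control regimes of rhythmic articulation as a
#' 1D principal-axis signal embedded in 3D (along the superior axis).
#' `"fixed-point"` concatenates critically damped point-attractor gestures
#' toward alternating targets, dwelling at each target for the remainder of
#' every half-beat; `"limit-cycle"` is a sustained harmonic oscillation with
#' stable amplitude, whose velocity has isolated zeros only.
#'
#' @param regime `"fixed-point"` or `"limit-cycle"`.
#' @param rate_hz cycle frequency, Hz (one full closing+opening per cycle).
#' @param duration signal length, s; must cover at least 5 cycles.
#' @param amplitude half peak-to-peak excursion, mm.
#' @param sample_rate output rate, Hz.
#' @param movement_fraction (fixed-point only) fraction of each half-beat
#'   spent moving; the rest is dwell at the target.
#' @return a [trajectory_recording()] with a single channel `PC` whose `y`
#'   carries the signal.
#' @export
generate_regime_signal <- function(regime = c("fixed-point", "limit-cycle"),
                                   rate_hz, duration, amplitude = 6,
                                   sample_rate = 1250 / 15,
                                   movement_fraction = 0.35) {
  regime <- match.arg(regime)
  if (duration < 5 / rate_hz)
    stop("duration must cover at least 5 cycles")
  n <- floor(duration * sample_rate) + 1L
  t <- (seq_len(n) - 1L) / sample_rate
  if (regime == "limit-cycle") {
    x <- amplitude * sin(2 * pi * rate_hz * t)
  } else {
    half <- 1 / (2 * rate_hz)
    # settle to ~1% of the step within movement_fraction of a half-beat
    om <- 6.64 / (movement_fraction * half)
    x <- numeric(n)
    x0 <- -amplitude; v0 <- 0
    k <- 0L
    for (i in seq_len(n)) {
      while (t[i] >= (k + 1) * half) {
        tau_end <- half
        target <- if (k %% 2 == 0) amplitude else -amplitude
        d0 <- x0 - target
        x0 <- target + (d0 + (v0 + om * d0) * tau_end) * exp(-om * tau_end)
        v0 <- (v0 - om * (v0 + om * d0) * tau_end) * exp(-om * tau_end)
        k <- k + 1L
      }
      tau <- t[i] - k * half
      target <- if (k %% 2 == 0) amplitude else -amplitude
      d0 <- x0 - target
      x[i] <- target + (d0 + (v0 + om * d0) * tau) * exp(-om * tau)
    }
  }
  trajectory_recording(list(PC = cbind(x = 0, y = x, z = 0)), sample_rate,
                       roles = c(PC = "tongue_tip"),
                       metadata = list(regime = regime, rate_hz = rate_hz))
}
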