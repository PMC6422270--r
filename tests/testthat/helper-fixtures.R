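# shared fixtures, all generated in code

fs_ema <- 1250 / 15   # conditioned sampling rate, Hz

# constant-angular-velocity ellipse recording (exact one-third-law motion)
make_ellipse_recording <- function(a = 5, b = 7.5, f_cycle = 1.5,
                                   duration = 8, fs = fs_ema, z = NULL) {
  t <- seq(0, duration, by = 1 / fs)
  om <- 2 * pi * f_cycle
  zc <- if (is.null(z)) 0 else z(t)
  trajectory_recording(list(TT = cbind(x = a * cos(om * t),
                                       y = b * sin(om * t), z = zc)), fs)
}

# tiny noise-free, head-still session for ground-truth comparisons
quiet_session <- function(rates = 150, syllables = 6, noise = 0, hm = 0,
                          seed = 5, fs = 1250, ...) {
  session_config(rates = rates, trials_per_rate = 1,
                 syllables_per_trial = syllables, noise_sd = noise,
                 amplitude_jitter = 0,
                 head_motion = list(translation_mm = hm, rotation_deg = 0.75 * hm),
                 sample_rate = fs, seed = seed, ...)
}

# condition + spline + segment one recording against its truth
analyze_trial <- function(rec, truth = NULL, cfg = pipeline_config()) {
  cond <- preprocess_recording(rec, cfg)
  sm <- fit_quintic_spline(cond, sensors = setdiff(names(cond$channels),
                                                   rec_sensors(cond, "reference"))[1])
  pm <- principal_motion(sm)
  segs <- segment_movements(pm)
  list(cond = cond, smooth = sm, pm = pm, segments = segs)
}

# rotation matrix about a unit axis (Rodrigues), independent of package code
rot_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
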