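test_that("power-law path on a circle moves at the closed-form constant speed", {
  circ <- figural_path("ellipse", extent = 10, aspect = 1)  # R = 5 mm
  for (beta in c(0, 0.4)) {
    rec <- generate_power_law_path(circ, beta = beta, k_gain = 30,
                                   n_cycles = 2, sample_rate = fs_ema)
    d <- diff(rec$channels$TT[, 1:2])
    speed <- sqrt(rowSums(d^2)) * fs_ema   # finite-difference speed estimate
    v_expect <- 30 * (1 / 5)^(-beta)       # kappa = 1/R constant
    # chord-length estimate carries O((omega dt)^2) discretization error
    expect_equal(mean(speed), v_expect, tolerance = 1e-3)
    expect_lt(stats::sd(speed) / mean(speed), 1e-4)
  }
})

test_that("beta = 1/3 path on an ellipse equals constant-angular-velocity tracing", {
  a <- 7.5; b <- 4.5
  ell <- figural_path("ellipse", extent = 2 * a, aspect = b / a)
  rec <- generate_power_law_path(ell, beta = 1 / 3, cycle_period = 0.8,
                                 n_cycles = 3, sample_rate = fs_ema,
                                 phase = 0)
  t <- rec_times(rec)
  om <- 2 * pi / 0.8
  # constant-angular-velocity parameterization starting at u = 0
  expect_equal(rec$channels$TT[, 1], b * cos(om * t), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rec$channels$TT[, 2], a * sin(om * t), tolerance = 1e-6,
               ignore_attr = TRUE)
  # implied velocity gain factor: k = omega (ab)^(1/3)
  expect_equal(attr(rec, "truth")$k_gain, om * (a * b)^(1 / 3),
               tolerance = 1e-6)
})

test_that("a path with vanishing curvature is rejected for beta > 0", {
  line <- figural_path(list(f = function(u) cbind(x = u, y = 0 * u),
                            d1 = function(u) cbind(x = 1 + 0 * u, y = 0 * u),
                            d2 = function(u) cbind(x = 0 * u, y = 0 * u)))
  expect_error(generate_power_law_path(line, beta = 0.3, k_gain = 10),
               "curvature vanishes")
  expect_error(generate_power_law_path(figural_path(), beta = -0.1, k_gain = 1),
               "beta")
})

test_that("session layout: one recording per rate x trial, rejecting bad rates", {
  cfg <- session_config(syllables_per_trial = 2, trials_per_rate = 4,
                        sample_rate = fs_ema, noise_sd = 0, seed = 1)
  s <- generate_session(cfg)
  expect_length(s$recordings, 8 * 4)      # eight rates, four trials each
  expect_length(s$truth, 8 * 4)
  expect_error(session_config(rates = c(30, 0, -90)), "0, -90")
})

test_that("degenerate settings give a planar, noise-free, head-still recording", {
  cfg <- quiet_session(rates = 150, syllables = 3, fs = fs_ema)
  cfg$lateral_fraction <- 0
  s <- generate_session(cfg)
  rec <- s$recordings[[1]]
  expect_true(all(rec$channels$TT[, "z"] == 0))
  ref <- rec$channels$REF_N
  expect_equal(max(apply(ref, 2, stats::sd)), 0)
})

test_that("identical seeds give identical sessions, different seeds differ", {
  cfg <- quiet_session(rates = 210, syllables = 3, noise = 0.05, hm = 2,
                       fs = fs_ema, seed = 42)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
  cfg$seed <- 43L
  expect_false(identical(generate_session(cfg)$recordings[[1]]$channels$TT,
                         s1$recordings[[1]]$channels$TT))
})

test_that("lateral RMS fraction of the tongue channel matches configuration", {
  for (lf in c(0.05, 0.075, 0.10)) {
    cfg <- quiet_session(rates = 150, syllables = 4, fs = fs_ema)
    cfg$lateral_fraction <- lf
    p <- generate_session(cfg)$recordings[[1]]$channels$TT
    xc <- p[, 1] - mean(p[, 1]); yc <- p[, 2] - mean(p[, 2])
    zc <- p[, 3] - mean(p[, 3])
    ratio <- sqrt(mean(zc^2)) / sqrt(mean(xc^2 + yc^2))
    expect_equal(ratio, lf, tolerance = 0.15)
    expect_gte(ratio, 0.045); expect_lte(ratio, 0.105)
  }
})

test_that("ground-truth delimiters alternate and match the y extremes", {
  s <- generate_session(quiet_session(rates = 150, syllables = 5, fs = fs_ema))
  gt <- s$truth[[1]]
  expect_true(all(diff(gt$zero_times) > 0))
  expect_true(all(gt$direction_after[-1] != head(gt$direction_after, -1)))
  # two movements per syllable cycle
  expect_equal(mean(diff(gt$zero_times)), gt$cycle_period / 2, tolerance = 1e-6)
  # delimiters sit at extremes of the superior coordinate
  y <- s$recordings[[1]]$channels$TT[, 2]
  t <- rec_times(s$recordings[[1]])
  interior <- gt$zero_times[gt$zero_times > 0.05 & gt$zero_times < max(t) - 0.05]
  for (zt in interior[1:4]) {
    i <- which.min(abs(t - zt))
    win <- y[max(1, i - 3):min(length(y), i + 3)]
    expect_true(min(win) == min(range(win)) &&
                  (abs(y[i] - max(win)) < 1e-3 * diff(range(y)) ||
                   abs(y[i] - min(win)) < 1e-3 * diff(range(y))))
  }
})

test_that("regime signals have the advertised dwell structure", {
  fp <- generate_regime_signal("fixed-point", rate_hz = 0.5, duration = 12)
  lc <- generate_regime_signal("limit-cycle", rate_hz = 3, duration = 4)
  vf <- abs(diff(fp$channels$PC[, 2])) * fp$sample_rate
  vl <- abs(diff(lc$channels$PC[, 2])) * lc$sample_rate
  # fixed point: most of the time is near-zero-velocity dwell
  expect_gt(mean(vf < 0.05 * max(vf)), 0.4)
  # limit cycle: velocity zeros are isolated (no runs of > 2 slow samples)
  slow <- vl < 0.02 * max(vl)
  runs <- rle(slow)
  expect_lt(max(c(0, runs$lengths[runs$values])), 3)
  expect_error(generate_regime_signal("limit-cycle", rate_hz = 1, duration = 2),
               "5 cycles")
})
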