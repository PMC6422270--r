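test_that("two-stage decimation: 1250 -> 83.33 Hz, DC exact, passband flat to 1%", {
  t <- seq(0, 4, by = 1 / 1250)
  rec <- trajectory_recording(
    list(S = cbind(x = 7, y = sin(2 * pi * 5 * t), z = -3.2)), 1250)
  d <- decimate_two_stage(rec)
  expect_equal(d$sample_rate, 1250 / 15, tolerance = 1e-12)
  expect_equal(unique(d$channels$S[, 1]), 7)          # DC preserved exactly
  expect_equal(unique(d$channels$S[, 3]), -3.2)
  td <- rec_times(d)
  core <- td > 0.5 & td < 3.5                         # exclude edge regions
  # compare against the analytically resampled sinusoid
  err <- d$channels$S[core, 2] - sin(2 * pi * 5 * td[core])
  expect_lt(max(abs(err)), 0.01)
  expect_error(decimate_two_stage(rec, stages = c(4.5, 3)), "integers")
})

test_that("decimation and filtering are time-invariant away from edges", {
  t <- seq(0, 4, by = 1 / 1250)
  sig <- function(tt) sin(2 * pi * 3 * tt) + 0.3 * cos(2 * pi * 11 * tt)
  r1 <- trajectory_recording(list(S = cbind(x = sig(t), y = 0, z = 0)), 1250)
  r2 <- trajectory_recording(list(S = cbind(x = sig(t + 15 / 1250), y = 0, z = 0)), 1250)
  d1 <- decimate_two_stage(r1); d2 <- decimate_two_stage(r2)
  # shifting the input by 15 raw samples shifts the output by 1 sample
  n <- rec_length(d1)
  core <- 30:(n - 30)
  expect_equal(d1$channels$S[core + 1, 1], d2$channels$S[core, 1],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("zero-delay Butterworth matches the digital squared magnitude response", {
  fs <- fs_ema
  t <- seq(0, 6, by = 1 / fs)
  rec <- trajectory_recording(
    list(S = cbind(x = sin(2 * pi * 40 * t),
                   y = sin(2 * pi * 2 * t) + sin(2 * pi * 40 * t),
                   z = 3.2)), fs)
  f <- lowpass_zero_delay(rec, cutoff = 25, order = 4)
  expect_equal(unique(f$channels$S[, 3]), 3.2)        # DC offset preserved
  # squared magnitude of the digital (bilinear) order-4 Butterworth
  Hsq <- function(freq) 1 / (1 + (tan(pi * freq / fs) / tan(pi * 25 / fs))^8)
  core <- t > 1 & t < 5
  amp40 <- max(abs(f$channels$S[core, 1]))
  expect_lt(abs(amp40 / Hsq(40) - 1), 0.05)
  # 2 Hz component of the composite signal survives within 1%
  comp2 <- f$channels$S[core, 2] - f$channels$S[core, 1]
  expect_equal(max(abs(comp2)), 1, tolerance = 0.01)
  expect_error(lowpass_zero_delay(rec, cutoff = 50), "Nyquist")
})

test_that("Horn's method recovers exact rigid transforms", {
  set.seed(2)
  src <- matrix(rnorm(15, sd = 20), 5, 3)
  expect_equal(estimate_rigid_transform(src, src)$rotation, diag(3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(estimate_rigid_transform(src, src)$translation, rep(0, 3),
               tolerance = 1e-10)
  R <- rot_about(c(0, 1, 0), 30 * pi / 180)
  tgt <- sweep(src %*% t(R), 2, c(1, 2, 3), `+`)
  tr <- estimate_rigid_transform(src, tgt)
  expect_equal(tr$rotation, R, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$translation, c(1, 2, 3), tolerance = 1e-10)
  resid <- apply_rigid_transform(tr, src) - tgt
  expect_lt(sqrt(max(rowSums(resid^2))), 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(tr$rotation), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(estimate_rigid_transform(collinear, collinear), "collinear")
})

test_that("Horn residual under isotropic noise follows the dof-counting law", {
  # with 6 rigid dof absorbed, E[RSS] = sigma^2 (3N - 6)
  set.seed(7)
  N <- 6; sigma <- 0.3
  rss <- replicate(300, {
    src <- matrix(rnorm(3 * N, sd = 15), N, 3)
    R <- rot_about(rnorm(3), runif(1, 0, pi))
    tgt <- sweep(src %*% t(R), 2, rnorm(3), `+`) +
      matrix(rnorm(3 * N, sd = sigma), N, 3)
    tr <- estimate_rigid_transform(src, tgt)
    sum((apply_rigid_transform(tr, src) - tgt)^2)
  })
  expect_equal(mean(rss), sigma^2 * (3 * N - 6), tolerance = 0.1)
})

test_that("head correction restores reference stillness and tongue traces", {
  cfg <- quiet_session(rates = 150, syllables = 4, hm = 2, fs = fs_ema, seed = 9)
  clean_cfg <- cfg; clean_cfg$head_motion <- list(translation_mm = 0, rotation_deg = 0)
  s <- generate_session(cfg)
  s0 <- generate_session(clean_cfg)
  corrected <- correct_head_and_align(
    s$recordings[[1]],
    template = t(vapply(c("REF_N", "REF_L", "REF_R"),
                        function(nm) s0$recordings[[1]]$channels[[nm]][1, ],
                        numeric(3))))
  for (nm in c("REF_N", "REF_L", "REF_R"))
    expect_lt(max(apply(corrected$channels[[nm]], 2, stats::sd)), 1e-9)
  expect_equal(corrected$channels$TT, s0$recordings[[1]]$channels$TT,
               tolerance = 1e-8, ignore_attr = TRUE)
  # rigidity: inter-sensor distances preserved frame by frame
  d_raw <- sqrt(rowSums((s$recordings[[1]]$channels$REF_N -
                           s$recordings[[1]]$channels$TT)^2))
  d_cor <- sqrt(rowSums((corrected$channels$REF_N - corrected$channels$TT)^2))
  expect_lt(max(abs(d_raw - d_cor)), 1e-9)
})

test_that("head correction is exact identity without head motion", {
  s <- generate_session(quiet_session(rates = 300, syllables = 3, fs = fs_ema))
  rec <- s$recordings[[1]]
  out <- correct_head_and_align(rec)
  expect_equal(out$channels$TT, rec$channels$TT, tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- rec
  bad$channels <- rec$channels["TT"]
  bad$roles <- rec$roles["TT"]
  expect_error(correct_head_and_align(bad), "reference")
})
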