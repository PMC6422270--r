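test_that("curvature of circle and helix matches closed forms", {
  fs <- fs_ema
  t <- seq(0, 8, by = 1 / fs)
  # circle radius 5 at 0.4 Hz
  om <- 2 * pi * 0.4
  circ <- trajectory_recording(
    list(S = cbind(x = 5 * cos(om * t), y = 5 * sin(om * t), z = 0)), fs)
  sc <- speed_and_curvature(fit_quintic_spline(circ), seq(1, 7, by = 0.05))
  expect_equal(sc$kappa, rep(1 / 5, nrow(sc)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(sc$v, rep(5 * om, nrow(sc)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # helix (a cos wt, a sin wt, c w t): kappa = a / (a^2 + c^2)
  a <- 4; cc <- 2; w <- 2
  helix <- trajectory_recording(
    list(S = cbind(x = a * cos(w * t), y = a * sin(w * t), z = cc * w * t)), fs)
  sh <- speed_and_curvature(fit_quintic_spline(helix), seq(1, 7, by = 0.05))
  expect_equal(sh$kappa, rep(a / (a^2 + cc^2), nrow(sh)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_false(any(sc$degenerate))
})

test_that("straight-line motion is flagged degenerate with zero curvature", {
  fs <- fs_ema
  t <- seq(0, 2, by = 1 / fs)
  slow <- trajectory_recording(
    list(S = cbind(x = 1e-5 * t, y = 0, z = 0)), fs)
  sc <- speed_and_curvature(fit_quintic_spline(slow), seq(0.5, 1.5, by = 0.05))
  expect_true(all(sc$degenerate))
  line <- trajectory_recording(list(S = cbind(x = 3 * t, y = 2 * t, z = t)), fs)
  sl <- speed_and_curvature(fit_quintic_spline(line), seq(0.5, 1.5, by = 0.05))
  expect_lt(max(sl$kappa), 1e-8)
  expect_error(speed_and_curvature(fit_quintic_spline(line), 5), "outside")
})

test_that("parabola vertex curvature in the mid-sagittal plane equals 2a", {
  fs <- 500
  a <- 0.3; v0 <- 4
  t <- seq(-1, 1, by = 1 / fs)
  rec <- trajectory_recording(
    list(S = cbind(x = v0 * t, y = a * (v0 * t)^2, z = 0)), fs, t0 = -1)
  sc <- speed_and_curvature(fit_quintic_spline(rec), 0)
  expect_equal(sc$kappa2d, 2 * a, tolerance = 1e-5)
  expect_equal(sc$kappa, sc$kappa2d, tolerance = 1e-10)
})

test_that("subsampling yields n strictly interior samples per movement", {
  rec <- make_ellipse_recording(duration = 4)
  pm <- principal_motion(fit_quintic_spline(rec))
  segs <- segment_movements(pm)
  sam <- subsample_movements(segs, pm$smooth, n = 5)
  expect_equal(nrow(sam), 5 * nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s_i <- sam[sam$movement == segs$movement[i], ]
    expect_true(all(s_i$t > segs$t_zero_on[i] & s_i$t < segs$t_zero_off[i]))
    expect_true(all(s_i$v > 0))
  }
  # circle-arc movement: all kappa equal 1/R
  circ <- make_ellipse_recording(a = 6, b = 6, duration = 4)
  pmc <- principal_motion(fit_quintic_spline(circ))
  sc <- subsample_movements(segment_movements(pmc), pmc$smooth)
  expect_equal(sc$kappa, rep(1 / 6, nrow(sc)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("exact-law samples recover beta and k with r2 = 1", {
  kappa <- 10^seq(-1.2, 0.8, length.out = 40)
  samples <- data.frame(v = 30 * kappa^(-0.4), kappa = kappa,
                        degenerate = FALSE)
  fit <- fit_power_law(samples)
  expect_equal(fit$beta, 0.4, tolerance = 1e-9)
  expect_equal(fit$k_gain, 30, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$k_gain, 10^fit$log_k, tolerance = 1e-12)
  expect_error(fit_power_law(samples[samples$kappa > 10, ]), "at least 3")
})

test_that("ellipse at constant angular velocity recovers the one-third law", {
  a <- 5; b <- 7.5; f_cyc <- 1.5
  rec <- make_ellipse_recording(a = a, b = b, f_cycle = f_cyc, duration = 8)
  pm <- principal_motion(fit_quintic_spline(rec))
  segs <- segment_movements(pm)
  fit <- fit_power_law(subsample_movements(segs, pm$smooth))
  om <- 2 * pi * f_cyc
  expect_equal(fit$beta, 1 / 3, tolerance = 1e-4)
  expect_equal(fit$k_gain, om * (a * b)^(1 / 3), tolerance = 1e-4 * om)
  expect_gt(fit$r2, 0.9999)
})

test_that("beta is scale-invariant; v and kappa transform equivariantly", {
  rec <- make_ellipse_recording(duration = 6)
  pm <- principal_motion(fit_quintic_spline(rec))
  segs <- segment_movements(pm)
  sam1 <- subsample_movements(segs, pm$smooth)
  s <- 2.5
  rec2 <- rec
  rec2$channels$TT <- rec$channels$TT * s
  pm2 <- principal_motion(fit_quintic_spline(rec2))
  sam2 <- subsample_movements(segment_movements(pm2), pm2$smooth)
  m <- min(nrow(sam1), nrow(sam2))
  expect_equal(sam2$v[1:m], s * sam1$v[1:m], tolerance = 1e-6)
  expect_equal(sam2$kappa[1:m], sam1$kappa[1:m] / s, tolerance = 1e-6)
  f1 <- fit_power_law(sam1); f2 <- fit_power_law(sam2)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  # gain transforms as s^(1 - beta) for a spatial scale s:
  # v' = s v = s k kappa^(-b) = k s^(1-b) (kappa/s)^(-b)
  expect_equal(f2$k_gain / f1$k_gain, s^(1 - f1$beta), tolerance = 1e-4)
})

test_that("log-base choice does not affect beta or r2", {
  kappa <- 10^seq(-1, 1, length.out = 30)
  set.seed(8)
  v <- 20 * kappa^(-0.35) * exp(rnorm(30, sd = 0.05))
  fit10 <- fit_power_law(data.frame(v = v, kappa = kappa, degenerate = FALSE))
  ln_fit <- stats::lm(log(v) ~ log(kappa))
  expect_equal(fit10$beta, -unname(coef(ln_fit)[2]), tolerance = 1e-12)
  expect_equal(fit10$r2, summary(ln_fit)$r.squared, tolerance = 1e-12)
  expect_equal(fit10$k_gain, exp(unname(coef(ln_fit)[1])), tolerance = 1e-9)
})

test_that("pooling strata with different slopes lowers r2 (superposition artifact)", {
  # same curvature range, disjoint speed ranges (different gains)
  k1 <- 10^seq(-1, 1, length.out = 25)
  k2 <- k1
  set.seed(9)
  s1 <- data.frame(v = 15 * k1^(-0.33) * exp(rnorm(25, sd = 0.02)),
                   kappa = k1, degenerate = FALSE)
  s2 <- data.frame(v = 300 * k2^(-0.46) * exp(rnorm(25, sd = 0.02)),
                   kappa = k2, degenerate = FALSE)
  f1 <- fit_power_law(s1); f2 <- fit_power_law(s2)
  fp <- fit_power_law(rbind(s1, s2))
  expect_lt(fp$r2, min(f1$r2, f2$r2))
  expect_false(fp$beta > max(f1$beta, f2$beta) || fp$beta < min(f1$beta, f2$beta))
})

test_that("stratified tables report fits per stratum and n/a for empty cells", {
  kappa <- 10^seq(-1, 1, length.out = 20)
  mk <- function(beta, k, seqc, dir, rate)
    data.frame(v = k * kappa^(-beta), kappa = kappa, kappa2d = kappa,
               v2d = k * kappa^(-beta), degenerate = FALSE,
               sequence = seqc, direction = dir, rate_bpm = rate)
  sam <- rbind(mk(0.45, 20, "ta", "closing", 30),
               mk(0.40, 30, "ta", "opening", 30),
               mk(0.35, 50, "ta", "closing", 300),
               mk(0.33, 60, "ta", "opening", 300)[1:2, ])  # too few samples
  tab <- rate_direction_tables(sam)
  expect_equal(nrow(tab), 4)
  full <- tab[!(tab$direction == "opening" & tab$rate_bpm == 300), ]
  expect_equal(sort(full$beta), sort(c(0.45, 0.40, 0.35)), tolerance = 1e-9)
  expect_true(is.na(tab$beta[tab$direction == "opening" & tab$rate_bpm == 300]))
})

test_that("planar trajectories give identical 2D and 3D analyses", {
  rec <- make_ellipse_recording(duration = 5)
  pm <- principal_motion(fit_quintic_spline(rec))
  sam <- subsample_movements(segment_movements(pm), pm$smooth)
  sam$sequence <- "ta"; sam$rate_bpm <- 150
  cmp <- project_midsagittal(sam)
  expect_equal(cmp$beta_2d, cmp$beta_3d, tolerance = 1e-10)
  expect_equal(cmp$r2_2d, cmp$r2_3d, tolerance = 1e-10)
})

test_that("a lateral component weakens the mid-sagittal 2D fit relative to 3D", {
  s <- generate_session(quiet_session(rates = c(90, 300), syllables = 6,
                                      fs = fs_ema))
  sam <- NULL
  for (id in names(s$recordings)) {
    tr <- analyze_trial(s$recordings[[id]])
    segs <- filter_targeted(tr$segments, truth = s$truth[[id]])
    x <- subsample_movements(segs, tr$smooth)
    x$direction <- segs$direction[match(x$movement, segs$movement)]
    x$sequence <- "ta"
    x$rate_bpm <- s$truth[[id]]$rate_bpm
    sam <- rbind(sam, x)
  }
  cmp <- project_midsagittal(sam)
  expect_gt(mean(cmp$r2_diff), 0)   # 3D beats 2D on average across strata
})
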