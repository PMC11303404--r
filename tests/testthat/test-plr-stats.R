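test_that("epoching cuts -2..+18 s windows and drops overruns", {
  fs <- 31
  x <- rnorm(31 * 60)
  ep <- epoch_events(x, 20, frame_rate_hz = fs)
  expect_equal(ncol(ep$data), round(20 * fs))   # 620 samples
  expect_equal(nrow(ep$data), 1)
  expect_equal(range(ep$t_s), c(-2, 18 - 1 / fs))

  # early onset underruns the window: trial dropped with a warning
  expect_warning(ep2 <- epoch_events(x, c(1, 20), frame_rate_hz = fs), "dropped")
  expect_equal(nrow(ep2$data), 1)
  expect_equal(ep2$onsets_used, 20)

  # periodic trace sampled at its period gives identical rows
  per <- rep(sin(2 * pi * (0:(10 * fs - 1)) / (10 * fs)), 8)
  ep3 <- epoch_events(per, c(20, 30, 40), window_s = c(-2, 8), frame_rate_hz = fs)
  expect_equal(ep3$data[1, ], ep3$data[2, ])
  expect_equal(ep3$data[2, ], ep3$data[3, ])
})

test_that("average response returns the pointwise mean and SEM", {
  ep <- structure(list(data = rbind(c(1, 2, 3), c(3, 2, 1)),
                       t_s = c(-1, 0, 1), source_roi = "x", frame_rate_hz = 1),
                  class = "epoch_matrix")
  avg <- average_response(ep)
  expect_equal(avg$mean, c(2, 2, 2))
  expect_equal(avg$sem, apply(ep$data, 2, sd) / sqrt(2))

  # opposite rows average to zero
  ep$data <- rbind(c(1, -2, 3), -c(1, -2, 3))
  expect_equal(average_response(ep)$mean, c(0, 0, 0))

  # single row: SEM defined as zero
  ep$data <- matrix(c(5, 6, 7), 1)
  avg1 <- average_response(ep)
  expect_equal(avg1$mean, c(5, 6, 7))
  expect_equal(avg1$sem, c(0, 0, 0))

  ep$data <- ep$data[0, , drop = FALSE]
  expect_error(average_response(ep), "no trials")

  # epoch/average linearity
  fs <- 8
  x <- rnorm(fs * 60); y <- rnorm(fs * 60)
  ons <- c(10, 25, 40)
  mx <- average_response(epoch_events(x, ons, c(-2, 8), fs))$mean
  my <- average_response(epoch_events(y, ons, c(-2, 8), fs))$mean
  mxy <- average_response(epoch_events(x + y, ons, c(-2, 8), fs))$mean
  expect_equal(mxy, mx + my, tolerance = 1e-12)
})

test_that("robust-PLR test calibrates correctly under null and signal", {
  fs <- 31
  kin <- plr_kinetics()
  sch <- stimulus_schedule(seq(10, by = 20, length.out = 9), 2, 200)
  template <- simulate_darkness_trace(
    simulate_plr_diameter(sch, kin, fs), "closed_eye", noise_sd_trace = 0)

  # constant epochs: not robust, p = 1
  const_ep <- epoch_events(rep(0.5, fs * 120), c(10, 40, 70), frame_rate_hz = fs)
  res0 <- robust_plr_test(const_ep)
  expect_false(res0$is_robust)
  expect_equal(res0$p_value, 1)

  expect_error(robust_plr_test(epoch_events(rep(0.5, fs * 60), c(10, 20),
                                            frame_rate_hz = fs)), "3 trials")

  # type-I error near 0.05 on pure-noise epochs (scaled-down replicate count)
  set.seed(31)
  n_null <- 300
  fp <- mean(replicate(n_null, {
    tr <- 0.35 + rnorm(length(template$values), 0, 0.002)
    robust_plr_test(epoch_events(tr, sch$onsets_s, frame_rate_hz = fs))$p_value < 0.05
  }))
  ci <- qbinom(c(0.025, 0.975), n_null, 0.05) / n_null
  expect_gte(fp, ci[1])
  expect_lte(fp, ci[2])

  # power ~1 at the default SNR
  set.seed(32)
  pw <- mean(replicate(50, {
    tr <- template$values + rnorm(length(template$values), 0, 0.002)
    robust_plr_test(epoch_events(tr, sch$onsets_s, frame_rate_hz = fs))$is_robust
  }))
  expect_gte(pw, 0.95)

  # affine invariance of the t statistic
  tr <- template$values + rnorm(length(template$values), 0, 0.002)
  r1 <- robust_plr_test(epoch_events(tr, sch$onsets_s, frame_rate_hz = fs))
  r2 <- robust_plr_test(epoch_events(3 * tr + 0.1, sch$onsets_s, frame_rate_hz = fs))
  expect_equal(r1$t_stat, r2$t_stat, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("trace correlation and the Fisher group test follow closed forms", {
  a <- sin(seq(0, 6, length.out = 100))
  expect_equal(trace_correlation(a, a)[c("r", "r2")], list(r = 1, r2 = 1))
  expect_equal(trace_correlation(a, -a)$r, -1)
  set.seed(3)
  b <- 2 * a + 1 + rnorm(100, 0, 0.02)
  expect_gt(trace_correlation(a, b)$r, 0.99)
  expect_error(trace_correlation(a, rep(1, 100)), "variance")
  expect_error(trace_correlation(a, a[1:50]), "length")

  expect_equal(atanh(0.57), 0.6475, tolerance = 1e-4)
  g0 <- fisher_group_test(rep(0, 10))
  expect_equal(g0$t_stat, 0)
  expect_equal(g0$p_value, 1)
  expect_error(fisher_group_test(c(0.5, 1, 0.3)), "infinite")
  expect_error(fisher_group_test(c(0.5, 0.2)), "n >= 3")

  # power at n = 40 with genuine concordance (scaled-down replicate count)
  set.seed(13)
  hits <- mean(replicate(50, {
    rs <- tanh(rnorm(40, atanh(0.57), 0.4))
    fisher_group_test(rs)$p_value < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("mean absolute error matches a brute-force oracle", {
  expect_equal(mean_absolute_error(1:5, 1:5), 0)
  expect_equal(mean_absolute_error(rep(1, 7), rep(0.6, 7)), 0.4)
  set.seed(17)
  a <- rnorm(200); b <- rnorm(200)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_lt(abs(mean_absolute_error(a, b) - acc / 200), 1e-12)
  expect_error(mean_absolute_error(1:3, 1:4), "mismatch")
})

test_that("measured constriction amplitude tracks truth across amplitudes", {
  # end-to-end at trace level: simulate, preprocess, epoch, calibrate back
  fs <- 31
  sch <- stimulus_schedule(seq(10, by = 20, length.out = 5), 2, 120)
  for (A in c(0.5, 1, 1.5)) {
    kin <- plr_kinetics(constriction_amplitude_mm = A)
    tru <- simulate_plr_diameter(sch, kin, fs)
    set.seed(round(100 * A))
    dk <- simulate_darkness_trace(tru, "closed_eye", noise_sd_trace = 0.002)
    # blink transients as in a real session: the mean + 1 SD blink rule
    # presumes blinks dominate the trace variance
    for (b in c(25, 60, 105)) {
      idx <- which(dk$t_s >= b & dk$t_s < b + 0.2)
      dk$values[idx] <- pmax(dk$values[idx] - 0.3, 0)
    }
    pp <- preprocess_trace(dk)
    cal <- calibrate_plr_session(pp$trace, tru$diameter_mm, sch$onsets_s)
    ep <- epoch_events(pp$trace, sch$onsets_s)
    avg <- baseline_normalize(colMeans(ep$data), ep$t_s)
    # amplitude read as the constriction-window (1.5-2.5 s) depth below
    # baseline -- a windowed mean is insensitive to the 1 Hz smoothing that
    # attenuates the instantaneous minimum
    win <- ep$t_s >= 1.5 & ep$t_s < 2.5
    cald <- apply_calibration(avg, cal$calib) - apply_calibration(0 * avg, cal$calib)
    measured <- -mean(cald[win])
    ept <- epoch_events(tru$diameter_mm, sch$onsets_s, frame_rate_hz = fs)
    avt <- baseline_normalize(colMeans(ept$data), ept$t_s)
    true_amp <- -mean(avt[win])
    expect_lt(abs(measured - true_amp) / true_amp, 0.15)
  }
})
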