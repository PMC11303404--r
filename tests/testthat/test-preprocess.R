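test_that("blink detection flags exactly the mean + 1 SD exceedances", {
  expect_length(detect_blinks(rep(0.4, 100)), 0)

  set.seed(5)
  x <- rnorm(1e5)
  frac <- length(detect_blinks(x)) / length(x)
  expect_lt(abs(frac - pnorm(-1)), 0.01)   # P(Z > 1) tail mass

  tr <- rep(0.3, 500); tr[c(100:102, 300:301)] <- 0.9
  expect_equal(detect_blinks(tr), c(100:102, 300:301))
  expect_error(detect_blinks(0.5), "length")
})

test_that("blink duration is read at 95% relative height of the mean profile", {
  fs <- 31; n <- 2000
  # identical rectangular blinks: width recovered within one frame
  tr <- rep(0.3, n)
  for (b in c(300, 900, 1500)) tr[b:(b + round(0.3 * fs) - 1)] <- 0.8
  d <- estimate_blink_duration(tr, detect_blinks(tr), fs)
  expect_lt(abs(d - 0.3), 1 / fs + 1e-9)

  # two identical blinks estimate like one (averaging is idempotent)
  tr1 <- rep(0.3, n); tr1[900:(900 + 8)] <- 0.8
  tr2 <- tr1; tr2[300:(300 + 8)] <- 0.8
  expect_equal(estimate_blink_duration(tr1, detect_blinks(tr1), fs),
               estimate_blink_duration(tr2, detect_blinks(tr2), fs))

  # triangular blink: 95% relative height cuts ~5% of the base
  base_w <- 31
  tr3 <- rep(0.3, n)
  tr3[1000:(1000 + base_w - 1)] <- 0.3 + 0.5 * (1 - abs(seq(-1, 1, length.out = base_w)))
  d3 <- estimate_blink_duration(tr3, detect_blinks(tr3), fs)
  expect_lt(d3, 0.05 * base_w / fs + 2 / fs)

  expect_error(estimate_blink_duration(rep(0.3, 100), integer(0), fs), "skip")
})

test_that("blink removal interpolates linearly and is idempotent", {
  fs <- 31
  # blink-free trace unchanged
  tr <- sin(seq(0, 4, length.out = 200))
  expect_identical(remove_blinks(tr, integer(0), 0.2, fs), tr)

  # flat trace with a spike comes back exactly flat
  fl <- rep(0.2, 300); fl[150:153] <- 0.9
  out <- remove_blinks(fl, 150:153, 0.2, fs)
  expect_equal(out, rep(0.2, 300))

  # a ramp with a spike is restored exactly (line through the endpoints)
  rmp <- seq(0, 1, length.out = 300)
  sp <- rmp; sp[100:104] <- 0.9
  out2 <- remove_blinks(sp, 100:104, 0.2, fs)
  expect_equal(out2, rmp, tolerance = 1e-12)

  # idempotence on its own output
  expect_equal(remove_blinks(out2, 100:104, 0.2, fs), out2)

  # boundary blink warns and extends the nearest value
  expect_warning(remove_blinks(fl, 1:3, 0.2, fs), "boundary")
})

test_that("zero-phase low-pass preserves DC, kills 5 Hz, adds no lag", {
  fs <- 31
  expect_lt(max(abs(lowpass_zero_phase(rep(0.37, 400), 1, fs) - 0.37)), 1e-9)

  # steady-state (interior) attenuation of a 5 Hz tone; filtfilt-style
  # edge effects on a pure off-phase tone are excluded, as in reference
  # implementations
  t <- (0:799) / fs
  hi <- sin(2 * pi * 5 * t)
  out <- lowpass_zero_phase(hi, 1, fs)
  expect_lt(max(abs(out[100:700])), 0.05)

  # zero phase: cross-correlation with the input peaks at lag 0
  set.seed(9)
  x <- as.numeric(stats::filter(rnorm(600), rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  y <- lowpass_zero_phase(x, 2, fs)
  cc <- stats::ccf(x, y, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  expect_error(lowpass_zero_phase(x, 16, fs), "Nyquist")
})

test_that("baseline normalization zeroes the pre-stimulus window", {
  t_s <- seq(-2, 18, by = 1 / 31)
  const <- rep(0.7, length(t_s))
  expect_equal(baseline_normalize(const, t_s), rep(0, length(t_s)))

  x <- 0.4 + 0.3 * sin(t_s)
  out <- baseline_normalize(x, t_s)
  expect_equal(mean(out[t_s >= -2 & t_s < 0]), 0, tolerance = 1e-12)
  expect_equal(out, x - mean(x[t_s >= -2 & t_s < 0]))
  expect_error(baseline_normalize(x, t_s, c(-5, -3)), "outside")
})

test_that("filtering and baseline normalization commute (both linear)", {
  set.seed(11)
  t_s <- seq(-2, 18, by = 1 / 31)
  x <- 0.5 + cumsum(rnorm(length(t_s), 0, 0.01))
  a <- baseline_normalize(lowpass_zero_phase(x, 1, 31), t_s)
  b <- lowpass_zero_phase(baseline_normalize(x, t_s), 1, 31)
  # both operators are linear; they differ only by how much smoothing
  # changes the baseline-window mean itself
  expect_lt(max(abs(a - b)), 1e-3)
})

test_that("full preprocessing recovers the blink-free trace", {
  fx <- blinky_trace(21)
  pp <- preprocess_trace(fx$dirty)

  # every injected blink peak flagged
  hits <- vapply(fx$blink_times, function(b) {
    idx <- which(fx$clean$t_s >= b & fx$clean$t_s < b + 0.2)
    any(idx %in% pp$log$flagged_idx)
  }, TRUE)
  expect_true(all(hits))

  # cleaned + filtered trace close to the filtered blink-free truth
  ref <- lowpass_zero_phase(fx$clean$values, 1, 31)
  amp <- diff(range(darkness_from_diameter(c(4, 5))))
  expect_lt(rmse(pp$trace$values, ref), 0.1 * amp)

  # the synthetic PLR epoch reaches its constriction depth after baseline
  # subtraction (kinetic truth propagates through the pipeline)
  ep <- epoch_events(pp$trace, fx$schedule$onsets_s)
  avg <- baseline_normalize(colMeans(ep$data), ep$t_s)
  darkness_amp <- diff(darkness_from_diameter(c(5, 4)))
  expect_lt(abs(min(avg) - (-abs(darkness_amp))) / abs(darkness_amp), 0.15)
})
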