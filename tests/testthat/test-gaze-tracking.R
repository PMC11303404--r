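test_that("pupil centre from boundary points is the coordinate mean", {
  th <- 2 * pi * (0:7) / 8
  oct <- cbind(10 + 3 * cos(th), 20 + 3 * sin(th))
  expect_equal(pupil_center_from_boundary(oct), c(10, 20), tolerance = 1e-12)

  same <- matrix(rep(c(4.2, -1.3), each = 8), 8)
  expect_equal(pupil_center_from_boundary(same), c(4.2, -1.3))

  set.seed(8)
  pts <- matrix(rnorm(16), 8)
  acc <- c(0, 0)
  for (i in 1:8) acc <- acc + pts[i, ]
  expect_lt(max(abs(pupil_center_from_boundary(pts) - acc / 8)), 1e-12)
  expect_error(pupil_center_from_boundary(pts[1:7, ]), "8 boundary")
})

test_that("relative positions use a median origin robust to outliers", {
  centers <- cbind(x = rep(10, 20), y = rep(5, 20))
  rel <- relative_positions(centers, 1:10, 5)
  expect_equal(unname(rel$origin_px), c(10, 5))
  expect_true(all(rel$rel_mm == 0))

  # one outlier during central fixation leaves the median origin unchanged
  centers2 <- centers; centers2[3, ] <- c(50, 50)
  rel2 <- relative_positions(centers2, 1:10, 5)
  expect_equal(unname(rel2$origin_px), c(10, 5))
  expect_error(relative_positions(centers, integer(0), 5), "origin undefined")
})

test_that("target reference angles follow the arctangent geometry", {
  geo <- setup_geometry(screen_distance_cm = 50)
  ang <- target_reference_angles(geo)
  ctr <- ang[ang$dx_cm == 0 & ang$dy_cm == 0, ]
  expect_equal(c(ctr$theta_x_dva, ctr$theta_y_dva), c(0, 0))

  # 10 cm at 50 cm: atan(0.2) in degrees, to 1e-9
  right <- ang[ang$dx_cm == 10 & ang$dy_cm == 0, ]
  expect_equal(right$theta_x_dva, atan(0.2) * 180 / pi, tolerance = 1e-9)
  expect_equal(right$theta_x_dva, 11.309932474, tolerance = 1e-9)

  # mirrored offsets give mirrored angles
  left <- ang[ang$dx_cm == -10 & ang$dy_cm == 0, ]
  expect_equal(left$theta_x_dva, -right$theta_x_dva)
})

test_that("the DVA ratio fit is proportional and scale-consistent", {
  rel <- cbind(c(-2, 0, 2, -2, 2), c(-1, 0, 1, 1, -1))
  ang <- cbind(0.8 * rel[, 1], 1.1 * rel[, 2])
  ratio <- fit_dva_ratio(rel, ang)
  expect_equal(unname(ratio), c(0.8, 1.1), tolerance = 1e-12)

  # doubling px_per_mm halves rel_mm and doubles the ratio; DVA invariant
  ratio2 <- fit_dva_ratio(rel / 2, ang)
  expect_equal(unname(ratio2), 2 * unname(ratio))
  expect_equal(rel[, 1] * ratio[1], (rel[, 1] / 2) * ratio2[1])

  expect_error(fit_dva_ratio(cbind(0 * rel[, 1], rel[, 2]), ang), "no spread")
})

test_that("gaze error is a per-axis MAE with alignment checks", {
  a <- cbind(1:5, 6:10)
  expect_equal(unname(gaze_error(a, a)), c(0, 0))
  b <- a; b[, 1] <- b[, 1] + 2
  expect_equal(unname(gaze_error(a, b)), c(2, 0))
  expect_error(gaze_error(a, a[1:3, ]), "misaligned")
})

test_that("surrogate test separates tracked from shuffled traces", {
  set.seed(91)
  n <- 40 * 8   # 40 s at 8 Hz
  sig <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))

  # identical traces attain the minimal p
  s0 <- surrogate_significance(sig, sig, segment_len_s = 5, n_shuffles = 99,
                               seed = 4, frame_rate_hz = 8)
  expect_equal(s0$p, 1 / 100)
  expect_equal(s0$real_mae, 0)

  # p is (super-)uniform when closed is independent of open
  ps <- vapply(1:120, function(k) {
    x <- matrix(rnorm(2 * 64), ncol = 2)
    y <- matrix(rnorm(2 * 64), ncol = 2)
    surrogate_significance(x, y, segment_len_s = 1, n_shuffles = 49,
                           seed = k, frame_rate_hz = 8)$p
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_gte(mean(ps <= 0.05) , 0)     # sanity: no crash path
  expect_lte(mean(ps <= 0.05), 0.12)   # level is controlled

  expect_error(surrogate_significance(sig[1:10, ], sig[1:10, ], 5, 10, 1, 8),
               "fewer than 2")
})

test_that("the gaze pipeline recovers target angles and beats the surrogate", {
  sess <- small_gaze_session(5, noise = FALSE)
  res <- analyze_gaze_session(sess, n_shuffles = 500, seed = 2)
  kf <- res$frames_used
  tru <- cbind(sess$truth$theta_x_dva, sess$truth$theta_y_dva)

  # noiseless recovery within 0.5 degrees, both eyes
  expect_lt(max(abs(res$dva_open[kf, ] - tru[kf, ])), 0.5)
  expect_lt(max(abs(res$dva_closed[kf, ] - tru[kf, ])), 0.5)

  # positive per-axis ratios (invariant) and sub-mm agreement
  expect_gt(res$calibration$dva_per_mm_x, 0)
  expect_gt(res$calibration$dva_per_mm_y, 0)
  expect_lt(max(res$mae_mm), 0.15)
  # real alignment beats essentially every segment shuffle
  expect_lt(res$surrogate$p, 0.02)

  # error grows monotonically-in-trend with lid noise: compare extremes
  noisy <- small_gaze_session(5, noise = TRUE)
  noisy$config$eyelid$noise_sd <- 0.05
  noisy$closed$frames <- pmin(pmax(noisy$closed$frames +
    array(rnorm(length(noisy$closed$frames), 0, 0.05),
          dim(noisy$closed$frames)), 0), 1)
  res_noisy <- analyze_gaze_session(noisy, n_shuffles = 99, seed = 2)
  expect_gt(mean(res_noisy$mae_dva), mean(res$mae_dva))
})

test_that("DVA output is invariant to the px_per_mm convention", {
  # rescaling the pixel size rescales rel_mm and the fitted ratio inversely
  centers <- cbind(c(rep(0, 10), rep(4, 10), rep(-4, 10)),
                   c(rep(0, 10), rep(2, 10), rep(-2, 10))) + 30
  for (ppm in c(2, 4)) {
    rel <- relative_positions(centers, 1:10, ppm)
    med <- rbind(colMeans(rel$rel_mm[11:20, ]), c(0, 0), colMeans(rel$rel_mm[21:30, ]))
    ang <- cbind(c(5, 0, -5), c(3, 0, -3))
    ratio <- fit_dva_ratio(med, ang)
    dva <- sweep(rel$rel_mm, 2, ratio, `*`)
    if (ppm == 2) dva_ref <- dva else expect_equal(dva, dva_ref, tolerance = 1e-9)
  }
})
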