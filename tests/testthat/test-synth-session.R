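test_that("PLR diameter trace follows the kinetic contract", {
  kin <- plr_kinetics()
  fs <- 31

  # no stimulus, no response
  empty <- simulate_plr_diameter(stimulus_schedule(numeric(0), 2, 30), kin, fs)
  expect_equal(empty$diameter_mm, rep(kin$baseline_diameter_mm, length(empty$t_s)))

  # single onset: global minimum location and depth (closed-form target:
  # baseline - A * (1 - exp(-stim/tau_c)))
  one <- simulate_plr_diameter(stimulus_schedule(10, 2, 60), kin, fs)
  dmin <- min(one$diameter_mm)
  imin <- which.min(one$diameter_mm)
  expect_lt(abs(dmin - (5 - 1)) / 1, 0.01)
  expect_gt(one$t_s[imin], 10)
  expect_lt(one$t_s[imin], 10 + 2 + 3 * kin$redilation_tau_s)
  expect_true(all(one$diameter_mm >= kin$baseline_diameter_mm -
                    kin$constriction_amplitude_mm))
  # baseline before first onset + latency
  expect_equal(one$diameter_mm[one$t_s < 10 + kin$latency_s],
               rep(5, sum(one$t_s < 10 + kin$latency_s)))

  # the full protocol: 10 stimuli, 240 s, one local minimum per trial
  full <- simulate_plr_diameter(default_plr_schedule(), kin, fs)
  expect_length(full$t_s, 7440)
  d <- full$diameter_mm
  expect_equal(sum(diff(sign(diff(d))) > 0), 10)

  # onsets too close for the kinetics to decay
  expect_error(simulate_plr_diameter(stimulus_schedule(c(10, 15), 2, 60), kin, fs),
               "too close")
})

test_that("gaze path timing and symmetry match the fixation protocol", {
  geo <- setup_geometry()
  tr <- simulate_gaze_path(geo, dwell_s = 5, baseline_s = 15, repeats = 2,
                           frame_rate_hz = 31, padding_s = 10)
  # 15 s baseline + 8 targets x 5 s x 2 repeats + 10 s padding = 105 s
  expect_length(tr$t_s, n_frames(105, 31))
  expect_equal(sum(tr$is_target_display) / 31, 80, tolerance = 0.01)

  # central target only: gaze stays at the origin
  cgeo <- setup_geometry(target_offsets_cm = matrix(c(0, 0), 1))
  ctr <- simulate_gaze_path(cgeo, dwell_s = 2, baseline_s = 2, repeats = 1,
                            frame_rate_hz = 8, padding_s = 1)
  expect_true(all(ctr$gaze_x_px == 0) && all(ctr$gaze_y_px == 0))

  # mirrored targets displace the pupil by equal and opposite amounts
  mgeo <- setup_geometry(target_offsets_cm = rbind(c(10, 0), c(0, 0), c(-10, 0)))
  mtr <- simulate_gaze_path(mgeo, dwell_s = 1, baseline_s = 1, repeats = 1,
                            frame_rate_hz = 8, padding_s = 1)
  dx <- vapply(1:3, function(k) mtr$gaze_x_px[which(mtr$target_idx == k)[1]], 0)
  expect_equal(dx[1], -dx[3])
  expect_equal(dx[2], 0)
})

test_that("rendered scenes honour the eyelid and forehead contracts", {
  geo <- setup_geometry()
  opt <- scene_optics(noise_sd = 0)

  # forehead frames carry no pupil dependence
  f1 <- render_frame(3, c(0, 0), geo, "forehead", optics = opt)
  f2 <- render_frame(6, c(0, 0), geo, "forehead", optics = opt)
  expect_identical(f1, f2)

  # identity eyelid: closed = open + lid brightness (away from clipping)
  lid0 <- eyelid_model(transmittance = 1, blur_sigma_px = 0,
                       lid_brightness = 0.1, noise_sd = 0)
  open <- render_frame(5, c(0, 0), geo, "open_eye", optics = opt)
  closed <- render_frame(5, c(0, 0), geo, "closed_eye", lid0, opt)
  expect_equal(closed, open + 0.1, tolerance = 1e-12)

  # bigger pupil -> more darkness behind the lid (pixel-summation oracle)
  lid <- eyelid_model(noise_sd = 0)
  roi <- circle_roi(opt$eye_center_px, 28, "closed_eye")
  d3 <- mean_circle_darkness(render_frame(3, c(0, 0), geo, "closed_eye", lid, opt), roi)
  d5 <- mean_circle_darkness(render_frame(5, c(0, 0), geo, "closed_eye", lid, opt), roi)
  expect_gt(d5, d3)

  # a pupil pushed outside the frame is an error
  expect_error(render_frame(5, c(60, 0), geo, "open_eye", optics = opt), "exceeds")
})

test_that("closed-eye darkness is strictly monotone in pupil area (noiseless)", {
  geo <- setup_geometry()
  opt <- scene_optics(noise_sd = 0)
  lid <- eyelid_model(noise_sd = 0)
  roi <- circle_roi(opt$eye_center_px, 28, "closed_eye")
  dk <- vapply(seq(2, 8, length.out = 20), function(dm) {
    mean_circle_darkness(render_frame(dm, c(0, 0), geo, "closed_eye", lid, opt), roi)
  }, 0)
  expect_true(all(diff(dk) > 0))
})

test_that("blink injection marks exactly the brightened frames", {
  tr <- simulate_plr_diameter(stimulus_schedule(numeric(0), 2, 5), plr_kinetics(), 31)
  geo <- setup_geometry()
  opt <- scene_optics(frame_size = c(48, 48), noise_sd = 0)
  stack <- render_stack(tr, setup_geometry(px_per_mm = 2), "open_eye", optics = opt)

  # no blinks: untouched
  res0 <- inject_blinks(stack, numeric(0))
  expect_identical(res0$stack$frames, stack$frames)
  expect_false(any(res0$blink_mask))

  # one 0.2 s blink at 31 Hz covers ceil(0.2 * 31) = 7 frames
  res1 <- inject_blinks(stack, 1, 0.2, 0.3)
  expect_equal(sum(res1$blink_mask), 7)
  expect_true(all(res1$stack$frames[, , res1$blink_mask] >=
                    stack$frames[, , res1$blink_mask]))
  expect_identical(res1$stack$frames[, , !res1$blink_mask],
                   stack$frames[, , !res1$blink_mask])

  # a blink at the session end is clipped to the last frame
  res2 <- inject_blinks(stack, max(tr$t_s), 0.5, 0.3)
  expect_true(res2$blink_mask[length(res2$blink_mask)])

  # overlapping windows merge with a warning
  expect_warning(inject_blinks(stack, c(1, 1.1), 0.2, 0.3), "merged")
})

test_that("render_session is seed-reproducible with seed-independent truth", {
  sch <- stimulus_schedule(c(5, 25), 2, 45)
  cfg <- session_config("plr", schedule = sch,
                        optics = scene_optics(frame_size = c(48, 48)),
                        geometry = setup_geometry(px_per_mm = 2),
                        frame_rate_hz = 4)
  s1 <- render_session(cfg, 11)
  s2 <- render_session(cfg, 11)
  s3 <- render_session(cfg, 12)
  expect_identical(s1$open$frames, s2$open$frames)
  expect_identical(s1$closed$frames, s2$closed$frames)
  expect_false(identical(s1$open$frames, s3$open$frames))
  expect_identical(s1$truth$diameter_mm, s3$truth$diameter_mm)
  expect_equal(dim(s1$open$frames)[3], n_frames(45, 4))

  # incomplete config reports missing fields
  broken <- cfg; broken$kinetics <- NULL
  expect_error(render_session(broken, 1), "kinetics")
})

test_that("rendered pupil size agrees with the geometric truth to half a pixel", {
  geo <- setup_geometry()
  opt <- scene_optics(noise_sd = 0)
  for (dm in c(3, 4, 5, 6)) {
    f <- render_frame(dm, c(0, 0), geo, "open_eye", optics = opt)
    fit <- segment_pupil(f, px_per_mm = geo$px_per_mm)
    expect_lt(abs(fit$diameter_px - dm * geo$px_per_mm), 0.5)
  }
})

test_that("type constructors enforce their invariants", {
  expect_error(stimulus_schedule(c(10, 5), 2, 240), "increasing")
  expect_error(stimulus_schedule(c(10, 11), 2, 240), "exceed")
  expect_error(stimulus_schedule(c(10, 235), 2, 240), "fit inside")
  expect_error(plr_kinetics(constriction_amplitude_mm = 6), "smaller")
  expect_error(plr_kinetics(redilation_tau_s = 0.1), "slower")
  expect_error(eyelid_model(transmittance = 0), "transmittance")
  expect_error(setup_geometry(target_offsets_cm = matrix(c(1, 1), 1)), "central")
  expect_error(frame_stack(array(2, c(4, 4, 2)), 31, "open_eye"), "\\[0, 1\\]")
})
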