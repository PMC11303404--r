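test_that("frame normalization is exact and affine-invariant", {
  set.seed(41)
  f <- matrix(runif(1024), 32)
  nf <- normalize_frame(f)
  expect_lt(abs(mean(nf)), 1e-9)
  expect_lt(abs(sd(nf) - 1), 1e-6)
  expect_equal(normalize_frame(5 * f + 2), nf, tolerance = 1e-9)

  # two-valued frame with equal counts maps onto +/- 0.5/sd
  two <- matrix(rep(c(0, 1), 512), 32)
  ntwo <- normalize_frame(two)
  expect_lt(max(abs(abs(ntwo) - 0.5 / sd(two))), 1e-9)
  expect_equal(sum(ntwo > 0), sum(ntwo < 0))
  expect_error(normalize_frame(flat_frame(0.3)), "constant")
})

test_that("trial split matches the protocol and stays disjoint", {
  s9 <- split_trials(9)
  expect_equal(s9$test_ids, c(5L, 7L))
  expect_equal(s9$val_ids, c(4L, 6L))
  expect_equal(s9$train_ids, c(1L, 2L, 3L, 8L, 9L))

  for (n in 5:14) {
    sp <- split_trials(n)
    ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
    expect_equal(sort(ids), seq_len(n))
    expect_equal(anyDuplicated(ids), 0L)
  }
  s5 <- split_trials(5)
  expect_length(s5$test_ids, 1)
  expect_length(s5$val_ids, 1)
  expect_error(split_trials(4), "at least 5")

  expect_error(unet_config(max_epochs = 5, patience_epochs = 10), "patience")
})

test_that("training is deterministic, early-stops, and never sees test frames", {
  sess <- swirpupil:::unet_cohort_session(9, frame_rate_hz = 4,
                                          frame_size = c(32, 32), px_per_mm = 1.6)
  T <- dim(sess$open$frames)[3]
  ev <- plr_event_frames(sess$config$schedule$onsets_s, 4, T)
  sp <- split_trials(length(ev))
  cfg <- unet_config(max_epochs = 4, patience_epochs = 2, channels = c(4, 8, 8),
                     seed = 2, train_stride = 16, val_stride = 16)

  m1 <- train_reconstructor(sess$closed, sess$open, ev, sp, cfg)
  m2 <- train_reconstructor(sess$closed, sess$open, ev, sp, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$weights$W1, m2$weights$W1)

  # data hygiene: the frames the optimizer saw exclude every test frame
  test_frames <- sort(unlist(ev[sp$test_ids]))
  expect_length(intersect(c(m1$frames$train, m1$frames$val), test_frames), 0)

  # early-stop contract: an unlearnable pure-noise target stagnates, and
  # patience 1 stops exactly one epoch past the best validation score
  set.seed(99)
  noise_y <- frame_stack(array(runif(32 * 32 * T), c(32, 32, T)), 4, "open_eye")
  cfg1 <- unet_config(max_epochs = 30, patience_epochs = 1, channels = c(4, 8, 8),
                      seed = 2, train_stride = 16, val_stride = 16)
  m3 <- train_reconstructor(sess$closed, noise_y, ev, sp, cfg1)
  expect_lt(m3$epochs_run, 30)
  expect_equal(m3$epochs_run, m3$best_epoch + 1)

  # geometry mismatch is rejected at prediction time
  other <- frame_stack(array(runif(24 * 24 * 3), c(24, 24, 3)), 4, "closed_eye")
  expect_error(predict_open_eye(m1, other), "geometry")
})

test_that("an identity task is learned to low validation error", {
  sess <- swirpupil:::unet_cohort_session(10, frame_rate_hz = 4,
                                          frame_size = c(32, 32), px_per_mm = 1.6)
  T <- dim(sess$open$frames)[3]
  ev <- plr_event_frames(sess$config$schedule$onsets_s, 4, T)
  sp <- split_trials(length(ev))
  cfg <- unet_config(max_epochs = 40, patience_epochs = 40, channels = c(8, 16, 32),
                     seed = 1, train_stride = 4, val_stride = 8)
  m <- train_reconstructor(sess$open, sess$open, ev, sp, cfg)
  expect_lt(m$best_val_mae, 0.05)

  # predictions on the test events reproduce the inputs
  test_frames <- sort(unlist(ev[sp$test_ids]))[seq(1, 60, by = 6)]
  pred <- predict_open_eye(m, sess$open, test_frames)
  err <- mean(abs(pred$frames - sess$open$frames[, , test_frames]))
  expect_lt(err, 0.05)
})

test_that("reconstruction evaluation compares models against diameter truth", {
  sess <- small_plr_session(12, frame_rate_hz = 4)
  idx <- 1:60
  truth_d <- sess$truth$diameter_mm[idx]
  stack <- frame_stack(sess$open$frames[, , idx], 4, "open_eye")

  # perfect predictions: near-zero MAE (segmentation + filter residual only)
  res <- evaluate_reconstruction(stack, stack, truth_d,
                                 sess$config$geometry$px_per_mm)
  expect_false(res$failed_closed)
  expect_lt(res$mae_closed, 0.15)

  # a blank stack cannot be segmented: marked failed
  blank <- frame_stack(array(0.5 + 1e-3 * runif(length(stack$frames)),
                             dim(stack$frames)), 4, "open_eye")
  res2 <- evaluate_reconstruction(blank, stack, truth_d,
                                  sess$config$geometry$px_per_mm)
  expect_true(res2$failed_closed)
})
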