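# Scaled-down encoder-decoder reconstruction of open-eye frames from
# closed-eye frames, with the trial-split and evaluation protocol.
#
# A separate model is trained per session (and per input region: closed eye
# or forehead control). The network is a 3-level fully convolutional
# encoder-decoder with skip connections; the raw input frame is also
# concatenated into the final 1x1 convolution (a global residual path).
# Training minimizes mean absolute error on per-frame z-normalized images.

#' Per-frame intensity normalization
#'
#' Subtracts the frame's mean brightness and divides by its standard
#' deviation, removing global brightness changes between frames.
#'
#' @param frame intensity matrix; must not be constant.
#' @return normalized matrix (mean 0, sd 1).
#' @export
normalize_frame <- function(frame) {
  s <- sd(frame)
  if (!is.finite(s) || s == 0) stopf("constant frame cannot be normalized")
  (frame - mean(frame)) / s
}

#' Trial split for the reconstruction protocol
#'
#' With nine PLR events the split is fixed: test events {5, 7}, validation
#' events {4, 6}, the rest train. For other counts the positions are mapped
#' proportionally (test near 5/9 and 7/9 of the sequence, validation near
#' 4/9 and 6/9, each set of size `max(1, round(2n/9))`).
#'
#' @param n_events number of PLR events (>= 5).
#' @return list(train_ids, val_ids, test_ids): disjoint, covering 1..n.
#' @export
split_trials <- function(n_events) {
  if (n_events < 5) stopf("need at least 5 events to split (got %d)", n_events)
  n <- as.integer(n_events)
  if (n == 9L) {
    test <- c(5L, 7L); val <- c(4L, 6L)
  } else {
    k <- max(1L, as.integer(round(2 * n / 9)))
    pick <- function(frac, avoid, k) {
      want <- pmin(pmax(as.integer(round(frac * n)), 1L), n)
      out <- integer(0)
      for (w in want) {
        if (length(out) >= k) break
        cand <- setdiff(seq_len(n), c(avoid, out))
        out <- c(out, cand[which.min(abs(cand - w))])
      }
      sort(out)
    }
    test <- pick(c(5, 7) / 9, integer(0), k)
    val <- pick(c(4, 6) / 9, test, k)
  }
  list(train_ids = setdiff(seq_len(n), c(val, test)), val_ids = val, test_ids = test)
}

#' Training configuration for the reconstruction network
#'
#' @param max_epochs maximum training epochs.
#' @param patience_epochs epochs without validation improvement before
#'   stopping; `max_epochs >= patience_epochs >= 1`.
#' @param channels encoder channel widths (3 levels).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed integer training seed (weight init + shuffling).
#' @param train_stride,val_stride frame subsampling strides applied to the
#'   training and validation events (desk-scale control).
#' @return An `unet_config` list.
#' @export
unet_config <- function(max_epochs = 200, patience_epochs = 20,
                        channels = c(16, 32, 64), lr = 1e-3, batch_size = 8,
                        seed = 1L, train_stride = 1L, val_stride = 1L) {
  if (!(max_epochs >= patience_epochs && patience_epochs >= 1)) {
    stopf("need max_epochs >= patience_epochs >= 1")
  }
  if (length(channels) != 3) stopf("channels must give the 3 encoder widths")
  list(max_epochs = as.integer(max_epochs), patience_epochs = as.integer(patience_epochs),
       channels = as.integer(channels), lr = lr, batch_size = as.integer(batch_size),
       seed = as.integer(seed), train_stride = as.integer(train_stride),
       val_stride = as.integer(val_stride))
}

#' Train the open-eye reconstruction model
#'
#' Trains the encoder-decoder to map z-normalized input frames (closed eye
#' or forehead control) to z-normalized open-eye frames under MAE loss with
#' Adam, early-stopping on the validation events. Only frames of the train
#' and validation events ever reach the optimizer.
#'
#' @param x_stack input [frame_stack()] (closed_eye or forehead).
#' @param y_stack target open-eye [frame_stack()], same geometry.
#' @param event_frames list of frame-index vectors, one per PLR event.
#' @param split a [split_trials()] result.
#' @param config an [unet_config()].
#' @return An `eyelid_net_model`: weights, per-epoch train/val MAE log,
#'   epochs run, frame bookkeeping, and the de-normalization statistics of
#'   the target training frames.
#' @export
train_reconstructor <- function(x_stack, y_stack, event_frames, split,
                                config = unet_config()) {
  stopifnot(inherits(x_stack, "frame_stack"), inherits(y_stack, "frame_stack"))
  if (!all(dim(x_stack$frames) == dim(y_stack$frames))) {
    stopf("input and target stacks have mismatching shapes")
  }
  sub <- function(idx, stride) idx[seq(1, length(idx), by = stride)]
  train_frames <- sub(sort(unique(unlist(event_frames[split$train_ids]))), config$train_stride)
  val_frames <- sub(sort(unique(unlist(event_frames[split$val_ids]))), config$val_stride)
  test_frames <- sort(unique(unlist(event_frames[split$test_ids])))
  if (length(intersect(c(train_frames, val_frames), test_frames))) {
    stopf("trial split leaks test frames into training/validation")
  }
  used <- sort(unique(c(train_frames, val_frames)))
  xn <- x_stack$frames[, , used, drop = FALSE]
  yn <- y_stack$frames[, , used, drop = FALSE]
  y_mu <- numeric(length(used)); y_sd <- numeric(length(used))
  for (i in seq_along(used)) {
    y_mu[i] <- mean(yn[, , i]); y_sd[i] <- sd(yn[, , i])
    xn[, , i] <- normalize_frame(xn[, , i])
    yn[, , i] <- normalize_frame(yn[, , i])
  }
  tr_pos <- match(train_frames, used) - 1L   # 0-based for C++
  va_pos <- match(val_frames, used) - 1L
  fit <- .unet_train_cpp(xn, yn, tr_pos, va_pos,
                         config$channels[1], config$channels[2], config$channels[3],
                         config$max_epochs, config$patience_epochs, config$lr,
                         config$batch_size, config$seed)
  structure(
    list(weights = fit$weights,
         log = data.frame(epoch = seq_along(fit$train_mae),
                          train_mae = as.numeric(fit$train_mae),
                          val_mae = as.numeric(fit$val_mae)),
         epochs_run = fit$epochs_run, best_epoch = fit$best_epoch,
         best_val_mae = fit$best_val_mae,
         frames = list(train = train_frames, val = val_frames, test = test_frames),
         denorm = c(mean = mean(y_mu), sd = mean(y_sd)),
         config = config, scene = x_stack$scene_label),
    class = "eyelid_net_model"
  )
}

#' Predict open-eye frames from input frames
#'
#' Normalizes each input frame, runs the trained model, and de-normalizes
#' the output to \[0, 1\] using the mean target statistics of the training
#' frames. Pupil segmentation downstream is threshold-quantile based and
#' therefore invariant to this (affine) de-normalization choice.
#'
#' @param model an `eyelid_net_model`.
#' @param stack input [frame_stack()] with the training geometry.
#' @param frames optional frame indices to predict (default all).
#' @return A [frame_stack()] of predicted open-eye frames.
#' @export
predict_open_eye <- function(model, stack, frames = NULL) {
  stopifnot(inherits(model, "eyelid_net_model"), inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[1] != model$weights$H || d[2] != model$weights$W) {
    stopf("frame geometry %dx%d does not match the trained model (%dx%d)",
          d[1], d[2], model$weights$H, model$weights$W)
  }
  frames <- frames %||% seq_len(d[3])
  xn <- stack$frames[, , frames, drop = FALSE]
  for (i in seq_along(frames)) xn[, , i] <- normalize_frame(xn[, , i])
  pred <- .unet_predict_cpp(model$weights, xn)
  pred <- pred * model$denorm["sd"] + model$denorm["mean"]
  pred <- pmin(pmax(pred, 0), 1)
  frame_stack(pred, stack$frame_rate_hz, "open_eye")
}

#' Evaluate reconstructed pupil dynamics against ground truth
#'
#' Extracts the pupil diameter from each predicted stack frame by frame
#' ([segment_pupil()]), converts to mm, suppresses prediction transients
#' with the 1 Hz zero-phase low-pass, and computes the MAE against the true
#' diameter over the supplied (test-event) frames. Diameters are expressed
#' as mm changes relative to the pre-stimulus baseline of each event when
#' `events` gives the per-event frame positions -- the convention used
#' throughout the PLR analysis, which also removes any shared absolute
#' offset a smooth reconstruction imposes on the segmented size. A model
#' whose segmentation fails on more than half its frames is marked failed.
#'
#' @param pred_closed,pred_forehead predicted open-eye [frame_stack()]s
#'   from the closed-eye and forehead-control models (test frames only).
#' @param truth_diameter_mm true diameter (mm) aligned with the predicted
#'   frames.
#' @param px_per_mm image scale.
#' @param cutoff_hz low-pass cutoff for the diameter traces.
#' @param events optional list of index vectors (positions within the
#'   prediction stack), one per test event, each starting `baseline_s`
#'   before stimulus onset; enables baseline-relative scoring.
#' @param baseline_s pre-stimulus baseline length at each event start (s).
#' @return list(mae_closed, mae_forehead, failed_closed, failed_forehead,
#'   diameter_closed, diameter_forehead).
#' @export
evaluate_reconstruction <- function(pred_closed, pred_forehead, truth_diameter_mm,
                                    px_per_mm, cutoff_hz = 1, events = NULL,
                                    baseline_s = 2) {
  rel <- function(d, fs) {
    if (is.null(events)) return(d)
    nb <- max(1L, as.integer(round(baseline_s * fs)))
    for (ev in events) {
      d[ev] <- d[ev] - mean(d[ev[seq_len(min(nb, length(ev)))]])
    }
    d
  }
  eval_one <- function(stack) {
    tr <- pupil_trace_from_stack(stack, px_per_mm, method = "midpoint")
    failed <- mean(is.na(tr$diameter_mm)) > 0.5
    if (failed) return(list(mae = NA_real_, failed = TRUE, diameter = tr$diameter_mm))
    d <- tr$diameter_mm
    if (anyNA(d)) {  # bridge isolated failures before filtering
      ok <- which(!is.na(d))
      d <- approx(ok, d[ok], xout = seq_along(d), rule = 2)$y
    }
    d <- lowpass_zero_phase(d, cutoff_hz, stack$frame_rate_hz)
    d <- rel(d, stack$frame_rate_hz)
    list(mae = mean_absolute_error(d, rel(truth_diameter_mm, stack$frame_rate_hz)),
         failed = FALSE, diameter = d)
  }
  ec <- eval_one(pred_closed)
  ef <- eval_one(pred_forehead)
  list(mae_closed = ec$mae, mae_forehead = ef$mae,
       failed_closed = ec$failed, failed_forehead = ef$failed,
       diameter_closed = ec$diameter, diameter_forehead = ef$diameter)
}

#' Frame indices of each PLR event in a session
#'
#' Epoch window indices (-2 to +18 s around each onset) clipped to trials
#' that fit in the recording.
#'
#' @param onsets_s stimulus onsets (s).
#' @param frame_rate_hz frame rate (Hz).
#' @param n_frames_total total frames in the session.
#' @param window_s epoch window.
#' @return list of integer frame-index vectors, one per retained event.
#' @export
plr_event_frames <- function(onsets_s, frame_rate_hz, n_frames_total,
                             window_s = c(-2, 18)) {
  ns <- as.integer(round((window_s[2] - window_s[1]) * frame_rate_hz))
  off0 <- as.integer(round(window_s[1] * frame_rate_hz))
  out <- list()
  for (on in onsets_s) {
    i0 <- as.integer(round(on * frame_rate_hz)) + 1L + off0
    i1 <- i0 + ns - 1L
    if (i0 >= 1 && i1 <= n_frames_total) out[[length(out) + 1L]] <- i0:i1
  }
  out
}

#' Paired closed-eye vs forehead reconstruction experiment on one session
#'
#' Trains the two models of the protocol (closed-eye input and
#' forehead-control input, same split and seed), predicts the test events,
#' and evaluates both against the true diameter.
#'
#' @param session a rendered PLR session from [render_session()].
#' @param config an [unet_config()].
#' @return list(mae_closed, mae_forehead, split, models, eval).
#' @export
unet_session_experiment <- function(session, config = unet_config()) {
  fs <- session$truth$frame_rate_hz
  T <- dim(session$open$frames)[3]
  ev <- plr_event_frames(session$config$schedule$onsets_s, fs, T)
  split <- split_trials(length(ev))
  m_closed <- train_reconstructor(session$closed, session$open, ev, split, config)
  m_fore <- train_reconstructor(session$forehead, session$open, ev, split, config)
  test_frames <- sort(unique(unlist(ev[split$test_ids])))
  pc <- predict_open_eye(m_closed, session$closed, test_frames)
  pf <- predict_open_eye(m_fore, session$forehead, test_frames)
  test_events <- lapply(ev[split$test_ids], function(fr) match(fr, test_frames))
  res <- evaluate_reconstruction(pc, pf, session$truth$diameter_mm[test_frames],
                                 session$config$geometry$px_per_mm,
                                 events = test_events)
  list(mae_closed = res$mae_closed, mae_forehead = res$mae_forehead,
       split = split, models = list(closed = m_closed, forehead = m_fore),
       eval = res, test_frames = test_frames)
}

#' Desk-scale reconstruction cohort
#'
#' Renders `n_sessions` synthetic PLR sessions at 64x64 and runs
#' [unet_session_experiment()] on each. The protocol mirrors the per-session
#' pairing of a closed-eye model against a forehead-control model: nine
#' 2 s stimuli at 20 s intervals, epochs of -2 to +18 s, the fixed
#' {5,7}/{4,6} trial split. Desk-scale choices (8 Hz sampling, frame
#' subsampling, 8/16/32 channels, 16 epochs) keep a session trainable in
#' about a minute on one CPU.
#'
#' @param n_sessions number of simulated sessions (participants).
#' @param seed cohort seed; session s uses child seed (seed, s).
#' @param frame_rate_hz acquisition rate for the cohort sessions.
#' @param channels,max_epochs,patience_epochs,train_stride,val_stride
#'   training controls, see [unet_config()].
#' @param transmittance eyelid transmittance of the rendered sessions.
#' @return data.frame(session, mae_closed, mae_forehead).
#' @export
unet_cohort_experiment <- function(n_sessions = 8, seed = 1L, frame_rate_hz = 8,
                                   channels = c(8, 16, 32), max_epochs = 16,
                                   patience_epochs = 6, train_stride = 8,
                                   val_stride = 16, transmittance = 0.35) {
  out <- data.frame(session = seq_len(n_sessions),
                    mae_closed = NA_real_, mae_forehead = NA_real_)
  for (s in seq_len(n_sessions)) {
    sess <- unet_cohort_session(child_seed(seed, s), frame_rate_hz, transmittance)
    cfgU <- unet_config(max_epochs = max_epochs, patience_epochs = patience_epochs,
                        channels = channels, seed = child_seed(seed, 100L + s),
                        train_stride = train_stride, val_stride = val_stride)
    res <- unet_session_experiment(sess, cfgU)
    out$mae_closed[s] <- res$mae_closed
    out$mae_forehead[s] <- res$mae_forehead
  }
  out
}

# One cohort session (default 64x64): nine 2 s stimuli, 20 s apart.
unet_cohort_session <- function(seed, frame_rate_hz = 8, transmittance = 0.35,
                                frame_size = c(64, 64), px_per_mm = 3.2) {
  sch <- stimulus_schedule(seq(5, by = 20, length.out = 9), 2, 185)
  geo <- setup_geometry(px_per_mm = px_per_mm)
  opt <- scene_optics(frame_size = frame_size, noise_sd = 0.01)
  lid <- eyelid_model(transmittance = transmittance)
  cfg <- session_config("plr", schedule = sch, geometry = geo, eyelid = lid,
                        optics = opt, frame_rate_hz = frame_rate_hz,
                        blink_rate_hz = 0)
  render_session(cfg, seed)
}
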