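# Synthetic closed-eye SWIR session generator.
#
# Generates seeded ground-truth dynamics (pupil diameter, gaze position,
# blink mask) and renders them into open-eye, closed-eye and forehead
# grayscale frame stacks so that every analysis stage can be validated
# against known truth.

# ---- domain type constructors -------------------------------------------

#' Stimulus schedule for a pupillary light reflex (PLR) session
#'
#' Describes when bright-light stimuli are shown. The default emulates a
#' standard protocol: ten 2 s white-screen stimuli separated by 20 +/- 2 s
#' dark intervals in a 240 s session.
#'
#' @param onsets_s strictly increasing stimulus onset times in seconds.
#' @param stim_duration_s light duration in seconds.
#' @param session_duration_s total session length in seconds.
#' @return A `stimulus_schedule` object.
#' @export
stimulus_schedule <- function(onsets_s, stim_duration_s = 2, session_duration_s = 240) {
  if (length(onsets_s) && any(diff(onsets_s) <= 0)) {
    stopf("stimulus onsets must be strictly increasing")
  }
  if (length(onsets_s) && any(diff(onsets_s) <= stim_duration_s)) {
    stopf("inter-onset gaps must exceed the stimulus duration (%g s)", stim_duration_s)
  }
  if (length(onsets_s) && max(onsets_s) + 18 > session_duration_s) {
    stopf("every onset + 18 s must fit inside the session (%g s)", session_duration_s)
  }
  structure(
    list(onsets_s = as.numeric(onsets_s), stim_duration_s = stim_duration_s,
         session_duration_s = session_duration_s),
    class = "stimulus_schedule"
  )
}

#' Default PLR stimulus schedule
#'
#' Ten 2 s stimuli with 20 +/- 2 s inter-stimulus intervals in a 240 s
#' session. The +/- 2 s jitter is drawn deterministically from `jitter_seed`.
#'
#' @param n_stim number of stimuli.
#' @param isi_s nominal inter-stimulus interval (s).
#' @param isi_jitter_s uniform jitter half-range (s).
#' @param first_onset_s onset of the first stimulus (s).
#' @param stim_duration_s stimulus duration (s).
#' @param session_duration_s session length (s).
#' @param jitter_seed integer seed for the jitter draw.
#' @return A [stimulus_schedule()].
#' @export
default_plr_schedule <- function(n_stim = 10, isi_s = 20, isi_jitter_s = 2,
                                 first_onset_s = 10, stim_duration_s = 2,
                                 session_duration_s = 240, jitter_seed = 7L) {
  jit <- if (isi_jitter_s > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(jitter_seed)
    j <- runif(max(n_stim - 1, 0), -isi_jitter_s, isi_jitter_s)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    j
  } else {
    rep(0, max(n_stim - 1, 0))
  }
  onsets <- first_onset_s + c(0, cumsum(isi_s + jit))
  stimulus_schedule(onsets, stim_duration_s, session_duration_s)
}

#' PLR kinetic parameters
#'
#' Parametric description of a single light-evoked pupil excursion: after a
#' latency, the diameter relaxes toward `baseline - amplitude` with time
#' constant `constriction_tau_s` while the light is on, then re-dilates
#' toward baseline with the slower `redilation_tau_s` (asymmetric response).
#'
#' @param baseline_diameter_mm dark-adapted pupil diameter (mm).
#' @param constriction_amplitude_mm maximal constriction depth (mm).
#' @param latency_s onset-to-response latency (s).
#' @param constriction_tau_s constriction time constant (s).
#' @param redilation_tau_s re-dilation time constant (s); must exceed
#'   `constriction_tau_s`.
#' @return A `plr_kinetics` object.
#' @export
plr_kinetics <- function(baseline_diameter_mm = 5, constriction_amplitude_mm = 1,
                         latency_s = 0.25, constriction_tau_s = 0.4,
                         redilation_tau_s = 4) {
  vals <- c(baseline_diameter_mm, constriction_amplitude_mm, latency_s,
            constriction_tau_s, redilation_tau_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) stopf("all kinetic parameters must be positive")
  if (constriction_amplitude_mm >= baseline_diameter_mm) {
    stopf("constriction amplitude must be smaller than the baseline diameter")
  }
  if (redilation_tau_s <= constriction_tau_s) {
    stopf("re-dilation must be slower than constriction (asymmetric PLR)")
  }
  structure(
    list(baseline_diameter_mm = baseline_diameter_mm,
         constriction_amplitude_mm = constriction_amplitude_mm,
         latency_s = latency_s, constriction_tau_s = constriction_tau_s,
         redilation_tau_s = redilation_tau_s),
    class = "plr_kinetics"
  )
}

#' Experimental setup geometry
#'
#' Viewing distance, fixation-target layout and image scale. Target offsets
#' are given in image-aligned screen axes: x increases rightward and y
#' increases *downward*, matching the image pixel convention, so that pupil
#' displacement has the same sign as the target offset on both axes.
#'
#' @param screen_distance_cm distance from the eye to the screen (cm).
#' @param target_offsets_cm two-column matrix of (dx, dy) target offsets
#'   from the screen centre, in cm. The default is a 3x3 grid at +/- 10 cm
#'   without the bottom-centre position (obscured by the camera), i.e. eight
#'   targets including the central one.
#' @param px_per_mm image scale from the in-view calibration target.
#' @param eye_radius_mm eyeball radius used by the rotation-to-translation
#'   gaze model (pupil displacement = `eye_radius_mm * sin(theta)`).
#' @return A `setup_geometry` object.
#' @export
setup_geometry <- function(screen_distance_cm = 50,
                           target_offsets_cm = NULL,
                           px_per_mm = 5,
                           eye_radius_mm = 12) {
  if (!is_scalar_num(screen_distance_cm) || screen_distance_cm <= 0) {
    stopf("screen_distance_cm must be a positive number")
  }
  if (!is_scalar_num(px_per_mm) || px_per_mm <= 0) stopf("px_per_mm must be positive")
  if (is.null(target_offsets_cm)) {
    g <- 10
    target_offsets_cm <- rbind(
      c(-g, -g), c(0, -g), c(g, -g),
      c(-g,  0), c(0,  0), c(g,  0),
      c(-g,  g), c(g,  g)   # bottom-centre (0, +g) omitted
    )
  }
  target_offsets_cm <- as.matrix(target_offsets_cm)
  if (ncol(target_offsets_cm) != 2) stopf("target_offsets_cm must have two columns (dx, dy)")
  if (!any(target_offsets_cm[, 1] == 0 & target_offsets_cm[, 2] == 0)) {
    stopf("the target layout must include the central target at (0, 0)")
  }
  colnames(target_offsets_cm) <- c("dx_cm", "dy_cm")
  structure(
    list(screen_distance_cm = screen_distance_cm,
         target_offsets_cm = target_offsets_cm,
         px_per_mm = px_per_mm, eye_radius_mm = eye_radius_mm),
    class = "setup_geometry"
  )
}

#' Eyelid optical model
#'
#' The closed-eye scene is the open-eye scene seen through the lid:
#' `closed = clip(blur(open, sigma) * transmittance + lid_brightness) + noise`.
#' Chosen as the simplest model that preserves the premise that pupil area
#' modulates the darkness measured behind the lid.
#'
#' @param transmittance multiplicative attenuation in (0, 1].
#' @param blur_sigma_px Gaussian blur scale in pixels (>= 0).
#' @param lid_brightness additive lid scattering offset.
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @return An `eyelid_model` object.
#' @export
eyelid_model <- function(transmittance = 0.35, blur_sigma_px = 3,
                         lid_brightness = 0.45, noise_sd = 0.01) {
  if (!is_scalar_num(transmittance) || transmittance <= 0 || transmittance > 1) {
    stopf("transmittance must lie in (0, 1]")
  }
  if (blur_sigma_px < 0) stopf("blur_sigma_px must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(
    list(transmittance = transmittance, blur_sigma_px = blur_sigma_px,
         lid_brightness = lid_brightness, noise_sd = noise_sd),
    class = "eyelid_model"
  )
}

#' Scene rendering optics
#'
#' Image-formation parameters shared by the rendered scenes: frame size, eye
#' position, iris size, intensity levels, sensor noise, and the fixed
#' forehead texture (generated once from `texture_seed` so that forehead
#' frames never depend on pupil state).
#'
#' @param frame_size c(height, width) in pixels.
#' @param eye_center_px (x, y) of the eye/iris centre, 0-based pixel
#'   coordinates (pixel centres at integers, x = column rightward,
#'   y = row downward).
#' @param iris_diameter_mm iris diameter (mm).
#' @param pupil_level,iris_level,sclera_level scene intensities in \[0, 1\]
#'   (SWIR: pupil dark, iris mid, sclera bright).
#' @param forehead_level mean forehead intensity.
#' @param forehead_texture_sd amplitude of the static forehead texture.
#' @param noise_sd sensor noise for open-eye and forehead scenes.
#' @param texture_seed integer seed for the static forehead texture.
#' @return A `scene_optics` object.
#' @export
scene_optics <- function(frame_size = c(96, 96), eye_center_px = NULL,
                         iris_diameter_mm = 11,
                         pupil_level = 0.05, iris_level = 0.55, sclera_level = 0.85,
                         forehead_level = 0.6, forehead_texture_sd = 0.05,
                         noise_sd = 0.01, texture_seed = 1234L) {
  frame_size <- as.integer(frame_size)
  if (length(frame_size) != 2 || any(frame_size < 8)) stopf("frame_size must be c(height, width) >= 8")
  if (is.null(eye_center_px)) eye_center_px <- c((frame_size[2] - 1) / 2, (frame_size[1] - 1) / 2)
  # static smooth texture so the forehead control carries no pupil signal
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(texture_seed)
  tex <- matrix(rnorm(prod(frame_size), 0, forehead_texture_sd), frame_size[1], frame_size[2])
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  tex <- gaussian_blur(tex, 2)
  structure(
    list(frame_size = frame_size, eye_center_px = as.numeric(eye_center_px),
         iris_diameter_mm = iris_diameter_mm, pupil_level = pupil_level,
         iris_level = iris_level, sclera_level = sclera_level,
         forehead_level = forehead_level, forehead_texture = tex,
         noise_sd = noise_sd, texture_seed = as.integer(texture_seed)),
    class = "scene_optics"
  )
}

#' Grayscale frame stack
#'
#' @param frames numeric array of dimension height x width x frames with
#'   values in \[0, 1\].
#' @param frame_rate_hz acquisition rate (Hz).
#' @param scene_label one of "open_eye", "closed_eye", "forehead".
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, frame_rate_hz, scene_label) {
  scene_label <- match.arg(scene_label, c("open_eye", "closed_eye", "forehead"))
  if (length(dim(frames)) != 3) stopf("frames must be a height x width x T array")
  if (!all(is.finite(frames)) || min(frames) < 0 || max(frames) > 1) {
    stopf("frame intensities must be finite and lie in [0, 1]")
  }
  if (!is_scalar_num(frame_rate_hz) || frame_rate_hz <= 0) stopf("frame_rate_hz must be positive")
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz, scene_label = scene_label),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %s: %d frames of %dx%d at %g Hz (%.1f s)\n",
              x$scene_label, d[3], d[1], d[2], x$frame_rate_hz, d[3] / x$frame_rate_hz))
  invisible(x)
}

#' Number of frames for a session duration and frame rate
#'
#' @param session_duration_s duration (s).
#' @param frame_rate_hz frame rate (Hz).
#' @return integer frame count, `round(duration * rate)`.
#' @export
n_frames <- function(session_duration_s, frame_rate_hz) {
  as.integer(round(session_duration_s * frame_rate_hz))
}

# ---- ground-truth dynamics ----------------------------------------------

#' Simulate the true pupil-diameter time course of a PLR session
#'
#' Each stimulus triggers, after `latency_s`, an exponential relaxation of
#' the diameter toward `baseline - amplitude` (time constant
#' `constriction_tau_s`) lasting while the light is on, followed by a slower
#' exponential re-dilation toward baseline (`redilation_tau_s`). Excursions
#' are continuous: each starts from the current diameter. If a stimulus
#' arrives before the previous excursion has decayed to under 5% of the
#' amplitude, the offending onset pair is reported as an error.
#'
#' @param schedule a [stimulus_schedule()].
#' @param kinetics a [plr_kinetics()].
#' @param frame_rate_hz sampling rate (Hz).
#' @return A `session_truth` list with `t_s`, `diameter_mm`, `blink_mask`
#'   (all FALSE), `schedule` and `frame_rate_hz`.
#' @export
simulate_plr_diameter <- function(schedule, kinetics = plr_kinetics(), frame_rate_hz = 31) {
  stopifnot(inherits(schedule, "stimulus_schedule"), inherits(kinetics, "plr_kinetics"))
  T <- n_frames(schedule$session_duration_s, frame_rate_hz)
  t <- (seq_len(T) - 1) / frame_rate_hz
  base <- kinetics$baseline_diameter_mm
  A <- kinetics$constriction_amplitude_mm
  d <- rep(base, T)
  ons <- schedule$onsets_s
  if (!length(ons)) {
    return(new_session_truth(t, d, frame_rate_hz, schedule = schedule))
  }
  d_prev_end <- base   # diameter entering the current excursion
  for (i in seq_along(ons)) {
    t0 <- ons[i] + kinetics$latency_s
    t1 <- t0 + schedule$stim_duration_s
    seg_end <- if (i < length(ons)) ons[i + 1] + kinetics$latency_s else max(t) + 1 / frame_rate_hz
    d_start <- d_prev_end
    if (i > 1) {
      resid <- base - d_start
      if (resid > 0.05 * A) {
        stopf("onsets %d (%.3g s) and %d (%.3g s) are too close: previous excursion has not decayed",
              i - 1, ons[i - 1], i, ons[i])
      }
    }
    target <- base - A
    ic <- which(t >= t0 & t < min(t1, seg_end))
    if (length(ic)) d[ic] <- target + (d_start - target) * exp(-(t[ic] - t0) / kinetics$constriction_tau_s)
    d1 <- target + (d_start - target) * exp(-(t1 - t0) / kinetics$constriction_tau_s)
    ir <- which(t >= t1 & t < seg_end)
    if (length(ir)) d[ir] <- base + (d1 - base) * exp(-(t[ir] - t1) / kinetics$redilation_tau_s)
    d_prev_end <- base + (d1 - base) * exp(-(max(seg_end, t1) - t1) / kinetics$redilation_tau_s)
  }
  new_session_truth(t, d, frame_rate_hz, schedule = schedule)
}

new_session_truth <- function(t_s, diameter_mm, frame_rate_hz, schedule = NULL,
                              gaze_x_px = NULL, gaze_y_px = NULL, target_idx = NULL,
                              theta_x_dva = NULL, theta_y_dva = NULL,
                              is_target_display = NULL, blink_mask = NULL) {
  T <- length(t_s)
  structure(
    list(t_s = t_s, diameter_mm = diameter_mm,
         gaze_x_px = gaze_x_px %||% rep(0, T), gaze_y_px = gaze_y_px %||% rep(0, T),
         target_idx = target_idx, theta_x_dva = theta_x_dva, theta_y_dva = theta_y_dva,
         is_target_display = is_target_display %||% rep(FALSE, T),
         blink_mask = blink_mask %||% rep(FALSE, T),
         schedule = schedule, frame_rate_hz = frame_rate_hz),
    class = "session_truth"
  )
}

#' Simulate the true gaze path of a fixation-grid session
#'
#' After a central-fixation baseline the targets of `geometry` are shown in
#' order, each for `dwell_s` seconds, and the sequence is repeated
#' `repeats` times, followed by a central-fixation padding period. Gaze is
#' piecewise constant; an eye rotation of theta displaces the pupil centre
#' by `eye_radius_mm * sin(theta)` per axis. `gaze_x_px`/`gaze_y_px` are
#' displacements from the central-fixation origin in pixels.
#'
#' @param geometry a [setup_geometry()].
#' @param dwell_s seconds each target is displayed.
#' @param baseline_s initial central-fixation period (s).
#' @param repeats number of passes over the target sequence.
#' @param frame_rate_hz sampling rate (Hz).
#' @param padding_s terminal central-fixation period (s).
#' @param baseline_diameter_mm constant pupil diameter during the session.
#' @return A `session_truth` with gaze fields, per-sample `target_idx`
#'   (NA outside target display) and true target angles in DVA.
#' @export
simulate_gaze_path <- function(geometry = setup_geometry(), dwell_s = 5, baseline_s = 15,
                               repeats = 2, frame_rate_hz = 31, padding_s = 10,
                               baseline_diameter_mm = 5) {
  stopifnot(inherits(geometry, "setup_geometry"), dwell_s > 0)
  tg <- geometry$target_offsets_cm
  nt <- nrow(tg)
  total_s <- baseline_s + nt * dwell_s * repeats + padding_s
  T <- n_frames(total_s, frame_rate_hz)
  t <- (seq_len(T) - 1) / frame_rate_hz
  target_idx <- rep(NA_integer_, T)
  display <- t >= baseline_s & t < baseline_s + nt * dwell_s * repeats
  k <- floor((t[display] - baseline_s) / dwell_s)
  target_idx[display] <- (k %% nt) + 1L
  ang <- target_reference_angles(geometry)
  central <- which(tg[, 1] == 0 & tg[, 2] == 0)[1]
  idx_eff <- ifelse(is.na(target_idx), central, target_idx)
  th_x <- ang$theta_x_dva[idx_eff]
  th_y <- ang$theta_y_dva[idx_eff]
  disp_mm_x <- geometry$eye_radius_mm * sin(th_x * pi / 180)
  disp_mm_y <- geometry$eye_radius_mm * sin(th_y * pi / 180)
  new_session_truth(
    t, rep(baseline_diameter_mm, T), frame_rate_hz,
    gaze_x_px = disp_mm_x * geometry$px_per_mm,
    gaze_y_px = disp_mm_y * geometry$px_per_mm,
    target_idx = target_idx, theta_x_dva = th_x, theta_y_dva = th_y,
    is_target_display = display
  )
}

# ---- rendering -----------------------------------------------------------

# Separable Gaussian blur via EBImage::filter2 (FFT, circular boundary).
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  EBImage::filter2(mat, k)
}

#' Render a single scene frame
#'
#' Open-eye frames show a dark pupil disk on a brighter iris annulus on a
#' bright sclera; closed-eye frames composite the open-eye scene through an
#' [eyelid_model()]; forehead frames show the static control texture with no
#' pupil dependence. Pixel membership is by pixel-centre-in-disk; noise is
#' drawn from the current RNG.
#'
#' @param diameter_mm true pupil diameter.
#' @param gaze_center_px (x, y) pupil-centre displacement from the eye
#'   centre, in pixels.
#' @param geometry a [setup_geometry()] (for the pixel scale).
#' @param scene_label "open_eye", "closed_eye" or "forehead".
#' @param eyelid an [eyelid_model()]; required for closed-eye frames.
#' @param optics a [scene_optics()].
#' @return A height x width intensity matrix in \[0, 1\].
#' @export
render_frame <- function(diameter_mm, gaze_center_px = c(0, 0),
                         geometry = setup_geometry(), scene_label = "open_eye",
                         eyelid = NULL, optics = scene_optics()) {
  scene_label <- match.arg(scene_label, c("open_eye", "closed_eye", "forehead"))
  H <- optics$frame_size[1]; W <- optics$frame_size[2]
  if (scene_label == "forehead") {
    f <- optics$forehead_level + optics$forehead_texture
    if (optics$noise_sd > 0) f <- f + matrix(rnorm(H * W, 0, optics$noise_sd), H, W)
    return(pmin(pmax(f, 0), 1))
  }
  ppm <- geometry$px_per_mm
  rp <- diameter_mm * ppm / 2
  ri <- optics$iris_diameter_mm * ppm / 2
  cx <- optics$eye_center_px[1] + gaze_center_px[1]
  cy <- optics$eye_center_px[2] + gaze_center_px[2]
  if (cx - rp < 0 || cx + rp > W - 1 || cy - rp < 0 || cy + rp > H - 1) {
    stopf("pupil disk (centre %.1f,%.1f radius %.1f px) exceeds the %dx%d frame",
          cx, cy, rp, H, W)
  }
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  d2_iris <- (x - optics$eye_center_px[1])^2 + (y - optics$eye_center_px[2])^2
  d2_pup <- (x - cx)^2 + (y - cy)^2
  f <- matrix(optics$sclera_level, H, W)
  f[d2_iris <= ri^2] <- optics$iris_level
  f[d2_pup <= rp^2] <- optics$pupil_level
  if (scene_label == "closed_eye") {
    if (is.null(eyelid)) stopf("closed-eye rendering requires an eyelid_model")
    f <- gaussian_blur(f, eyelid$blur_sigma_px) * eyelid$transmittance + eyelid$lid_brightness
    f <- pmin(pmax(f, 0), 1)
    if (eyelid$noise_sd > 0) f <- f + matrix(rnorm(H * W, 0, eyelid$noise_sd), H, W)
  } else if (optics$noise_sd > 0) {
    f <- f + matrix(rnorm(H * W, 0, optics$noise_sd), H, W)
  }
  pmin(pmax(f, 0), 1)
}

#' Render a whole frame stack from ground truth
#'
#' @param truth a `session_truth`.
#' @param geometry a [setup_geometry()].
#' @param scene_label scene to render.
#' @param eyelid an [eyelid_model()] (closed-eye scenes).
#' @param optics a [scene_optics()].
#' @return A [frame_stack()].
#' @export
render_stack <- function(truth, geometry = setup_geometry(), scene_label = "open_eye",
                         eyelid = NULL, optics = scene_optics()) {
  T <- length(truth$t_s)
  H <- optics$frame_size[1]; W <- optics$frame_size[2]
  frames <- array(0, c(H, W, T))
  for (i in seq_len(T)) {
    frames[, , i] <- render_frame(
      truth$diameter_mm[i], c(truth$gaze_x_px[i], truth$gaze_y_px[i]),
      geometry, scene_label, eyelid, optics
    )
  }
  frame_stack(frames, truth$frame_rate_hz, scene_label)
}

#' Inject blink brightness transients into a frame stack
#'
#' Frames whose timestamps fall in a blink window are brightened by
#' `blink_gain` (saturating at 1). Overlapping windows are merged with a
#' warning; a blink running past the session end is clipped to the last
#' frame.
#'
#' @param stack a [frame_stack()].
#' @param blink_times_s blink onset times (s).
#' @param blink_duration_s blink duration (s).
#' @param blink_gain additive intensity gain (> 0).
#' @return list(stack = brightened [frame_stack()], blink_mask = logical
#'   per-frame mask marking exactly the affected frames).
#' @export
inject_blinks <- function(stack, blink_times_s, blink_duration_s = 0.2, blink_gain = 0.3) {
  stopifnot(inherits(stack, "frame_stack"), blink_gain > 0, blink_duration_s > 0)
  T <- dim(stack$frames)[3]
  t <- (seq_len(T) - 1) / stack$frame_rate_hz
  mask <- rep(FALSE, T)
  if (length(blink_times_s)) {
    bt <- sort(blink_times_s)
    if (any(bt < 0) || any(bt > max(t))) stopf("blink windows must start within the session")
    if (any(diff(bt) < blink_duration_s)) warnf("overlapping blink windows merged")
    for (b in bt) mask[t >= b & t < b + blink_duration_s] <- TRUE
  }
  if (any(mask)) {
    stack$frames[, , mask] <- pmin(stack$frames[, , mask] + blink_gain, 1)
  }
  list(stack = stack, blink_mask = mask)
}

# ---- full session --------------------------------------------------------

#' Session configuration for the synthetic generator
#'
#' Bundles every parameter of a synthetic session with defaults that
#' emulate the study conditions: 31 Hz frames, ten 2 s stimuli at 20 +/- 2 s
#' intervals (PLR) or a 3x3 fixation grid with 5 s dwells repeated twice
#' after a 15 s baseline (gaze).
#'
#' @param experiment "plr" or "gaze".
#' @param schedule a [stimulus_schedule()] (PLR sessions).
#' @param kinetics a [plr_kinetics()].
#' @param geometry a [setup_geometry()].
#' @param eyelid an [eyelid_model()].
#' @param optics a [scene_optics()].
#' @param frame_rate_hz acquisition rate (Hz).
#' @param blink_rate_hz mean blink rate; 0.05 Hz (3 per minute).
#' @param blink_duration_s blink duration (s).
#' @param blink_gain blink brightness gain.
#' @param dwell_s,baseline_s,repeats,padding_s gaze-protocol timing.
#' @return A `session_config` list.
#' @export
session_config <- function(experiment = c("plr", "gaze"),
                           schedule = NULL, kinetics = plr_kinetics(),
                           geometry = setup_geometry(), eyelid = eyelid_model(),
                           optics = NULL, frame_rate_hz = 31,
                           blink_rate_hz = 0.05, blink_duration_s = 0.2, blink_gain = 0.3,
                           dwell_s = 5, baseline_s = 15, repeats = 2, padding_s = 10) {
  experiment <- match.arg(experiment)
  if (is.null(schedule) && experiment == "plr") schedule <- default_plr_schedule()
  if (is.null(optics)) optics <- scene_optics()
  cfg <- list(experiment = experiment, schedule = schedule, kinetics = kinetics,
              geometry = geometry, eyelid = eyelid, optics = optics,
              frame_rate_hz = frame_rate_hz, blink_rate_hz = blink_rate_hz,
              blink_duration_s = blink_duration_s, blink_gain = blink_gain,
              dwell_s = dwell_s, baseline_s = baseline_s, repeats = repeats,
              padding_s = padding_s)
  class(cfg) <- "session_config"
  cfg
}

validate_session_config <- function(config) {
  required <- c("experiment", "kinetics", "geometry", "eyelid", "optics", "frame_rate_hz")
  if (config$experiment %||% "" == "plr") required <- c(required, "schedule")
  missing <- required[vapply(required, function(f) is.null(config[[f]]), logical(1))]
  if (length(missing)) stopf("incomplete session config; missing: %s", paste(missing, collapse = ", "))
  invisible(config)
}

#' Render a complete synthetic session
#'
#' Generates ground truth, renders the open-eye, closed-eye and forehead
#' stacks, and injects blink transients into both eye stacks (same times).
#' Deterministic given `seed`: blink placement and pixel noise use
#' independent child streams of it, while the truth diameter/gaze path is
#' seed-independent.
#'
#' @param config a [session_config()].
#' @param seed integer session seed.
#' @return list(open, closed, forehead = [frame_stack()]s,
#'   truth = `session_truth` with the blink mask filled in,
#'   config = the config used, seed = the seed).
#' @export
render_session <- function(config = session_config(), seed = 1L) {
  validate_session_config(config)
  truth <- if (config$experiment == "plr") {
    simulate_plr_diameter(config$schedule, config$kinetics, config$frame_rate_hz)
  } else {
    simulate_gaze_path(config$geometry, config$dwell_s, config$baseline_s,
                       config$repeats, config$frame_rate_hz, config$padding_s,
                       config$kinetics$baseline_diameter_mm)
  }
  dur <- length(truth$t_s) / config$frame_rate_hz
  # blink placement stream
  set.seed(child_seed(seed, 1L))
  n_blinks <- round(config$blink_rate_hz * dur)
  blink_times <- numeric(0)
  if (n_blinks > 0) {
    cand <- sort(runif(n_blinks, 1, dur - 1))
    keep <- c(TRUE, diff(cand) > 2)         # >= 2 s apart
    blink_times <- cand[keep]
  }
  # pixel-noise stream
  set.seed(child_seed(seed, 2L))
  open <- render_stack(truth, config$geometry, "open_eye", optics = config$optics)
  closed <- render_stack(truth, config$geometry, "closed_eye", config$eyelid, config$optics)
  forehead <- render_stack(truth, config$geometry, "forehead", optics = config$optics)
  if (length(blink_times)) {
    bo <- inject_blinks(open, blink_times, config$blink_duration_s, config$blink_gain)
    bc <- inject_blinks(closed, blink_times, config$blink_duration_s, config$blink_gain)
    open <- bo$stack; closed <- bc$stack
    truth$blink_mask <- bo$blink_mask
  }
  list(open = open, closed = closed, forehead = forehead, truth = truth,
       config = config, seed = as.integer(seed))
}

# ---- trace-level shortcut ------------------------------------------------

#' Closed-form fixed-circle darkness for a given pupil diameter
#'
#' Continuous-area approximation of the mean darkness inside a circular ROI
#' of radius `roi_radius_px` centred on the eye, for any of the three
#' scenes. Used for fast trace-level statistical simulations; the rendered
#' pixel version is `darkness_timeseries()`.
#'
#' @param diameter_mm pupil diameter(s), mm.
#' @param geometry a [setup_geometry()].
#' @param optics a [scene_optics()].
#' @param eyelid an [eyelid_model()] (closed-eye scene).
#' @param roi_radius_px ROI radius in pixels.
#' @param scene_label scene.
#' @return darkness value(s) in \[0, 1\].
#' @export
darkness_from_diameter <- function(diameter_mm, geometry = setup_geometry(),
                                   optics = scene_optics(), eyelid = eyelid_model(),
                                   roi_radius_px = 28, scene_label = "closed_eye") {
  scene_label <- match.arg(scene_label, c("open_eye", "closed_eye", "forehead"))
  ppm <- geometry$px_per_mm
  a_roi <- pi * roi_radius_px^2
  if (scene_label == "forehead") {
    return(rep(1 - optics$forehead_level, length(diameter_mm)))
  }
  a_pup <- pmin(pi * (diameter_mm * ppm / 2)^2, a_roi)
  a_iris <- pmin(pi * (optics$iris_diameter_mm * ppm / 2)^2, a_roi)
  mean_int <- (a_pup * optics$pupil_level + (a_iris - a_pup) * optics$iris_level +
                 (a_roi - a_iris) * optics$sclera_level) / a_roi
  if (scene_label == "closed_eye") {
    mean_int <- mean_int * eyelid$transmittance + eyelid$lid_brightness
  }
  1 - pmin(pmax(mean_int, 0), 1)
}

#' Simulate a darkness trace directly from ground truth
#'
#' Trace-level shortcut: maps the true diameter through
#' [darkness_from_diameter()] and adds white Gaussian noise representing
#' residual trace-level fluctuations. Orders of magnitude faster than
#' rendering; used for statistical calibration experiments.
#'
#' @param truth a `session_truth`.
#' @param scene_label scene.
#' @param noise_sd_trace trace-level noise standard deviation.
#' @param geometry,optics,eyelid,roi_radius_px forwarded to
#'   [darkness_from_diameter()].
#' @return A [darkness_trace()].
#' @export
simulate_darkness_trace <- function(truth, scene_label = "closed_eye",
                                    noise_sd_trace = 0.002,
                                    geometry = setup_geometry(),
                                    optics = scene_optics(), eyelid = eyelid_model(),
                                    roi_radius_px = 28) {
  v <- darkness_from_diameter(truth$diameter_mm, geometry, optics, eyelid,
                              roi_radius_px, scene_label)
  if (noise_sd_trace > 0) v <- v + rnorm(length(v), 0, noise_sd_trace)
  darkness_trace(truth$t_s, pmin(pmax(v, 0), 1), scene_label, truth$frame_rate_hz)
}
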