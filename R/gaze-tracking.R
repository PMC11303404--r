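# Pupil-position based gaze estimation in degrees of visual angle (DVA).
#
# Pupil centres (open eye: segmented pupil; closed eye: the dark circle
# visible through the lid) are expressed relative to the median position
# during central fixation, scaled to mm, and mapped to DVA with a per-axis
# proportional calibration ratio fitted against the geometric reference
# angles of the fixation targets. Accuracy is quantified per axis as MAE
# and tested against a segment-shuffle surrogate null.

#' Pupil centre from eight boundary points
#'
#' @param points an 8 x 2 matrix of (x, y) points on the pupil
#'   circumference.
#' @return (x, y) centre: the arithmetic mean of the coordinates.
#' @export
pupil_center_from_boundary <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 8 || ncol(points) != 2) stopf("exactly 8 boundary points required")
  if (any(!is.finite(points))) stopf("boundary points must be finite")
  colMeans(points)
}

#' Relative pupil positions in mm
#'
#' The (0, 0) origin is the per-axis median pupil-centre position over the
#' central-fixation frames; relative positions are origin-subtracted pixel
#' coordinates scaled by `px_per_mm`.
#'
#' @param centers_px data.frame or matrix with columns x, y (pixels).
#' @param central_fixation_frames indices of frames with central fixation.
#' @param px_per_mm image scale.
#' @return list(rel_mm = n x 2 matrix, origin_px = (x, y)).
#' @export
relative_positions <- function(centers_px, central_fixation_frames, px_per_mm) {
  centers_px <- as.matrix(centers_px)[, 1:2, drop = FALSE]
  if (!length(central_fixation_frames)) stopf("origin undefined: no central-fixation frames")
  origin <- c(median(centers_px[central_fixation_frames, 1], na.rm = TRUE),
              median(centers_px[central_fixation_frames, 2], na.rm = TRUE))
  rel <- sweep(centers_px, 2, origin) / px_per_mm
  colnames(rel) <- c("x_mm", "y_mm")
  list(rel_mm = rel, origin_px = origin)
}

#' Geometric reference angles of the fixation targets
#'
#' Per axis, theta = atan(offset / screen distance) in degrees.
#'
#' @param geometry a [setup_geometry()].
#' @return data.frame(dx_cm, dy_cm, theta_x_dva, theta_y_dva), one row per
#'   target.
#' @export
target_reference_angles <- function(geometry) {
  stopifnot(inherits(geometry, "setup_geometry"))
  tg <- geometry$target_offsets_cm
  data.frame(
    dx_cm = tg[, 1], dy_cm = tg[, 2],
    theta_x_dva = atan(tg[, 1] / geometry$screen_distance_cm) * 180 / pi,
    theta_y_dva = atan(tg[, 2] / geometry$screen_distance_cm) * 180 / pi
  )
}

#' Fit the per-axis mm-to-DVA calibration ratio
#'
#' Least-squares slope through the origin of the reference angle on the
#' per-target median relative position, independently per axis:
#' `ratio = sum(theta * mm) / sum(mm^2)`.
#'
#' @param target_rel_mm n_targets x 2 matrix of median relative positions.
#' @param target_angles_dva n_targets x 2 matrix (or data.frame with
#'   theta_x_dva, theta_y_dva) of reference angles.
#' @return c(dva_per_mm_x, dva_per_mm_y).
#' @export
fit_dva_ratio <- function(target_rel_mm, target_angles_dva) {
  target_rel_mm <- as.matrix(target_rel_mm)
  if (is.data.frame(target_angles_dva) || !is.null(colnames(target_angles_dva))) {
    ta <- as.data.frame(target_angles_dva)
    if (all(c("theta_x_dva", "theta_y_dva") %in% names(ta))) {
      target_angles_dva <- cbind(ta$theta_x_dva, ta$theta_y_dva)
    }
  }
  target_angles_dva <- as.matrix(target_angles_dva)
  ratio <- numeric(2)
  for (ax in 1:2) {
    mm <- target_rel_mm[, ax]; th <- target_angles_dva[, ax]
    ok <- is.finite(mm) & is.finite(th)
    if (sum(ok & mm != 0) < 1 || sum(abs(mm[ok])) == 0) {
      stopf("axis %d: no spread in target positions; ratio undefined", ax)
    }
    if (length(unique(th[ok])) < 2) stopf("axis %d: need >= 2 distinct target angles", ax)
    ratio[ax] <- sum(th[ok] * mm[ok]) / sum(mm[ok]^2)
  }
  names(ratio) <- c("dva_per_mm_x", "dva_per_mm_y")
  ratio
}

#' Per-axis gaze error
#'
#' Mean absolute per-axis difference between two aligned gaze traces,
#' typically open-eye ground truth vs the closed-eye estimate, restricted
#' by the caller to target-display frames.
#'
#' @param a,b n x 2 matrices (x, y), in mm or DVA.
#' @return c(mae_x, mae_y) in the input units.
#' @export
gaze_error <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stopf("gaze traces are misaligned (%dx%d vs %dx%d)",
                                    nrow(a), ncol(a), nrow(b), ncol(b))
  c(mae_x = mean(abs(a[, 1] - b[, 1]), na.rm = TRUE),
    mae_y = mean(abs(a[, 2] - b[, 2]), na.rm = TRUE))
}

#' Segment-shuffle surrogate test of gaze-tracking accuracy
#'
#' Compares the real open/closed MAE against the distribution of MAEs
#' obtained when the closed-eye trace is cut into non-overlapping segments
#' of one target-dwell length and permuted in time. The p-value uses the
#' add-one correction `p = (1 + #{surrogate <= real}) / (1 + n_shuffles)`,
#' which is super-uniform under the null by construction.
#'
#' @param open_trace,closed_trace n x 2 aligned gaze traces.
#' @param segment_len_s segment length (s); default one 5 s dwell.
#' @param n_shuffles number of random segment permutations.
#' @param seed integer seed.
#' @param frame_rate_hz sampling rate (Hz).
#' @return list(p, real_mae, surrogate_mae = vector of length n_shuffles,
#'   n_segments).
#' @export
surrogate_significance <- function(open_trace, closed_trace, segment_len_s = 5,
                                   n_shuffles = 10000, seed = 1L, frame_rate_hz = 31) {
  open_trace <- as.matrix(open_trace); closed_trace <- as.matrix(closed_trace)
  if (!all(dim(open_trace) == dim(closed_trace))) stopf("traces are misaligned")
  n <- nrow(open_trace)
  seg <- max(1L, as.integer(round(segment_len_s * frame_rate_hz)))
  n_seg <- n %/% seg
  if (n_seg < 2) stopf("traces too short: fewer than 2 segments of %g s", segment_len_s)
  use <- seq_len(n_seg * seg)
  ot <- open_trace[use, , drop = FALSE]
  ct <- closed_trace[use, , drop = FALSE]
  real <- mean(gaze_error(ot, ct))
  set.seed(seed)
  surr <- numeric(n_shuffles)
  within_seg <- seq_len(seg)
  for (k in seq_len(n_shuffles)) {
    perm <- sample.int(n_seg)
    idx <- rep((perm - 1L) * seg, each = seg) + within_seg
    surr[k] <- mean(gaze_error(ot, ct[idx, , drop = FALSE]))
  }
  list(p = (1 + sum(surr <= real)) / (1 + n_shuffles),
       real_mae = real, surrogate_mae = surr, n_segments = n_seg)
}

#' Pupil-centre trace from a frame stack
#'
#' Applies [segment_pupil()] per frame and returns the centres; works on
#' open-eye frames and on closed-eye frames (where the dark circle behind
#' the lid is segmented).
#'
#' @param stack a [frame_stack()].
#' @param threshold_quantile forwarded to [segment_pupil()]. Centre
#'   estimation defaults to the darkest 2% of pixels: the compact pupil
#'   core is insensitive to the brightness tilt that eyelid blur spreads
#'   across the pupil near the iris boundary, which biases centroids taken
#'   over looser thresholds.
#' @return n x 2 matrix of (x, y) centres in pixels (NA on failure).
#' @export
pupil_centers_from_stack <- function(stack, threshold_quantile = 0.02) {
  stopifnot(inherits(stack, "frame_stack"))
  T <- dim(stack$frames)[3]
  out <- matrix(NA_real_, T, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(T)) {
    fit <- tryCatch(segment_pupil(stack$frames[, , i], threshold_quantile),
                    error = function(e) NULL)
    if (!is.null(fit)) out[i, ] <- fit$center_px
  }
  out
}

#' Full gaze analysis of a synthetic fixation-grid session
#'
#' Segments pupil centres in the open- and closed-eye stacks, defines the
#' origin from central-target frames, fits the per-axis DVA ratio on the
#' open eye, converts both traces to DVA, and reports per-axis MAE (mm and
#' DVA) plus the surrogate p-value. Error statistics use only
#' target-display frames with the first `trim_s` of each dwell discarded
#' (gaze transitions).
#'
#' @param session output of [render_session()] for a gaze session.
#' @param trim_s seconds trimmed from the start of each dwell.
#' @param n_shuffles surrogate permutations.
#' @param seed surrogate seed.
#' @return list with calibration, per-axis errors, dva traces and the
#'   surrogate test.
#' @export
analyze_gaze_session <- function(session, trim_s = 0.5, n_shuffles = 10000, seed = 1L) {
  truth <- session$truth
  geometry <- session$config$geometry
  fs <- truth$frame_rate_hz
  centers_open <- pupil_centers_from_stack(session$open)
  centers_closed <- pupil_centers_from_stack(session$closed)
  ang <- target_reference_angles(geometry)
  central_target <- which(ang$dx_cm == 0 & ang$dy_cm == 0)[1]
  keep <- dwell_frames(truth, trim_s)
  central <- which(keep & !is.na(truth$target_idx) & truth$target_idx == central_target)
  if (!length(central)) stopf("origin undefined: no central-fixation frames in session")
  rel_open <- relative_positions(centers_open, central, geometry$px_per_mm)
  rel_closed <- relative_positions(centers_closed, central, geometry$px_per_mm)
  # per-target median open-eye positions
  tmed <- t(vapply(seq_len(nrow(ang)), function(k) {
    idx <- which(keep & !is.na(truth$target_idx) & truth$target_idx == k)
    c(median(rel_open$rel_mm[idx, 1], na.rm = TRUE),
      median(rel_open$rel_mm[idx, 2], na.rm = TRUE))
  }, numeric(2)))
  ratio <- fit_dva_ratio(tmed, ang)
  dva_open <- sweep(rel_open$rel_mm, 2, ratio, `*`)
  dva_closed <- sweep(rel_closed$rel_mm, 2, ratio, `*`)
  colnames(dva_open) <- colnames(dva_closed) <- c("x_dva", "y_dva")
  kf <- which(keep)
  err_mm <- gaze_error(rel_open$rel_mm[kf, ], rel_closed$rel_mm[kf, ])
  err_dva <- gaze_error(dva_open[kf, ], dva_closed[kf, ])
  surr <- surrogate_significance(dva_open[kf, ], dva_closed[kf, ],
                                 segment_len_s = session$config$dwell_s,
                                 n_shuffles = n_shuffles, seed = seed,
                                 frame_rate_hz = fs)
  list(
    calibration = list(origin_open_px = rel_open$origin_px,
                       origin_closed_px = rel_closed$origin_px,
                       px_per_mm = geometry$px_per_mm,
                       dva_per_mm_x = unname(ratio[1]), dva_per_mm_y = unname(ratio[2])),
    target_median_rel_mm = tmed, reference_angles = ang,
    mae_mm = err_mm, mae_dva = err_dva,
    dva_open = dva_open, dva_closed = dva_closed, frames_used = kf,
    surrogate = surr
  )
}

# Frames within a target dwell, excluding the first trim_s after each
# target switch.
dwell_frames <- function(truth, trim_s) {
  ti <- truth$target_idx
  keep <- !is.na(ti)
  if (trim_s > 0 && any(keep)) {
    code <- ifelse(is.na(ti), -1L, ti)
    switches <- which(c(TRUE, diff(code) != 0))
    for (s in switches) {
      drop <- truth$t_s >= truth$t_s[s] & truth$t_s < truth$t_s[s] + trim_s
      keep[drop] <- FALSE
    }
  }
  keep
}
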