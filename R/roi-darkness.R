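# Fixed-circle darkness measurement and movement-based session exclusion.
#
# The core measurement: pixel darkness (1 - intensity) averaged within a
# static circle covering pupil + iris. Pupil constriction shrinks the dark
# disk inside the circle and lowers the mean darkness, proxying pupil area
# without segmentation -- which is what makes the approach usable behind a
# closed eyelid.

#' Circular region of interest
#'
#' @param center_px (x, y) circle centre in 0-based pixel coordinates.
#' @param radius_px circle radius in pixels (> 0).
#' @param label scene the ROI belongs to.
#' @return A `circle_roi` object.
#' @export
circle_roi <- function(center_px, radius_px, label = c("closed_eye", "open_eye", "forehead")) {
  label <- match.arg(label)
  if (!is_scalar_num(radius_px) || radius_px <= 0) stopf("radius_px must be positive")
  if (length(center_px) != 2 || !all(is.finite(center_px))) stopf("center_px must be (x, y)")
  structure(list(center_px = as.numeric(center_px), radius_px = radius_px, label = label),
            class = "circle_roi")
}

# Logical membership mask: pixels whose centres lie within the radius.
# Errors if the circle is not fully inside the frame.
circle_mask <- function(dim_hw, roi) {
  H <- dim_hw[1]; W <- dim_hw[2]
  cx <- roi$center_px[1]; cy <- roi$center_px[2]; r <- roi$radius_px
  if (cx - r < -0.5 || cx + r > W - 0.5 || cy - r < -0.5 || cy + r > H - 0.5) {
    stopf("ROI (centre %.1f,%.1f radius %.1f) extends outside the %dx%d frame", cx, cy, r, H, W)
  }
  x <- matrix(0:(W - 1), H, W, byrow = TRUE)
  y <- matrix(0:(H - 1), H, W)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Darkness trace container
#'
#' @param t_s time axis (s).
#' @param values mean darkness per frame, in \[0, 1\].
#' @param roi_label label of the source ROI.
#' @param frame_rate_hz frame rate (Hz).
#' @return A `darkness_trace` object.
#' @export
darkness_trace <- function(t_s, values, roi_label, frame_rate_hz) {
  if (length(t_s) != length(values)) stopf("t_s and values must have equal length")
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1) {
    stopf("darkness values must be finite and lie in [0, 1]")
  }
  structure(list(t_s = t_s, values = values, roi_label = roi_label,
                 frame_rate_hz = frame_rate_hz),
            class = "darkness_trace")
}

#' Mean pixel darkness inside a circle
#'
#' Averages `1 - intensity` over the pixels whose centres lie within the
#' ROI. No anti-aliasing of partial border pixels is applied; values differ
#' from the continuous-area ideal by O(1/radius).
#'
#' @param frame intensity matrix in \[0, 1\].
#' @param roi a [circle_roi()] fully inside the frame.
#' @return mean darkness, a single number in \[0, 1\].
#' @export
mean_circle_darkness <- function(frame, roi) {
  m <- circle_mask(dim(frame), roi)
  mean(1 - frame[m])
}

#' Per-frame darkness time course of a stack
#'
#' @param stack a [frame_stack()].
#' @param roi a [circle_roi()].
#' @return A [darkness_trace()] with `t_s = frame_index / frame_rate_hz`.
#' @export
darkness_timeseries <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  m <- circle_mask(d[1:2], roi)
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  vals <- 1 - colMeans(flat[as.vector(m), , drop = FALSE])
  darkness_trace((seq_len(d[3]) - 1) / stack$frame_rate_hz, vals,
                 roi$label, stack$frame_rate_hz)
}

#' Horizontal movement statistic of a session (STDt)
#'
#' Sample standard deviation over time of the horizontal pupil-centre
#' coordinate (denominator n - 1).
#'
#' @param center_x_px per-frame horizontal pupil-centre positions.
#' @return STDt, a single number.
#' @export
horizontal_movement_std <- function(center_x_px) {
  if (!length(center_x_px)) stopf("empty position trace")
  if (any(!is.finite(center_x_px))) stopf("position trace contains non-finite values")
  if (length(center_x_px) == 1L) return(0)
  sd(center_x_px)
}

#' Movement-based session exclusion
#'
#' Sessions whose STDt exceeds `mean(stds) + 1 * sd(stds)` across sessions
#' are excluded (strict inequality, so identical sessions are all kept).
#'
#' @param stds per-session STDt values (>= 2 sessions).
#' @return list(include = logical vector, threshold = numeric).
#' @export
select_sessions <- function(stds) {
  if (length(stds) < 2) stopf("session exclusion needs at least 2 sessions")
  threshold <- mean(stds) + sd(stds)
  list(include = !(stds > threshold), threshold = threshold)
}

#' Darkest-circle search (experimental)
#'
#' Automatic closed-eye ROI placement: scans a grid of candidate centres
#' and returns the circle of the given radius with maximal mean darkness.
#' Intended as a fallback when no manual ROI is available; placement from
#' configuration/truth is preferred.
#'
#' @param frame intensity matrix.
#' @param radius_px circle radius.
#' @param stride_px grid step for candidate centres.
#' @param label label for the returned ROI.
#' @return A [circle_roi()] at the darkest grid position.
#' @export
find_dark_circle <- function(frame, radius_px, stride_px = 2,
                             label = "closed_eye") {
  H <- nrow(frame); W <- ncol(frame)
  cxs <- seq(ceiling(radius_px), floor(W - 1 - radius_px), by = stride_px)
  cys <- seq(ceiling(radius_px), floor(H - 1 - radius_px), by = stride_px)
  if (!length(cxs) || !length(cys)) stopf("radius too large for frame")
  best <- NULL; best_val <- -Inf
  for (cy in cys) for (cx in cxs) {
    roi <- circle_roi(c(cx, cy), radius_px, label)
    v <- mean_circle_darkness(frame, roi)
    if (v > best_val) { best_val <- v; best <- roi }
  }
  best
}
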