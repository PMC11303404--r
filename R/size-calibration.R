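# Open-eye pupil segmentation, pixel-to-mm scaling, and the linear
# darkness-to-diameter calibration.
#
# Segmentation is a classical percentile-threshold + largest-component
# localizer standing in for landmark tracking of the open-eye pupil; the
# calibration exploits the affine darkness-area relationship to express
# closed-eye darkness traces as pupil diameter in mm.

#' Segment the pupil in a single frame
#'
#' Thresholds the darkest pixels (percentile-based, robust to global
#' brightness), keeps the largest connected dark component, and returns its
#' centroid and equivalent-area diameter `2 * sqrt(area / pi)`.
#'
#' @param frame intensity matrix in \[0, 1\] containing one dark disk on a
#'   brighter surround.
#' @param threshold_quantile intensity quantile defining "dark" (default
#'   the 10th percentile).
#' @param min_area_px minimum component area in pixels.
#' @param px_per_mm optional scale; when given, `diameter_mm` is filled in.
#' @param method "quantile" thresholds at `threshold_quantile` (sharp
#'   frames whose pupil plateau is well separated from the surround);
#'   "midpoint" thresholds halfway between the pupil-core intensity (2nd
#'   percentile) and the iris level (25th percentile) -- the half-maximum
#'   contour, which stays meaningful on smooth reconstructed frames where
#'   a fixed pixel fraction would be an artifact.
#' @return A `pupil_fit`: list(center_px = (x, y), diameter_px,
#'   diameter_mm, area_px).
#' @export
segment_pupil <- function(frame, threshold_quantile = 0.1, min_area_px = 9,
                          px_per_mm = NULL, method = c("quantile", "midpoint")) {
  method <- match.arg(method)
  thr <- if (method == "midpoint") {
    mean(quantile(frame, c(0.02, 0.25), names = FALSE))
  } else {
    quantile(frame, threshold_quantile, names = FALSE)
  }
  dark <- frame < thr
  # noiseless renders can put the whole pupil plateau exactly at the
  # threshold value; fall back to closed comparison then
  if (!any(dark)) dark <- frame <= thr
  if (all(dark) || !any(dark)) stopf("darkness threshold does not separate a dark component")
  lab <- EBImage::bwlabel(dark * 1)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_area_px) {
    stopf("no dark component of at least %d px found", min_area_px)
  }
  biggest <- which.max(sizes)
  idx <- which(lab == biggest, arr.ind = TRUE)
  area <- nrow(idx)
  # arr.ind: row = y + 1, col = x + 1 (0-based pixel coordinates)
  center <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
  diameter_px <- 2 * sqrt(area / pi)
  structure(
    list(center_px = center, diameter_px = diameter_px,
         diameter_mm = if (is.null(px_per_mm)) NA_real_ else diameter_px / px_per_mm,
         area_px = area),
    class = "pupil_fit"
  )
}

#' Convert pixels to millimetres
#'
#' @param value_px value(s) in pixels.
#' @param px_per_mm image scale (> 0).
#' @return value(s) in mm.
#' @export
px_to_mm <- function(value_px, px_per_mm) {
  if (!is_scalar_num(px_per_mm) || px_per_mm <= 0) stopf("px_per_mm must be positive")
  value_px / px_per_mm
}

#' Fit the linear darkness-to-diameter calibration
#'
#' Ordinary least squares of `diameter ~ darkness` on aligned samples.
#' Typically both series are baseline-relative changes of the averaged PLR
#' event (see [calibrate_plr_session()]).
#'
#' @param darkness_trace numeric darkness values.
#' @param diameter_trace_mm aligned pupil diameters (mm).
#' @param min_samples minimum number of paired samples.
#' @return A `linear_calibration`: list(slope = mm per darkness unit,
#'   intercept = mm, r2_fit, n).
#' @export
fit_darkness_to_diameter <- function(darkness_trace, diameter_trace_mm, min_samples = 10) {
  if (length(darkness_trace) != length(diameter_trace_mm)) {
    stopf("darkness and diameter traces must be aligned and of equal length")
  }
  if (length(darkness_trace) < min_samples) stopf("calibration needs >= %d samples", min_samples)
  if (sd(darkness_trace) == 0 || sd(diameter_trace_mm) == 0) {
    stopf("degenerate (constant) trace; calibration undefined")
  }
  fit <- lm(diameter_trace_mm ~ darkness_trace)
  # suppressed: summary.lm warns on exactly collinear (noise-free) input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2_fit = r2, n = length(darkness_trace)),
    class = "linear_calibration"
  )
}

#' Apply a linear calibration to a darkness trace
#'
#' @param darkness values or a [darkness_trace()].
#' @param calib a `linear_calibration`.
#' @return pupil diameter trace in mm (numeric vector).
#' @export
apply_calibration <- function(darkness, calib) {
  stopifnot(inherits(calib, "linear_calibration"))
  v <- if (inherits(darkness, "darkness_trace")) darkness$values else as.numeric(darkness)
  calib$slope * v + calib$intercept
}

#' Calibrate a PLR session: darkness to diameter on the averaged event
#'
#' Fits the darkness-to-diameter map on baseline-relative averaged PLR
#' events: the (preprocessed) closed-eye darkness trace and the reference
#' diameter trace are epoched at the stimulus onsets, averaged across
#' trials, baseline-subtracted, and regressed. With `averaged = FALSE` the
#' concatenated baseline-subtracted epochs are used instead.
#'
#' @param darkness a [darkness_trace()] (closed-eye, preprocessed).
#' @param diameter_mm reference pupil diameter trace (mm), same sampling.
#' @param onsets_s stimulus onsets (s).
#' @param averaged fit on the trial-averaged event (default) or on
#'   concatenated trials.
#' @param window_s epoch window.
#' @return list(calib = `linear_calibration`,
#'   baseline_diameter_mm = mean pre-stimulus diameter, onsets_used).
#' @export
calibrate_plr_session <- function(darkness, diameter_mm, onsets_s,
                                  averaged = TRUE, window_s = c(-2, 18)) {
  ed <- epoch_events(darkness, onsets_s, window_s)
  ep <- epoch_events(diameter_mm, onsets_s, window_s, frame_rate_hz = darkness$frame_rate_hz)
  bsl <- ed$t_s >= -2 & ed$t_s < 0
  if (averaged) {
    dk <- baseline_normalize(colMeans(ed$data), ed$t_s)
    di <- baseline_normalize(colMeans(ep$data), ep$t_s)
  } else {
    dk <- as.vector(t(ed$data - rowMeans(ed$data[, bsl, drop = FALSE])))
    di <- as.vector(t(ep$data - rowMeans(ep$data[, bsl, drop = FALSE])))
  }
  calib <- fit_darkness_to_diameter(dk, di)
  list(calib = calib,
       baseline_diameter_mm = mean(ep$data[, bsl]),
       onsets_used = ed$onsets_used)
}

#' Pupil diameter time course from an open-eye stack
#'
#' Applies [segment_pupil()] frame by frame.
#'
#' @param stack a [frame_stack()].
#' @param px_per_mm image scale.
#' @param threshold_quantile,method forwarded to [segment_pupil()].
#' @return data.frame(t_s, x_px, y_px, diameter_px, diameter_mm); frames
#'   where segmentation fails carry NA.
#' @export
pupil_trace_from_stack <- function(stack, px_per_mm, threshold_quantile = 0.1,
                                   method = "quantile") {
  stopifnot(inherits(stack, "frame_stack"))
  T <- dim(stack$frames)[3]
  out <- data.frame(t_s = (seq_len(T) - 1) / stack$frame_rate_hz,
                    x_px = NA_real_, y_px = NA_real_,
                    diameter_px = NA_real_, diameter_mm = NA_real_)
  for (i in seq_len(T)) {
    fit <- tryCatch(segment_pupil(stack$frames[, , i], threshold_quantile,
                                  px_per_mm = px_per_mm, method = method),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      out$x_px[i] <- fit$center_px[1]; out$y_px[i] <- fit$center_px[2]
      out$diameter_px[i] <- fit$diameter_px; out$diameter_mm[i] <- fit$diameter_mm
    }
  }
  out
}
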