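# End-to-end PLR analysis of one session: fixed-circle darkness in the
# three regions of interest, blink removal and filtering, stimulus-locked
# epoching, the robust-PLR criterion, open/closed concordance, and the
# darkness-to-diameter calibration.

#' Default ROIs of a rendered session
#'
#' One circle over pupil + iris of the (shared) eye position for the open
#' and closed scenes, and one control circle at the forehead-frame centre.
#'
#' @param session a rendered session from [render_session()].
#' @param roi_radius_px circle radius; the default covers pupil and iris at
#'   the default optics.
#' @return named list of [circle_roi()]s: open, closed, forehead.
#' @export
session_rois <- function(session, roi_radius_px = 28) {
  ec <- session$config$optics$eye_center_px
  list(
    open = circle_roi(ec, roi_radius_px, "open_eye"),
    closed = circle_roi(ec, roi_radius_px, "closed_eye"),
    forehead = circle_roi(ec, roi_radius_px, "forehead")
  )
}

#' Full PLR analysis of a session
#'
#' Runs the fixed-circle pipeline on the three scenes: darkness time
#' courses, blink removal + 1 Hz zero-phase filtering, epoching (-2 to
#' +18 s), the robust-PLR test on the closed-eye ROI, concordance between
#' the open- and closed-eye average events, and (when ground truth is
#' available) the darkness-to-diameter calibration fitted on the averaged
#' closed-eye event.
#'
#' @param session a rendered session from [render_session()].
#' @param roi_radius_px ROI radius in pixels.
#' @param rois optional named list (open, closed, forehead) overriding
#'   [session_rois()].
#' @return list with traces, epochs, averages, robust test, concordance,
#'   calibration and a tidy per-statistic summary data.frame.
#' @export
analyze_plr_session <- function(session, roi_radius_px = 28, rois = NULL) {
  if (session$config$experiment != "plr") stopf("not a PLR session")
  rois <- rois %||% session_rois(session, roi_radius_px)
  onsets <- session$config$schedule$onsets_s
  stacks <- list(open = session$open, closed = session$closed, forehead = session$forehead)
  traces <- cleaned <- epochs <- avgs <- list()
  for (nm in names(stacks)) {
    traces[[nm]] <- darkness_timeseries(stacks[[nm]], rois[[nm]])
    cleaned[[nm]] <- preprocess_trace(traces[[nm]])$trace
    epochs[[nm]] <- epoch_events(cleaned[[nm]], onsets)
    ep <- epochs[[nm]]
    ep$data <- t(apply(ep$data, 1, baseline_normalize, t_s = ep$t_s))
    epochs[[nm]] <- ep
    avgs[[nm]] <- average_response(ep)
  }
  robust <- robust_plr_test(epochs$closed)
  concordance <- trace_correlation(avgs$open$mean, avgs$closed$mean)
  calib <- NULL
  if (!is.null(session$truth$diameter_mm)) {
    calib <- calibrate_plr_session(cleaned$closed, session$truth$diameter_mm, onsets)
  }
  summary <- data.frame(
    roi = c("closed_eye", "closed_eye", "open_vs_closed", "open_vs_closed", "open_vs_closed"),
    statistic = c("robust_plr_p", "is_robust", "pearson_r", "r_squared", "fisher_z"),
    value = c(robust$p_value, as.numeric(robust$is_robust),
              concordance$r, concordance$r2, concordance$fisher_z)
  )
  if (!is.null(calib)) {
    summary <- rbind(summary, data.frame(
      roi = "closed_eye", statistic = c("calib_slope_mm", "calib_intercept_mm", "calib_r2"),
      value = c(calib$calib$slope, calib$calib$intercept, calib$calib$r2_fit)
    ))
  }
  list(traces = traces, cleaned = cleaned, epochs = epochs, averages = avgs,
       robust = robust, concordance = concordance,
       calibration_fit = if (is.null(calib)) NULL else calib$calib,
       calibration = calib, summary = summary)
}
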