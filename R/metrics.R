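# The two indirect pressurization metrics. FLEF interrogates bulk flow at
# the entry tear; MSDR interrogates the deceleration of the proximal FL
# velocity envelope.

#' False lumen ejection fraction (FLEF)
#'
#' FLEF = 100 x (retrograde flow volume at the entry tear during diastole) /
#' (antegrade flow volume over the full cycle). A surrogate of FL
#' pressurization: diastolic reversal at the tear happens when FL diastolic
#' pressure exceeds TL pressure.
#'
#' @param field a [velocity_field].
#' @param tear_plane an [analysis_plane] at the dominant entry tear with a
#'   region of interest restricted to the tear cross-section.
#' @param phases a [cardiac_phases]; when `NULL`, detected from the tear
#'   trace itself.
#' @return list of class `flef_result`: `flef_pct`, `antegrade_ml`,
#'   `retrograde_diastolic_ml`, `plane_id`, `phases`, `trace`.
#'   Errors (rather than returning 0) when the antegrade volume vanishes:
#'   FLEF is undefined, which is distinct from a true absence of reversal.
#' @export
compute_flef <- function(field, tear_plane, phases = NULL) {
  trace <- compute_flow_trace(field, tear_plane)
  if (is.null(phases)) phases <- detect_cardiac_phases(trace)
  vols <- antegrade_retrograde_volumes(trace, phases)
  if (vols$antegrade_ml <= 0)
    stop("antegrade volume is zero: FLEF undefined (measurement failure, ",
         "not FLEF = 0)")
  structure(list(flef_pct = 100 * vols$retrograde_diastolic_ml /
                   vols$antegrade_ml,
                 antegrade_ml = vols$antegrade_ml,
                 retrograde_diastolic_ml = vols$retrograde_diastolic_ml,
                 plane_id = tear_plane$id, phases = phases, trace = trace),
            class = "flef_result")
}

#' @export
print.flef_result <- function(x, ...) {
  cat(sprintf(
    "FLEF = %.1f%%  (antegrade %.2f ml, diastolic retrograde %.2f ml)\n",
    x$flef_pct, x$antegrade_ml, x$retrograde_diastolic_ml))
  invisible(x)
}

#' Maximum systolic deceleration rate (MSDR)
#'
#' The absolute difference between the maximum and minimum acceleration of
#' the subsection mean speed during systole, divided by the time between
#' those extrema (cm/s^3). Larger values indicate more abrupt systolic
#' deceleration, consistent with a pressurized, high-resistance FL.
#'
#' @param trace an `acceleration_trace` with the acceleration filled (see
#'   [mean_speed_trace] and [differentiate_trace]).
#' @param phases a [cardiac_phases]; systole must contain at least 3 frames.
#' @return list of class `msdr_result`: `msdr_cm_s3`, `a_max`, `a_min`,
#'   their times, `degenerate` flag, `subsection_id`. When the acceleration
#'   is constant over systole the result is 0 with `degenerate = TRUE`.
#'   A warning is emitted when peak deceleration precedes peak acceleration.
#' @export
compute_msdr <- function(trace, phases) {
  a <- trace$acceleration_cm_s2
  if (anyNA(a)) stop("acceleration not computed; run differentiate_trace()")
  sys <- phases$systole
  if (length(sys) < 3) stop("systole too short (< 3 frames) for MSDR")
  a_s <- a[sys]
  i_max <- sys[which.max(a_s)]
  i_min <- sys[which.min(a_s)]
  t_max <- trace$time_s[i_max]
  t_min <- trace$time_s[i_min]
  degenerate <- i_max == i_min
  msdr <- if (degenerate) 0 else
    abs(a[i_max] - a[i_min]) / abs(t_min - t_max)
  if (!degenerate && t_min < t_max)
    warning("peak deceleration precedes peak acceleration in systole")
  structure(list(msdr_cm_s3 = msdr,
                 a_max_cm_s2 = a[i_max], t_a_max_s = t_max,
                 a_min_cm_s2 = a[i_min], t_a_min_s = t_min,
                 degenerate = degenerate,
                 subsection_id = trace$subsection_id),
            class = "msdr_result")
}

#' @export
print.msdr_result <- function(x, ...) {
  cat(sprintf(
    "MSDR = %.0f cm/s^3  (a_max %.1f at %.3f s, a_min %.1f at %.3f s)%s\n",
    x$msdr_cm_s3, x$a_max_cm_s2, x$t_a_max_s, x$a_min_cm_s2, x$t_a_min_s,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
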