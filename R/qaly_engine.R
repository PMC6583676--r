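#' QALY change by the trapezoidal area-under-the-curve method
#'
#' Integrates the utility-change trajectory of one arm up to the horizon:
#' the sum over grid intervals of `0.5 * (delta_prev + delta_curr) *
#' width_years`, with the change at the origin equal to 0. Because the
#' integrand is the change from baseline (not the absolute utility), the
#' result is the QALY gain relative to a flat baseline and can be negative;
#' see [qaly_auc_absolute()] for the absolute-utility area.
#'
#' @param trajectory A `cea_trajectory` from [build_trajectory()].
#' @param horizon_months Horizon; must be one of the trajectory's grid points.
#' @param arm `"active"` or `"placebo"`.
#' @return QALY change (years, double precision).
#' @export
qaly_auc <- function(trajectory, horizon_months, arm = c("active", "placebo")) {
  arm <- match.arg(arm)
  stopifnot(inherits(trajectory, "cea_trajectory"))
  idx <- match(horizon_months, trajectory$t_months)
  if (is.na(idx))
    stop("horizon ", horizon_months, " months is not a grid point (grid: ",
         paste(trajectory$t_months[-1], collapse = ", "), ")")
  d <- trajectory[[paste0("delta_", arm)]]
  w <- trajectory$width_years
  if (idx == 1L) return(0)
  sum(0.5 * (d[2:idx] + d[1:(idx - 1L)]) * w[2:idx])
}

#' QALY changes for both arms at every grid horizon
#'
#' @param trajectory A `cea_trajectory`.
#' @return Data frame with one row per non-origin grid point: `t_months`,
#'   `qaly_active`, `qaly_placebo`, `incremental_qaly`.
#' @export
qaly_table <- function(trajectory) {
  horizons <- trajectory$t_months[-1]
  qa <- vapply(horizons, function(h) qaly_auc(trajectory, h, "active"), numeric(1))
  qp <- vapply(horizons, function(h) qaly_auc(trajectory, h, "placebo"), numeric(1))
  data.frame(t_months = horizons, qaly_active = qa, qaly_placebo = qp,
             incremental_qaly = qa - qp)
}

#' Absolute-utility area under the curve
#'
#' Trapezoidal area under a sequence of absolute utility values at given
#' times. Provided for completeness; the cost-effectiveness pipeline works on
#' utility *changes* via [qaly_auc()].
#'
#' @param times_years Increasing numeric vector of times in years.
#' @param utilities Utility values at those times.
#' @return Area in QALYs.
#' @export
qaly_auc_absolute <- function(times_years, utilities) {
  stopifnot(length(times_years) == length(utilities), length(times_years) >= 2,
            all(diff(times_years) > 0))
  sum(0.5 * (utilities[-1] + utilities[-length(utilities)]) * diff(times_years))
}
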