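# Year fractions between grid points are truncated (not rounded) at two
# decimals: 2 months -> 0.16 y, 1 month -> 0.08 y, 3 months -> 0.25 y. This
# is the only convention that reproduces the published QALY tables exactly;
# exact twelfths are available via year_fraction = "exact". The small epsilon
# guards against 16.999... style floating-point representations.
trunc2 <- function(x) trunc(x * 100 + 1e-9) / 100

#' Pool per-study utility changes at one time point
#'
#' In the main mode, the pooled change at `t_months` is the sample-size
#' weighted mean of the utility changes of the studies whose duration is
#' exactly `t_months` (weights are total study N). In the sensitivity mode,
#' every study at least `t_months` long contributes its change prorated by
#' the exact fraction `t_months / duration_months` (a 36-month study
#' contributes 3/36 of its effect at month 3); studies shorter than
#' `t_months` are excluded.
#'
#' @param studies A [study_table] (already restricted to one formulation
#'   class if that is the comparison of interest).
#' @param t_months Time point in months.
#' @param mode `"main"` or `"sensitivity"`.
#' @return Named vector `c(delta_active, delta_placebo)` with attributes
#'   `study_id` and `weight` (weights sum to 1).
#' @export
pooled_change <- function(studies, t_months, mode = c("main", "sensitivity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(studies, "study_table"), t_months >= 1)
  if (mode == "main") {
    elig <- studies$duration_months == t_months
    frac <- rep(1, sum(elig))
  } else {
    elig <- studies$duration_months >= t_months
    frac <- t_months / studies$duration_months[elig]
  }
  if (!any(elig))
    stop("no eligible study at t = ", t_months, " months (available durations: ",
         paste(sort(unique(studies$duration_months)), collapse = ", "), ")")
  s <- studies[elig, , drop = FALSE]
  w <- s$n / sum(s$n)
  out <- c(delta_active = sum(w * s$delta_active * frac),
           delta_placebo = sum(w * s$delta_placebo * frac))
  attr(out, "study_id") <- s$study_id
  attr(out, "weight") <- w
  out
}

#' Build a pooled utility-change trajectory over a time grid
#'
#' Prepends the implicit origin (t = 0, change 0) and evaluates
#' [pooled_change()] at every grid point. Each interval's width in years is
#' the two-decimal truncation of `(t_k - t_{k-1}) / 12` (or the exact
#' fraction with `year_fraction = "exact"`).
#'
#' @param studies A [study_table].
#' @param grid Increasing integer vector of months; defaults to the sorted
#'   distinct study durations.
#' @param mode `"main"` or `"sensitivity"`.
#' @param year_fraction `"trunc2"` (default) or `"exact"`.
#' @return Data frame of class `cea_trajectory` with columns `t_months`,
#'   `width_years`, `delta_active`, `delta_placebo`; attribute `mode`.
#' @export
build_trajectory <- function(studies, grid = NULL,
                             mode = c("main", "sensitivity"),
                             year_fraction = c("trunc2", "exact")) {
  mode <- match.arg(mode)
  year_fraction <- match.arg(year_fraction)
  if (is.null(grid)) grid <- sort(unique(studies$duration_months))
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  deltas <- lapply(grid, function(t) {
    tryCatch(pooled_change(studies, t, mode),
             error = function(e)
               stop("grid point t = ", t, ": ", conditionMessage(e)))
  })
  widths <- diff(c(0, grid)) / 12
  if (year_fraction == "trunc2") widths <- trunc2(widths)
  out <- data.frame(
    t_months = c(0, grid),
    width_years = c(0, widths),
    delta_active = c(0, vapply(deltas, `[[`, numeric(1), "delta_active")),
    delta_placebo = c(0, vapply(deltas, `[[`, numeric(1), "delta_placebo")))
  attr(out, "mode") <- mode
  attr(out, "year_fraction") <- year_fraction
  attr(out, "contributions") <- lapply(deltas, function(d)
    data.frame(study_id = attr(d, "study_id"), weight = attr(d, "weight")))
  class(out) <- c("cea_trajectory", "data.frame")
  out
}
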