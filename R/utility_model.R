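#' Utility regression coefficients
#'
#' The health-utility score of a simulated patient is a linear function of
#' the five clinical variables plus a female indicator (fixed at 1 here, as
#' the simulated populations are treated as female):
#' `utility = intercept + b_pain*pain + b_function*function + b_stiffness*stiffness
#'  + b_age*age + b_years*years_since_oa + b_female*female`.
#' The coefficient values come from an external utility-mapping regression
#' and are supplied as a configuration profile; the package does not
#' re-estimate them. The bundled profile
#' (`inst/extdata/utility_profile_synthetic.yaml`) is a clearly-labelled
#' synthetic placeholder with plausible signs and magnitudes, intended for
#' tests and synthetic trials only.
#'
#' @param intercept,pain,womac_function,stiffness,age,years_since_oa,female
#'   Finite regression coefficients (`womac_function` multiplies the WOMAC
#'   function subscale).
#' @param source Free-text label recording where the values came from.
#' @return Named numeric vector of class `utility_coefficients`.
#' @export
utility_coefficients <- function(intercept, pain, womac_function, stiffness,
                                 age, years_since_oa, female = 0,
                                 source = "user") {
  vals <- c(intercept = intercept, pain = pain, "function" = womac_function,
            stiffness = stiffness, age = age, years_since_oa = years_since_oa,
            female = female)
  missing_terms <- names(vals)[!vapply(vals, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(missing_terms) > 0L)
    stop("unset or non-finite coefficient(s): ",
         paste(missing_terms, collapse = ", "))
  structure(vals, source = source, class = "utility_coefficients")
}

#' Read a utility-coefficient profile from YAML
#'
#' @param path Path to a YAML file with keys `intercept`, `pain`, `function`,
#'   `stiffness`, `age`, `years_since_oa`, `female` and optionally `source`.
#'   The name of a bundled profile (currently `"synthetic"`) is also accepted.
#' @return A [utility_coefficients] object.
#' @export
read_utility_profile <- function(path = "synthetic") {
  if (!file.exists(path)) {
    bundled <- system.file("extdata",
                           paste0("utility_profile_", path, ".yaml"),
                           package = "aggcea")
    if (!nzchar(bundled)) stop("utility profile not found: ", path)
    path <- bundled
  }
  cfg <- yaml::read_yaml(path)
  need <- c("intercept", "pain", "function", "stiffness", "age",
            "years_since_oa", "female")
  missing_terms <- setdiff(need, names(cfg))
  if (length(missing_terms) > 0L)
    stop("utility profile is missing term(s): ",
         paste(missing_terms, collapse = ", "))
  utility_coefficients(intercept = cfg$intercept, pain = cfg$pain,
                       womac_function = cfg[["function"]],
                       stiffness = cfg$stiffness, age = cfg$age,
                       years_since_oa = cfg$years_since_oa,
                       female = cfg$female,
                       source = if (is.null(cfg$source)) path else cfg$source)
}

#' Compute health-utility scores for patient records
#'
#' Applies the linear utility equation to each record. Utilities are raw
#' regression outputs and are deliberately not clamped to \[0, 1\]; pass
#' `clamp = TRUE` to clamp. A diagnostic warning (not an error) is raised
#' when any utility leaves the plausible \[-0.5, 1\] band.
#'
#' @param records Data frame with the five clinical-variable columns and
#'   optionally `female` (defaults to 1).
#' @param coef A [utility_coefficients] object.
#' @param clamp Clamp utilities into \[0, 1\].
#' @return Numeric vector of utilities, one per record.
#' @export
compute_utility <- function(records, coef, clamp = FALSE) {
  stopifnot(inherits(coef, "utility_coefficients"))
  missing_cols <- setdiff(CEA_VARS, names(records))
  if (length(missing_cols) > 0L)
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "))
  female <- if ("female" %in% names(records)) records[["female"]] else 1
  u <- rep(coef[["intercept"]], nrow(records)) + coef[["female"]] * female
  for (v in CEA_VARS) u <- u + coef[[v]] * records[[v]]
  if (any(u < -0.5 | u > 1))
    warning("some utilities fall outside the plausible [-0.5, 1] band")
  if (clamp) u <- pmin(pmax(u, 0), 1)
  u
}

#' Mean utility change between two visits
#'
#' @param baseline,endpoint Record data frames for the two visits (need not
#'   be paired; only the means enter).
#' @param coef A [utility_coefficients] object.
#' @return `mean(utility(endpoint)) - mean(utility(baseline))`.
#' @export
summarize_change <- function(baseline, endpoint, coef) {
  if (nrow(baseline) == 0L || nrow(endpoint) == 0L)
    stop("baseline and endpoint record collections must be non-empty")
  mean(compute_utility(endpoint, coef)) - mean(compute_utility(baseline, coef))
}
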