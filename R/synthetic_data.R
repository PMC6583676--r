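#' Specify a synthetic trial with known ground truth
#'
#' A truth specification fixes, per arm and visit, the true means and SDs of
#' the five clinical variables, a shared cross-sectional correlation matrix,
#' the true utility coefficients, the per-arm sample size, the trial
#' duration, and a seed. Baseline and endpoint are generated as two
#' correlated visits: the same-variable correlation across visits defaults
#' to 0.6 so that change scores have realistic (non-degenerate) variance.
#' The default means and SDs emulate moderate knee osteoarthritis (baseline
#' pain 10 +/- 3 on the 0-20 subscale, function 30 +/- 10, stiffness
#' 4 +/- 1.5, age 62 +/- 8, 6 +/- 2 years since diagnosis) with a modest
#' active-arm improvement; every value is configurable and none is a claim
#' about any real trial.
#'
#' @param n_per_arm Patients per arm (>= 2).
#' @param duration_months Trial duration.
#' @param means_baseline True baseline means (both arms).
#' @param improvement_active,improvement_placebo Mean change from baseline to
#'   endpoint per arm (subtracted from the baseline means; age is kept fixed
#'   and years since OA advances by the trial duration).
#' @param sds True SDs (both visits).
#' @param corr Cross-sectional 5x5 correlation matrix.
#' @param within_correlation Same-variable baseline-endpoint correlation.
#' @param coef True [utility_coefficients].
#' @param formulation Formulation label for the emitted study row.
#' @param study_id Identifier for the emitted study row.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of class `truth_spec`.
#' @export
truth_spec <- function(n_per_arm = 10000, duration_months = 6,
                       means_baseline = c(10, 30, 4, 62, 6),
                       improvement_active = c(2.5, 7, 0.8, 0, 0),
                       improvement_placebo = c(1, 3, 0.3, 0, 0),
                       sds = c(3, 10, 1.5, 8, 2),
                       corr = default_corr(),
                       within_correlation = 0.6,
                       coef = read_utility_profile("synthetic"),
                       formulation = "pCGS",
                       study_id = "synthetic-trial",
                       seed = 1) {
  stopifnot(n_per_arm >= 2, duration_months >= 1,
            abs(within_correlation) < 1, inherits(coef, "utility_coefficients"))
  means_baseline <- as_var_vector(means_baseline, "means_baseline")
  sds <- as_var_vector(sds, "sds")
  corr <- as_corr_matrix(corr)
  mk_endpoint <- function(impr) {
    m <- means_baseline - as_var_vector(impr, "improvement")
    m["age"] <- means_baseline["age"]
    m["years_since_oa"] <- means_baseline["years_since_oa"] + duration_months / 12
    m
  }
  arms <- list(
    active = list(baseline = means_baseline,
                  endpoint = mk_endpoint(improvement_active)),
    placebo = list(baseline = means_baseline,
                   endpoint = mk_endpoint(improvement_placebo)))
  structure(list(arms = arms, sds = sds, corr = corr,
                 within_correlation = within_correlation, coef = coef,
                 n_per_arm = as.integer(n_per_arm),
                 duration_months = as.integer(duration_months),
                 formulation = formulation, study_id = study_id,
                 seed = as.integer(seed)),
            class = "truth_spec")
}

#' Generate a synthetic trial with ground truth
#'
#' Draws, per arm, `n_per_arm` paired baseline/endpoint vectors from the
#' 10-dimensional normal implied by the spec (covariance
#' `D (K kron R) D` with `K` the 2x2 visit-correlation matrix and `R` the
#' cross-sectional correlation), rejecting any patient whose vector leaves
#' the permissible ranges at either visit. True utilities are attached via
#' the spec's coefficients; per-visit aggregates are computed from the
#' generated records; the emitted study row carries the true mean utility
#' changes. Identical seeds give identical output.
#'
#' @param spec A [truth_spec].
#' @param ranges A [permissible_ranges] matrix.
#' @return List with `ipd` (long data frame: `arm`, `visit`, `patient_id`,
#'   clinical variables, `female`, `utility`), `aggregates` (nested list
#'   `aggregates[[arm]][[visit]]` of [arm_aggregate]s computed from the
#'   generated records) and `study` (a one-row [study_table] with the true
#'   per-arm utility changes).
#' @export
generate_trial <- function(spec, ranges = permissible_ranges()) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(spec$seed)
  k <- length(CEA_VARS)
  K <- matrix(c(1, spec$within_correlation, spec$within_correlation, 1), 2)
  R2 <- kronecker(K, spec$corr)
  D <- diag(rep(spec$sds, 2))
  sigma <- D %*% R2 %*% D
  lower <- rep(ranges[, "lower"], 2)
  upper <- rep(ranges[, "upper"], 2)

  ipd <- list()
  aggregates <- list()
  deltas <- c(active = NA_real_, placebo = NA_real_)
  for (arm in c("active", "placebo")) {
    mu <- c(spec$arms[[arm]]$baseline, spec$arms[[arm]]$endpoint)
    res <- rejection_sample(spec$n_per_arm, mu, sigma, lower, upper)
    per_visit <- list(baseline = res$values[, 1:k, drop = FALSE],
                      endpoint = res$values[, k + 1:k, drop = FALSE])
    for (visit in names(per_visit)) {
      m <- per_visit[[visit]]
      colnames(m) <- CEA_VARS
      df <- as.data.frame(m)
      df$female <- 1
      df$utility <- compute_utility(df, spec$coef)
      df <- cbind(arm = arm, visit = visit,
                  patient_id = seq_len(nrow(df)), df)
      ipd[[length(ipd) + 1L]] <- df
      aggregates[[arm]][[visit]] <- arm_aggregate(
        means = colMeans(m),
        sds = apply(m, 2, stats::sd),
        corr = regularize_sample_corr(m),
        n = nrow(m), visit = visit)
    }
    deltas[arm] <- mean(ipd[[length(ipd)]]$utility) -
      mean(ipd[[length(ipd) - 1L]]$utility)
  }

  study <- study_table(data.frame(
    study_id = spec$study_id, formulation = spec$formulation,
    n = 2L * spec$n_per_arm, duration_months = spec$duration_months,
    delta_active = deltas[["active"]], delta_placebo = deltas[["placebo"]]))
  list(ipd = do.call(rbind, ipd), aggregates = aggregates, study = study)
}

# Sample correlation of degenerate (zero-variance) columns is undefined;
# report the identity pattern there so the aggregate stays a valid
# correlation matrix.
regularize_sample_corr <- function(m) {
  s <- apply(m, 2, stats::sd)
  r <- diag(ncol(m))
  ok <- s > 0
  if (sum(ok) > 1L) r[ok, ok] <- stats::cor(m[, ok, drop = FALSE])
  dimnames(r) <- list(colnames(m), colnames(m))
  r
}
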