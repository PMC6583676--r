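# Shared generators and independent oracles for the test suite.

vars5 <- c("pain", "function", "stiffness", "age", "years_since_oa")

# Random positive-definite correlation matrix via a Gram construction.
rand_corr <- function(k = 5) {
  a <- matrix(rnorm(k * k), k)
  stats::cov2cor(crossprod(a) + diag(k))
}

# Deterministic non-trivial correlation matrix for recovery tests.
rand_corr_fixed <- function() {
  r <- diag(5)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 0.4
  r[2, 3] <- r[3, 2] <- 0.45
  r[4, 5] <- r[5, 4] <- 0.3
  r[1, 4] <- r[4, 1] <- 0.1
  r
}

# Random complete aggregate with means comfortably inside the permissible
# boxes so rejection rates stay high.
rand_aggregate <- function(n = 500, visit = "baseline") {
  arm_aggregate(
    means = c(runif(1, 8, 12), runif(1, 25, 35), runif(1, 3.5, 4.5),
              runif(1, 55, 70), runif(1, 4, 8)),
    sds = c(runif(1, 2, 3), runif(1, 7, 10), runif(1, 1, 1.4),
            runif(1, 6, 9), runif(1, 1.5, 2.5)),
    corr = rand_corr(), n = n, visit = visit)
}

# Random utility-change trajectory (as build_trajectory() would emit).
rand_trajectory <- function(max_points = 5) {
  k <- sample(2:max_points, 1)
  grid <- sort(sample(1:40, k))
  tr <- data.frame(
    t_months = c(0, grid),
    width_years = c(0, trunc(diff(c(0, grid)) / 12 * 100 + 1e-9) / 100),
    delta_active = c(0, runif(k, -0.2, 0.2)),
    delta_placebo = c(0, runif(k, -0.2, 0.2)))
  attr(tr, "mode") <- "main"
  class(tr) <- c("cea_trajectory", "data.frame")
  tr
}

# Fine-grid trapezoid integration of the piecewise-linear interpolant of a
# trajectory arm, on the cumulative width axis -- the independent oracle for
# qaly_auc().
oracle_auc <- function(trajectory, horizon_months, arm, step = 1e-5) {
  idx <- match(horizon_months, trajectory$t_months)
  x <- cumsum(trajectory$width_years[seq_len(idx)])
  y <- trajectory[[paste0("delta_", arm)]][seq_len(idx)]
  if (idx == 1L || max(x) == 0) return(0)
  xo <- sort(unique(c(seq(0, max(x), by = step), x)))
  yo <- approx(x, y, xout = xo)$y
  sum(0.5 * (yo[-1] + yo[-length(yo)]) * diff(xo))
}

# Brute-force one-dimensional rejection sampling oracle for truncated-normal
# marginal means.
oracle_trunc_mean <- function(mean, sd, lower, upper, n_draws = 1e6) {
  x <- rnorm(n_draws, mean, sd)
  x <- x[x >= lower & x <= upper]
  c(mean = mean(x), se = sd(x) / sqrt(length(x)), n = length(x))
}

# Hand-computed sample-size-weighted mean of per-study changes.
oracle_weighted <- function(n, delta, frac = 1) sum(n * delta * frac) / sum(n)

# The bundled ten-trial utility-change table, transcribed independently of
# the package reader so fixture regressions are caught.
reference_studies <- function() {
  data.frame(
    study_id = c("Giordano", "Herrero-Beaumont", "Reginster", "Pavelka",
                 "Houpt", "McAlindon", "Frestedt", "Chopra", "Cibere", "Clegg"),
    formulation = rep(c("pCGS", "other_glucosamine"), c(4, 6)),
    n = c(60, 210, 212, 202, 101, 205, 35, 70, 137, 630),
    duration_months = c(3, 6, 36, 36, 2, 3, 3, 3, 6, 6),
    delta_active = c(0.135, 0.0785, 0.1606, 0.0487, 0.0293, -0.0465,
                     0.1629, 0.0016, 0.0096, 0.0242),
    delta_placebo = c(-0.0742, 0.0315, 0.1427, 0.0207, 0.0129, -0.0339,
                      0.0613, 0.1232, 0.0006, 0.0383),
    stringsAsFactors = FALSE)
}

# Synthetic utility coefficients used across tests (same values as the
# bundled placeholder profile).
test_coef <- function() {
  utility_coefficients(intercept = 0.85, pain = -0.012,
                       womac_function = -0.004, stiffness = -0.008,
                       age = -0.0015, years_since_oa = -0.002,
                       female = -0.01, source = "test")
}
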