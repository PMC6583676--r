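#' Permissible ranges of the clinical variables
#'
#' Simulated vectors are accepted only when every coordinate lies inside its
#' closed permissible interval: pain 0-20, function 0-68, stiffness 0-8, age
#' 0-100, years since OA diagnosis 0-100.
#'
#' @param lower,upper Numeric vectors of 5 bounds in canonical variable order.
#' @return A 5x2 matrix with columns `lower` and `upper`, class
#'   `permissible_ranges`.
#' @export
permissible_ranges <- function(lower = c(0, 0, 0, 0, 0),
                               upper = c(20, 68, 8, 100, 100)) {
  lower <- as_var_vector(lower, "lower")
  upper <- as_var_vector(upper, "upper")
  if (any(lower > upper)) stop("every lower bound must be <= its upper bound")
  structure(cbind(lower = lower, upper = upper), class = "permissible_ranges")
}

# Covariance from SDs and correlation: diag(sd) %*% corr %*% diag(sd).
assemble_covariance <- function(sds, corr) {
  sigma <- corr * tcrossprod(sds)
  dimnames(sigma) <- dimnames(corr)
  sigma
}

check_psd <- function(sigma, repair = FALSE, tol = 1e-8) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    if (!repair)
      stop("covariance matrix is not positive semi-definite; ",
           "pass repair_psd = TRUE to project onto the nearest PSD matrix")
    sigma <- as.matrix(Matrix::nearPD(sigma, keepDiag = TRUE)$mat)
  }
  sigma
}

# Joint rejection sampler: draw whole vectors from N(mu, sigma), discard any
# vector with a coordinate outside its box, repeat until n accepted. Used by
# both sample_ipd() and the synthetic-trial generator (in 2*k dimensions).
rejection_sample <- function(n, mu, sigma, lower, upper,
                             max_draws = 1e6, min_acceptance = 1e-4) {
  k <- length(mu)
  accepted <- matrix(numeric(0), ncol = k)
  drawn <- 0L
  batch <- max(1000L, 2L * n)
  while (nrow(accepted) < n) {
    if (drawn >= max_draws) {
      rate <- nrow(accepted) / drawn
      if (rate < min_acceptance)
        stop(sprintf(paste0("rejection sampling infeasible: acceptance rate ",
                            "%.2e after %d draws (floor %.0e)"),
                     rate, drawn, min_acceptance))
    }
    m <- MASS::mvrnorm(batch, mu = mu, Sigma = sigma)
    if (batch == 1L) m <- matrix(m, nrow = 1L)
    keep <- rep(TRUE, nrow(m))
    for (j in seq_len(k))
      keep <- keep & m[, j] >= lower[j] & m[, j] <= upper[j]
    accepted <- rbind(accepted, m[keep, , drop = FALSE])
    drawn <- drawn + batch
    rate <- max(nrow(accepted) / drawn, min_acceptance / 10)
    batch <- min(1e6L, max(1000L, ceiling(1.2 * (n - nrow(accepted)) / rate)))
  }
  list(values = accepted[seq_len(n), , drop = FALSE],
       acceptance_rate = nrow(accepted) / drawn, n_draws = drawn)
}

#' Simulate individual patient records from one arm aggregate
#'
#' Draws correlated normal vectors of the five clinical variables with the
#' aggregate's means and covariance (`diag(sd) corr diag(sd)`), and discards
#' every vector with any coordinate outside its permissible range until
#' `n_sim` whole vectors have been accepted. Truncation is by joint rejection
#' of the full vector, never by clipping: clipping would pile mass on the
#' boundaries and bias the correlations. The aggregate's means and SDs are
#' treated as parameters of the untruncated normal, so the moments of the
#' accepted sample are pulled slightly inward when a mean sits near a bound.
#'
#' @param aggregate A complete [arm_aggregate].
#' @param n_sim Number of accepted records required.
#' @param ranges A [permissible_ranges] matrix.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @param max_draws Draw budget before the acceptance-rate floor is checked.
#' @param min_acceptance Acceptance-rate floor; below it the aggregate is
#'   declared infeasible.
#' @param repair_psd Project a non-PSD covariance onto the nearest PSD matrix
#'   instead of failing.
#' @return A data frame of `n_sim` patient records (five clinical variables,
#'   `female = 1`, `utility = NA` until [compute_utility()] fills it), with
#'   attributes `acceptance_rate` and `n_draws`.
#' @export
sample_ipd <- function(aggregate, n_sim, ranges = permissible_ranges(),
                       seed = NULL, max_draws = 1e6, min_acceptance = 1e-4,
                       repair_psd = FALSE) {
  stopifnot(inherits(aggregate, "arm_aggregate"), n_sim >= 1)
  if (anyNA(aggregate$means) || anyNA(aggregate$sds) || anyNA(aggregate$corr))
    stop("aggregate is incomplete; run apply_fallback() first")
  if (!is.null(seed)) set.seed(seed)
  sigma <- check_psd(assemble_covariance(aggregate$sds, aggregate$corr),
                     repair = repair_psd)
  res <- rejection_sample(n_sim, aggregate$means, sigma,
                          ranges[, "lower"], ranges[, "upper"],
                          max_draws = max_draws, min_acceptance = min_acceptance)
  out <- as.data.frame(res$values)
  names(out) <- CEA_VARS
  out$female <- 1
  out$utility <- NA_real_
  attr(out, "acceptance_rate") <- res$acceptance_rate
  attr(out, "n_draws") <- res$n_draws
  out
}

# Deterministic seed-splitting rule: the i-th simulation unit (studies, arms
# and visits taken in their given order) gets seed (root + 1009 * i) mod
# 2^31 - 1, so adding a study at the end never perturbs earlier streams.
child_seed <- function(root, index) {
  as.integer((as.numeric(root) + 1009 * as.numeric(index)) %% 2147483647)
}

#' Simulate pseudo-IPD for a batch of studies
#'
#' Runs [sample_ipd()] for every study/arm/visit aggregate with one child
#' seed per unit derived from the root seed, and collects per-unit
#' diagnostics (acceptance rate, first-moment error).
#'
#' @param studies Nested list: `studies[[study_id]][[arm]][[visit]]` is a
#'   complete [arm_aggregate]; `arm` in `"active"`/`"placebo"`, `visit` in
#'   `"baseline"`/`"endpoint"`.
#' @param n_per_arm Accepted records per arm and visit (default 10000, i.e.
#'   20000 patients per study over both arms).
#' @param seed Root integer seed.
#' @param ranges A [permissible_ranges] matrix.
#' @param ... Passed on to [sample_ipd()].
#' @return List with `ipd` (same nesting as `studies`, each leaf a record
#'   data frame) and `report` (one row per unit: acceptance rate and maximum
#'   absolute mean error across the five variables).
#' @export
simulate_studies <- function(studies, n_per_arm = 10000, seed = 1,
                             ranges = permissible_ranges(), ...) {
  ipd <- list()
  report <- list()
  index <- 0L
  for (sid in names(studies)) {
    for (arm in names(studies[[sid]])) {
      for (visit in names(studies[[sid]][[arm]])) {
        index <- index + 1L
        agg <- studies[[sid]][[arm]][[visit]]
        rec <- tryCatch(
          sample_ipd(agg, n_per_arm, ranges = ranges,
                     seed = child_seed(seed, index), ...),
          error = function(e)
            stop("study '", sid, "', arm '", arm, "', visit '", visit,
                 "': ", conditionMessage(e)))
        ipd[[sid]][[arm]][[visit]] <- rec
        mom <- colMeans(rec[CEA_VARS])
        report[[index]] <- data.frame(
          study_id = sid, arm = arm, visit = visit,
          acceptance_rate = attr(rec, "acceptance_rate"),
          max_mean_error = max(abs(mom - agg$means)))
      }
    }
  }
  list(ipd = ipd, report = do.call(rbind, report))
}
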