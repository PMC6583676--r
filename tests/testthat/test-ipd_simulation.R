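test_that("zero-SD aggregates give a point mass at the means", {
  agg <- arm_aggregate(c(10, 30, 4, 60, 5), rep(0, 5), diag(5), 50)
  rec <- sample_ipd(agg, n_sim = 5, seed = 1)
  expect_equal(nrow(rec), 5L)
  for (v in vars5)
    expect_equal(rec[[v]], rep(agg$means[[v]], 5))
  expect_equal(attr(rec, "acceptance_rate"), 1)
})

test_that("sampling is deterministic in the seed and every record is in range", {
  agg <- arm_aggregate(c(10, 30, 4, 60, 5), c(3, 10, 2, 8, 4),
                       diag(5), 100)
  a <- sample_ipd(agg, 500, seed = 42)
  b <- sample_ipd(agg, 500, seed = 42)
  c <- sample_ipd(agg, 500, seed = 43)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$pain, c$pain)))
  rng <- permissible_ranges()
  set.seed(7)
  for (rep in 1:5) {
    rec <- sample_ipd(rand_aggregate(), 400)
    for (v in vars5) {
      expect_true(all(rec[[v]] >= rng[v, "lower"]))
      expect_true(all(rec[[v]] <= rng[v, "upper"]))
    }
  }
})

test_that("marginal means match one-dimensional rejection oracles", {
  agg <- arm_aggregate(c(10, 30, 4, 60, 5), c(3, 10, 2, 8, 4),
                       diag(5), 100)
  rec <- sample_ipd(agg, 2e4, seed = 11)
  set.seed(99)
  for (v in vars5) {
    i <- match(v, vars5)
    orc <- oracle_trunc_mean(agg$means[i], agg$sds[i], 0,
                             permissible_ranges()[v, "upper"], n_draws = 5e5)
    se <- sqrt(orc[["se"]]^2 + var(rec[[v]]) / nrow(rec))
    expect_lt(abs(mean(rec[[v]]) - orc[["mean"]]), 3 * se)
  }
})

test_that("upper truncation pulls the pain mean strictly inward", {
  agg <- arm_aggregate(c(19, 30, 4, 60, 5), c(5, 10, 2, 8, 4),
                       diag(5), 100)
  rec <- sample_ipd(agg, 5e3, seed = 3)
  expect_true(all(rec$pain <= 20))
  expect_lt(mean(rec$pain), 19)
  orc <- oracle_trunc_mean(19, 5, 0, 20, n_draws = 5e5)
  se <- sqrt(orc[["se"]]^2 + var(rec$pain) / nrow(rec))
  expect_lt(abs(mean(rec$pain) - orc[["mean"]]), 3 * se)
})

test_that("with unbounded boxes the sample recovers the input aggregate", {
  agg <- arm_aggregate(c(10, 30, 4, 60, 5), c(3, 10, 2, 8, 4),
                       rand_corr_fixed(), 100)
  wide <- permissible_ranges(lower = rep(-1e9, 5), upper = rep(1e9, 5))
  rec <- sample_ipd(agg, 1e5, ranges = wide, seed = 5)
  expect_equal(attr(rec, "acceptance_rate"), 1)
  n <- nrow(rec)
  for (i in seq_along(vars5)) {
    v <- vars5[i]
    expect_lt(abs(mean(rec[[v]]) - agg$means[i]), 3 * agg$sds[i] / sqrt(n))
    # SE of a normal SD estimate is sd / sqrt(2 n)
    expect_lt(abs(sd(rec[[v]]) - agg$sds[i]), 3 * agg$sds[i] / sqrt(2 * n))
  }
  r_hat <- cor(as.matrix(rec[vars5]))
  # Fisher-z SE of a correlation is 1/sqrt(n - 3)
  expect_lt(max(abs(atanh(r_hat[upper.tri(r_hat)]) -
                    atanh(agg$corr[upper.tri(agg$corr)]))), 3 / sqrt(n - 3))
})

test_that("widening a range never lowers the acceptance rate", {
  agg <- arm_aggregate(c(16, 55, 6.5, 60, 2), c(4, 12, 2, 8, 2.5),
                       diag(5), 100)
  narrow <- permissible_ranges()
  wider <- permissible_ranges(lower = c(0, 0, 0, 0, -50),
                              upper = c(40, 100, 16, 150, 100))
  a1 <- attr(sample_ipd(agg, 2000, ranges = narrow, seed = 8), "acceptance_rate")
  a2 <- attr(sample_ipd(agg, 2000, ranges = wider, seed = 8), "acceptance_rate")
  expect_gte(a2, a1)
})

test_that("infeasible aggregates and non-PSD covariances fail informatively", {
  far <- arm_aggregate(c(-50, 30, 4, 60, 5), c(0.5, 10, 2, 8, 4),
                       diag(5), 100)
  expect_error(sample_ipd(far, 10, max_draws = 1e4), "infeasible")

  # a corrupted correlation matrix (bypassing the constructor) must trip
  # sample_ipd's own covariance guard
  agg <- arm_aggregate(c(10, 30, 4, 60, 5), c(3, 10, 2, 8, 4), diag(5), 100)
  agg$corr[1, 2] <- agg$corr[2, 1] <- 0.9
  agg$corr[1, 3] <- agg$corr[3, 1] <- 0.9
  agg$corr[2, 3] <- agg$corr[3, 2] <- -0.9
  expect_error(sample_ipd(agg, 10, seed = 1), "repair_psd")
  rec <- sample_ipd(agg, 50, seed = 1, repair_psd = TRUE)
  expect_equal(nrow(rec), 50L)
})

test_that("batch simulation is seed-stable per study and reports diagnostics", {
  mk <- function(n) list(
    active = list(baseline = rand_aggregate(n), endpoint = rand_aggregate(n, "endpoint")),
    placebo = list(baseline = rand_aggregate(n), endpoint = rand_aggregate(n, "endpoint")))
  set.seed(21)
  studies <- list(s1 = mk(100), s2 = mk(200))
  out <- simulate_studies(studies, n_per_arm = 50, seed = 123)
  expect_equal(nrow(out$report), 8L)
  expect_equal(nrow(out$ipd$s1$active$baseline), 50L)
  # appending a study must not perturb the earlier streams
  set.seed(21)
  studies3 <- list(s1 = mk(100), s2 = mk(200))
  studies3$s3 <- studies3$s1
  out3 <- simulate_studies(studies3, n_per_arm = 50, seed = 123)
  expect_identical(out$ipd$s1, out3$ipd$s1)
  expect_identical(out$ipd$s2, out3$ipd$s2)
})
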