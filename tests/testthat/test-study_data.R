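test_that("bundled study table reproduces every transcribed cell", {
  st <- glucosamine_studies()
  expect_s3_class(st, "study_table")
  expect_equal(nrow(st), 10L)
  expect_equal(sum(st$formulation == "pCGS"), 4L)
  ref <- reference_studies()
  expect_equal(as.data.frame(st), ref, ignore_attr = TRUE)
})

test_that("study tables round-trip through CSV and JSON bit-identically", {
  st <- glucosamine_studies()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_study_table(st, csv)
  expect_identical(as.data.frame(read_study_table(csv)), as.data.frame(st))
  json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(as.data.frame(st), json, digits = NA)
  expect_identical(as.data.frame(read_study_table(json)), as.data.frame(st))
})

test_that("reader validates schema, parses errors with context, warns on empty", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study_id,formulation,n,duration_months,delta_active",
               "A,pCGS,60,3,0.1"), tmp)
  expect_error(read_study_table(tmp), "delta_placebo")

  writeLines(c("study_id,formulation,n,duration_months,delta_active,delta_placebo",
               "A,pCGS,60,3,abc,0.1"), tmp)
  expect_error(read_study_table(tmp), "row 1")

  writeLines("study_id,formulation,n,duration_months,delta_active,delta_placebo",
             tmp)
  expect_warning(empty <- read_study_table(tmp), "no rows")
  expect_equal(nrow(empty), 0L)
})

test_that("study-table invariants reject bad rows and unknown formulations", {
  good <- reference_studies()
  bad <- good; bad$duration_months[1] <- 0
  expect_error(study_table(bad), "duration_months")
  bad <- good; bad$n[2] <- 0
  expect_error(study_table(bad), "'n'")
  bad <- good; bad$delta_active[3] <- 1.5
  expect_error(study_table(bad), "\\[-1, 1\\]")
  bad <- good; bad$formulation[1] <- "glucosamine_hcl"
  expect_error(study_table(bad), "unknown formulation")
})

test_that("aggregate constructor enforces correlation-matrix structure", {
  m <- c(10, 30, 4, 60, 5); s <- c(3, 10, 2, 8, 4)
  r <- diag(5)
  expect_s3_class(arm_aggregate(m, s, r, 100), "arm_aggregate")
  r_asym <- r; r_asym[1, 2] <- 0.5
  expect_error(arm_aggregate(m, s, r_asym, 100), "symmetric")
  r_diag <- r; diag(r_diag)[1] <- 0.9
  expect_error(arm_aggregate(m, s, r_diag, 100), "unit diagonal")
  r_npd <- matrix(0.99, 5, 5) * (1 - diag(5)) + diag(5)
  r_npd[1, 2] <- r_npd[2, 1] <- -0.99
  expect_error(arm_aggregate(m, s, r_npd, 100), "positive semi-definite")
  expect_error(arm_aggregate(m, -s, r, 100), "non-negative")
  expect_error(arm_aggregate(m, s, r, 0), "positive integer")
})

test_that("apply_fallback fills gaps, flags provenance, errors when hopeless", {
  fb <- default_fallback()
  partial <- arm_aggregate(c(10, 30, 4, 60, NA), c(3, 10, 2, 8, NA),
                           diag(5), 100, partial = TRUE)
  full <- apply_fallback(partial, fb)
  prov <- attr(full, "provenance")
  expect_equal(unname(full$means["years_since_oa"]),
               unname(fb$means["years_since_oa"]))
  expect_equal(unname(full$sds["years_since_oa"]),
               unname(fb$sds["years_since_oa"]))
  expect_equal(unname(prov$means[["years_since_oa"]]), "fallback")
  expect_equal(unname(prov$sds[["pain"]]), "observed")

  complete <- arm_aggregate(c(10, 30, 4, 60, 5), c(3, 10, 2, 8, 4),
                            diag(5), 100)
  out <- apply_fallback(complete, fb)
  expect_equal(out$means, complete$means)
  expect_true(all(attr(out, "provenance")$means == "observed"))

  hopeless_fb <- fb
  hopeless_fb$means["age"] <- NA
  partial_age <- arm_aggregate(c(10, 30, 4, NA, 5), c(3, 10, 2, 8, 4),
                               diag(5), 100, partial = TRUE)
  expect_error(apply_fallback(partial_age, hopeless_fb), "age")
})
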