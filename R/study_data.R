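# Clinical variables entering the utility regression, in canonical order.
# WOMAC subscales are on the normalized scales pain 0-20, function 0-68,
# stiffness 0-8; age and years since OA diagnosis in years.
CEA_VARS <- c("pain", "function", "stiffness", "age", "years_since_oa")

# Closed set of formulation classes; the whole contrast of the analysis is
# prescription crystalline glucosamine sulfate versus everything else.
CEA_FORMULATIONS <- c("pCGS", "other_glucosamine")

STUDY_COLUMNS <- c("study_id", "formulation", "n", "duration_months",
                   "delta_active", "delta_placebo")

#' Construct a study-level results table
#'
#' A study table holds one row per randomized trial: the formulation class,
#' the number of subjects contributing to the pooled analysis, the trial
#' duration, and the mean health-utility change from baseline in each arm.
#'
#' @param df Data frame with columns `study_id`, `formulation` (one of
#'   `"pCGS"`, `"other_glucosamine"`), `n` (total subjects, >= 1),
#'   `duration_months` (>= 1), `delta_active` and `delta_placebo`
#'   (utility changes, finite, in \[-1, 1\]).
#' @return The validated data frame with class `study_table`.
#' @export
study_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("study table is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[STUDY_COLUMNS]
  if (nrow(df) == 0L) {
    class(df) <- c("study_table", "data.frame")
    return(df)
  }
  df$study_id <- as.character(df$study_id)
  df$formulation <- as.character(df$formulation)
  bad <- !df$formulation %in% CEA_FORMULATIONS
  if (any(bad))
    stop("unknown formulation(s): ", paste(unique(df$formulation[bad]), collapse = ", "),
         " (expected one of: ", paste(CEA_FORMULATIONS, collapse = ", "), ")")
  for (col in c("n", "duration_months", "delta_active", "delta_placebo")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(coerced))
        stop("non-numeric value in column '", col, "' at row ",
             which(is.na(coerced))[1L])
      v <- coerced
    }
    if (anyNA(v) || any(!is.finite(v)))
      stop("missing or non-finite value in column '", col, "' at row ",
           which(!is.finite(v))[1L])
    df[[col]] <- as.numeric(v)
  }
  if (any(df$n < 1 | df$n != round(df$n)))
    stop("'n' must be a positive integer for every study")
  if (any(df$duration_months < 1 | df$duration_months != round(df$duration_months)))
    stop("'duration_months' must be a positive integer for every study")
  for (col in c("delta_active", "delta_placebo"))
    if (any(abs(df[[col]]) > 1))
      stop("utility changes in '", col, "' must lie in [-1, 1]")
  rownames(df) <- NULL
  class(df) <- c("study_table", "data.frame")
  df
}

#' Read a study-level results table from CSV or JSON
#'
#' @param path Path to the file.
#' @param format `"csv"` (header row, UTF-8, "." decimal separator) or
#'   `"json"` (array of row objects). Guessed from the file extension by
#'   default.
#' @return A [study_table] data frame (possibly empty, with a warning).
#' @export
read_study_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  }
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("study table '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    warning("study table '", path, "' contains no rows")
  study_table(df)
}

#' Write a study table to CSV
#'
#' @param studies A [study_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  stopifnot(inherits(studies, "study_table"))
  utils::write.csv(as.data.frame(studies), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Utility changes observed in ten published glucosamine trials
#'
#' The bundled table of per-study health-utility changes: four trials of
#' prescription crystalline glucosamine sulfate (pCGS) and six of other
#' glucosamine formulations, each with total contributing subjects, trial
#' duration in months, and the mean utility change from baseline in the
#' glucosamine and placebo arms.
#'
#' @return A [study_table] with ten rows.
#' @export
glucosamine_studies <- function() {
  read_study_table(system.file("extdata", "glucosamine_studies.csv",
                               package = "aggcea", mustWork = TRUE))
}

#' Daily price summaries for glucosamine formulations
#'
#' Low/median/high prices in EUR per day for each formulation class, as
#' derived from international selling-price data by trimmed-mean bounds
#' (see [price_range()]); the placebo price is zero by construction.
#'
#' @return Data frame with columns `formulation`, `level`, `price_eur_per_day`.
#' @export
glucosamine_prices <- function() {
  utils::read.csv(system.file("extdata", "glucosamine_prices.csv",
                              package = "aggcea", mustWork = TRUE))
}

#' Construct per-arm aggregate statistics for one visit
#'
#' An `arm_aggregate` carries the published summary statistics of the five
#' clinical variables (WOMAC pain/function/stiffness, age, years since OA
#' diagnosis) for one trial arm at one visit: means, standard deviations, the
#' correlation matrix, and the arm sample size. Entries may be `NA` when a
#' publication omits them; [apply_fallback()] completes such partial
#' aggregates before simulation.
#'
#' @param means Numeric vector of 5 means, in the order pain, function,
#'   stiffness, age, years_since_oa (names optional).
#' @param sds Numeric vector of 5 non-negative standard deviations.
#' @param corr 5x5 correlation matrix: symmetric, unit diagonal, entries in
#'   \[-1, 1\], positive semi-definite.
#' @param n Arm sample size (positive integer).
#' @param visit `"baseline"` or `"endpoint"`.
#' @param partial Allow `NA` entries in `means`/`sds`/`corr` (to be filled by
#'   [apply_fallback()]).
#' @return An object of class `arm_aggregate`.
#' @export
arm_aggregate <- function(means, sds, corr, n,
                          visit = c("baseline", "endpoint"),
                          partial = FALSE) {
  visit <- match.arg(visit)
  means <- as_var_vector(means, "means")
  sds <- as_var_vector(sds, "sds")
  corr <- as_corr_matrix(corr, partial = partial)
  if (!partial) {
    if (anyNA(means) || anyNA(sds))
      stop("aggregate has NA entries; use partial = TRUE and apply_fallback()")
  }
  if (any(sds < 0, na.rm = TRUE)) stop("standard deviations must be non-negative")
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  structure(list(means = means, sds = sds, corr = corr, n = as.integer(n),
                 visit = visit),
            class = "arm_aggregate")
}

as_var_vector <- function(x, what) {
  if (length(x) != length(CEA_VARS))
    stop("'", what, "' must have ", length(CEA_VARS), " entries (",
         paste(CEA_VARS, collapse = ", "), ")")
  x <- as.numeric(x)
  names(x) <- CEA_VARS
  if (any(!is.na(x) & !is.finite(x))) stop("'", what, "' has non-finite entries")
  x
}

as_corr_matrix <- function(corr, partial = FALSE, tol = 1e-8) {
  corr <- as.matrix(corr)
  p <- length(CEA_VARS)
  if (!all(dim(corr) == c(p, p)))
    stop("'corr' must be a ", p, "x", p, " matrix")
  dimnames(corr) <- list(CEA_VARS, CEA_VARS)
  if (anyNA(corr)) {
    if (!partial) stop("'corr' has NA entries; use partial = TRUE")
    return(corr)
  }
  if (max(abs(corr - t(corr))) > tol) stop("'corr' must be symmetric")
  if (max(abs(diag(corr) - 1)) > tol) stop("'corr' must have a unit diagonal")
  if (any(abs(corr) > 1 + tol)) stop("'corr' entries must lie in [-1, 1]")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop("'corr' must be positive semi-definite")
  corr
}

#' Default values used to complete incomplete published summaries
#'
#' Publications sometimes omit a standard deviation or a whole variable
#' (typically years since OA diagnosis). A fallback table supplies default
#' means, SDs and a default correlation matrix used to fill those gaps.
#' The values shipped by `default_fallback()` are a synthetic profile
#' emulating a moderate knee-osteoarthritis population; they are not taken
#' from any trial.
#'
#' @param means,sds Numeric vectors of 5 values in canonical variable order.
#' @param corr 5x5 correlation matrix.
#' @return Object of class `fallback_table`.
#' @export
fallback_table <- function(means, sds, corr) {
  structure(list(means = as_var_vector(means, "means"),
                 sds = as_var_vector(sds, "sds"),
                 corr = as_corr_matrix(corr)),
            class = "fallback_table")
}

#' @rdname fallback_table
#' @export
default_fallback <- function() {
  fallback_table(means = c(10, 30, 4, 62, 6),
                 sds = c(3, 10, 1.5, 8, 2),
                 corr = default_corr())
}

# Moderate positive correlation among WOMAC subscales, weak links with age
# and disease duration: a plausible knee-OA structure, synthetic by design.
default_corr <- function() {
  r <- diag(5)
  dimnames(r) <- list(CEA_VARS, CEA_VARS)
  womac <- 1:3
  r[womac, womac] <- 0.5
  diag(r) <- 1
  r["age", "years_since_oa"] <- r["years_since_oa", "age"] <- 0.3
  r["age", womac] <- r[womac, "age"] <- 0.1
  r["years_since_oa", womac] <- r[womac, "years_since_oa"] <- 0.1
  r
}

#' Complete a partial aggregate from a fallback table
#'
#' Fills every `NA` mean, SD or correlation entry from the fallback table and
#' records, per field, whether the value was observed or substituted.
#'
#' @param aggregate A (possibly partial) [arm_aggregate].
#' @param fallback A [fallback_table].
#' @return A complete `arm_aggregate` whose `"provenance"` attribute holds,
#'   for means and sds, a character vector per variable (`"observed"` or
#'   `"fallback"`), and for the correlation matrix a single flag.
#' @export
apply_fallback <- function(aggregate, fallback = default_fallback()) {
  stopifnot(inherits(aggregate, "arm_aggregate"), inherits(fallback, "fallback_table"))
  prov <- list(means = rep("observed", length(CEA_VARS)),
               sds = rep("observed", length(CEA_VARS)),
               corr = "observed")
  names(prov$means) <- names(prov$sds) <- CEA_VARS
  means <- aggregate$means
  sds <- aggregate$sds
  for (v in CEA_VARS) {
    if (is.na(means[v])) {
      if (is.na(fallback$means[v]))
        stop("mean of '", v, "' missing from both aggregate and fallback")
      means[v] <- fallback$means[v]
      prov$means[v] <- "fallback"
    }
    if (is.na(sds[v])) {
      if (is.na(fallback$sds[v]))
        stop("SD of '", v, "' missing from both aggregate and fallback")
      sds[v] <- fallback$sds[v]
      prov$sds[v] <- "fallback"
    }
  }
  corr <- aggregate$corr
  if (anyNA(corr)) {
    corr[is.na(corr)] <- fallback$corr[is.na(corr)]
    prov$corr <- "fallback"
  }
  out <- arm_aggregate(means, sds, corr, aggregate$n, aggregate$visit)
  attr(out, "provenance") <- prov
  out
}

#' @export
print.arm_aggregate <- function(x, ...) {
  cat("Arm aggregate (", x$visit, ", n = ", x$n, ")\n", sep = "")
  print(rbind(mean = x$means, sd = x$sds))
  invisible(x)
}
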