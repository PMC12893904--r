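#' Fit a quadratic age-response standard curve
#'
#' Ordinary least squares of `response = a + b*age + c*age^2`. The fitted
#' object records the coefficient covariance, residual variance, R
#' squared, residual degrees of freedom `n - 3` and the calibration age
#' range, and supports [predict_band()], [invert_age()], [tidy()],
#' [glance()] and [autoplot()].
#'
#' @param data Data frame of calibration animals.
#' @param age,response Column names (strings) holding age (weeks) and the
#'   response; >= 4 points over >= 3 distinct ages.
#' @return An object of class `age_response_curve`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' curve <- fit_quadratic(cohort)
#' glance(curve)
#' @export
fit_quadratic <- function(data, age = "age", response = "response") {
  data <- as_tibble(data)
  if (!all(c(age, response) %in% names(data))) {
    abort_bad_arg("`data` must contain the age and response columns.",
                  "immunokit_bad_config")
  }
  x <- data[[age]]
  y <- data[[response]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4 || length(unique(x)) < 3) {
    abort_bad_arg("need >= 4 points over >= 3 distinct ages.",
                  "immunokit_bad_config")
  }
  fit <- lm(y ~ x + I(x^2))
  if (any(is.na(coef(fit)))) {
    abort_bad_arg("rank-deficient quadratic design.",
                  "immunokit_rank_deficient")
  }
  n <- length(x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  xtx_inv <- chol2inv(fit$qr$qr[1:3, 1:3, drop = FALSE])
  structure(
    list(
      coefficients = setNames(unname(coef(fit)), c("a", "b", "c")),
      vcov = unname(xtx_inv * rss / (n - 3)),
      sigma2 = rss / (n - 3),
      r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
      df = n - 3,
      n = n,
      age_range = range(x),
      fit = fit
    ),
    class = "age_response_curve"
  )
}

#' @export
print.age_response_curve <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<age_response_curve> response = %.4g %+.4g*age %+.4g*age^2\n",
    co["a"], co["b"], co["c"]
  ))
  cat(sprintf("  n = %d, df = %d, R^2 = %.4f, ages %g-%g weeks\n",
              x$n, x$df, x$r_squared, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' @describeIn fit_quadratic Coefficient-level summary (term, estimate,
#'   std.error, statistic, p.value).
#' @param x,object An `age_response_curve`.
#' @param ... Unused.
#' @export
tidy.age_response_curve <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("a", "b", "c"),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @describeIn fit_quadratic One-row fit summary (r.squared, sigma, df,
#'   nobs, age range).
#' @export
glance.age_response_curve <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, sigma = sqrt(x$sigma2), df = x$df,
    nobs = x$n, age_min = x$age_range[1], age_max = x$age_range[2]
  )
}

#' Pointwise confidence band of the fitted mean response
#'
#' `fitted mean +/- t_{df, 1-alpha/2} * se(fitted mean)` with the standard
#' error from the coefficient covariance (`sqrt(x0' V x0)` for the design
#' row `x0 = (1, age, age^2)`). These are confidence bands for the mean
#' curve, not prediction intervals for new animals.
#'
#' @param curve An [fit_quadratic()] object.
#' @param ages Ages (weeks) at which to evaluate the band.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Tibble: `age`, `fit`, `lower`, `upper`, `se`.
#' @export
predict_band <- function(curve, ages, level = 0.95) {
  stopifnot(inherits(curve, "age_response_curve"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort_bad_arg("`level` must lie strictly between 0 and 1.",
                  "immunokit_bad_config")
  }
  if (any(!is.finite(ages))) {
    abort_bad_arg("`ages` must be finite.", "immunokit_bad_config")
  }
  co <- curve$coefficients
  x0 <- cbind(1, ages, ages^2)
  fit <- drop(x0 %*% co)
  se <- sqrt(pmax(rowSums((x0 %*% curve$vcov) * x0), 0))
  tcrit <- qt(1 - (1 - level) / 2, df = curve$df)
  tibble(age = ages, fit = fit,
         lower = fit - tcrit * se, upper = fit + tcrit * se, se = se)
}

#' Invert the standard curve: immunological vaccination response age
#'
#' Solves `c*age^2 + b*age + (a - response) = 0` per animal and keeps real
#' roots inside the calibration age range (optionally widened by
#' `extrapolation_margin`). When both roots are valid, the root on the
#' monotone branch covering the majority of the calibration range is
#' selected. `root_status` records `"unique"`, `"selected"` or
#' `"out_of_range"`; no silent extrapolation occurs.
#'
#' @param curve An [fit_quadratic()] object.
#' @param responses Numeric vector of observed responses (or a data frame
#'   with a `response` column; other columns are carried through).
#' @param extrapolation_margin Weeks beyond the calibration range to
#'   accept (default 0).
#' @return Tibble: carried columns, `response`, `est_age`, `root_status`.
#' @examples
#' curve <- fit_quadratic(simulate_cohort(noise_sd = 0, seed = 1))
#' y40 <- predict_band(curve, 40)$fit
#' invert_age(curve, y40)$est_age # 40
#' @export
invert_age <- function(curve, responses, extrapolation_margin = 0) {
  stopifnot(inherits(curve, "age_response_curve"))
  carried <- NULL
  if (is.data.frame(responses)) {
    carried <- as_tibble(responses)
    if (!"response" %in% names(carried)) {
      abort_bad_arg("`responses` data frame needs a `response` column.",
                    "immunokit_bad_config")
    }
    responses <- carried$response
    carried$response <- NULL
  }
  co <- curve$coefficients
  lo <- curve$age_range[1] - extrapolation_margin
  hi <- curve$age_range[2] + extrapolation_margin
  vertex <- if (abs(co["c"]) > 0) -co["b"] / (2 * co["c"]) else Inf
  # which monotone branch covers the majority of calibration ages?
  upper_branch <- (curve$age_range[2] - vertex) >
    (vertex - curve$age_range[1])

  one <- function(y) {
    if (abs(co["c"]) < 1e-12) {
      if (abs(co["b"]) < 1e-12) {
        return(tibble(est_age = NA_real_, root_status = "out_of_range"))
      }
      roots <- (y - co["a"]) / co["b"]
    } else {
      disc <- co["b"]^2 - 4 * co["c"] * (co["a"] - y)
      if (disc < 0) {
        return(tibble(est_age = NA_real_, root_status = "out_of_range"))
      }
      roots <- (-co["b"] + c(-1, 1) * sqrt(disc)) / (2 * co["c"])
    }
    valid <- roots[roots >= lo & roots <= hi]
    if (length(valid) == 0) {
      tibble(est_age = NA_real_, root_status = "out_of_range")
    } else if (length(valid) == 1) {
      tibble(est_age = unname(valid), root_status = "unique")
    } else {
      pick <- if (upper_branch) max(valid) else min(valid)
      tibble(est_age = unname(pick), root_status = "selected")
    }
  }
  out <- dplyr::bind_rows(lapply(responses, one))
  out <- dplyr::bind_cols(tibble(response = responses), out)
  if (!is.null(carried)) out <- dplyr::bind_cols(carried, out)
  out
}

#' Two-sample comparison of estimated immunological ages
#'
#' Student's two-sample t-test with pooled variance, two-tailed. With zero
#' pooled variance the limit is reported (`t = 0, p = 1` for equal means;
#' `p = 0` with `degenerate = TRUE` otherwise).
#'
#' @param group1,group2 Numeric vectors (>= 2 values each), e.g. estimated
#'   ages of treated and control animals.
#' @return One-row tibble: `estimate1`, `estimate2`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
compare_groups <- function(group1, group2) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) {
    abort_bad_arg("need >= 2 finite values per group.",
                  "immunokit_bad_config")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / df
  delta <- mean(group1) - mean(group2)
  if (sp2 == 0) {
    if (delta == 0) {
      return(tibble(estimate1 = mean(group1), estimate2 = mean(group2),
                    t = 0, df = df, p = 1, degenerate = TRUE))
    }
    return(tibble(estimate1 = mean(group1), estimate2 = mean(group2),
                  t = sign(delta) * Inf, df = df, p = 0,
                  degenerate = TRUE))
  }
  tval <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(
    estimate1 = mean(group1), estimate2 = mean(group2),
    t = tval, df = df, p = 2 * pt(-abs(tval), df), degenerate = FALSE
  )
}
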