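#' Simulate an age-response vaccination cohort
#'
#' Draws per-animal responses around a quadratic mean curve
#' `a + b*age + c*age^2` with Gaussian noise, the generative counterpart of
#' a tetramer-frequency standard curve across the lifespan. Negative draws
#' are clipped to zero and flagged.
#'
#' Defaults mimic a calibration design of 8 ages x 4 animals (32 animals,
#' residual df 29 for a three-coefficient fit) with a response declining
#' from about 5.9% at 6 weeks to about 0.5% at 72 weeks.
#'
#' @param ages Ages in weeks; at least 3 distinct values (quadratic
#'   identifiability).
#' @param n_per_age Animals per age.
#' @param coeffs Numeric `c(a, b, c)` of the mean quadratic.
#' @param noise_sd Gaussian response noise (>= 0), in response units.
#' @param seed Integer seed.
#' @return Tibble with `animal_id`, `age`, `response`, `clipped`.
#' @examples
#' cohort <- simulate_cohort(seed = 1)
#' nrow(cohort) # 32
#' @export
simulate_cohort <- function(ages = c(6, 12, 20, 28, 36, 44, 56, 72),
                            n_per_age = 4,
                            coeffs = c(6.8, -0.16, 0.001),
                            noise_sd = 0.4,
                            seed = 1L) {
  if (length(unique(ages)) < 3) {
    abort_bad_arg("need >= 3 distinct ages for an identifiable quadratic.",
                  "immunokit_bad_config")
  }
  check_number(n_per_age, "n_per_age", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (length(coeffs) != 3 || !is.numeric(coeffs)) {
    abort_bad_arg("`coeffs` must be numeric c(a, b, c).",
                  "immunokit_bad_config")
  }
  with_seed_or_current(seed, {
    age <- rep(ages, each = n_per_age)
    mu <- coeffs[1] + coeffs[2] * age + coeffs[3] * age^2
    resp <- mu + rnorm(length(age), sd = noise_sd)
    clipped <- resp < 0
    resp[clipped] <- 0
    tibble(
      animal_id = sprintf("animal%03d", seq_along(age)),
      age = age,
      response = resp,
      clipped = clipped
    )
  })
}
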