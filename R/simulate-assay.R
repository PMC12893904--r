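#' Simulate small assay read-outs: pharmacokinetic series or qPCR Ct values
#'
#' * `mode = "pk"`: a concentration time course over `times` (hours) with
#'   multiplicative log-normal noise. `model = "bateman"` gives the classic
#'   rise-and-fall absorption/elimination shape on top of a baseline;
#'   `model = "exp_decay"` gives `c0 * exp(-ke * t)`. Concentrations are
#'   never negative by construction.
#' * `mode = "qpcr"`: paired technical-replicate Ct values for a target
#'   amplicon and a reference amplicon, with additive Gaussian noise, such
#'   that the true `-dCt` per sample equals `neg_delta_ct`.
#'
#' @param mode `"pk"` or `"qpcr"`.
#' @param times PK sampling times in hours (non-empty, includes 0 for a
#'   baseline).
#' @param model PK shape, `"bateman"` or `"exp_decay"`.
#' @param baseline,amplitude,ka,ke,c0 PK parameters: baseline level,
#'   absorption amplitude, absorption and elimination rates (1/h), and the
#'   `exp_decay` intercept.
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param n_samples Number of qPCR samples.
#' @param neg_delta_ct True `-dCt` per sample (recycled to `n_samples`).
#' @param ct_ref_mean Mean reference-amplicon Ct.
#' @param ct_noise_sd Additive Ct noise sd (>= 0).
#' @param duplicates Technical replicates per target.
#' @param seed Integer seed.
#' @return A list with `data` and `truth` tibbles. PK data has columns
#'   `time`, `value`; qPCR data has `sample_id`, `target`
#'   (`"TREC"`/`"TCRA"`), `replicate`, `ct`.
#' @examples
#' pk <- simulate_assay("pk", noise_cv = 0, seed = 1)
#' pk$data
#' @export
simulate_assay <- function(mode = c("pk", "qpcr"),
                           times = c(0, 3, 6, 12, 24, 48),
                           model = c("bateman", "exp_decay"),
                           baseline = 2, amplitude = 40,
                           ka = 0.8, ke = 0.12, c0 = 40,
                           noise_cv = 0.1,
                           n_samples = 6,
                           neg_delta_ct = -5,
                           ct_ref_mean = 25,
                           ct_noise_sd = 0.15,
                           duplicates = 2,
                           seed = 1L) {
  mode <- match.arg(mode)
  with_seed_or_current(seed, {
    if (mode == "pk") {
      if (length(times) == 0) {
        abort_bad_arg("`times` must be a non-empty time grid.",
                      "immunokit_bad_config")
      }
      model <- match.arg(model)
      check_number(noise_cv, "noise_cv", lower = 0)
      mu <- if (model == "bateman") {
        baseline + amplitude * (exp(-ke * times) - exp(-ka * times))
      } else {
        c0 * exp(-ke * times)
      }
      value <- if (noise_cv > 0) {
        sl <- sqrt(log(1 + noise_cv^2))
        mu * rlnorm(length(mu), meanlog = -sl^2 / 2, sdlog = sl)
      } else {
        mu
      }
      list(data = tibble(time = times, value = value),
           truth = tibble(time = times, value = mu))
    } else {
      check_number(ct_noise_sd, "ct_noise_sd", lower = 0)
      ndc <- rep_len(neg_delta_ct, n_samples)
      ids <- sprintf("sample%02d", seq_len(n_samples))
      grid <- tidyr::expand_grid(
        sample_id = ids,
        target = c("TREC", "TCRA"),
        replicate = seq_len(duplicates)
      )
      true_ct <- ifelse(grid$target == "TCRA",
                        ct_ref_mean,
                        ct_ref_mean - ndc[match(grid$sample_id, ids)])
      grid$ct <- true_ct + rnorm(nrow(grid), sd = ct_noise_sd)
      list(data = grid,
           truth = tibble(sample_id = ids, neg_delta_ct = ndc))
    }
  })
}
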