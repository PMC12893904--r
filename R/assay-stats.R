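#' TREC abundance as -dCt
#'
#' Averages the technical replicates of each target and returns
#' `-(mean Ct_TREC - mean Ct_TCRA)`, so higher values reflect greater
#' relative sjTREC abundance (more recent thymic emigrants).
#'
#' @param ct_trec,ct_tcra Numeric vectors of replicate Ct values (>= 1
#'   each, positive and finite).
#' @return A single numeric `-dCt`.
#' @examples
#' trec_neg_delta_ct(c(30, 31), c(25, 25)) # -5.5
#' @export
trec_neg_delta_ct <- function(ct_trec, ct_tcra) {
  for (v in list(ct_trec, ct_tcra)) {
    if (length(v) < 1 || any(!is.finite(v)) || any(v <= 0)) {
      abort_bad_arg("Ct replicates must be positive and finite.",
                    "immunokit_bad_config")
    }
  }
  -(mean(ct_trec) - mean(ct_tcra))
}

#' Trapezoid area under a concentration time course
#'
#' Trapezoid rule over the observed points from time 0 up to `t_end`
#' (hours). When `t_end` falls between observations the last segment is
#' linearly interpolated.
#'
#' @param times Strictly increasing times in hours, starting at 0.
#' @param values Non-negative concentrations matching `times`.
#' @param t_end Upper integration limit (<= max time), default 48.
#' @return The AUC (concentration x hours).
#' @examples
#' auc_trapezoid(c(0, 24, 48), c(2, 2, 2)) # 96
#' @export
auc_trapezoid <- function(times, values, t_end = 48) {
  if (length(times) < 2 || length(times) != length(values)) {
    abort_bad_arg("need >= 2 matching time/value points.",
                  "immunokit_bad_config")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort_bad_arg("times must be strictly increasing (no duplicates).",
                  "immunokit_bad_series")
  }
  if (times[1] != 0) {
    abort_bad_arg("the series must include a t = 0 baseline.",
                  "immunokit_bad_series")
  }
  if (t_end > max(times) || t_end <= 0) {
    abort_bad_arg("`t_end` must lie in (0, max(times)].",
                  "immunokit_bad_series")
  }
  if (t_end < max(times)) {
    v_end <- stats::approx(times, values, xout = t_end)$y
    keep <- times < t_end
    times <- c(times[keep], t_end)
    values <- c(values[keep], v_end)
  }
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Normalise a time course to fold change from baseline
#'
#' Divides every value by the t = 0 baseline, which therefore maps to
#' 1.0. Any per-organ weight normalisation is a caller-supplied divisor
#' applied before this step.
#'
#' @param times Times in hours (must include 0).
#' @param values Concentrations; the baseline must be > 0.
#' @return Tibble: `time`, `fold_change`.
#' @export
fold_change_series <- function(times, values) {
  if (length(times) != length(values)) {
    abort_bad_arg("`times` and `values` must match.",
                  "immunokit_bad_series")
  }
  i0 <- which(times == 0)
  if (length(i0) != 1 || !is.finite(values[i0]) || values[i0] <= 0) {
    abort_bad_arg("a single positive t = 0 baseline is required.",
                  "immunokit_bad_baseline")
  }
  tibble(time = times, fold_change = values / values[i0])
}
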