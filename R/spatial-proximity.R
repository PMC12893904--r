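#' Count close cross-type cell pairs
#'
#' Number of (a, b) pairs with `a` of `type_a`, `b` of `type_b`, and
#' Euclidean distance at most `radius` (µm). For distinct types each
#' unordered cross pair is counted once; for `type_a == type_b` pairs are
#' unordered and self-pairs are excluded.
#'
#' @param cells Data frame with columns `x`, `y` (µm) and `cell_type`.
#' @param type_a,type_b Type labels; both must be present in `cells`.
#' @param radius Distance threshold in µm (> 0).
#' @return Integer pair count.
#' @examples
#' m <- data.frame(x = c(0, 30), y = c(0, 0), cell_type = c("A", "B"))
#' count_pairs_within(m, "A", "B", 50)
#' @export
count_pairs_within <- function(cells, type_a, type_b, radius) {
  check_cell_map(cells)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE,
               class = "immunokit_bad_radius")
  for (ty in unique(c(type_a, type_b))) {
    if (!ty %in% cells$cell_type) {
      abort_bad_arg(sprintf("cell type '%s' is absent from the map.", ty),
                    "immunokit_type_absent")
    }
  }
  a <- cells[cells$cell_type == type_a, c("x", "y")]
  b <- cells[cells$cell_type == type_b, c("x", "y")]
  r2 <- radius^2
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  if (identical(type_a, type_b)) {
    # unordered, no self-pairs: strict upper triangle
    sum(d2[upper.tri(d2)] <= r2)
  } else {
    sum(d2 <= r2)
  }
}

#' Spatial interaction Z statistic for a cell-type pair
#'
#' Standardises the observed number of close cross-type pairs (within
#' `r_obs`, default 50 µm) against a null built from a wider local
#' neighbourhood (within `r_null`, default 150 µm):
#'
#' * `null_mode = "area"`: the null expectation is the wide-radius count
#'   scaled by the area ratio `(r_obs / r_null)^2` and the null standard
#'   deviation is `sqrt(expected)` (Poisson approximation: close-pair
#'   counts are sums of sparse indicators). `z = (observed - expected) /
#'   sqrt(expected)`.
#' * `null_mode = "permutation"`: cell-type labels are permuted over all
#'   cells of the array `n_perm` times; the permuted close-pair counts give
#'   the null mean and standard deviation. The wide-radius count is
#'   reported as a diagnostic (`observed_null`) but does not enter the
#'   statistic.
#'
#' No edge correction is applied: both radii share the same edge bias,
#' which partially cancels in the area ratio (see the methods vignette for
#' the residual bias this leaves on small domains).
#'
#' @inheritParams count_pairs_within
#' @param r_obs,r_null Observation and null radii in µm, `0 < r_obs <
#'   r_null`.
#' @param null_mode `"area"` or `"permutation"`.
#' @param n_perm Number of label permutations (>= 99) in permutation mode.
#' @param seed Integer seed for permutation mode.
#' @return One-row tibble: `type_a`, `type_b`, `age`, `observed`,
#'   `observed_null`, `expected`, `null_sd`, `z`, `null_mode`.
#' @examples
#' tis <- simulate_tissue(c(A = 80, B = 80), width = 2000, height = 2000,
#'                        seed = 3)
#' interaction_zscore(tis, "A", "B")
#' @export
interaction_zscore <- function(cells, type_a, type_b,
                               r_obs = 50, r_null = 150,
                               null_mode = c("area", "permutation"),
                               n_perm = 999, seed = 1L) {
  null_mode <- rlang::arg_match(null_mode)
  if (!is.numeric(r_obs) || !is.numeric(r_null) || r_obs <= 0 ||
      r_obs >= r_null) {
    abort_bad_arg("need 0 < r_obs < r_null.", "immunokit_bad_radius")
  }
  observed <- count_pairs_within(cells, type_a, type_b, r_obs)
  observed_null <- count_pairs_within(cells, type_a, type_b, r_null)
  age <- if ("age" %in% names(cells)) cells$age[1] else NA_real_

  if (null_mode == "area") {
    if (observed_null == 0) {
      abort_bad_arg(
        "no pairs within `r_null`; the interaction statistic is undefined.",
        "immunokit_undefined_statistic"
      )
    }
    expected <- observed_null * (r_obs / r_null)^2
    null_sd <- sqrt(expected)
  } else {
    if (n_perm < 99) {
      abort_bad_arg("permutation mode needs `n_perm` >= 99.",
                    "immunokit_bad_config")
    }
    # pairs within r_obs among all cells, once; each permutation then only
    # re-labels the endpoints
    n <- nrow(cells)
    d2 <- outer(cells$x, cells$x, "-")^2 + outer(cells$y, cells$y, "-")^2
    close <- which(upper.tri(d2) & d2 <= r_obs^2, arr.ind = TRUE)
    labs <- cells$cell_type
    same <- identical(type_a, type_b)
    perm_counts <- with_seed_or_current(seed, {
      vapply(seq_len(n_perm), function(i) {
        pl <- labs[sample.int(n)]
        la <- pl[close[, 1]]
        lb <- pl[close[, 2]]
        if (same) {
          sum(la == type_a & lb == type_a)
        } else {
          sum((la == type_a & lb == type_b) |
                (la == type_b & lb == type_a))
        }
      }, numeric(1))
    })
    expected <- mean(perm_counts)
    null_sd <- sd(perm_counts)
    if (!is.finite(null_sd) || null_sd == 0) {
      abort_bad_arg(
        "degenerate permutation null (zero variance); statistic undefined.",
        "immunokit_undefined_statistic"
      )
    }
  }
  tibble(
    type_a = type_a, type_b = type_b, age = age,
    observed = observed, observed_null = observed_null,
    expected = expected, null_sd = null_sd,
    z = (observed - expected) / null_sd,
    null_mode = null_mode
  )
}

#' Pearson age trend of interaction Z scores
#'
#' Correlates interaction Z scores with age across timepoints for each
#' cell-type pair. Replicate arrays at one age are summarised by their mean
#' Z (with a message) before the trend test. The two-sided p-value uses the
#' t transform with n - 2 degrees of freedom.
#'
#' @param z_scores Tibble of [interaction_zscore()] rows (columns `type_a`,
#'   `type_b`, `age`, `z`), covering >= 3 distinct ages per pair.
#' @return Tibble with one row per pair: `type_a`, `type_b`, `r`, `p`, `n`.
#' @examples
#' zs <- dplyr::bind_rows(lapply(1:4, function(a) {
#'   tibble::tibble(type_a = "A", type_b = "B", age = a * 10,
#'                  z = 5 - 0.1 * a + rnorm(1, sd = 0.01))
#' }))
#' zscore_age_trend(zs)
#' @export
zscore_age_trend <- function(z_scores) {
  z_scores <- as_tibble(z_scores)
  need <- c("type_a", "type_b", "age", "z")
  if (!all(need %in% names(z_scores))) {
    abort_bad_arg("`z_scores` needs columns type_a, type_b, age, z.",
                  "immunokit_bad_config")
  }
  z_scores %>%
    group_by(.data$type_a, .data$type_b) %>%
    dplyr::group_modify(function(df, key) {
      if (anyDuplicated(df$age)) {
        rlang::inform("replicate arrays per age summarised by mean z.")
        df <- df %>%
          group_by(.data$age) %>%
          summarise(z = mean(.data$z), .groups = "drop")
      }
      n <- nrow(df)
      if (n < 3) {
        abort_bad_arg("need >= 3 ages for an age trend.",
                      "immunokit_bad_config")
      }
      if (sd(df$z) == 0 || sd(df$age) == 0) {
        abort_bad_arg(
          "constant z or age: correlation undefined.",
          "immunokit_undefined_correlation"
        )
      }
      ct <- cor.test(df$age, df$z, method = "pearson")
      tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
    }) %>%
    ungroup()
}
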