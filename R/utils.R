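# internal helpers shared across modules

# Deterministic 31-bit seed derived from a base seed and a numeric key
# (e.g. an age). Linear-congruential style mixing keeps derived streams
# stable when new keys are added: the stream for one key never depends on
# which other keys are present.
mix_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  s <- as.double(seed) %% m
  k <- as.double(round(key * 1000)) %% m
  out <- (s * 48271 + k * 16807 + 12345) %% m
  as.integer(out)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL uses (and advances) the current stream.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

abort_bad_arg <- function(msg, class) {
  abort(msg, class = c(class, "immunokit_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, class = "immunokit_bad_config") {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    abort_bad_arg(
      sprintf("`%s` must be a single finite number in [%s, %s]%s; got %s.",
              name, format(lower), format(upper),
              if (strict_lower) " (exclusive lower bound)" else "",
              paste(format(x), collapse = ", ")),
      class
    )
  }
  invisible(x)
}

# cells: data frame with at least x, y, cell_type
check_cell_map <- function(cells, require_age = FALSE) {
  if (!is.data.frame(cells)) {
    abort_bad_arg("`cells` must be a data frame of cell positions.",
                  "immunokit_bad_map")
  }
  needed <- c("x", "y", "cell_type")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    abort_bad_arg(
      sprintf("`cells` is missing column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "immunokit_bad_map"
    )
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    abort_bad_arg("cell coordinates must be finite.", "immunokit_bad_map")
  }
  if (require_age && !"age" %in% names(cells)) {
    abort_bad_arg("`cells` must carry an `age` column.", "immunokit_bad_map")
  }
  invisible(cells)
}
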