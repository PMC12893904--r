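#' Call clones from CDR3 amino-acid junctions
#'
#' Cells sharing the same clone key share a clone. The key concatenates
#' the per-chain junctions (`TRA|TRB` when both chains are present, the
#' single chain's junction otherwise); cells with multiple junctions of
#' one chain contribute them sorted. Rows with empty junctions are
#' dropped, and cells left with no usable chain are excluded with a
#' reason.
#'
#' @param clonotypes AIRR-style long tibble: `cell_id`, `chain`
#'   (`"TRA"`/`"TRB"`), `junction_aa`; optional `run_id`, `treatment` are
#'   carried through (first value per cell).
#' @return Tibble with one row per retained cell: `cell_id`, `clone_key`,
#'   `clone_id`, plus carried metadata. Excluded cells are recorded in the
#'   `"excluded"` attribute (`cell_id`, `reason`).
#' @examples
#' tbl <- tibble::tibble(cell_id = c("c1", "c2"), chain = "TRB",
#'                       junction_aa = c("CASSLGF", "CASSLGF"))
#' call_clones(tbl)
#' @export
call_clones <- function(clonotypes) {
  clonotypes <- as_tibble(clonotypes)
  need <- c("cell_id", "chain", "junction_aa")
  if (!all(need %in% names(clonotypes)) || nrow(clonotypes) == 0) {
    abort_bad_arg(
      "`clonotypes` must be non-empty with cell_id, chain, junction_aa.",
      "immunokit_bad_config"
    )
  }
  ok <- !is.na(clonotypes$junction_aa) & nzchar(clonotypes$junction_aa)
  dropped_rows <- clonotypes[!ok, , drop = FALSE]
  usable <- clonotypes[ok, , drop = FALSE]
  excluded <- tibble(
    cell_id = setdiff(dropped_rows$cell_id, usable$cell_id),
    reason = "empty_junction"
  )
  if (nrow(usable) == 0) {
    abort_bad_arg("no cells with usable junctions.",
                  "immunokit_bad_config")
  }
  per_cell <- usable %>%
    group_by(.data$cell_id) %>%
    summarise(
      clone_key = paste(
        vapply(split(.data$junction_aa, .data$chain),
               function(j) paste(sort(j), collapse = ";"), character(1)),
        collapse = "|"
      ),
      .groups = "drop"
    )
  meta_cols <- intersect(c("run_id", "treatment"), names(usable))
  if (length(meta_cols)) {
    meta <- usable %>%
      group_by(.data$cell_id) %>%
      dplyr::slice(1) %>%
      ungroup() %>%
      select(dplyr::all_of(c("cell_id", meta_cols)))
    per_cell <- dplyr::left_join(per_cell, meta, by = "cell_id")
  }
  keys <- unique(per_cell$clone_key)
  per_cell$clone_id <- sprintf(
    "clone%04d", match(per_cell$clone_key, keys)
  )
  attr(per_cell, "excluded") <- excluded
  per_cell
}

#' Clonal proportions per run
#'
#' @param clones Output of [call_clones()].
#' @param by Grouping column (default `"run_id"` when present, otherwise
#'   the whole table is one run).
#' @return Tibble: grouping column, `clone_id`, `n_cells`, `proportion`
#'   (summing to 1 within each group).
#' @export
clone_proportions <- function(clones, by = "run_id") {
  clones <- as_tibble(clones)
  if (!by %in% names(clones)) {
    clones[[by]] <- "all"
  }
  clones %>%
    count(.data[[by]], .data$clone_id, name = "n_cells") %>%
    group_by(.data[[by]]) %>%
    mutate(proportion = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup()
}

#' Shannon diversity of a clone-size distribution
#'
#' `H = -sum(p_i * log(p_i))` in nats over clone frequencies. With
#' `downsample_n` set, cells are repeatedly downsampled without
#' replacement to that depth and `H` is the mean over `n_boot` bootstrap
#' draws — the equal-depth convention for comparing repertoires of
#' different sizes.
#'
#' @param clone_sizes Positive integer vector of cells per clone (names
#'   optional).
#' @param downsample_n Optional downsampling depth (<= total cells).
#' @param n_boot Bootstrap draws when downsampling.
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `H`, `n_cells`, `n_clones`, `downsample_n`,
#'   `n_boot`.
#' @examples
#' shannon_diversity(rep(5, 8))$H # log(8)
#' @export
shannon_diversity <- function(clone_sizes, downsample_n = NULL,
                              n_boot = 100, seed = 1L) {
  clone_sizes <- clone_sizes[clone_sizes > 0]
  if (length(clone_sizes) == 0) {
    abort_bad_arg("need at least one clone.", "immunokit_bad_config")
  }
  n_cells <- sum(clone_sizes)
  entropy <- function(sizes) {
    p <- sizes / sum(sizes)
    -sum(p * log(p))
  }
  if (is.null(downsample_n)) {
    h <- entropy(clone_sizes)
  } else {
    if (downsample_n > n_cells) {
      abort_bad_arg("`downsample_n` exceeds the number of cells.",
                    "immunokit_bad_config")
    }
    pool <- rep(seq_along(clone_sizes), times = clone_sizes)
    h <- with_seed_or_current(seed, {
      mean(vapply(seq_len(n_boot), function(i) {
        entropy(tabulate(pool[sample.int(n_cells, downsample_n)]))
      }, numeric(1)))
    })
  }
  tibble(
    H = h, n_cells = n_cells, n_clones = length(clone_sizes),
    downsample_n = downsample_n %||% NA_integer_, n_boot = n_boot
  )
}

#' Centred log-ratio normalisation of tag counts
#'
#' Per tag, `CLR(x) = log1p(x) - mean(log1p(x))` across cells (pseudocount
#' 1 via `log1p`; the margin is across cells, recorded in the
#' `"clr_margin"` attribute), so each tag's CLR values have mean 0 by
#' construction.
#'
#' @param counts Cells x tags matrix of non-negative counts.
#' @return Matrix of CLR values, same dimensions and dimnames.
#' @export
clr_normalize <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  if (any(counts < 0)) {
    abort_bad_arg("tag counts must be non-negative.",
                  "immunokit_bad_matrix")
  }
  lx <- log1p(counts)
  out <- sweep(lx, 2, colMeans(lx))
  attr(out, "clr_margin") <- "per tag across cells, log1p"
  out
}

#' Gate tetramer-positive cells on CLR-normalised signal
#'
#' Flags a cell antigen-specific (`Tet+`) when its CLR-normalised tag
#' signal strictly exceeds the threshold (default 1.7).
#'
#' @param clr CLR matrix from [clr_normalize()] (or a named vector for a
#'   single tag).
#' @param tag Tag (column) name to gate on.
#' @param threshold Gate threshold in CLR units; the inequality is strict,
#'   so a value exactly at the threshold is `Tet-`.
#' @return Tibble: `cell_id`, `clr`, `tet_pos`.
#' @export
tetramer_gate <- function(clr, tag = "tetramer", threshold = 1.7) {
  if (is.vector(clr)) clr <- matrix(clr, ncol = 1,
                                    dimnames = list(names(clr), tag))
  if (!tag %in% colnames(clr)) {
    abort_bad_arg(sprintf("tag '%s' is absent from the CLR matrix.", tag),
                  "immunokit_tag_absent")
  }
  check_number(threshold, "threshold")
  vals <- clr[, tag]
  tibble(
    cell_id = rownames(clr) %||% as.character(seq_along(vals)),
    clr = unname(vals),
    tet_pos = unname(vals > threshold)
  )
}

#' Downsample groups of cells to equal depth
#'
#' Samples every group without replacement down to the smallest group's
#' size, deterministically for a given seed.
#'
#' @param cells Data frame with a `cell_id` column.
#' @param group Name of the grouping column (e.g. treatment condition).
#' @param seed Integer seed.
#' @return The downsampled tibble (all groups the same size).
#' @export
downsample_equal <- function(cells, group = "treatment", seed = 1L) {
  cells <- as_tibble(cells)
  if (!group %in% names(cells)) {
    abort_bad_arg(sprintf("grouping column '%s' is absent.", group),
                  "immunokit_bad_config")
  }
  sizes <- table(cells[[group]])
  if (length(sizes) == 0 || any(sizes == 0)) {
    abort_bad_arg("every group must contain at least one cell.",
                  "immunokit_bad_config")
  }
  target <- min(sizes)
  with_seed_or_current(seed, {
    cells %>%
      group_by(.data[[group]]) %>%
      slice_sample(n = target) %>%
      ungroup()
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
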