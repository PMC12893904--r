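#' A minimal cell-by-gene expression container
#'
#' Bundles a cells-by-genes count matrix with a tibble of per-cell metadata.
#' Raw counts live in `$counts`; [preprocess_expression()] adds a normalised
#' matrix in `$norm`. Rows of both matrices are cells (named by `cell_id`),
#' columns are genes.
#'
#' @param counts Numeric matrix, cells in rows, genes in columns. Row and
#'   column names are required and must be unique; entries must be
#'   non-negative.
#' @param cells Optional data frame of per-cell metadata with a `cell_id`
#'   column matching the matrix rownames (any order). Defaults to a bare
#'   `cell_id` tibble.
#' @return An object of class `expr_set`: a list with elements `counts`,
#'   `norm` (or `NULL`) and `cells`.
#' @examples
#' m <- matrix(rpois(20, 3), 4, 5,
#'             dimnames = list(paste0("c", 1:4), paste0("g", 1:5)))
#' es <- expr_set(m)
#' dim(es)
#' @export
expr_set <- function(counts, cells = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort_bad_arg("`counts` must be a numeric matrix (cells x genes).",
                  "immunokit_bad_matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_bad_arg("`counts` needs cell rownames and gene colnames.",
                  "immunokit_bad_matrix")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort_bad_arg("cell and gene names must be unique.",
                  "immunokit_bad_matrix")
  }
  if (any(counts < 0)) {
    abort_bad_arg("expression counts must be non-negative.",
                  "immunokit_bad_matrix")
  }
  if (is.null(cells)) {
    cells <- tibble(cell_id = rownames(counts))
  } else {
    cells <- as_tibble(cells)
    if (!"cell_id" %in% names(cells)) {
      abort_bad_arg("`cells` metadata needs a `cell_id` column.",
                    "immunokit_bad_matrix")
    }
    if (!setequal(cells$cell_id, rownames(counts))) {
      abort_bad_arg("`cells$cell_id` must match the matrix rownames.",
                    "immunokit_bad_matrix")
    }
    cells <- cells[match(rownames(counts), cells$cell_id), , drop = FALSE]
  }
  structure(list(counts = counts, norm = NULL, cells = cells),
            class = "expr_set")
}

#' @export
dim.expr_set <- function(x) dim(x$counts)

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d cells x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm)) " (raw counts)" else " (normalised)"))
  extra <- setdiff(names(x$cells), "cell_id")
  if (length(extra)) {
    cat("  cell metadata:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn expr_set Long-format view: one row per (cell, gene) with the
#'   count and, when present, the normalised value.
#' @param x An `expr_set`.
#' @param ... Unused.
#' @export
tidy.expr_set <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE))
  names(long) <- c("cell_id", "gene", "count")
  if (!is.null(x$norm)) {
    long$value <- as.vector(x$norm)
  }
  dplyr::left_join(long, x$cells, by = "cell_id")
}

# internal: subset an expr_set to a set of cell ids (keeps order of `ids`)
subset_cells <- function(es, ids) {
  keep <- match(ids, rownames(es$counts))
  out <- es
  out$counts <- es$counts[keep, , drop = FALSE]
  if (!is.null(es$norm)) out$norm <- es$norm[keep, , drop = FALSE]
  out$cells <- es$cells[keep, , drop = FALSE]
  out
}
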