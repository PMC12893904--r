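#' Default three-level marker hierarchy for immune cell typing
#'
#' A hierarchy node holds the marker panel clustered at that level, the
#' number of k-means clusters `k`, per-type `signatures` (the designated
#' marker genes whose mean centroid expression decides each cluster's
#' label) and, optionally, `children` keyed by assigned label.
#'
#' Level 1 clusters a 19-gene pan-immune panel into 24 clusters mapped to
#' four types (T cell, B cell, macrophage, dendritic cell). Level 2
#' refines each type with lineage panels; level 3 refines CD4/CD8 T cells
#' with a 15-marker state panel (naive / effector / memory / exhausted).
#' Panels use generic mouse marker names and are meant for the synthetic
#' fixtures; real analyses supply their own hierarchy in the same shape.
#'
#' @param levels Maximum depth to include (1, 2 or 3).
#' @return A list with element `level1` (a hierarchy node).
#' @export
default_typing_hierarchy <- function(levels = 3) {
  sig1 <- list(
    "T cell" = c("Cd3e", "Cd3d", "Thy1", "Lck"),
    "B cell" = c("Cd19", "Ms4a1", "Cd79a", "Cd79b"),
    "macrophage" = c("Itgam", "Adgre1", "Csf1r", "Lyz2"),
    "dendritic cell" = c("Itgax", "Flt3", "Zbtb46", "Batf3")
  )
  level1 <- list(
    markers = c(unlist(sig1, use.names = FALSE),
                "Ptprc", "Cd52", "H2-Aa"),
    k = 24,
    signatures = sig1,
    children = NULL
  )
  if (levels >= 2) {
    t15 <- c("Tcf7", "Lef1", "Ccr7", "Il7r", "Cd69", "Gzmb", "Prf1",
             "Ifng", "Pdcd1", "Ctla4", "Lag3", "Havcr2", "Tox", "Eomes",
             "Tbx21")
    t_state <- list(
      markers = t15, k = 6,
      signatures = list(
        "naive" = c("Tcf7", "Lef1", "Ccr7", "Il7r"),
        "effector" = c("Gzmb", "Prf1", "Ifng"),
        "memory" = c("Eomes", "Cd69"),
        "exhausted" = c("Pdcd1", "Ctla4", "Lag3", "Havcr2", "Tox")
      ),
      children = NULL
    )
    level1$children <- list(
      "T cell" = list(
        markers = c("Cd4", "Cd8a", "Cd8b1", "Sell", "Cd44", "Foxp3"),
        k = 6,
        signatures = list(
          "CD4 T" = "Cd4",
          "CD8 T" = c("Cd8a", "Cd8b1"),
          "Treg" = "Foxp3"
        ),
        children = if (levels >= 3) {
          list("CD4 T" = t_state, "CD8 T" = t_state)
        } else NULL
      ),
      "B cell" = list(
        markers = c("Cd22", "Cd40", "Itgax", "Tbx21"), k = 4,
        signatures = list(
          "mature B" = c("Cd22", "Cd40"),
          "age-associated B" = c("Itgax", "Tbx21")
        ),
        children = NULL
      ),
      "macrophage" = list(
        markers = c("Mrc1", "Nos2", "Cd68", "Arg1"), k = 4,
        signatures = list(
          "M1-like" = "Nos2",
          "M2-like" = c("Mrc1", "Arg1")
        ),
        children = NULL
      ),
      "dendritic cell" = list(
        markers = c("Xcr1", "Clec9a", "Sirpa", "Siglech"), k = 4,
        signatures = list(
          "cDC1" = c("Xcr1", "Clec9a"),
          "cDC2" = "Sirpa",
          "pDC" = "Siglech"
        ),
        children = NULL
      )
    )
  }
  list(level1 = level1)
}

# all genes referenced anywhere in a hierarchy
typing_gene_panel <- function(hierarchy) {
  collect <- function(node) {
    if (is.null(node)) return(character())
    c(node$markers, unlist(node$signatures, use.names = FALSE),
      unlist(lapply(node$children, collect), use.names = FALSE))
  }
  unique(collect(hierarchy$level1))
}

#' Quality-control filter on raw counts
#'
#' Removes cells with fewer than `min_reads` total reads or fewer than
#' `min_genes` detected genes (either condition failing excludes the
#' cell). Removal reasons are logged per cell in the `"qc_log"` attribute.
#'
#' @param expr An [expr_set] of raw counts.
#' @param min_reads Minimum total reads per cell (default 2: cells with
#'   less than two reads are excluded).
#' @param min_genes Minimum detected genes per cell (default 2).
#' @return The filtered `expr_set`; attribute `"qc_log"` is a tibble
#'   (`cell_id`, `total_reads`, `n_genes`, `qc_pass`, `dropped_reason`).
#' @examples
#' m <- matrix(c(0, 1, 5, 2, 0, 0, 0, 2), 4, 2,
#'             dimnames = list(paste0("c", 1:4), c("g1", "g2")))
#' qc <- qc_filter(expr_set(m))
#' attr(qc, "qc_log")
#' @export
qc_filter <- function(expr, min_reads = 2, min_genes = 2) {
  if (!inherits(expr, "expr_set")) {
    abort_bad_arg("`expr` must be an expr_set.", "immunokit_bad_matrix")
  }
  total <- rowSums(expr$counts)
  ngene <- rowSums(expr$counts > 0)
  low_reads <- total < min_reads
  low_genes <- ngene < min_genes
  pass <- !(low_reads | low_genes)
  reason <- rep(NA_character_, length(pass))
  reason[low_reads & low_genes] <- "low_reads;low_genes"
  reason[low_reads & !low_genes] <- "low_reads"
  reason[!low_reads & low_genes] <- "low_genes"
  log <- tibble(
    cell_id = rownames(expr$counts),
    total_reads = unname(total),
    n_genes = unname(ngene),
    qc_pass = unname(pass),
    dropped_reason = reason
  )
  if (!any(pass)) {
    abort_bad_arg("no cells pass quality control.",
                  "immunokit_empty_after_qc")
  }
  out <- subset_cells(expr, rownames(expr$counts)[pass])
  attr(out, "qc_log") <- log
  out
}

#' Normalise and scale a QC-filtered count matrix
#'
#' Standard depth normalisation and scaling: per-cell totals are rescaled
#' to the cohort median total, values are log1p-transformed, and each gene
#' is centred to mean 0 and scaled to unit variance (genes with zero
#' variance are left at 0). The result is stored in the `norm` slot; raw
#' counts are kept.
#'
#' @param expr A QC-filtered [expr_set].
#' @return The `expr_set` with a populated `norm` matrix and a
#'   `"norm_params"` attribute (median total used).
#' @export
preprocess_expression <- function(expr) {
  if (!inherits(expr, "expr_set")) {
    abort_bad_arg("`expr` must be an expr_set.", "immunokit_bad_matrix")
  }
  total <- rowSums(expr$counts)
  if (any(total == 0)) {
    abort_bad_arg("zero-total cell encountered; run qc_filter() first.",
                  "immunokit_zero_total")
  }
  target <- median(total)
  scaled <- expr$counts * (target / total)
  logged <- log1p(scaled)
  mu <- colMeans(logged)
  sdev <- apply(logged, 2, sd)
  sdev[sdev == 0] <- 1 # constant gene: centred value is 0 either way
  expr$norm <- sweep(sweep(logged, 2, mu), 2, sdev, "/")
  attr(expr, "norm_params") <- list(median_total = target)
  expr
}

# k-means on a marker submatrix, clusters mapped to the signature type
# with the maximal centroid score; returns per-cell labels ("unassigned"
# when no signature is positive in the centroid)
classify_node <- function(values, node, seed) {
  missing_markers <- setdiff(node$markers, colnames(values))
  if (length(missing_markers)) {
    abort_bad_arg(
      sprintf("marker(s) absent from the matrix: %s.",
              paste(missing_markers, collapse = ", ")),
      "immunokit_gene_absent"
    )
  }
  sub <- values[, node$markers, drop = FALSE]
  k <- min(node$k, nrow(sub))
  cl <- with_seed_or_current(seed, {
    if (k == 1) {
      rep(1L, nrow(sub))
    } else if (nrow(sub) <= k) {
      seq_len(nrow(sub))
    } else {
      suppressWarnings(
        kmeans(sub, centers = k, nstart = 10, iter.max = 100)$cluster
      )
    }
  })
  centroids <- rowsum(sub, cl) / as.vector(table(cl))
  types <- names(node$signatures)
  score <- vapply(types, function(ty) {
    g <- intersect(node$signatures[[ty]], colnames(sub))
    rowMeans(centroids[, g, drop = FALSE])
  }, numeric(nrow(centroids)))
  score <- matrix(score, nrow = nrow(centroids),
                  dimnames = list(rownames(centroids), types))
  best <- types[max.col(score, ties.method = "first")]
  best[apply(score, 1, max) <= 0] <- "unassigned"
  unname(best[match(as.character(cl), rownames(score))])
}

#' Hierarchical marker-based cell typing
#'
#' Three-stage assignment on a preprocessed matrix: (i) cells with zero
#' raw expression across the level-1 marker panel are removed; (ii)
#' k-means with the level's `k` on the panel submatrix of normalised
#' values; (iii) each cluster is mapped to the type whose signature (mean
#' of its designated markers in the cluster centroid) is maximal, or
#' `"unassigned"` when no signature is positive; (iv) the procedure
#' recurses into each assigned type's child node. Child labels always
#' nest under their parent label by construction.
#'
#' @param expr A preprocessed [expr_set] (see [preprocess_expression()]).
#' @param hierarchy A hierarchy as built by [default_typing_hierarchy()].
#' @param seed Integer seed (k-means restarts at every node derive their
#'   seeds from it).
#' @return Tibble with one row per input cell: `cell_id`, `qc_pass`
#'   (FALSE only for cells dropped here), `dropped_reason`, `level1`,
#'   `level2`, `level3` (NA where a level does not apply).
#' @export
hierarchical_classify <- function(expr, hierarchy = default_typing_hierarchy(),
                                  seed = 1L) {
  if (!inherits(expr, "expr_set") || is.null(expr$norm)) {
    abort_bad_arg("`expr` must be a preprocessed expr_set.",
                  "immunokit_bad_matrix")
  }
  node <- hierarchy$level1
  panel <- intersect(node$markers, colnames(expr$counts))
  if (length(panel) < length(node$markers)) {
    abort_bad_arg("level-1 marker panel is not a subset of matrix genes.",
                  "immunokit_gene_absent")
  }
  no_marker <- rowSums(expr$counts[, panel, drop = FALSE]) == 0
  out <- tibble(
    cell_id = rownames(expr$counts),
    qc_pass = unname(!no_marker),
    dropped_reason = unname(ifelse(no_marker, "no_marker_expression",
                                   NA_character_)),
    level1 = NA_character_, level2 = NA_character_,
    level3 = NA_character_
  )
  kept <- subset_cells(expr, out$cell_id[!no_marker])
  if (nrow(kept$counts) == 0) {
    abort_bad_arg("no cells express any level-1 marker.",
                  "immunokit_empty_after_qc")
  }

  assign_level <- function(values, node, depth, seed) {
    labels <- classify_node(values, node, seed)
    res <- list(labels)
    if (!is.null(node$children)) {
      deeper <- rep(NA_character_, nrow(values))
      deeper2 <- rep(NA_character_, nrow(values))
      for (ty in names(node$children)) {
        idx <- which(labels == ty)
        if (length(idx) < 2) next
        child <- node$children[[ty]]
        sub_res <- assign_level(values[idx, , drop = FALSE], child,
                                depth + 1, mix_seed(seed, depth + 1))
        deeper[idx] <- sub_res[[1]]
        if (length(sub_res) > 1) deeper2[idx] <- sub_res[[2]]
      }
      res <- c(res, list(deeper), if (any(!is.na(deeper2)))
        list(deeper2))
    }
    res
  }
  levels_out <- assign_level(kept$norm, node, 1, seed)
  keep_idx <- match(rownames(kept$counts), out$cell_id)
  out$level1[keep_idx] <- levels_out[[1]]
  if (length(levels_out) >= 2) out$level2[keep_idx] <- levels_out[[2]]
  if (length(levels_out) >= 3) out$level3[keep_idx] <- levels_out[[3]]
  out
}
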