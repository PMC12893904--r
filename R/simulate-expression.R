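#' Simulate a cell-by-gene count matrix with region or type structure
#'
#' Draws negative-binomial counts per cell and gene, with per-group mean
#' multipliers ("programs") imprinting either spatial region structure or
#' cell-type marker structure:
#'
#' * `mode = "regions"`: cells are scattered uniformly over a rectangle and
#'   assigned to `n_regions` contiguous vertical bands; each region elevates
#'   its own block of marker genes by `effect`.
#' * `mode = "types"`: cells are split evenly across the level-1 cell types
#'   of [default_typing_hierarchy()] (T cell, B cell, macrophage, dendritic
#'   cell); each type elevates its signature markers by `effect` over the
#'   full hierarchy gene panel.
#'
#' Ground-truth labels are returned separately from the observations; the
#' observed metadata never contains the truth column.
#'
#' @param mode `"regions"` or `"types"`.
#' @param n_cells Total number of cells.
#' @param n_genes Genes in `"regions"` mode (ignored for `"types"`, which
#'   uses the hierarchy panel).
#' @param n_regions Number of contiguous spatial bands (`"regions"` mode).
#' @param markers_per_region Marker genes elevated per region.
#' @param effect Mean multiplier for marker genes (> 1 separates groups).
#'   Default `NULL` picks 3 for `"regions"` (regional programs shift
#'   expression moderately) and 8 for `"types"` (lineage markers are
#'   near on/off).
#' @param nb_mean Baseline negative-binomial mean per gene (> 0).
#' @param nb_dispersion Negative-binomial size parameter (> 0); variance is
#'   `mu + mu^2 / size`.
#' @param poisson If `TRUE`, draw Poisson counts (the infinite-dispersion
#'   limit) instead of negative-binomial.
#' @param width,height Spatial domain in µm (`"regions"` mode).
#' @param programs Optional custom multiplier matrix (groups x genes, with
#'   dimnames); overrides the built-in program layout.
#' @param seed Integer seed.
#' @return A list with `expr` (an [expr_set]; in `"regions"` mode the cell
#'   metadata carries `x`, `y`) and `truth` (tibble `cell_id` + `region` or
#'   `cell_type`).
#' @examples
#' sim <- simulate_expression("regions", n_cells = 90, n_genes = 12,
#'                            seed = 1)
#' dim(sim$expr)
#' head(sim$truth)
#' @export
simulate_expression <- function(mode = c("regions", "types"),
                                n_cells = 1200,
                                n_genes = 30,
                                n_regions = 3,
                                markers_per_region = 8,
                                effect = NULL,
                                nb_mean = 2,
                                nb_dispersion = 2,
                                poisson = FALSE,
                                width = 1500, height = 1000,
                                programs = NULL,
                                seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(effect)) effect <- if (mode == "regions") 3 else 8
  check_number(n_cells, "n_cells", lower = 1)
  check_number(nb_mean, "nb_mean", lower = 0, strict_lower = TRUE)
  check_number(nb_dispersion, "nb_dispersion", lower = 0,
               strict_lower = TRUE)
  check_number(effect, "effect", lower = 0, strict_lower = TRUE)

  if (mode == "regions") {
    if (is.null(programs)) {
      n_genes <- max(n_genes, n_regions * markers_per_region)
      genes <- sprintf("g%02d", seq_len(n_genes))
      programs <- matrix(1, n_regions, n_genes,
                         dimnames = list(sprintf("region%d", seq_len(n_regions)),
                                         genes))
      for (r in seq_len(n_regions)) {
        idx <- ((r - 1) * markers_per_region + 1):(r * markers_per_region)
        programs[r, idx] <- effect
      }
    }
  } else {
    hier <- default_typing_hierarchy()
    genes <- typing_gene_panel(hier)
    if (is.null(programs)) {
      types <- names(hier$level1$signatures)
      programs <- matrix(1, length(types), length(genes),
                         dimnames = list(types, genes))
      for (ty in types) {
        programs[ty, hier$level1$signatures[[ty]]] <- effect
      }
      # pan-immune genes moderately expressed everywhere
      shared <- setdiff(hier$level1$markers,
                        unlist(hier$level1$signatures))
      programs[, shared] <- 2
    }
  }
  if (is.null(dimnames(programs)) || is.null(rownames(programs))) {
    abort_bad_arg("`programs` must carry group rownames and gene colnames.",
                  "immunokit_bad_config")
  }
  genes <- colnames(programs)
  groups <- rownames(programs)

  with_seed_or_current(seed, {
    if (mode == "regions") {
      x <- runif(n_cells, 0, width)
      y <- runif(n_cells, 0, height)
      band <- pmin(findInterval(x, seq(0, width, length.out =
                                         nrow(programs) + 1),
                                rightmost.closed = TRUE),
                   nrow(programs))
      group_idx <- band
    } else {
      group_idx <- rep(seq_along(groups), length.out = n_cells)
      group_idx <- sample(group_idx) # shuffle type order over cells
    }
    mu <- nb_mean * programs[group_idx, , drop = FALSE]
    counts <- if (poisson) {
      matrix(rpois(length(mu), lambda = mu), nrow = n_cells)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = nb_dispersion),
             nrow = n_cells)
    }
    ids <- sprintf("cell%05d", seq_len(n_cells))
    dimnames(counts) <- list(ids, genes)
    meta <- if (mode == "regions") {
      tibble(cell_id = ids, x = x, y = y)
    } else {
      tibble(cell_id = ids)
    }
    truth <- if (mode == "regions") {
      tibble(cell_id = ids, region = groups[group_idx])
    } else {
      tibble(cell_id = ids, cell_type = groups[group_idx])
    }
    list(expr = expr_set(counts, meta), truth = truth)
  })
}
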