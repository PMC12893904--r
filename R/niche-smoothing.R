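#' Delaunay triangulation adjacency of cell positions
#'
#' Builds the undirected spatial neighbour graph whose edges are the
#' Delaunay triangulation of the 2-D cell positions (computed with
#' \pkg{deldir}). Optionally prunes edges longer than `prune_above` to
#' avoid long sliver edges across empty space.
#'
#' @param points Data frame with columns `x`, `y` (and optionally
#'   `cell_id`); >= 3 non-collinear, distinct points.
#' @param prune_above Optional length cutoff in the coordinate units;
#'   `NULL` (default) keeps all triangulation edges.
#' @return An object of class `spatial_graph`: list with `edges` (tibble
#'   `from`, `to`, `length`; 1-based node indices, `from < to`), `n`
#'   nodes, `degree`, and the node `ids`.
#' @examples
#' g <- delaunay_adjacency(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)))
#' nrow(g$edges) # 3
#' @export
delaunay_adjacency <- function(points, prune_above = NULL) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    abort_bad_arg("`points` must have columns x and y.",
                  "immunokit_bad_map")
  }
  n <- nrow(points)
  if (n < 3) {
    abort_bad_arg("need >= 3 points for a triangulation.",
                  "immunokit_bad_map")
  }
  if (anyDuplicated(points[, c("x", "y")])) {
    abort_bad_arg("duplicate coordinates; jitter the points first.",
                  "immunokit_duplicate_points")
  }
  xr <- range(points$x); yr <- range(points$y)
  # collinearity: zero area of the point cloud's convex hull
  cx <- points$x - mean(points$x); cy <- points$y - mean(points$y)
  if (abs(sum(cx * cy)^2 - sum(cx^2) * sum(cy^2)) < 1e-12 *
      max(1, sum(cx^2) * sum(cy^2))) {
    abort_bad_arg("points are collinear; no triangulation exists.",
                  "immunokit_collinear_points")
  }
  dd <- deldir::deldir(points$x, points$y, suppressMsge = TRUE)
  e <- dd$delsgs
  from <- pmin(e$ind1, e$ind2)
  to <- pmax(e$ind1, e$ind2)
  len <- sqrt((e$x1 - e$x2)^2 + (e$y1 - e$y2)^2)
  keep <- !duplicated(cbind(from, to))
  edges <- tibble(from = from[keep], to = to[keep], length = len[keep])
  if (!is.null(prune_above)) {
    edges <- edges[edges$length <= prune_above, , drop = FALSE]
  }
  deg <- tabulate(c(edges$from, edges$to), nbins = n)
  ids <- if ("cell_id" %in% names(points)) points$cell_id else
    as.character(seq_len(n))
  structure(list(edges = edges, n = n, degree = deg, ids = ids),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> %d nodes, %d edges (Delaunay)\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Heat-kernel smoothing of a cell-by-gene matrix over a spatial graph
#'
#' Low-pass filters each gene column by the graph heat kernel
#' `exp(-t * L_rw)` with the random-walk normalised Laplacian
#' `L_rw = I - D^{-1} A`. Random-walk normalisation preserves constant
#' signals exactly and makes the diffusion time `t` degree-independent.
#' The kernel is evaluated per connected component through the symmetric
#' normalised Laplacian: `exp(-t L_rw) = D^{-1/2} U exp(-t Lambda) U' D^{1/2}`
#' with `U`, `Lambda` the eigenpairs of `L_sym = I - D^{-1/2} A D^{-1/2}`.
#' Isolated nodes (degree 0) are left unsmoothed with a warning.
#'
#' @param x Numeric matrix, rows = graph nodes (cells), columns = genes;
#'   `nrow(x)` must equal the number of graph nodes.
#' @param graph A `spatial_graph` from [delaunay_adjacency()].
#' @param t Diffusion time (>= 0); `t = 0` returns `x` unchanged.
#' @return The smoothed matrix, same dimensions and dimnames as `x`.
#' @examples
#' g <- delaunay_adjacency(data.frame(x = runif(20), y = runif(20)))
#' x <- matrix(rnorm(40), 20, 2)
#' xs <- heat_smooth(x, g, t = 10)
#' @export
heat_smooth <- function(x, graph, t = 10) {
  if (!inherits(graph, "spatial_graph")) {
    abort_bad_arg("`graph` must be a spatial_graph.", "immunokit_bad_map")
  }
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != graph$n) {
    abort_bad_arg(
      sprintf("matrix has %d rows but the graph has %d nodes.",
              nrow(x), graph$n),
      "immunokit_dim_mismatch"
    )
  }
  check_number(t, "t", lower = 0)
  if (t == 0) return(x)
  if (any(graph$degree == 0)) {
    warn("isolated node(s) with degree 0 left unsmoothed.")
  }
  ig <- igraph::graph_from_edgelist(
    as.matrix(graph$edges[, c("from", "to")]), directed = FALSE
  )
  ig <- igraph::add_vertices(ig, max(0, graph$n - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  out <- x
  for (cid in unique(comp)) {
    nodes <- which(comp == cid)
    if (length(nodes) == 1) next # isolated: left as-is
    sub <- graph$edges[graph$edges$from %in% nodes, , drop = FALSE]
    sub <- sub[sub$to %in% nodes, , drop = FALSE]
    idx <- match(seq_len(graph$n), nodes)
    a <- matrix(0, length(nodes), length(nodes))
    fi <- idx[sub$from]; ti <- idx[sub$to]
    a[cbind(fi, ti)] <- 1
    a[cbind(ti, fi)] <- 1
    d <- rowSums(a)
    dis <- 1 / sqrt(d)
    lsym <- diag(length(nodes)) - (dis * a) %*% diag(dis)
    lsym <- (lsym + t(lsym)) / 2
    eg <- eigen(lsym, symmetric = TRUE)
    damp <- exp(-t * pmax(eg$values, 0))
    xs <- x[nodes, , drop = FALSE] * sqrt(d)       # D^{1/2} x
    xs <- eg$vectors %*% (damp * (t(eg$vectors) %*% xs))
    out[nodes, ] <- xs * dis                        # D^{-1/2} result
  }
  out
}

#' Identify tissue regions from a smoothed expression matrix
#'
#' Principal component analysis (per-gene centring, no rescaling) on the
#' low-pass-filtered cell-by-gene matrix followed by k-means clustering in
#' PC space (k-means++-free base k-means with multiple restarts under a
#' fixed seed; k-means avoids smoothing-induced spatial autocorrelation
#' artefacts that neighbour-graph clustering would amplify). Region labels
#' are relabelled by decreasing cluster size and returned as contiguous
#' integers starting at 0.
#'
#' @param x Smoothed cell-by-gene matrix (rows = cells).
#' @param n_pcs Number of principal components (<= min(cells, genes)).
#' @param k Number of regions (1 <= k <= cells).
#' @param seed Integer seed; identical inputs give identical labels.
#' @param n_start k-means restarts.
#' @return Tibble with `cell_id` (rownames of `x`, or row index) and
#'   integer `region` in `0:(k-1)`; attributes `k`, `n_pcs`, `seed`.
#' @export
region_call <- function(x, n_pcs = 10, k = 3, seed = 1L, n_start = 10) {
  if (k < 1 || k > nrow(x)) {
    abort_bad_arg("`k` must be between 1 and the number of cells.",
                  "immunokit_bad_config")
  }
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1)
  cl <- with_seed_or_current(seed, {
    if (k == 1) {
      rep(1L, nrow(x))
    } else {
      pcs <- prcomp(x, center = TRUE, scale. = FALSE,
                    rank. = n_pcs)$x
      kmeans(pcs, centers = k, nstart = n_start,
             iter.max = 100)$cluster
    }
  })
  # contiguous 0-based ids, largest region first (ties: first occurrence)
  sizes <- table(cl)
  ord <- names(sort(sizes, decreasing = TRUE))
  relab <- setNames(seq_along(ord) - 1L, ord)
  out <- tibble(
    cell_id = if (!is.null(rownames(x))) rownames(x) else
      as.character(seq_len(nrow(x))),
    region = unname(relab[as.character(cl)])
  )
  attr(out, "k") <- k
  attr(out, "n_pcs") <- n_pcs
  attr(out, "seed") <- seed
  out
}
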