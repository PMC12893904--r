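# shared fixtures and independent oracles

# brute-force double-loop pair count (independent of count_pairs_within)
brute_pair_count <- function(cells, type_a, type_b, radius) {
  a <- which(cells$cell_type == type_a)
  b <- which(cells$cell_type == type_b)
  n <- 0L
  for (i in a) {
    for (j in b) {
      if (identical(type_a, type_b) && j <= i) next
      d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
      if (d <= radius) n <- n + 1L
    }
  }
  n
}

# a map with one A cell at the origin and rings of B cells
ring_map <- function(n_inner, n_annulus, r_inner = 10, r_annulus = 100) {
  ang1 <- seq(0, 2 * pi, length.out = n_inner + 1)[seq_len(n_inner)]
  ang2 <- seq(0, 2 * pi, length.out = n_annulus + 1)[seq_len(n_annulus)]
  data.frame(
    x = c(0, r_inner * cos(ang1), r_annulus * cos(ang2)),
    y = c(0, r_inner * sin(ang1), r_annulus * sin(ang2)),
    cell_type = c("A", rep("B", n_inner + n_annulus))
  )
}

# brute-force Delaunay edges: edges of every triangle whose circumcircle
# is empty of the remaining points (general position assumed)
brute_delaunay_edges <- function(points) {
  n <- nrow(points)
  x <- points$x; y <- points$y
  edges <- list()
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]
        cx <- x[k]; cy <- y[k]
        d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(d) < 1e-12) next
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / d
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / d
        r2 <- (ax - ux)^2 + (ay - uy)^2
        others <- setdiff(seq_len(n), c(i, j, k))
        if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 + 1e-9))) {
          edges <- c(edges, list(c(i, j), c(i, k), c(j, k)))
        }
      }
    }
  }
  m <- unique(do.call(rbind, edges))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# dense random-walk Laplacian of a spatial_graph
dense_lrw <- function(graph) {
  a <- matrix(0, graph$n, graph$n)
  a[cbind(graph$edges$from, graph$edges$to)] <- 1
  a[cbind(graph$edges$to, graph$edges$from)] <- 1
  d <- rowSums(a)
  diag(graph$n) - a / d
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  (sum_ij - expected) / (maxi - expected)
}

# toy expr_set whose "normalised" values are set directly
toy_lr_set <- function(values, types, ages = NULL) {
  ids <- sprintf("c%03d", seq_len(nrow(values)))
  dimnames(values) <- list(ids, colnames(values))
  meta <- tibble::tibble(cell_id = ids, cell_type = types)
  if (!is.null(ages)) meta$age <- ages
  es <- expr_set(matrix(0, nrow(values), ncol(values),
                        dimnames = dimnames(values)), meta)
  es$norm <- values
  es
}

level1_accuracy <- function(typed, truth) {
  m <- match(truth$cell_id, typed$cell_id)
  mean(typed$level1[m] == truth$cell_type, na.rm = TRUE)
}
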