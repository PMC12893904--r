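toy_counts <- function() {
  m <- rbind(
    c1 = c(1, 0, 0), # 1 read, 1 gene: fails both
    c2 = c(1, 1, 0), # 2 reads over 2 genes: boundary, retained
    c3 = c(5, 0, 0), # 5 reads in 1 gene: fails the gene condition
    c4 = c(3, 2, 1)
  )
  colnames(m) <- c("g1", "g2", "g3")
  m
}

test_that("qc filter applies the reads/genes boundary exactly", {
  qc <- qc_filter(expr_set(toy_counts()))
  log <- attr(qc, "qc_log")
  expect_equal(rownames(qc$counts), c("c2", "c4"))
  expect_false(log$qc_pass[log$cell_id == "c1"])
  expect_true(log$qc_pass[log$cell_id == "c2"])
  expect_equal(log$dropped_reason[log$cell_id == "c3"], "low_genes")
  expect_equal(log$dropped_reason[log$cell_id == "c1"],
               "low_reads;low_genes")

  empty <- expr_set(matrix(0, 2, 2,
                           dimnames = list(c("a", "b"), c("g1", "g2"))))
  expect_error(qc_filter(empty), class = "immunokit_empty_after_qc")
})

test_that("relaxing qc thresholds never drops a previously retained cell", {
  set.seed(31)
  m <- matrix(rpois(400, 0.8), 40, 10,
              dimnames = list(sprintf("c%02d", 1:40),
                              sprintf("g%02d", 1:10)))
  m[1, ] <- c(9, rep(0, 9)) # keep at least one cell under any threshold
  strict <- rownames(qc_filter(expr_set(m), min_reads = 3,
                               min_genes = 3)$counts)
  relaxed <- rownames(qc_filter(expr_set(m), min_reads = 1,
                                min_genes = 1)$counts)
  expect_true(all(strict %in% relaxed))
})

test_that("preprocessing centres and scales genes after depth normalisation", {
  sim <- simulate_expression("types", n_cells = 150, seed = 32)
  es <- preprocess_expression(qc_filter(sim$expr))
  expect_equal(unname(colMeans(es$norm)), rep(0, ncol(es$norm)),
               tolerance = 1e-8)
  sds <- apply(es$norm, 2, sd)
  expect_equal(unname(sds[sds > 0]), rep(1, sum(sds > 0)),
               tolerance = 1e-8)
  # depth normalisation rescales every cell to the cohort median total
  total <- rowSums(es$counts)
  target <- attr(es, "norm_params")$median_total
  rescaled <- rowSums(es$counts * (target / total))
  expect_equal(unname(rescaled), rep(target, nrow(es$counts)),
               tolerance = 1e-8)
  expect_identical(es$norm,
                   preprocess_expression(qc_filter(sim$expr))$norm)
})

test_that("zero-total cells are rejected by preprocessing", {
  m <- matrix(c(0, 2, 0, 3), 2, 2,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(preprocess_expression(expr_set(m)),
               class = "immunokit_zero_total")
})

test_that("cells without any level-1 marker are removed with a reason", {
  sim <- simulate_expression("types", n_cells = 200, seed = 33)
  es <- preprocess_expression(qc_filter(sim$expr))
  hier <- default_typing_hierarchy()
  # force one cell to zero across the level-1 panel
  victim <- rownames(es$counts)[1]
  es$counts[victim, hier$level1$markers] <- 0
  typed <- hierarchical_classify(es, hier, seed = 1)
  row <- typed[typed$cell_id == victim, ]
  expect_false(row$qc_pass)
  expect_equal(row$dropped_reason, "no_marker_expression")
  expect_true(is.na(row$level1))
  # conservation: dropped + typed = input
  expect_equal(nrow(typed), nrow(es$counts))
  expect_equal(sum(!typed$qc_pass) + sum(!is.na(typed$level1)),
               nrow(es$counts))
})

test_that("level-2 labels nest under their level-1 parents", {
  sim <- simulate_expression("types", n_cells = 400, seed = 34)
  es <- preprocess_expression(qc_filter(sim$expr))
  hier <- default_typing_hierarchy()
  typed <- hierarchical_classify(es, hier, seed = 1)
  kids <- typed[!is.na(typed$level2), ]
  for (i in seq_len(nrow(kids))) {
    parent <- kids$level1[i]
    expect_true(kids$level2[i] %in%
                  c(names(hier$level1$children[[parent]]$signatures),
                    "unassigned"))
  }
  # level 3 only ever appears under CD4/CD8 T cells
  l3 <- typed[!is.na(typed$level3), ]
  expect_true(all(l3$level2 %in% c("CD4 T", "CD8 T")))
})

test_that("classification accuracy is high and degrades as separation shrinks", {
  acc_at <- function(effect) {
    sim <- simulate_expression("types", n_cells = 500, effect = effect,
                               seed = 35)
    es <- preprocess_expression(qc_filter(sim$expr))
    level1_accuracy(hierarchical_classify(es, seed = 1), sim$truth)
  }
  a_hi <- acc_at(8)
  a_mid <- acc_at(3)
  a_lo <- acc_at(1.2)
  expect_gte(a_hi, 0.9)
  expect_gte(a_hi, a_mid)
  expect_gt(a_mid, a_lo)
})

test_that("missing marker panels raise an explicit error", {
  sim <- simulate_expression("regions", n_cells = 60, n_genes = 10,
                             seed = 36)
  es <- preprocess_expression(qc_filter(sim$expr))
  expect_error(hierarchical_classify(es, seed = 1),
               class = "immunokit_gene_absent")
})
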