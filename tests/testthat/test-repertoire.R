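test_that("clone calling groups cells by CDR3 key and logs exclusions", {
  tbl <- tibble::tibble(
    cell_id = c("c1", "c2", "c3", "c3", "c4"),
    chain = c("TRB", "TRB", "TRA", "TRB", "TRB"),
    junction_aa = c("CASSLGF", "CASSLGF", "CAVRDF", "CASSLGF", ""),
    run_id = "r1"
  )
  cl <- call_clones(tbl)
  # identical TRB junction, no TRA: same clone
  expect_equal(cl$clone_id[cl$cell_id == "c1"],
               cl$clone_id[cl$cell_id == "c2"])
  # paired-chain cell gets a different key than TRB-only cells
  expect_false(cl$clone_id[cl$cell_id == "c3"] %in%
                 cl$clone_id[cl$cell_id %in% c("c1", "c2")])
  excluded <- attr(cl, "excluded")
  expect_equal(excluded$cell_id, "c4")
  expect_equal(excluded$reason, "empty_junction")
  # conservation: clone sizes sum to retained cells
  expect_equal(sum(table(cl$clone_id)), 3)
})

test_that("clonal proportions match a group-by oracle and sum to one", {
  sim <- simulate_repertoire(120, "geometric", n_clones = 10, seed = 41)
  cl <- call_clones(sim$table)
  props <- clone_proportions(cl)
  oracle <- table(cl$clone_id) / nrow(cl)
  expect_equal(props$proportion[match(names(oracle), props$clone_id)],
               as.vector(oracle))
  expect_equal(sum(props$proportion), 1)
  # called clones agree with generator truth up to labelling
  m <- match(sim$truth$cell_id, cl$cell_id)
  expect_equal(ari(cl$clone_id[m], sim$truth$clone_id), 1)
})

test_that("Shannon diversity closed forms hold", {
  expect_equal(shannon_diversity(rep(5, 8))$H, log(8), tolerance = 1e-12)
  expect_equal(shannon_diversity(40)$H, 0)
  expect_equal(shannon_diversity(c(2, 1, 1))$H,
               -(0.5 * log(0.5) + 0.25 * log(0.25) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(shannon_diversity(c(2, 1, 1))$H, 1.0397, tolerance = 1e-4)
})

test_that("diversity is invariant to relabelling/scaling and grows on splits", {
  sizes <- c(7, 3, 2, 1)
  expect_equal(shannon_diversity(sizes)$H,
               shannon_diversity(rev(sizes))$H)
  expect_equal(shannon_diversity(sizes)$H,
               shannon_diversity(sizes * 10)$H)
  split <- c(3.5, 3.5, 3, 2, 1) # first clone split in equal halves
  expect_gt(shannon_diversity(split)$H, shannon_diversity(sizes)$H)
})

test_that("bootstrap downsampling is seeded and converges for uniform clones", {
  sizes <- rep(50, 8)
  h1 <- shannon_diversity(sizes, downsample_n = 100, n_boot = 50,
                          seed = 3)
  h2 <- shannon_diversity(sizes, downsample_n = 100, n_boot = 50,
                          seed = 3)
  expect_identical(h1, h2)
  expect_lt(abs(h1$H - log(8)), 0.05)
  expect_error(shannon_diversity(sizes, downsample_n = 1000),
               class = "immunokit_bad_config")
})

test_that("CLR normalisation matches the direct formula with zero tag means", {
  same <- matrix(7, 10, 1, dimnames = list(sprintf("c%d", 1:10), "tag"))
  expect_equal(unname(clr_normalize(same)[, 1]), rep(0, 10))

  set.seed(42)
  m <- matrix(rpois(60, 20), 20, 3,
              dimnames = list(sprintf("c%d", 1:20), c("t1", "t2", "t3")))
  clr <- clr_normalize(m)
  oracle <- apply(m, 2, function(x) log1p(x) - mean(log1p(x)))
  expect_equal(clr, oracle, ignore_attr = TRUE)
  expect_true(all(abs(colMeans(clr)) < 1e-12))
  expect_error(clr_normalize(m - 100), class = "immunokit_bad_matrix")
})

test_that("the tetramer gate is strict at the threshold", {
  clr <- matrix(c(1.71, 1.70, 1.699, 2.5), ncol = 1,
                dimnames = list(paste0("c", 1:4), "tetramer"))
  g <- tetramer_gate(clr)
  expect_equal(g$tet_pos, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(tetramer_gate(clr, tag = "isotype"),
               class = "immunokit_tag_absent")
})

test_that("gating recovers well-separated simulated positives", {
  adt <- simulate_adt(2000, pos_fraction = 0.1, seed = 44)
  gate <- tetramer_gate(clr_normalize(adt$counts))
  truth <- adt$truth$positive[match(gate$cell_id, adt$truth$cell_id)]
  expect_gte(mean(gate$tet_pos[truth]), 0.95)   # sensitivity
  expect_gte(mean(!gate$tet_pos[!truth]), 0.95) # specificity
})

test_that("equal-depth downsampling is balanced, duplicate-free and seeded", {
  cells <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:160),
    treatment = rep(c("DFI", "Luc"), c(100, 60))
  )
  d1 <- downsample_equal(cells, seed = 9)
  expect_equal(as.vector(table(d1$treatment)), c(60, 60))
  expect_false(anyDuplicated(d1$cell_id) > 0)
  expect_identical(d1, downsample_equal(cells, seed = 9))
  expect_error(downsample_equal(cells, group = "batch"),
               class = "immunokit_bad_config")
})
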