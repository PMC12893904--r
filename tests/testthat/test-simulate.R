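test_that("generators are deterministic given a seed", {
  cfgs <- list(
    function() simulate_tissue(c(A = 40, B = 20), seed = 7),
    function() simulate_expression("regions", n_cells = 60, n_genes = 10,
                                   seed = 7),
    function() simulate_cohort(seed = 7),
    function() simulate_repertoire(30, "geometric", seed = 7),
    function() simulate_adt(50, seed = 7),
    function() simulate_assay("pk", seed = 7),
    function() simulate_assay("qpcr", seed = 7)
  )
  for (f in cfgs) expect_identical(f(), f())
})

test_that("tissue generator conserves requested counts and validates input", {
  tis <- simulate_tissue(c(A = 100, B = 50), seed = 1)
  expect_equal(nrow(tis), 150)
  expect_equal(sum(tis$cell_type == "A"), 100)
  cfg <- attr(tis, "config")
  expect_equal(cfg$n_per_type, c(A = 100, B = 50))

  expect_error(simulate_tissue(c(A = 10), width = 0),
               class = "immunokit_bad_config")
  expect_error(
    simulate_tissue(c(A = 10, B = 10),
                    attraction = data.frame(parent = "C", offspring = "B",
                                            alpha = 0.5)),
    class = "immunokit_unknown_type"
  )
  expect_error(
    simulate_tissue(c(A = 10, B = 10),
                    attraction = data.frame(parent = "A", offspring = "B",
                                            alpha = 1.5)),
    class = "immunokit_bad_config"
  )
})

test_that("all coordinates stay inside the domain, clustered or not", {
  tis <- simulate_tissue(
    c(A = 100, B = 100), width = 800, height = 400, cluster_sd = 200,
    attraction = data.frame(parent = "A", offspring = "B", alpha = 1),
    seed = 3
  )
  expect_true(all(tis$x >= 0 & tis$x <= 800))
  expect_true(all(tis$y >= 0 & tis$y <= 400))
})

test_that("tissue series derives per-age seeds stably", {
  sched <- data.frame(age = c(4, 10, 20), alpha = c(0.8, 0.4, 0))
  maps3 <- simulate_tissue_series(c(4, 10, 20), sched,
                                  n_per_type = c(A = 30, B = 30), seed = 5)
  maps2 <- simulate_tissue_series(c(4, 20), sched,
                                  n_per_type = c(A = 30, B = 30), seed = 5)
  expect_length(maps3, 3)
  # dropping an age leaves the other ages' maps untouched
  expect_identical(maps3[[1]], maps2[[1]])
  expect_identical(maps3[[3]], maps2[[2]])
  expect_error(
    simulate_tissue_series(c(4, 8), sched, n_per_type = c(A = 10, B = 10)),
    class = "immunokit_missing_age"
  )
  single <- simulate_tissue_series(4, sched,
                                   n_per_type = c(A = 10, B = 10))
  expect_length(single, 1)
})

test_that("expression generator separates truth from observations", {
  sim <- simulate_expression("regions", n_cells = 80, n_genes = 12,
                             seed = 2)
  expect_false(any(c("region", "cell_type") %in% names(sim$expr$cells)))
  expect_named(sim$truth, c("cell_id", "region"))
  simt <- simulate_expression("types", n_cells = 80, seed = 2)
  expect_false("cell_type" %in% names(simt$expr$cells))
  expect_named(simt$truth, c("cell_id", "cell_type"))
  expect_error(simulate_expression("regions", nb_dispersion = 0),
               class = "immunokit_bad_config")
})

test_that("poisson limit gives unit variance-to-mean counts", {
  sim <- simulate_expression("regions", n_cells = 10000, n_genes = 6,
                             n_regions = 1, markers_per_region = 6,
                             effect = 1, poisson = TRUE, seed = 4)
  disp <- apply(sim$expr$counts, 2, var) / colMeans(sim$expr$counts)
  expect_true(all(abs(disp - 1) < 0.1))
})

test_that("cohort generator follows the quadratic and clips at zero", {
  clean <- simulate_cohort(noise_sd = 0, seed = 1)
  mu <- 6.8 - 0.16 * clean$age + 0.001 * clean$age^2
  expect_equal(clean$response, mu)
  expect_equal(nrow(clean), 32) # 8 ages x 4 animals
  expect_false(any(clean$clipped))

  noisy <- simulate_cohort(coeffs = c(0.1, 0, 0), noise_sd = 2, seed = 2)
  expect_true(all(noisy$response >= 0))
  expect_true(any(noisy$clipped))
  expect_error(simulate_cohort(ages = c(5, 5, 10)),
               class = "immunokit_bad_config")
})

test_that("repertoire generator matches the requested clone structure", {
  unif <- simulate_repertoire(40, "uniform", n_clones = 8, seed = 1)
  expect_equal(as.vector(table(unif$truth$clone_id)), rep(5L, 8))
  one <- simulate_repertoire(20, "uniform", n_clones = 1, seed = 1)
  expect_equal(dplyr::n_distinct(one$truth$clone_id), 1)
  expect_error(simulate_repertoire(10, "zipf"), class = "rlang_error")

  # heavier power-law tails reduce expected downstream diversity
  h_for <- function(expo, seed) {
    sim <- simulate_repertoire(400, "powerlaw", n_clones = 30,
                               exponent = expo, seed = seed)
    shannon_diversity(table(sim$truth$clone_id))$H
  }
  h_flat <- vapply(1:20, function(s) h_for(0.5, s), numeric(1))
  h_steep <- vapply(1:20, function(s) h_for(2.5, s), numeric(1))
  expect_gt(mean(h_flat), mean(h_steep))
})

test_that("ADT generator controls the positive fraction", {
  none <- simulate_adt(200, pos_fraction = 0, seed = 1)
  expect_false(any(none$truth$positive))
  expect_error(simulate_adt(10, pos_fraction = 1.2),
               class = "immunokit_bad_fraction")
  expect_error(simulate_adt(10, neg_logmean = 3, pos_logmean = 2),
               class = "immunokit_bad_config")
})

test_that("pk series matches closed-form AUC at zero noise and stays non-negative", {
  pk <- simulate_assay("pk", model = "exp_decay", c0 = 40, ke = 0.1,
                       noise_cv = 0, seed = 1)
  auc <- auc_trapezoid(pk$data$time, pk$data$value, t_end = 48)
  closed <- 40 / 0.1 * (1 - exp(-0.1 * 48))
  # trapezoid overestimates a convex decay by at most sum(dt^3/12)*max|f''|
  bound <- sum(diff(pk$data$time)^3) / 12 * 40 * 0.1^2
  expect_lt(abs(auc - closed), bound)

  noisy <- simulate_assay("pk", noise_cv = 0.5, seed = 2)
  expect_true(all(noisy$data$value >= 0))
  expect_error(simulate_assay("pk", times = numeric(0)),
               class = "immunokit_bad_config")
})

test_that("qpcr duplicates at zero noise recover the configured -dCt", {
  q <- simulate_assay("qpcr", neg_delta_ct = -5.5, ct_noise_sd = 0,
                      n_samples = 3, seed = 1)
  for (s in unique(q$data$sample_id)) {
    rec <- q$data[q$data$sample_id == s, ]
    got <- trec_neg_delta_ct(rec$ct[rec$target == "TREC"],
                             rec$ct[rec$target == "TCRA"])
    expect_equal(got, -5.5)
  }
})
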