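test_that("pair counts match hand geometry and the brute-force oracle", {
  m <- data.frame(x = c(0, 30), y = c(0, 0), cell_type = c("A", "B"))
  expect_equal(count_pairs_within(m, "A", "B", 50), 1)
  m2 <- data.frame(x = c(0, 60), y = c(0, 0), cell_type = c("A", "B"))
  expect_equal(count_pairs_within(m2, "A", "B", 50), 0)

  set.seed(11)
  big <- data.frame(
    x = runif(200, 0, 500), y = runif(200, 0, 500),
    cell_type = sample(c("A", "B", "C"), 200, replace = TRUE)
  )
  for (r in c(30, 80, 200)) {
    expect_equal(count_pairs_within(big, "A", "B", r),
                 brute_pair_count(big, "A", "B", r))
    expect_equal(count_pairs_within(big, "A", "A", r),
                 brute_pair_count(big, "A", "A", r))
  }
})

test_that("cross-type counts are symmetric and monotone in radius", {
  set.seed(12)
  m <- data.frame(x = runif(120, 0, 300), y = runif(120, 0, 300),
                  cell_type = rep(c("A", "B"), 60))
  radii <- c(20, 50, 100, 150)
  counts <- vapply(radii, function(r) count_pairs_within(m, "A", "B", r),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  for (r in radii) {
    expect_equal(count_pairs_within(m, "A", "B", r),
                 count_pairs_within(m, "B", "A", r))
  }
  expect_error(count_pairs_within(m, "A", "Z", 50),
               class = "immunokit_type_absent")
})

test_that("area-mode z follows the forced formula cases", {
  # C(50) = 30, C(150) = 270: expected = 270/9 = 30, z = 0
  z0 <- interaction_zscore(ring_map(30, 240), "A", "B")
  expect_equal(z0$observed, 30)
  expect_equal(z0$observed_null, 270)
  expect_equal(z0$expected, 30)
  expect_equal(z0$z, 0)

  # C(50) = C(150) = 90: expected = 10, z = 80/sqrt(10)
  z1 <- interaction_zscore(ring_map(90, 0), "A", "B")
  expect_equal(z1$expected, 10)
  expect_equal(z1$z, 80 / sqrt(10))

  expect_error(interaction_zscore(ring_map(2, 2), "A", "B", r_obs = 150,
                                  r_null = 50),
               class = "immunokit_bad_radius")
  far <- data.frame(x = c(0, 1000), y = c(0, 0),
                    cell_type = c("A", "B"))
  expect_error(interaction_zscore(far, "A", "B"),
               class = "immunokit_undefined_statistic")
})

test_that("z increases monotonically with generator attraction", {
  alphas <- c(0, 0.2, 0.4, 0.6, 0.8)
  z <- vapply(alphas, function(al) {
    tis <- simulate_tissue(
      c(A = 150, B = 150), width = 2500, height = 2500,
      attraction = data.frame(parent = "A", offspring = "B", alpha = al),
      seed = 21
    )
    interaction_zscore(tis, "A", "B")$z
  }, numeric(1))
  expect_gt(cor(z, alphas, method = "spearman"), 0.9)
})

test_that("permutation null agrees with the analytic null on CSR tissue", {
  tis <- simulate_tissue(c(A = 120, B = 120), width = 1800, height = 1800,
                         seed = 31)
  za <- interaction_zscore(tis, "A", "B", null_mode = "area")
  zp <- interaction_zscore(tis, "A", "B", null_mode = "permutation",
                           n_perm = 499, seed = 32)
  # same observed count; null expectations agree within a few null sd
  expect_equal(zp$observed, za$observed)
  expect_lt(abs(zp$expected - za$expected), 3 * zp$null_sd)
  expect_error(
    interaction_zscore(tis, "A", "B", null_mode = "permutation",
                       n_perm = 10),
    class = "immunokit_bad_config"
  )
})

test_that("age trend recovers exact linear decline and rejects degenerate input", {
  zs <- tibble::tibble(type_a = "A", type_b = "B",
                       age = c(4, 10, 20, 30),
                       z = 10 - 0.2 * c(4, 10, 20, 30))
  tr <- zscore_age_trend(zs)
  expect_equal(tr$r, -1)
  expect_equal(tr$n, 4)

  const <- tibble::tibble(type_a = "A", type_b = "B",
                          age = c(4, 10, 20), z = c(1, 1, 1))
  expect_error(zscore_age_trend(const),
               class = "immunokit_undefined_correlation")
  two <- tibble::tibble(type_a = "A", type_b = "B", age = c(4, 10),
                        z = c(1, 2))
  expect_error(zscore_age_trend(two), class = "immunokit_bad_config")
})

test_that("replicate arrays at one age are averaged before the trend", {
  zs <- tibble::tibble(
    type_a = "A", type_b = "B",
    age = c(4, 4, 10, 20),
    z = c(9.0, 9.4, 8, 6) # mean at age 4 is 9.2: z = 10 - 0.2*age
  )
  expect_message(tr <- zscore_age_trend(zs), "mean")
  expect_equal(tr$r, -1, tolerance = 1e-12)
  expect_equal(tr$n, 3)
})

test_that("a declining attraction schedule yields a detectable negative trend", {
  ages <- c(4, 12, 20, 28, 36, 44)
  sched <- data.frame(age = ages, alpha = seq(0.8, 0, length.out = 6))
  maps <- simulate_tissue_series(ages, sched,
                                 n_per_type = c(A = 150, B = 150),
                                 width = 2500, height = 2500, seed = 41)
  zs <- dplyr::bind_rows(lapply(maps, interaction_zscore, "A", "B"))
  tr <- zscore_age_trend(zs)
  expect_lt(tr$r, 0)
  expect_lt(tr$p, 0.05)
})
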