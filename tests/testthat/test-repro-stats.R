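# Brute-force formula oracles, kept independent of the package's code paths.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
oracle_rank <- function(v) {
  # average ranks for ties, built from first principles
  vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2, numeric(1))
}

test_that("correlations match brute-force formula evaluations", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 5)
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)

  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)

  # any strictly monotone transform gives perfect rank correlation
  expect_equal(spearman_s(x, exp(x)), 1)
  expect_equal(spearman_s(x, rev(x)), -1)

  # 5-point vector with one tie: average ranks, hand-checked
  xt <- c(10, 20, 20, 30, 40)
  yt <- c(1, 2, 3, 5, 4)
  expect_equal(oracle_rank(xt), c(1, 2.5, 2.5, 4, 5))
  expect_equal(spearman_s(xt, yt), oracle_pearson(oracle_rank(xt), oracle_rank(yt)),
    tolerance = 1e-12
  )

  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(pearson_r(a, b), oracle_pearson(a, b), tolerance = 1e-12)
    expect_equal(spearman_s(a, b), oracle_pearson(oracle_rank(a), oracle_rank(b)),
      tolerance = 1e-12
    )
  }
})

test_that("correlations reject degenerate input", {
  expect_error(pearson_r(1:3, 1:4), class = "lightboxr_input_error")
  expect_error(pearson_r(1:2, 2:3), class = "lightboxr_input_error")
  expect_error(pearson_r(c(1, 1, 1), 1:3), class = "lightboxr_input_error")
  expect_error(spearman_s(1:3, c(2, 2, 2)), class = "lightboxr_input_error")
})

test_that("correlations are invariant to positive affine / monotone transforms", {
  set.seed(3)
  x <- rnorm(10)
  y <- rnorm(10)
  expect_equal(pearson_r(3 * x + 7, y), pearson_r(x, y), tolerance = 1e-12)
  expect_equal(spearman_s(x^3, y), spearman_s(x, y), tolerance = 1e-12)
})

test_that("replicate CV matches hand arithmetic and is scale-invariant", {
  expect_equal(cv_replicates(c(-100, -100, -100)), 0)
  expect_equal(cv_replicates(c(-100, -300)), sd(c(-100, -300)) / 200 * 100)
  expect_equal(cv_replicates(c(-100, -300)), 70.71068, tolerance = 1e-6)
  expect_equal(cv_replicates(c(-90, -100, -110)), 10)

  set.seed(4)
  v <- rnorm(5, -500, 50)
  for (c_mult in c(0.5, 2, -3)) {
    expect_equal(cv_replicates(c_mult * v), cv_replicates(v), tolerance = 1e-12)
  }
  expect_error(cv_replicates(c(-1, 1)), class = "lightboxr_input_error")
  expect_error(cv_replicates(-5), class = "lightboxr_input_error")
})

test_that("RMSE relative to the replicate mean pools squared deviations", {
  expect_equal(rmse_vs_replicate_mean(list(c(-5, -5), c(-9, -9)))$rmse, 0)

  # a single pair deviates symmetrically: rmse = |a - b| / 2
  one <- rmse_vs_replicate_mean(list(c(-400, -480)))
  expect_equal(one$rmse, 40)
  expect_equal(one$rmse_over_mean, 40 / 440 * 100)

  two <- rmse_vs_replicate_mean(list(c(-400, -480), c(-100, -100)))
  expect_equal(two$rmse, sqrt((40^2 + 40^2 + 0 + 0) / 4))
  expect_equal(two$rmse, 28.28427, tolerance = 1e-6)

  # pair closed form on random pairs
  set.seed(5)
  for (i in 1:25) {
    p <- rnorm(2, -800, 300)
    expect_equal(rmse_vs_replicate_mean(list(p))$rmse, abs(p[1] - p[2]) / 2,
      tolerance = 1e-12
    )
  }
  expect_error(rmse_vs_replicate_mean(list()), class = "lightboxr_input_error")
  expect_error(rmse_vs_replicate_mean(list(-4)), class = "lightboxr_input_error")
})

test_that("grouped agreement tables match direct per-group recomputation", {
  set.seed(6)
  pairs <- tibble::tibble(
    location_id = sprintf("L%02d", 1:10),
    date = rep(c(33, 55), each = 5),
    delta_a = rnorm(10, -800, 400)
  )
  pairs$delta_b <- pairs$delta_a + rnorm(10, 0, 60)

  tab_all <- agreement_by_group(pairs, "all")
  expect_equal(nrow(tab_all), 1L)
  expect_equal(tab_all$n_pairs, 10L)
  expect_equal(tab_all$pearson_r, cor(pairs$delta_a, pairs$delta_b))
  expect_equal(
    tab_all$mean_delta_pi,
    mean(c(pairs$delta_a, pairs$delta_b))
  )

  tab_date <- agreement_by_group(pairs, "by_date")
  for (d in c(33, 55)) {
    sub <- pairs[pairs$date == d, ]
    row <- tab_date[tab_date$group == as.character(d), ]
    expect_equal(row$pearson_r, cor(sub$delta_a, sub$delta_b))
    expect_equal(row$spearman_s, cor(sub$delta_a, sub$delta_b, method = "spearman"))
    expect_equal(row$rmse, sqrt(mean(((sub$delta_a - sub$delta_b) / 2)^2)))
  }

  # identical members: perfect correlation, zero error
  same <- pairs
  same$delta_b <- same$delta_a
  tab_same <- agreement_by_group(same, "all")
  expect_equal(tab_same$pearson_r, 1)
  expect_equal(tab_same$rmse, 0)
})

test_that("quintile grouping splits pairs into equal-count groups", {
  set.seed(7)
  pairs <- tibble::tibble(
    location_id = rep(sprintf("L%02d", 1:20), times = 7),
    date = rep(c(33, 55, 90, 118, 173, 209, 258), each = 20),
    delta_a = rnorm(140, -900, 500)
  )
  pairs$delta_b <- pairs$delta_a + rnorm(140, 0, 80)
  tab <- agreement_by_group(pairs, "by_quintile")
  expect_equal(tab$group, paste0("Q", 1:5))
  expect_equal(tab$n_pairs, rep(28L, 5))
  # quintiles are ordered by pair-mean delta-PI
  expect_true(all(diff(tab$mean_delta_pi) > 0))
  # every pair lands in exactly one quintile: pooled RMSE recombines
  pooled <- rmse_vs_replicate_mean(
    mapply(c, pairs$delta_a, pairs$delta_b, SIMPLIFY = FALSE)
  )$rmse
  expect_equal(sqrt(sum(tab$n_pairs * 2 * tab$rmse^2) / sum(tab$n_pairs * 2)),
    pooled,
    tolerance = 1e-12
  )
})

test_that("small groups are reported without correlations, with a warning", {
  pairs <- tibble::tibble(
    location_id = c("L1", "L2", "L3", "L4"),
    date = c(33, 33, 33, 55),
    delta_a = c(-100, -200, -300, -400),
    delta_b = c(-110, -190, -320, -380)
  )
  expect_warning(tab <- agreement_by_group(pairs, "by_date"), "pair")
  expect_true(is.na(tab$pearson_r[tab$group == "55"]))
  expect_false(is.na(tab$pearson_r[tab$group == "33"]))
  # zero-variance member vector: correlation not available, no error
  flat <- tibble::tibble(
    location_id = c("L1", "L2", "L3"), date = 33,
    delta_a = c(-100, -100, -100), delta_b = c(-90, -120, -100)
  )
  tab2 <- agreement_by_group(flat, "all")
  expect_true(is.na(tab2$pearson_r))
  expect_gt(tab2$rmse, 0)
})

test_that("variability decomposes into among, within and replicate components", {
  # all values identical -> all three CVs are 0
  const <- tidyr::expand_grid(
    location_id = c("L1", "L2"), sampler_id_suffix = c("S1", "S2"),
    exposure_time = c(33, 55)
  )
  const$sampler_id <- paste(const$location_id, const$sampler_id_suffix)
  const$delta_pi <- -500
  v0 <- variability_decomposition(const)
  expect_equal(unlist(v0), c(
    among_location_cv = 0, within_location_cv = 0,
    replicate_cv = 0
  ))

  # two locations, constant in time, exact replicates: the among-location
  # CV equals the hand-computed CV of the two location means
  two <- const
  two$delta_pi <- ifelse(two$location_id == "L1", -200, -800)
  v2 <- variability_decomposition(two)
  expect_equal(v2$among_location_cv, sd(c(-200, -800)) / 500 * 100)
  expect_equal(v2$within_location_cv, 0)
  expect_equal(v2$replicate_cv, 0)

  # controlled variance components: large spatial spread, mild temporal
  # drift, small replicate noise -> among > within > replicate
  set.seed(8)
  grid <- tidyr::expand_grid(
    location_id = sprintf("L%02d", 1:8), rep = 1:2,
    exposure_time = c(33, 55, 90, 118)
  )
  loc_level <- stats::setNames(-exp(rnorm(8, log(800), 1)), sprintf("L%02d", 1:8))
  grid$sampler_id <- paste0(grid$location_id, "_S", grid$rep)
  grid$delta_pi <- loc_level[grid$location_id] *
    (grid$exposure_time / 90)^0.9 * exp(rnorm(nrow(grid), 0, 0.05))
  v <- variability_decomposition(grid)
  expect_gt(v$among_location_cv, v$within_location_cv)
  expect_gt(v$within_location_cv, v$replicate_cv)

  expect_error(variability_decomposition(const[const$location_id == "L1", ]),
    class = "lightboxr_input_error"
  )
})
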