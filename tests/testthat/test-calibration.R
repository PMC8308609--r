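test_that("launch aggregation gives order statistics and mean", {
  a <- aggregate_launch(c(5, 5, 5))
  expect_equal(c(a$d_min, a$d_median, a$d_mean, a$d_max), rep(5, 4))
  b <- aggregate_launch(c(1, 2, 3, 10))
  expect_equal(b$d_min, 1)
  expect_equal(b$d_median, 2.5)
  expect_equal(b$d_mean, 4)
  expect_equal(b$d_max, 10)
  expect_error(aggregate_launch(numeric(0)), "at least one")
})

test_that("aggregating a launch table yields one row per launch", {
  exp <- generate_launch_experiment(seed = 42)
  agg <- aggregate_launches(exp$launches, exp$winds)
  expect_equal(nrow(agg), 37)
  expect_setequal(agg$launch_id, unique(exp$launches$launch_id))
  expect_true(all(agg$d_min <= agg$d_median & agg$d_median <= agg$d_max))
  expect_true(all(agg$d_min <= agg$d_mean & agg$d_mean <= agg$d_max))
})

test_that("wind-distance correlation table identifies the strongest pair", {
  v <- c(1, 3, 5, 7, 9)
  agg <- data.frame(v_median_ms = 0.75 * v, v_mean_ms = 0.8 * v, v_max_ms = v,
                    d_min = v, d_median = 1.5 * v, d_mean = 2 * v,
                    d_max = 3 * v + c(0.3, -0.2, 0.1, 0, -0.1))
  res <- correlate_aggregates(agg)
  expect_equal(nrow(res$table), 12)
  row <- res$table[res$table$wind == "v_max_ms" &
                     res$table$distance == "d_mean", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  agg$v_max_ms <- 5
  expect_error(correlate_aggregates(agg), "v_max_ms")
})

test_that("on model-generated launches v_max and d_mean correlate strongest", {
  exp <- generate_launch_experiment(seed = 314)
  agg <- aggregate_launches(exp$launches, exp$winds)
  res <- correlate_aggregates(agg)
  expect_gt(res$best$r, 0.8)
  expect_equal(res$best$distance, "d_mean")
})

test_that("launch predictions use the launch v_max and release height", {
  expect_equal(predict_launch_mean(3, 4, 1.72, "ballistic"), 6.977,
               tolerance = 1e-3)
  expect_equal(predict_launch_mean(3, 4, 1.72, "gradient", alpha = 0.29),
               6.977 / 1.29, tolerance = 1e-3)
  expect_equal(predict_launch_mean(3, 0, 1.72, "gradient"), 0)
})

test_that("alpha calibration recovers the generating exponent exactly without noise", {
  spec <- generator_spec(launch_noise = FALSE, alpha_true = 0.30)
  exp <- generate_launch_experiment(spec, seed = 99)
  agg <- aggregate_launches(exp$launches, exp$winds)
  cal <- calibrate_alpha(agg, spec$launch_vt_ms)
  expect_equal(cal$alpha_opt, 0.30)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  expect_true(cal$alpha_opt %in% cal$grid$alpha)
  # slope profile is monotone increasing in alpha for fixed empirical data
  expect_true(all(diff(cal$grid$slope) > 0))
})

test_that("alpha calibration recovers 0.29 from noisy 37-launch experiments", {
  # a 37-launch design with per-propagule spread noise estimates alpha with
  # an intrinsic replicate sd near 0.04, so a single experiment is checked
  # at ~2.3 sd and unbiasedness at the precision of a 10-replicate mean
  spec <- generator_spec()
  alphas <- vapply(1:10, function(s) {
    exp <- generate_launch_experiment(spec, seed = s)
    agg <- aggregate_launches(exp$launches, exp$winds)
    cal <- calibrate_alpha(agg, spec$launch_vt_ms)
    expect_gte(cal$alpha_opt, 0.05)
    expect_lte(cal$alpha_opt, 0.50)
    cal$alpha_opt
  }, numeric(1))
  expect_true(all(abs(alphas - 0.29) <= 0.1))
  expect_lte(abs(mean(alphas) - 0.29), 0.03)
})

test_that("spread regression recovers exact linear spread coefficients", {
  cls <- exact_spread_classes(v_classes = 0:8 + 0.5, slope = 0.35,
                              intercept = 0.51)
  fit <- distance_spread_regression(cls$distances_m, cls$v_max_ms)
  expect_equal(fit$slope, 0.35, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.51, tolerance = 1e-10)
  expect_equal(nrow(fit$classes), 9)
  one <- exact_spread_classes(v_classes = 2.5, slope = 0.35, intercept = 0.51)
  expect_error(distance_spread_regression(one$distances_m, one$v_max_ms),
               "at least 3 wind classes")
})

test_that("spread regression on synthetic launches recovers the noise slope", {
  exp <- generate_launch_experiment(seed = 7)
  joined <- merge(exp$launches, exp$winds, by = "launch_id")
  fit <- distance_spread_regression(joined$distance_m, joined$v_max_ms)
  expect_lte(abs(fit$slope - 0.35), 0.15)
})
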