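test_that("linear spread model gives the documented sds", {
  expect_equal(dispersal_sd(12), 4.71)
  expect_equal(round(dispersal_sd(12)), 5)
  expect_equal(dispersal_sd(17), 6.46)
  expect_equal(round(dispersal_sd(17)), 6)
  expect_equal(dispersal_sd(0), 0.51)
  expect_error(dispersal_sd(-1), "wind_speed_ms")
})

test_that("station-wind LDD estimate reproduces the worked examples", {
  # slowest measured mericarp (V_t = 0.91 m/s)
  syk <- max_dispersal_estimate(16, 10, 3.85, 0.91, alpha = 0.29)
  expect_equal(syk$corrected_wind_ms, 12)
  expect_equal(syk$distance_m, 39)
  expect_equal(syk$sd_m, 5)

  kaz <- max_dispersal_estimate(23, 10, 3.85, 0.91, alpha = 0.29)
  expect_equal(kaz$corrected_wind_ms, 17)
  expect_lte(abs(kaz$distance_m - 55), 1)
  expect_equal(kaz$sd_m, 6)

  # median mericarp
  syk_med <- max_dispersal_estimate(16, 10, 3.85, 1.65, alpha = 0.29)
  expect_equal(syk_med$corrected_wind_ms, 12)
  expect_equal(syk_med$distance_m, 22)
  kaz_med <- max_dispersal_estimate(23, 10, 3.85, 1.65, alpha = 0.29)
  expect_equal(kaz_med$distance_m, 31)
})

test_that("rounding lives only in the reporting layer", {
  est <- max_dispersal_estimate(16, 10, 3.85, 0.91, alpha = 0.29)
  expect_equal(est$corrected_wind_exact_ms, 12.13, tolerance = 1e-3)
  expect_equal(est$distance_exact_m,
               gradient_distance(3.85, 12, 0.91, 0.29))
})

test_that("propagules release at the first gust reaching their critical wind", {
  wind <- constant_wind_series(3, gust = 5)
  wind$gust_ms <- c(3, 5, 8)
  wind$mean_speed_ms <- c(2, 4, 6)
  expect_equal(release_times(wind, 0), 1L)
  expect_equal(release_times(wind, 99), NA_integer_)
  expect_equal(release_times(wind, 6), 3L)
  expect_equal(release_times(wind, c(0, 6, 99)), c(1L, 3L, NA))
  shuffled <- wind[c(2, 1, 3), ]
  expect_error(release_times(shuffled, 0), "time-ordered")
})

test_that("noise-free kernel equals the deterministic gradient distance", {
  wind <- constant_wind_series(10, gust = 8)
  cfg <- kernel_config(n_propagules = 50, alpha = 0.29,
                       terminal_velocity_ms = 1.62, release_height_m = 3,
                       critical_wind_range_ms = c(0, 0), noise = FALSE,
                       seed = 1)
  kern <- simulate_kernel(wind, cfg)
  corrected <- wind_at_height(8, 10, 3, 0.29)
  expect_equal(kern$n_released, 50)
  expect_equal(kern$propagules$distance_m,
               rep(gradient_distance(3, corrected, 1.62, 0.29), 50))
})

test_that("kernel with alpha = 0 and no noise collapses to the ballistic value", {
  wind <- constant_wind_series(5, gust = 6)
  cfg <- kernel_config(n_propagules = 20, alpha = 0,
                       terminal_velocity_ms = 1.5, release_height_m = 2.5,
                       critical_wind_range_ms = c(0, 0), noise = FALSE,
                       seed = 3)
  kern <- simulate_kernel(wind, cfg)
  expect_equal(kern$propagules$distance_m,
               rep(ballistic_distance(2.5, 6, 1.5), 20))
})

test_that("unreleased propagules are conserved and distances non-negative", {
  wind <- constant_wind_series(10, gust = 4)
  cfg <- kernel_config(n_propagules = 30, terminal_velocity_ms = 1.6,
                       release_height_m = 3,
                       critical_wind_range_ms = c(5, 15), seed = 5)
  kern <- simulate_kernel(wind, cfg)
  expect_equal(kern$n_released, 0)
  expect_equal(kern$n_not_released, 30)

  cfg2 <- kernel_config(n_propagules = 500, terminal_velocity_ms = 1.6,
                        release_height_m = 3,
                        critical_wind_range_ms = c(0, 5), seed = 6)
  kern2 <- simulate_kernel(wind, cfg2)
  expect_equal(kern2$n_released + kern2$n_not_released, 500)
  expect_true(all(kern2$propagules$distance_m[kern2$propagules$released] >= 0))
})

test_that("kernels are reproducible given the seed", {
  wind <- generate_wind_series(generator_spec(n_days = 2), seed = 10)
  cfg <- kernel_config(n_propagules = 200, terminal_velocity_ms = c(1.2, 1.6),
                       release_height_m = c(2.5, 3.5), seed = 77)
  k1 <- simulate_kernel(wind, cfg)
  k2 <- simulate_kernel(wind, cfg)
  expect_identical(k1$propagules, k2$propagules)
  cfg2 <- kernel_config(n_propagules = 200, terminal_velocity_ms = c(1.2, 1.6),
                        release_height_m = c(2.5, 3.5), seed = 78)
  k3 <- simulate_kernel(wind, cfg2)
  expect_false(identical(k1$propagules$distance_m, k3$propagules$distance_m))
})

test_that("noisy kernel mean and sd converge to the generating model", {
  wind <- constant_wind_series(10, gust = 10)
  cfg <- kernel_config(n_propagules = 10000, alpha = 0.29,
                       terminal_velocity_ms = 1.62, release_height_m = 3,
                       critical_wind_range_ms = c(0, 0), noise = TRUE,
                       seed = 42)
  kern <- simulate_kernel(wind, cfg)
  corrected <- wind_at_height(10, 10, 3, 0.29)
  d0 <- gradient_distance(3, corrected, 1.62, 0.29)
  sd0 <- dispersal_sd(corrected)
  d <- kern$propagules$distance_m
  expect_lte(abs(mean(d) - d0), 3 * sd0 / sqrt(10000))
  expect_lte(abs(sd(d) - sd0) / sd0, 0.10)
})

test_that("the kernel tail grows with the series' maximum gust", {
  spec <- generator_spec(n_days = 3)
  q99 <- sapply(c(8, 12, 16, 20), function(g) {
    wind <- generate_wind_series(generator_spec(n_days = 3, max_gust_ms = g),
                                 seed = 20)
    cfg <- kernel_config(n_propagules = 400, terminal_velocity_ms = 1.62,
                         release_height_m = 3, seed = 21)
    simulate_kernel(wind, cfg)$quantiles["q99"]
  })
  expect_true(all(diff(q99) >= 0))
})
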