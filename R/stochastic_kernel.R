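#' Standard deviation of flight distances at a given wind speed
#'
#' Propagules of identical shape and wing loading released together still
#' land at different distances, and the spread grows linearly with wind
#' speed. The empirical spread model is
#' \deqn{D_{sd} = 0.35 v + 0.51}
#' (metres, with v in m/s), fitted over nine 1 m/s wind classes of field
#' launch data. The coefficients are configurable so a re-fitted spread
#' model ([distance_spread_regression()]) can be plugged in.
#'
#' @param wind_speed_ms Wind speed (m/s, >= 0).
#' @param slope,intercept Spread-model coefficients (defaults 0.35, 0.51).
#' @return Distance standard deviation (m). Vectorised.
#' @examples
#' dispersal_sd(12)
#' @export
dispersal_sd <- function(wind_speed_ms, slope = 0.35, intercept = 0.51) {
  check_nonneg(wind_speed_ms, "wind_speed_ms")
  slope * wind_speed_ms + intercept
}

#' Maximum-dispersal estimate from a weather-station wind record
#'
#' The long-distance-dispersal workflow: take the seasonal maximum wind
#' recorded by a weather station (anemometer typically at 10 m), correct it
#' down to the propagule release height with the Hellmann profile, round the
#' corrected wind to the nearest integer m/s (reporting convention), compute
#' the gradient-model flight distance, round to the nearest metre, and
#' attach the spread-model standard deviation at the corrected wind, also
#' rounded to the nearest metre. Rounding happens only in this reporting
#' layer, never in the core model functions.
#'
#' @param station_wind_ms Station wind speed (m/s, >= 0).
#' @param anemometer_height_m Station measurement height (m, default 10).
#' @param release_height_m Propagule release height (m, > 0).
#' @param terminal_velocity_ms Terminal velocity (m/s, > 0).
#' @param alpha Hellmann exponent (default 0.29).
#' @return List with `corrected_wind_ms` (integer-rounded), `distance_m`
#'   (metre-rounded), `sd_m` (metre-rounded), plus the unrounded
#'   `corrected_wind_exact_ms` and `distance_exact_m`.
#' @examples
#' max_dispersal_estimate(16, 10, 3.85, 0.91, alpha = 0.29)
#' @export
max_dispersal_estimate <- function(station_wind_ms, anemometer_height_m = 10,
                                   release_height_m, terminal_velocity_ms,
                                   alpha = 0.29) {
  v_exact <- wind_at_height(station_wind_ms, anemometer_height_m,
                            release_height_m, alpha)
  v_round <- round(v_exact)
  d_exact <- gradient_distance(release_height_m, v_round,
                               terminal_velocity_ms, alpha)
  list(corrected_wind_ms = v_round,
       corrected_wind_exact_ms = v_exact,
       distance_m = round(d_exact),
       distance_exact_m = d_exact,
       sd_m = round(dispersal_sd(v_round)))
}

#' Release times of propagules given their critical wind speeds
#'
#' Each propagule has a critical wind speed: the minimum wind at which it
#' detaches from the umbel. Scanning a time-ordered wind series, a
#' propagule releases at the first record whose gust reaches its critical
#' wind; if no gust ever does, it stays on the umbel for the season.
#'
#' @param wind Data frame with at least `timestamp` and `gust_ms`,
#'   time-ordered (as from [read_wind_series()]).
#' @param critical_wind_ms Critical wind speed(s), m/s, >= 0.
#' @return Integer vector of row indices into `wind` (NA when never
#'   released), one per critical wind.
#' @export
release_times <- function(wind, critical_wind_ms) {
  if (nrow(wind) == 0L) {
    stop("wind series is empty", call. = FALSE)
  }
  ts <- parse_timestamps(wind$timestamp)
  if (anyNA(ts) || is.unsorted(ts)) {
    stop("wind series timestamps must be present and time-ordered",
         call. = FALSE)
  }
  check_nonneg(critical_wind_ms, "critical_wind_ms")
  # running maximum makes the first-crossing search a binary search-free scan
  vapply(critical_wind_ms, function(cw) {
    idx <- which(wind$gust_ms >= cw)
    if (length(idx) == 0L) NA_integer_ else idx[1]
  }, integer(1))
}

#' Configuration for the individual-based kernel simulator
#'
#' Bundles and validates every knob of [simulate_kernel()]. Terminal
#' velocity and release height may each be a single fixed value or a vector
#' of empirical measurements to resample with replacement, reflecting the
#' individual-based design in which each propagule's flight is computed
#' separately from its own sampled traits.
#'
#' @param n_propagules Number of propagules to simulate (>= 1).
#' @param alpha Hellmann exponent (default 0.29, the launch-calibrated
#'   value).
#' @param terminal_velocity_ms Fixed value or empirical sample (m/s, > 0).
#' @param release_height_m Fixed value or empirical sample (m, > 0).
#' @param critical_wind_range_ms Range of the uniform critical-wind
#'   distribution, m/s; default `c(0, 15)` spanning release at near-zero
#'   wind through retention after gusts over 15 m/s. A degenerate range
#'   (`min == max`) gives every propagule that critical wind.
#' @param noise Add stochastic spread around the deterministic distance
#'   (default TRUE), with sd from [dispersal_sd()] at the corrected wind.
#' @param sd_slope,sd_intercept Spread-model coefficients.
#' @param negative_handling How to keep distances non-negative when noise
#'   is on: `"resample"` (redraw the noise; default) or `"floor"` (clamp
#'   at 0).
#' @param ldd_threshold_m Distances beyond this count as long-distance
#'   dispersal (default 10 m).
#' @param seed Mandatory integer seed; the simulation is bit-identical
#'   given the seed.
#' @return Object of class `kernel_config`.
#' @export
kernel_config <- function(n_propagules, alpha = 0.29,
                          terminal_velocity_ms, release_height_m,
                          critical_wind_range_ms = c(0, 15),
                          noise = TRUE, sd_slope = 0.35, sd_intercept = 0.51,
                          negative_handling = c("resample", "floor"),
                          ldd_threshold_m = 10, seed) {
  n_propagules <- check_count(n_propagules, "n_propagules")
  check_nonneg(alpha, "alpha")
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  check_positive(release_height_m, "release_height_m")
  if (length(critical_wind_range_ms) != 2L ||
      critical_wind_range_ms[2] < critical_wind_range_ms[1]) {
    stop("'critical_wind_range_ms' must be c(min, max) with max >= min",
         call. = FALSE)
  }
  check_nonneg(critical_wind_range_ms, "critical_wind_range_ms")
  check_flag(noise, "noise")
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' is mandatory for the kernel simulation", call. = FALSE)
  }
  structure(list(
    n_propagules = n_propagules,
    alpha = alpha,
    terminal_velocity_ms = terminal_velocity_ms,
    release_height_m = release_height_m,
    critical_wind_range_ms = critical_wind_range_ms,
    noise = noise,
    sd_slope = sd_slope,
    sd_intercept = sd_intercept,
    negative_handling = match.arg(negative_handling),
    ldd_threshold_m = ldd_threshold_m,
    seed = as.integer(seed)
  ), class = "kernel_config")
}

#' Simulate a dispersal kernel from a weather-station wind series
#'
#' Individual-based Monte Carlo simulation of the landing-distance
#' distribution. For each propagule: sample terminal velocity and release
#' height (fixed or resampled with replacement from empirical values),
#' draw a critical wind speed, find the first gust reaching it
#' ([release_times()]), correct that gust from anemometer height to the
#' release height via the Hellmann profile, compute the gradient-model
#' distance, and, when noise is on, add zero-mean Gaussian spread with sd
#' from [dispersal_sd()] at the corrected wind (negatives redrawn or
#' floored per the config). Propagules whose critical wind is never
#' reached stay unreleased.
#'
#' @param wind Data frame with `timestamp`, `gust_ms`,
#'   `anemometer_height_m` (and usually `mean_speed_ms`), time-ordered.
#' @param config A [kernel_config()].
#' @return Object of class `dispersal_kernel`: list with `propagules`
#'   (one row each: `propagule_id`, `released`, `release_index`,
#'   `release_timestamp`, `critical_wind_ms`, `v_t_ms`, `h_r_m`,
#'   `corrected_wind_ms`, `distance_m`), `n_released`, `n_not_released`,
#'   `quantiles` (median, q95, q99, max over released propagules),
#'   `n_beyond_threshold`, `ldd_threshold_m`, `config`.
#' @export
simulate_kernel <- function(wind, config) {
  if (!inherits(config, "kernel_config")) {
    stop("'config' must be built with kernel_config()", call. = FALSE)
  }
  if (nrow(wind) == 0L) {
    stop("wind series is empty", call. = FALSE)
  }
  n <- config$n_propagules
  set.seed(config$seed)

  sample_vals <- function(x, n) {
    if (length(x) == 1L) rep(x, n) else sample(x, n, replace = TRUE)
  }
  v_t <- sample_vals(config$terminal_velocity_ms, n)
  h_r <- sample_vals(config$release_height_m, n)
  rng <- config$critical_wind_range_ms
  cw <- if (rng[1] == rng[2]) rep(rng[1], n) else stats::runif(n, rng[1], rng[2])

  idx <- release_times(wind, cw)
  released <- !is.na(idx)

  corrected <- rep(NA_real_, n)
  dist <- rep(NA_real_, n)
  if (any(released)) {
    gi <- idx[released]
    corrected[released] <- wind_at_height(wind$gust_ms[gi],
                                          wind$anemometer_height_m[gi],
                                          h_r[released], config$alpha)
    d0 <- gradient_distance(h_r[released], corrected[released],
                            v_t[released], config$alpha)
    if (config$noise) {
      sdv <- dispersal_sd(corrected[released], config$sd_slope,
                          config$sd_intercept)
      d <- d0 + stats::rnorm(length(d0), 0, sdv)
      if (config$negative_handling == "resample") {
        for (tries in 1:100) {
          neg <- which(d < 0)
          if (length(neg) == 0L) break
          d[neg] <- d0[neg] + stats::rnorm(length(neg), 0, sdv[neg])
        }
        d[d < 0] <- 0
      } else {
        d <- pmax(0, d)
      }
    } else {
      d <- d0
    }
    dist[released] <- d
  }

  prop <- data.frame(
    propagule_id = sprintf("p%05d", seq_len(n)),
    released = released,
    release_index = idx,
    release_timestamp = ifelse(released, as.character(wind$timestamp[idx]),
                               NA_character_),
    critical_wind_ms = cw,
    v_t_ms = v_t,
    h_r_m = h_r,
    corrected_wind_ms = corrected,
    distance_m = dist,
    stringsAsFactors = FALSE
  )
  rel_d <- dist[released]
  q <- if (length(rel_d) > 0L) {
    c(median = unname(stats::median(rel_d)),
      q95 = unname(stats::quantile(rel_d, 0.95, type = 7)),
      q99 = unname(stats::quantile(rel_d, 0.99, type = 7)),
      max = max(rel_d))
  } else {
    c(median = NA_real_, q95 = NA_real_, q99 = NA_real_, max = NA_real_)
  }
  out <- list(propagules = prop,
              n_released = sum(released),
              n_not_released = sum(!released),
              quantiles = q,
              n_beyond_threshold = sum(rel_d > config$ldd_threshold_m),
              ldd_threshold_m = config$ldd_threshold_m,
              config = config)
  class(out) <- "dispersal_kernel"
  out
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("Dispersal kernel (individual-based simulation)\n")
  cat(sprintf("  propagules: %d (%d released, %d not released)\n",
              x$n_released + x$n_not_released, x$n_released,
              x$n_not_released))
  if (x$n_released > 0L) {
    cat(sprintf("  distance quantiles: median %.2f m, 95%% %.2f m, 99%% %.2f m, max %.2f m\n",
                x$quantiles["median"], x$quantiles["q95"], x$quantiles["q99"],
                x$quantiles["max"]))
    cat(sprintf("  beyond %.0f m (LDD): %d propagules\n", x$ldd_threshold_m,
                x$n_beyond_threshold))
  }
  invisible(x)
}

#' Kernel summary as a plain list (for JSON output)
#'
#' @param kernel A `dispersal_kernel`.
#' @return List of counts, quantiles and exceedances.
#' @export
kernel_summary <- function(kernel) {
  list(n_propagules = kernel$n_released + kernel$n_not_released,
       n_released = kernel$n_released,
       n_not_released = kernel$n_not_released,
       median_m = unname(kernel$quantiles["median"]),
       q95_m = unname(kernel$quantiles["q95"]),
       q99_m = unname(kernel$quantiles["q99"]),
       max_m = unname(kernel$quantiles["max"]),
       ldd_threshold_m = kernel$ldd_threshold_m,
       n_beyond_threshold = kernel$n_beyond_threshold)
}
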