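#' Generator settings for synthetic field data
#'
#' Defaults mirror the field study's measured structure: North-group trait
#' medians/IQRs (mass 11.0 +/- 3.2 mg, area 0.56 +/- 0.17 cm2, terminal
#' velocity 1.62 m/s with sd 0.25), the artificial-propagule block (mass
#' 21.5 +/- 0.5 mg, area 0.966 +/- 0.018 cm2, terminal velocity
#' 1.72 +/- 0.11 m/s), a 37-launch experiment with 8-20 propagules per
#' batch at 0-9 m/s winds generated from the gradient model at
#' `alpha_true = 0.29` plus the linear spread noise (0.35 v + 0.51), and a
#' 30-minute weather-station series. Override any element by name.
#'
#' @param ... Named overrides of the defaults, e.g.
#'   `generator_spec(n_launches = 10)`.
#' @return Object of class `generator_spec` (a named list).
#' @export
generator_spec <- function(...) {
  spec <- list(
    groups = list(
      North = list(mass_median = 11.0, mass_iqr = 3.2,
                   area_median = 0.56, area_iqr = 0.17,
                   vt_median = 1.62, vt_sd = 0.25, vt_r2 = 0.8),
      South = list(mass_median = 11.0, mass_iqr = 3.2,
                   area_median = 0.56, area_iqr = 0.17,
                   vt_median = 1.62, vt_sd = 0.25, vt_r2 = 0.8),
      artificial = list(mass_median = 21.5, mass_iqr = 0.5,
                        area_median = 0.966, area_iqr = 0.018,
                        vt_median = 1.72, vt_iqr = 0.11)
    ),
    # launch experiment
    n_launches = 37,
    batch_size_range = c(8L, 20L),
    launch_wind_range_ms = c(0, 9),
    alpha_true = 0.29,
    launch_release_height_m = 3.0,
    launch_vt_ms = 1.72,
    sd_slope = 0.35,
    sd_intercept = 0.51,
    launch_noise = TRUE,
    vmean_frac = 0.8,
    vmedian_frac = 0.75,
    # drop trials
    drop_height_m = 2.68,
    drop_reps = 5L,
    drop_timing_cv = 0.05,
    # wind series
    interval_min = 30,
    n_days = 7,
    wind_weibull_shape = 2,
    wind_weibull_scale = 4,
    gust_factor_range = c(1.1, 1.6),
    max_gust_ms = NULL,
    anemometer_height_m = 10
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad) > 0L) {
    stop(sprintf("unknown generator setting(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  spec[names(dots)] <- dots
  class(spec) <- "generator_spec"
  spec
}

# Log-normal parameters matched to a target median and IQR: mu = log(median),
# sigma solved so that exp(mu + q75 sigma) - exp(mu - q75 sigma) = IQR.
lnorm_from_median_iqr <- function(median, iqr) {
  q <- stats::qnorm(0.75)
  f <- function(s) median * (exp(q * s) - exp(-q * s)) - iqr
  sigma <- stats::uniroot(f, c(1e-8, 5))$root
  list(meanlog = log(median), sdlog = sigma)
}

#' Generate a synthetic propagule trait table
#'
#' Masses and areas are drawn from independent log-normal distributions
#' whose medians and IQRs match the group targets (positive support and
#' right skew consistent with the near-equal means and medians of measured
#' traits). Terminal velocity is tied to wing loading through a linear
#' relation plus Gaussian noise, with the signal-to-noise ratio chosen so
#' wing loading explains about the configured share of terminal-velocity
#' variance (default 0.8). The artificial group instead draws a tight
#' terminal-velocity distribution around its target median.
#'
#' @param n Number of propagules (>= 1).
#' @param group `"North"`, `"South"`, or `"artificial"`.
#' @param spec A [generator_spec()].
#' @param seed Mandatory integer seed.
#' @return Data frame: `propagule_id`, `group`, `mass_mg`, `area_cm2`,
#'   `wing_loading_g_cm2`, `terminal_velocity_ms`.
#' @export
generate_traits <- function(n, group = "North", spec = generator_spec(),
                            seed) {
  n <- check_count(n, "n")
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (!group %in% names(spec$groups)) {
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  }
  g <- spec$groups[[group]]
  set.seed(seed)
  mp <- lnorm_from_median_iqr(g$mass_median, g$mass_iqr)
  ap <- lnorm_from_median_iqr(g$area_median, g$area_iqr)
  mass <- stats::rlnorm(n, mp$meanlog, mp$sdlog)
  area <- stats::rlnorm(n, ap$meanlog, ap$sdlog)
  wl <- wing_loading(mass, area)
  if (group == "artificial") {
    vt_sd <- g$vt_iqr / (2 * stats::qnorm(0.75))
    vt <- stats::rnorm(n, g$vt_median, vt_sd)
  } else {
    # slope from the target R^2 against the realised wing-loading spread
    sd_wl <- if (n > 1) stats::sd(wl) else g$mass_median / 1000 / g$area_median * 0.3
    if (sd_wl == 0) sd_wl <- 1e-6
    b <- sqrt(g$vt_r2) * g$vt_sd / sd_wl
    a <- g$vt_median - b * stats::median(wl)
    vt <- a + b * wl + stats::rnorm(n, 0, sqrt(1 - g$vt_r2) * g$vt_sd)
  }
  vt <- pmax(vt, 0.2)  # physical floor: hogweed mericarps fall faster than this
  data.frame(
    propagule_id = sprintf("%s%04d", substr(group, 1, 1), seq_len(n)),
    group = group,
    mass_mg = mass,
    area_cm2 = area,
    wing_loading_g_cm2 = wl,
    terminal_velocity_ms = vt,
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic timed-drop trials for a trait table
#'
#' Each propagule is "dropped" `drop_reps` times from `drop_height_m`; the
#' recorded times are the true fall time (height over the propagule's
#' terminal velocity) perturbed by multiplicative Gaussian timing error
#' with coefficient of variation `drop_timing_cv` (stopwatch and reaction
#' noise).
#'
#' @param traits Trait table with `propagule_id` and
#'   `terminal_velocity_ms`.
#' @param spec A [generator_spec()].
#' @param seed Mandatory integer seed.
#' @return Data frame in the wide drop-trial layout: `propagule_id`,
#'   `release_height_m`, `t1_s` ... `t5_s`.
#' @export
generate_drop_trials <- function(traits, spec = generator_spec(), seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(seed)
  n <- nrow(traits)
  reps <- spec$drop_reps
  t_true <- spec$drop_height_m / traits$terminal_velocity_ms
  times <- matrix(t_true, n, reps) *
    matrix(1 + stats::rnorm(n * reps, 0, spec$drop_timing_cv), n, reps)
  times[times <= 0] <- 0.01
  out <- data.frame(propagule_id = traits$propagule_id,
                    release_height_m = spec$drop_height_m,
                    stringsAsFactors = FALSE)
  for (j in seq_len(reps)) out[[sprintf("t%d_s", j)]] <- times[, j]
  out
}

#' Generate a synthetic launch experiment
#'
#' Emulates the field design: `n_launches` batch releases of 8-20
#' standardised propagules at maximum winds drawn uniformly over the
#' configured range (default 0-9 m/s). Each propagule's landing distance is
#' the gradient-model distance at the launch's v_max and `alpha_true` plus
#' zero-mean Gaussian noise with sd from the linear spread model, floored
#' at 0. Per-launch mean and median winds are fixed fractions of v_max
#' (defaults 0.8 and 0.75).
#'
#' @param spec A [generator_spec()].
#' @param seed Mandatory integer seed.
#' @return List with `launches` (data frame `launch_id`,
#'   `release_height_m`, `distance_m`, one row per propagule) and `winds`
#'   (data frame `launch_id`, `v_median_ms`, `v_mean_ms`, `v_max_ms`).
#' @export
generate_launch_experiment <- function(spec = generator_spec(), seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(seed)
  nl <- spec$n_launches
  v_max <- stats::runif(nl, spec$launch_wind_range_ms[1],
                        spec$launch_wind_range_ms[2])
  sizes <- sample(seq(spec$batch_size_range[1], spec$batch_size_range[2]),
                  nl, replace = TRUE)
  ids <- sprintf("L%02d", seq_len(nl))
  h_r <- spec$launch_release_height_m
  vt <- spec$launch_vt_ms
  launches <- do.call(rbind, lapply(seq_len(nl), function(i) {
    d0 <- gradient_distance(h_r, v_max[i], vt, spec$alpha_true)
    d <- rep(d0, sizes[i])
    if (spec$launch_noise) {
      d <- d + stats::rnorm(sizes[i], 0,
                            dispersal_sd(v_max[i], spec$sd_slope,
                                         spec$sd_intercept))
      d <- pmax(0, d)
    }
    data.frame(launch_id = ids[i], release_height_m = h_r, distance_m = d,
               stringsAsFactors = FALSE)
  }))
  winds <- data.frame(launch_id = ids,
                      v_median_ms = spec$vmedian_frac * v_max,
                      v_mean_ms = spec$vmean_frac * v_max,
                      v_max_ms = v_max,
                      stringsAsFactors = FALSE)
  list(launches = launches, winds = winds)
}

#' Generate a synthetic weather-station wind series
#'
#' Time-ordered records at the configured interval (default 30 minutes,
#' matching airport-station practice). Mean speeds are Weibull draws (the
#' conventional family for surface wind speeds); each record's gust is its
#' mean inflated by a uniform gust factor. When `max_gust_ms` is set, the
#' whole series is rescaled so the seasonal maximum gust equals it exactly
#' (to emulate a station's recorded seasonal maximum).
#'
#' @param spec A [generator_spec()].
#' @param seed Mandatory integer seed.
#' @param start Start timestamp (POSIXct or ISO-8601 string, UTC).
#' @return Data frame: `timestamp` (ISO-8601 UTC), `mean_speed_ms`,
#'   `gust_ms`, `anemometer_height_m`.
#' @export
generate_wind_series <- function(spec = generator_spec(), seed,
                                 start = "2020-08-01T00:00:00Z") {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  set.seed(seed)
  n <- as.integer(spec$n_days * 24 * 60 / spec$interval_min)
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (is.na(t0)) t0 <- as.POSIXct(start, tz = "UTC")
  ts <- t0 + seq(0, by = spec$interval_min * 60, length.out = n)
  mean_speed <- stats::rweibull(n, spec$wind_weibull_shape,
                                spec$wind_weibull_scale)
  gust <- mean_speed * stats::runif(n, spec$gust_factor_range[1],
                                    spec$gust_factor_range[2])
  if (!is.null(spec$max_gust_ms)) {
    f <- spec$max_gust_ms / max(gust)
    mean_speed <- mean_speed * f
    gust <- gust * f
  }
  data.frame(
    timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    mean_speed_ms = mean_speed,
    gust_ms = gust,
    anemometer_height_m = spec$anemometer_height_m,
    stringsAsFactors = FALSE
  )
}
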