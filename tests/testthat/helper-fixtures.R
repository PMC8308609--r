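# Random valid flight conditions for property-style tests.
random_conditions <- function(n, seed) {
  set.seed(seed)
  data.frame(
    h_r = runif(n, 0.1, 5),
    v_hr = runif(n, 0, 30),
    v_t = runif(n, 0.1, 5),
    alpha = runif(n, 0, 1)
  )
}

# Numerical oracle for the gradient model: adaptive quadrature of the
# instantaneous wind over the fall, independent of the closed form.
gradient_distance_quadrature <- function(h_r, v_hr, v_t, alpha) {
  tf <- h_r / v_t
  stats::integrate(function(t) {
    v_hr * pmax(0, (h_r - v_t * t) / h_r)^alpha
  }, 0, tf, rel.tol = 1e-12, abs.tol = 0)$value
}

# Wind-class fixture whose per-class distance sd follows sd = slope*v +
# intercept exactly: two distances at m +/- s/sqrt(2) give sd(m) == s.
exact_spread_classes <- function(v_classes, slope, intercept, mean_dist = 10) {
  d <- numeric(0)
  v <- numeric(0)
  for (vc in v_classes) {
    s <- slope * vc + intercept
    d <- c(d, mean_dist - s / sqrt(2), mean_dist + s / sqrt(2))
    v <- c(v, vc, vc)
  }
  list(distances_m = d, v_max_ms = v)
}

# Constant wind series for degenerate-kernel tests.
constant_wind_series <- function(n, gust, mean_frac = 0.8, height = 10) {
  t0 <- as.POSIXct("2020-08-01 00:00:00", tz = "UTC")
  data.frame(
    timestamp = format(t0 + seq(0, by = 1800, length.out = n),
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    mean_speed_ms = gust * mean_frac,
    gust_ms = gust,
    anemometer_height_m = height,
    stringsAsFactors = FALSE
  )
}
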