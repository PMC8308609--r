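#' Aggregate one launch's landing distances
#'
#' Order statistics and mean of the per-propagule landing distances of a
#' single batch release: minimum, median, mean, maximum, and the
#' interquartile range used in the distance-spread analysis.
#'
#' @param distances_m Landing distances (m, each >= 0, at least one).
#' @return One-row data frame: `n`, `d_min`, `d_median`, `d_mean`, `d_max`,
#'   `d_iqr`.
#' @export
aggregate_launch <- function(distances_m) {
  if (length(distances_m) == 0L) {
    stop("'distances_m' must contain at least one distance", call. = FALSE)
  }
  check_nonneg(distances_m, "distances_m")
  data.frame(
    n = length(distances_m),
    d_min = min(distances_m),
    d_median = stats::median(distances_m),
    d_mean = mean(distances_m),
    d_max = max(distances_m),
    d_iqr = stats::IQR(distances_m, type = 7)
  )
}

#' Aggregate a launch table and join per-launch wind statistics
#'
#' Groups the per-propagule distance table by `launch_id`, computes
#' [aggregate_launch()] statistics for each launch, and (optionally) joins
#' the per-launch wind aggregates.
#'
#' @param launches Data frame with `launch_id`, `release_height_m`,
#'   `distance_m` (one row per propagule), as from
#'   [read_launch_distances()].
#' @param winds Optional data frame with `launch_id`, `v_median_ms`,
#'   `v_mean_ms`, `v_max_ms`, as from [read_launch_winds()].
#' @return Data frame with one row per launch: `launch_id`,
#'   `release_height_m`, the distance aggregates, and the wind columns when
#'   supplied.
#' @export
aggregate_launches <- function(launches, winds = NULL) {
  ids <- unique(launches$launch_id)
  rows <- lapply(ids, function(id) {
    sub <- launches[launches$launch_id == id, , drop = FALSE]
    agg <- aggregate_launch(sub$distance_m)
    cbind(data.frame(launch_id = id,
                     release_height_m = sub$release_height_m[1],
                     stringsAsFactors = FALSE),
          agg)
  })
  out <- do.call(rbind, rows)
  if (!is.null(winds)) {
    missing <- setdiff(out$launch_id, winds$launch_id)
    if (length(missing) > 0L) {
      stop(sprintf("no wind record for launch(es): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    out <- merge(out, winds, by = "launch_id", sort = FALSE)
  }
  out
}

#' Correlate wind aggregates with distance aggregates across launches
#'
#' Pearson correlations for every pairing of a per-launch wind statistic
#' (`v_median_ms`, `v_mean_ms`, `v_max_ms`) with a per-launch distance
#' aggregate (`d_min`, `d_median`, `d_mean`, `d_max`), identifying the pair
#' with the largest absolute correlation. In the field experiments the
#' (v_max, D_mean) pair correlates most strongly, which motivates driving
#' the flight models with the maximum wind during a launch.
#'
#' @param aggregates Data frame from [aggregate_launches()] including the
#'   wind columns; at least 3 launches.
#' @return List with `table` (data frame: `wind`, `distance`, `r`,
#'   `p_value`) and `best` (the row with max |r|).
#' @export
correlate_aggregates <- function(aggregates) {
  wind_cols <- c("v_median_ms", "v_mean_ms", "v_max_ms")
  dist_cols <- c("d_min", "d_median", "d_mean", "d_max")
  need <- c(wind_cols, dist_cols)
  if (!all(need %in% names(aggregates))) {
    stop("aggregates must contain wind and distance aggregate columns",
         call. = FALSE)
  }
  if (nrow(aggregates) < 3L) {
    stop("at least 3 launches are required", call. = FALSE)
  }
  for (w in wind_cols) {
    if (stats::var(aggregates[[w]]) == 0) {
      stop(sprintf("wind covariate '%s' is constant; correlation undefined", w),
           call. = FALSE)
    }
  }
  grid <- expand.grid(wind = wind_cols, distance = dist_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- stats::cor.test(aggregates[[grid$wind[i]]],
                          aggregates[[grid$distance[i]]])
    data.frame(wind = grid$wind[i], distance = grid$distance[i],
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  list(table = tab, best = tab[which.max(abs(tab$r)), , drop = FALSE])
}

#' Modelled mean flight distance for a launch
#'
#' Applies the ballistic or gradient model to one launch, using the
#' launch's maximum recorded wind as the wind at release height.
#'
#' @param release_height_m Launch release height (m, > 0).
#' @param wind_ms Wind speed at release height, normally the launch v_max
#'   (m/s, >= 0).
#' @param terminal_velocity_ms Propagule terminal velocity (m/s, > 0).
#' @param model `"gradient"` or `"ballistic"`.
#' @param alpha Hellmann exponent (ignored by the ballistic model).
#' @return Modelled distance (m). Vectorised.
#' @export
predict_launch_mean <- function(release_height_m, wind_ms,
                                terminal_velocity_ms,
                                model = c("gradient", "ballistic"),
                                alpha = 0.29) {
  model <- match.arg(model)
  if (model == "ballistic") {
    ballistic_distance(release_height_m, wind_ms, terminal_velocity_ms)
  } else {
    gradient_distance(release_height_m, wind_ms, terminal_velocity_ms, alpha)
  }
}

#' Calibrate the Hellmann exponent against launch experiments
#'
#' Sweeps the Hellmann exponent over a grid (default 0.05 to 0.50 in steps
#' of 0.01). For each alpha the gradient model predicts a mean flight
#' distance per launch from its v_max and release height; the empirical
#' mean distances are regressed (OLS with intercept) on the modelled ones.
#' The optimal alpha is the grid value whose regression slope is closest
#' to 1 (the modelled and empirical distances agree on average); ties break
#' toward the smaller alpha. Diagnostics at the optimum: Pearson r between
#' empirical and modelled means and a two-sample Kolmogorov-Smirnov p-value
#' comparing the two samples of launch means.
#'
#' @param aggregates Data frame from [aggregate_launches()] with
#'   `release_height_m`, `d_mean`, and the wind covariate column; at least
#'   3 launches with non-constant winds.
#' @param terminal_velocity_ms Terminal velocity of the launched propagules
#'   (m/s, > 0).
#' @param alpha_grid Candidate exponents (default `seq(0.05, 0.50, 0.01)`).
#' @param wind_col Wind covariate column (default `"v_max_ms"`).
#' @return Object of class `alpha_calibration`: list with `grid` (data
#'   frame: `alpha`, `slope`, `intercept`, `r_squared`), `alpha_opt`,
#'   `slope`, `intercept`, `r_squared`, `pearson_r`, `ks_p`, `n_launches`.
#' @export
calibrate_alpha <- function(aggregates, terminal_velocity_ms,
                            alpha_grid = seq(0.05, 0.50, by = 0.01),
                            wind_col = "v_max_ms") {
  if (!all(c("release_height_m", "d_mean", wind_col) %in% names(aggregates))) {
    stop(sprintf("aggregates must contain 'release_height_m', 'd_mean', '%s'",
                 wind_col), call. = FALSE)
  }
  if (nrow(aggregates) < 3L) {
    stop("at least 3 launches are required", call. = FALSE)
  }
  check_positive(terminal_velocity_ms, "terminal_velocity_ms")
  check_nonneg(alpha_grid, "alpha_grid")
  wind <- aggregates[[wind_col]]
  if (stats::var(wind) == 0) {
    stop(sprintf("wind covariate '%s' is constant across launches", wind_col),
         call. = FALSE)
  }
  emp <- aggregates$d_mean
  h_r <- aggregates$release_height_m
  fits <- lapply(alpha_grid, function(a) {
    mod <- gradient_distance(h_r, wind, terminal_velocity_ms, a)
    if (stats::var(mod) == 0) {
      stop(sprintf("modelled distances degenerate at alpha = %.2f", a),
           call. = FALSE)
    }
    fit <- stats::lm(emp ~ mod)
    data.frame(alpha = a,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = ols_r_squared(fit, emp))
  })
  grid <- do.call(rbind, fits)
  opt <- which.min(abs(grid$slope - 1))  # ascending grid: ties -> smaller alpha
  alpha_opt <- grid$alpha[opt]
  mod_opt <- gradient_distance(h_r, wind, terminal_velocity_ms, alpha_opt)
  ks <- suppressWarnings(stats::ks.test(emp, mod_opt))
  out <- list(grid = grid,
              alpha_opt = alpha_opt,
              slope = grid$slope[opt],
              intercept = grid$intercept[opt],
              r_squared = grid$r_squared[opt],
              pearson_r = stats::cor(emp, mod_opt),
              ks_p = ks$p.value,
              n_launches = nrow(aggregates))
  class(out) <- "alpha_calibration"
  out
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat("Hellmann exponent calibration\n")
  cat(sprintf("  launches: %d, grid: %.2f..%.2f\n", x$n_launches,
              min(x$grid$alpha), max(x$grid$alpha)))
  cat(sprintf("  alpha_opt = %.2f (slope %.3f, intercept %.3f, R^2 %.3f)\n",
              x$alpha_opt, x$slope, x$intercept, x$r_squared))
  cat(sprintf("  Pearson r = %.3f, KS p = %.3f\n", x$pearson_r, x$ks_p))
  invisible(x)
}

#' Regression of distance spread on wind speed
#'
#' Landing distances vary within a launch, and the spread grows with wind
#' speed. Distances are binned into left-closed 1 m/s classes on the
#' launch maximum wind; the standard deviation of distances in each class
#' is regressed on the class mean wind speed, giving the linear spread
#' model `D_sd = slope * v + intercept` used as the stochastic component of
#' the kernel simulator (defaults 0.35 and 0.51; see [dispersal_sd()]).
#' Classes with fewer than 2 distances are dropped (sd undefined).
#'
#' @param distances_m Per-propagule landing distances (m).
#' @param v_max_ms Per-propagule launch maximum wind speed (m/s), same
#'   length as `distances_m`.
#' @param bin_width_ms Wind class width (m/s, default 1).
#' @return List with `slope`, `intercept`, `r_squared`, and `classes`
#'   (data frame: `wind_class`, `v_ms`, `n`, `d_sd`).
#' @export
distance_spread_regression <- function(distances_m, v_max_ms,
                                       bin_width_ms = 1) {
  if (length(distances_m) != length(v_max_ms)) {
    stop("'distances_m' and 'v_max_ms' must have the same length",
         call. = FALSE)
  }
  check_nonneg(distances_m, "distances_m")
  check_nonneg(v_max_ms, "v_max_ms")
  check_positive(bin_width_ms, "bin_width_ms")
  cls <- floor(v_max_ms / bin_width_ms)
  keep_cls <- names(which(table(cls) >= 2))
  rows <- lapply(keep_cls, function(k) {
    idx <- cls == as.numeric(k)
    data.frame(wind_class = as.numeric(k) * bin_width_ms,
               v_ms = mean(v_max_ms[idx]),
               n = sum(idx),
               d_sd = stats::sd(distances_m[idx]))
  })
  classes <- do.call(rbind, rows)
  if (is.null(classes) || nrow(classes) < 3L) {
    stop("at least 3 wind classes with >= 2 distances are required",
         call. = FALSE)
  }
  fit <- stats::lm(d_sd ~ v_ms, data = classes)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = ols_r_squared(fit, classes$d_sd),
       classes = classes)
}
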