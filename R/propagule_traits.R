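#' Wing loading of a propagule
#'
#' Wing loading (WL, g/cm2) is the ratio of propagule mass in grams to the
#' area of one of its sides in cm2. It is the strongest single predictor of
#' terminal velocity for hogweed mericarps. Masses are supplied in
#' milligrams, matching the units trait tables are recorded in; conversion
#' to grams happens here and nowhere else.
#'
#' @param mass_mg Propagule air-dry mass (mg, > 0).
#' @param area_cm2 One-side area (cm2, > 0).
#' @return Wing loading in g/cm2. Vectorised.
#' @examples
#' wing_loading(11.0, 0.56)
#' @export
wing_loading <- function(mass_mg, area_cm2) {
  check_positive(mass_mg, "mass_mg")
  check_positive(area_cm2, "area_cm2")
  (mass_mg / 1000) / area_cm2
}

#' Terminal velocity from a timed-drop trial
#'
#' A propagule is dropped several times (nominally five) from a known height
#' in still air and the fall is timed; the falling-velocity estimate is the
#' release height divided by the median fall time. The median of an even
#' number of replicates is the midpoint of the central pair.
#'
#' @param release_height_m Drop height (m, > 0).
#' @param fall_times_s Replicate fall times (s, each > 0, at least one).
#' @return Terminal velocity estimate (m/s).
#' @examples
#' terminal_velocity_from_drops(2.68, c(1.5, 1.6, 1.7, 1.8, 1.9))
#' @export
terminal_velocity_from_drops <- function(release_height_m, fall_times_s) {
  check_positive(release_height_m, "release_height_m")
  if (length(fall_times_s) == 0L) {
    stop("'fall_times_s' must contain at least one replicate", call. = FALSE)
  }
  check_positive(fall_times_s, "fall_times_s")
  release_height_m / stats::median(fall_times_s)
}

#' Terminal velocities for a table of drop trials
#'
#' Applies [terminal_velocity_from_drops()] to each row of a drop-trial
#' table in the wide CSV layout (`t1_s` .. `t5_s`; trailing replicate
#' columns may be empty).
#'
#' @param drops Data frame as returned by [read_drop_trials()].
#' @return Data frame with `propagule_id`, `release_height_m`, `n_reps`,
#'   `terminal_velocity_ms`.
#' @export
drop_velocities <- function(drops) {
  time_cols <- grep("^t[0-9]+_s$", names(drops), value = TRUE)
  if (length(time_cols) == 0L) {
    stop("no replicate time columns (t1_s, t2_s, ...) found", call. = FALSE)
  }
  vt <- vapply(seq_len(nrow(drops)), function(i) {
    times <- as.numeric(drops[i, time_cols])
    times <- times[!is.na(times)]
    terminal_velocity_from_drops(drops$release_height_m[i], times)
  }, numeric(1))
  nrep <- rowSums(!is.na(drops[, time_cols, drop = FALSE]))
  data.frame(
    propagule_id = drops$propagule_id,
    release_height_m = drops$release_height_m,
    n_reps = as.integer(nrep),
    terminal_velocity_ms = vt,
    stringsAsFactors = FALSE
  )
}

#' Summary statistics for propagule traits
#'
#' Computes, per trait, the five statistics used to characterise propagule
#' samples: mean, median, standard deviation, interquartile range, and
#' standard error of the mean. Quartiles use linear interpolation of the
#' empirical distribution (`stats::quantile()` type 7).
#'
#' @param traits Data frame with numeric columns among `mass_mg`,
#'   `area_cm2`, `wing_loading_g_cm2`, `terminal_velocity_ms`; a missing
#'   wing-loading column is derived from mass and area. At least 2 rows.
#' @return Data frame with one row per trait: `trait`, `n`, `mean`,
#'   `median`, `sd`, `iqr`, `sem`.
#' @export
summarize_traits <- function(traits) {
  if (nrow(traits) < 2L) {
    stop("at least 2 propagules are required (sd undefined for n < 2)",
         call. = FALSE)
  }
  if (!"wing_loading_g_cm2" %in% names(traits) &&
      all(c("mass_mg", "area_cm2") %in% names(traits))) {
    traits$wing_loading_g_cm2 <- wing_loading(traits$mass_mg, traits$area_cm2)
  }
  wanted <- c("mass_mg", "area_cm2", "wing_loading_g_cm2",
              "terminal_velocity_ms")
  present <- intersect(wanted, names(traits))
  if (length(present) == 0L) {
    stop("no trait columns found", call. = FALSE)
  }
  rows <- lapply(present, function(col) {
    x <- traits[[col]]
    x <- x[!is.na(x)]
    data.frame(
      trait = col,
      n = length(x),
      mean = mean(x),
      median = stats::median(x),
      sd = stats::sd(x),
      iqr = stats::IQR(x, type = 7),
      sem = stats::sd(x) / sqrt(length(x)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Regression of terminal velocity on a propagule trait
#'
#' Ordinary least-squares fit (with intercept) of measured terminal velocity
#' on one trait: wing loading, mass, or area. Wing loading typically
#' explains over 80% of terminal-velocity variance in hogweed mericarps;
#' mass, around 50%.
#'
#' @param traits Data frame with `terminal_velocity_ms` and the predictor
#'   column (`wing_loading_g_cm2`, `mass_mg`, or `area_cm2`). At least 3
#'   rows, predictor not constant.
#' @param predictor One of `"wing_loading"`, `"mass"`, `"area"`.
#' @return List with `slope`, `intercept`, `r_squared`, `n`, `predictor`.
#' @export
velocity_trait_regression <- function(traits,
                                      predictor = c("wing_loading", "mass",
                                                    "area")) {
  predictor <- match.arg(predictor)
  col <- switch(predictor,
                wing_loading = "wing_loading_g_cm2",
                mass = "mass_mg",
                area = "area_cm2")
  if (col == "wing_loading_g_cm2" && !col %in% names(traits) &&
      all(c("mass_mg", "area_cm2") %in% names(traits))) {
    traits[[col]] <- wing_loading(traits$mass_mg, traits$area_cm2)
  }
  if (!all(c(col, "terminal_velocity_ms") %in% names(traits))) {
    stop(sprintf("columns '%s' and 'terminal_velocity_ms' are required", col),
         call. = FALSE)
  }
  keep <- stats::complete.cases(traits[, c(col, "terminal_velocity_ms")])
  x <- traits[[col]][keep]
  y <- traits$terminal_velocity_ms[keep]
  if (length(x) < 3L) {
    stop("at least 3 propagules with measured terminal velocity are required",
         call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop(sprintf("predictor '%s' is constant; regression undefined", predictor),
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    # flat response: slope 0, no variance explained
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                n = length(x), predictor = predictor))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = ols_r_squared(fit, y),
       n = length(x),
       predictor = predictor)
}
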