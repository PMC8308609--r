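# CSV schemas. Each table kind lists its required columns, which of them are
# numeric, and row-level invariants; validation errors cite the row number and
# column so bad field data is easy to locate. Extra columns are preserved.

table_schemas <- list(
  traits = list(
    required = c("propagule_id", "group", "mass_mg", "area_cm2"),
    numeric = c("mass_mg", "area_cm2"),
    row_check = function(row, i) {
      if (row$mass_mg <= 0) sprintf("row %d: mass_mg must be > 0", i)
      else if (row$area_cm2 <= 0) sprintf("row %d: area_cm2 must be > 0", i)
      else NULL
    }
  ),
  drops = list(
    required = c("propagule_id", "release_height_m", "t1_s"),
    numeric = c("release_height_m", "t1_s"),
    row_check = function(row, i) {
      if (row$release_height_m <= 0) {
        sprintf("row %d: release_height_m must be > 0", i)
      } else NULL
    }
  ),
  launches = list(
    required = c("launch_id", "release_height_m", "distance_m"),
    numeric = c("release_height_m", "distance_m"),
    row_check = function(row, i) {
      if (row$release_height_m <= 0) {
        sprintf("row %d: release_height_m must be > 0", i)
      } else if (row$distance_m < 0) {
        sprintf("row %d: distance_m must be >= 0", i)
      } else NULL
    }
  ),
  launch_winds = list(
    required = c("launch_id", "v_median_ms", "v_mean_ms", "v_max_ms"),
    numeric = c("v_median_ms", "v_mean_ms", "v_max_ms"),
    row_check = function(row, i) {
      if (row$v_median_ms < 0 || row$v_mean_ms < 0 || row$v_max_ms < 0) {
        sprintf("row %d: wind speeds must be >= 0", i)
      } else if (row$v_max_ms < row$v_mean_ms ||
                 row$v_max_ms < row$v_median_ms) {
        sprintf("row %d: v_max_ms must be >= v_mean_ms and v_median_ms", i)
      } else NULL
    }
  ),
  wind_series = list(
    required = c("timestamp", "mean_speed_ms", "gust_ms",
                 "anemometer_height_m"),
    numeric = c("mean_speed_ms", "gust_ms", "anemometer_height_m"),
    row_check = function(row, i) {
      if (row$mean_speed_ms < 0) {
        sprintf("row %d: mean_speed_ms must be >= 0", i)
      } else if (row$gust_ms < row$mean_speed_ms) {
        sprintf("row %d: gust_ms must be >= mean_speed_ms", i)
      } else if (row$anemometer_height_m <= 0) {
        sprintf("row %d: anemometer_height_m must be > 0", i)
      } else NULL
    }
  )
)

read_validated_csv <- function(path, kind) {
  schema <- table_schemas[[kind]]
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing <- setdiff(schema$required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  num_cols <- schema$numeric
  if (kind == "drops") {
    num_cols <- union(num_cols, grep("^t[0-9]+_s$", names(df), value = TRUE))
  }
  for (col in num_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("%s: row %d: column '%s' is not numeric ('%s')",
                   path, bad[1], col, raw[bad[1]]), call. = FALSE)
    }
    required_here <- col %in% schema$required
    if (required_here && any(is.na(val) | raw == "")) {
      i <- which(is.na(val) | raw == "")[1]
      stop(sprintf("%s: row %d: column '%s' is missing", path, i, col),
           call. = FALSE)
    }
    df[[col]] <- val
  }
  for (i in seq_len(nrow(df))) {
    msg <- schema$row_check(df[i, , drop = FALSE], i)
    if (!is.null(msg)) stop(sprintf("%s: %s", path, msg), call. = FALSE)
  }
  df
}

#' Read a propagule trait table
#'
#' CSV with columns `propagule_id,group,mass_mg,area_cm2` (extra columns
#' such as `terminal_velocity_ms` are preserved). Rows violating the
#' schema raise errors naming the row and column.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_trait_table <- function(path) read_validated_csv(path, "traits")

#' Read a drop-trial table
#'
#' CSV with columns `propagule_id,release_height_m,t1_s,...,t5_s`;
#' trailing replicate columns may be empty.
#'
#' @inheritParams read_trait_table
#' @return Validated data frame.
#' @export
read_drop_trials <- function(path) {
  df <- read_validated_csv(path, "drops")
  time_cols <- grep("^t[0-9]+_s$", names(df), value = TRUE)
  for (i in seq_len(nrow(df))) {
    times <- as.numeric(df[i, time_cols])
    times <- times[!is.na(times)]
    if (length(times) == 0L) {
      stop(sprintf("%s: row %d: no fall times recorded", path, i),
           call. = FALSE)
    }
    if (any(times <= 0)) {
      stop(sprintf("%s: row %d: fall times must be > 0", path, i),
           call. = FALSE)
    }
  }
  df
}

#' Read a launch distance table
#'
#' CSV with columns `launch_id,release_height_m,distance_m`, one row per
#' propagule.
#'
#' @inheritParams read_trait_table
#' @return Validated data frame.
#' @export
read_launch_distances <- function(path) read_validated_csv(path, "launches")

#' Read a per-launch wind aggregate table
#'
#' CSV with columns `launch_id,v_median_ms,v_mean_ms,v_max_ms`.
#'
#' @inheritParams read_trait_table
#' @return Validated data frame.
#' @export
read_launch_winds <- function(path) read_validated_csv(path, "launch_winds")

#' Read a weather-station wind series
#'
#' CSV with columns `timestamp,mean_speed_ms,gust_ms,anemometer_height_m`.
#' Timestamps are ISO-8601; UTC is assumed when no offset is given. The
#' series must be time-ordered and every gust at least the mean speed.
#'
#' @inheritParams read_trait_table
#' @return Validated data frame.
#' @export
read_wind_series <- function(path) {
  df <- read_validated_csv(path, "wind_series")
  ts <- parse_timestamps(df$timestamp)
  if (anyNA(ts)) {
    stop(sprintf("%s: row %d: unparseable timestamp '%s'", path,
                 which(is.na(ts))[1], df$timestamp[which(is.na(ts))[1]]),
         call. = FALSE)
  }
  if (is.unsorted(ts)) {
    stop(sprintf("%s: wind series is not time-ordered", path), call. = FALSE)
  }
  df
}

parse_timestamps <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC")
  }
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC")
  }
  out
}

#' Write a table in the package's CSV conventions
#'
#' Plain CSV, no row names, no quoting of numerics; the file can be read
#' back by the matching reader with field-level equality.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` (or `key: value`) pair per line; blank lines and
#' lines starting with `#` are ignored. Values that parse as numbers are
#' returned numeric; `true`/`false` become logical.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else {
      val
    }
  }
  out
}
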