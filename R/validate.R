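# Internal argument checks. All user-facing errors name the offending field so
# failures in file-driven workflows point back at a column.

check_positive <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  if (any(x <= 0)) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be numeric and non-missing", name), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 1 || x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

# R^2 computed from residuals directly; summary.lm warns on noiseless fits,
# which are legitimate inputs here (closed-loop and worked-example data).
ols_r_squared <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

check_flag <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.logical(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}
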