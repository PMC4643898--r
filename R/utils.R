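# Internal helpers: logging, validation, numerics shared across the pipeline.

.log_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

#' Emit a timestamped log message
#'
#' Pipeline stages log their input/output dimensions through this helper.
#' The threshold is controlled by `options(sepsimet.log_level = "INFO")`;
#' messages below the threshold are suppressed.
#'
#' @param level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... Message parts, pasted together.
#' @return Invisibly, the formatted message (or `NULL` if suppressed).
#' @export
log_msg <- function(level = "INFO", ...) {
  level <- match.arg(level, names(.log_levels))
  threshold <- getOption("sepsimet.log_level", "WARN")
  if (.log_levels[[level]] < .log_levels[[match.arg(threshold, names(.log_levels))]]) {
    return(invisible(NULL))
  }
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}

# stop() with a condition class so callers can test for specific failures
stop_sepsimet <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "sepsimet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# Cumulative trapezoidal integral; C[1] = 0, C[i] = integral x[1]..x[i]
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1L] + y[-n]) / 2))
}

# Trapezoidal integral of (x, y) over [lo, hi], with linear interpolation of
# y at the interval endpoints when they fall between grid points.
trapz_interval <- function(x, y, lo, hi) {
  if (lo >= hi) return(0)
  if (lo < x[1L] || hi > x[length(x)]) {
    stop_sepsimet("sepsimet_range_error",
                  "interval [%g, %g) outside axis range [%g, %g]",
                  lo, hi, x[1L], x[length(x)])
  }
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
}

# Wilson score 95% (or other level) confidence interval for a proportion
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
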