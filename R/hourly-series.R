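#' Regular time series with explicit missing slots
#'
#' The basic data container of the package: one variable sampled on a regular
#' (typically hourly) UTC grid, with `NA` marking slots where no usable
#' observation exists (e.g. unusable video frames). All downstream analyses
#' (periodogram, correlations, variation partitioning) consume this container
#' and never impute or interpolate the gaps.
#'
#' @param time `POSIXct` timestamps (UTC), strictly increasing with a constant
#'   step.
#' @param values numeric vector of the same length; `NA` = missing slot.
#' @param units unit label carried along for printing (e.g. `"ind/m2"`,
#'   `"degC"`).
#' @return An object of class `hourly_series`: a list with elements `time`,
#'   `values`, `units` and `step_hours`.
#' @examples
#' g <- build_grid("2011-10-07 08:00", "2011-10-07 13:00")
#' s <- hourly_series(g, c(1, 2, NA, 4, 5, 6), units = "ind/m2")
#' n_missing(s)
#' @export
hourly_series <- function(time, values, units = "") {
  if (is.character(time)) time <- parse_utc(time)
  if (!inherits(time, "POSIXct")) stop("'time' must be POSIXct", call. = FALSE)
  n <- length(time)
  if (length(values) != n) stop("'time' and 'values' lengths differ", call. = FALSE)
  if (n > 1L) {
    d <- diff(as.numeric(time))
    if (any(d <= 0)) stop("'time' must be strictly increasing", call. = FALSE)
    if (diff(range(d)) > 1e-6) stop("'time' must be on a regular grid", call. = FALSE)
    step_hours <- d[1L] / 3600
  } else step_hours <- NA_real_
  structure(
    list(time = time, values = as.numeric(values), units = as.character(units),
         step_hours = step_hours),
    class = "hourly_series"
  )
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d"))
  if (anyNA(out)) stop("unparseable timestamp(s)", call. = FALSE)
  out
}

#' @rdname hourly_series
#' @param x an `hourly_series`.
#' @export
n_slots <- function(x) {
  stopifnot(inherits(x, "hourly_series"))
  length(x$values)
}

#' @rdname hourly_series
#' @export
n_missing <- function(x) {
  stopifnot(inherits(x, "hourly_series"))
  sum(is.na(x$values))
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("<hourly_series> %d slots (%d missing), step %s h%s\n",
              n_slots(x), n_missing(x),
              format(x$step_hours),
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  cat(sprintf("  %s .. %s UTC\n",
              format(x$time[1L], "%Y-%m-%d %H:%M"),
              format(x$time[length(x$time)], "%Y-%m-%d %H:%M")))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.4g, median %.4g, max %.4g\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' @export
as.data.frame.hourly_series <- function(x, ...) {
  data.frame(time = x$time, value = x$values)
}
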