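#' Build an hourly timestamp grid
#'
#' Closed-interval hourly grid between two whole-hour UTC timestamps. The
#' study design this package emulates runs from 2011-10-07 08:00 to
#' 2011-10-30 14:00 UTC, a grid of 559 hourly slots.
#'
#' @param start,end timestamps (`POSIXct` or parseable strings, interpreted in
#'   UTC), both aligned on a whole hour, `start <= end`.
#' @return `POSIXct` vector of hourly timestamps, inclusive of both ends.
#' @examples
#' length(build_grid("2011-10-07 08:00", "2011-10-30 14:00"))  # 559
#' @export
build_grid <- function(start, end) {
  if (is.character(start)) start <- parse_utc(start)
  if (is.character(end)) end <- parse_utc(end)
  for (tt in list(start, end)) {
    if (!inherits(tt, "POSIXct") || length(tt) != 1L)
      stop("'start' and 'end' must be single timestamps", call. = FALSE)
    if (as.numeric(tt) %% 3600 != 0)
      stop("grid bounds must be aligned on a whole hour", call. = FALSE)
  }
  if (start > end) stop("'start' must not be after 'end'", call. = FALSE)
  seq(start, end, by = 3600)
}

#' Average irregular sensor records onto an hourly grid
#'
#' Aggregates high-frequency sensor records (e.g. 30-s temperature readings)
#' into hourly means. Each grid slot collects the raw records with timestamps
#' in `[slot, slot + 1h)` (left-closed, right-open); a slot with no record
#' becomes missing.
#'
#' @param time raw record timestamps (`POSIXct` or strings, UTC), nondecreasing.
#' @param values raw record values.
#' @param grid hourly grid from [build_grid()].
#' @param units unit label for the result.
#' @return An [hourly_series] on `grid`.
#' @export
hourly_average <- function(time, values, grid, units = "") {
  if (is.character(time)) time <- parse_utc(time)
  stopifnot(length(time) == length(values))
  out <- rep(NA_real_, length(grid))
  if (length(time)) {
    if (is.unsorted(as.numeric(time))) stop("raw timestamps must be nondecreasing", call. = FALSE)
    step <- if (length(grid) > 1L) diff(as.numeric(grid))[1L] else 3600
    idx <- findInterval(as.numeric(time), as.numeric(grid))
    ok <- idx >= 1L & (as.numeric(time) - as.numeric(grid)[pmax(idx, 1L)]) < step &
      !is.na(values)
    if (any(ok)) {
      sums <- rowsum(as.numeric(values[ok]), idx[ok])
      cnts <- rowsum(rep(1, sum(ok)), idx[ok])
      out[as.integer(rownames(sums))] <- sums / cnts
    }
  }
  hourly_series(grid, out, units = units)
}

#' Reduce repeated in-situ chemistry measurement cycles
#'
#' In-situ iron analysers run several measurement cycles per timepoint; only
#' the last cycles are chemically stable, so the concentration retained per
#' timepoint is the mean of the final two cycles. Timepoints with fewer than
#' two cycles are flagged missing with a warning.
#'
#' @param time one timestamp per timepoint.
#' @param cycles list with one numeric vector of cycle readings per timepoint.
#' @return `data.frame` with columns `time` and `value` (`NA` where < 2 cycles).
#' @examples
#' fe_cycle_reduce(Sys.time(), list(c(1, 2, 3)))$value  # 2.5
#' @export
fe_cycle_reduce <- function(time, cycles) {
  stopifnot(is.list(cycles), length(time) == length(cycles))
  vals <- vapply(cycles, function(cy) {
    cy <- as.numeric(cy)
    if (length(cy) < 2L) return(NA_real_)
    mean(cy[c(length(cy) - 1L, length(cy))])
  }, numeric(1))
  if (anyNA(vals))
    warning(sum(is.na(vals)), " timepoint(s) with < 2 cycles flagged missing",
            call. = FALSE)
  data.frame(time = time, value = vals)
}

#' Convert frame counts to densities
#'
#' Individuals counted in the field of view become densities (ind/m^2) by
#' dividing by the filmed area; the study design uses ~0.0355 m^2.
#'
#' @param s an [hourly_series] of counts.
#' @param area_m2 filmed area in m^2, > 0.
#' @return An [hourly_series] in ind/m^2; missing slots preserved.
#' @export
counts_to_density <- function(s, area_m2) {
  stopifnot(inherits(s, "hourly_series"))
  if (!is.numeric(area_m2) || length(area_m2) != 1L || is.na(area_m2) || area_m2 <= 0)
    stop("'area_m2' must be a single positive number", call. = FALSE)
  hourly_series(s$time, s$values / area_m2, units = "ind/m2")
}

#' Test an hourly series for a linear trend (stationarity screen)
#'
#' Periodogram analysis assumes stationarity in the mean; series are screened
#' with an ordinary least-squares regression of the values on the slot index
#' and a two-sided t-test on the slope. A significant slope means the series
#' should be detrended ([detrend()]) before the periodogram.
#'
#' @param s an [hourly_series] with at least 3 non-missing values.
#' @param alpha significance level for the slope test (default 0.05).
#' @return list with `slope` (per slot), `p_value`, and `stationary`
#'   (`TRUE` iff `p_value >= alpha`).
#' @export
trend_test <- function(s, alpha = 0.05) {
  stopifnot(inherits(s, "hourly_series"))
  stop_if_not_scalar_prob(alpha, "alpha")
  obs <- !is.na(s$values)
  if (sum(obs) < 3L) stop("need >= 3 non-missing values", call. = FALSE)
  idx <- seq_along(s$values) - 1L
  fit <- stats::lm(s$values ~ idx)
  co <- suppressWarnings(stats::coef(summary(fit)))   # perfect fits are fine here
  if (nrow(co) < 2L || is.na(co[2L, 4L])) {   # constant series: zero-variance slope
    return(list(slope = 0, p_value = 1, stationary = TRUE))
  }
  p <- co[2L, 4L]
  list(slope = unname(co[2L, 1L]), p_value = unname(p), stationary = p >= alpha)
}

#' Remove a linear trend from an hourly series
#'
#' Replaces the non-missing values by the residuals of an ordinary
#' least-squares regression on the slot index. Missing slots are preserved
#' untouched; residuals have mean zero.
#'
#' @inheritParams trend_test
#' @return A detrended [hourly_series] (same grid, same missing pattern).
#' @export
detrend <- function(s) {
  stopifnot(inherits(s, "hourly_series"))
  obs <- !is.na(s$values)
  if (sum(obs) < 3L) stop("need >= 3 non-missing values", call. = FALSE)
  idx <- seq_along(s$values) - 1L
  fit <- stats::lm(s$values ~ idx, na.action = stats::na.exclude)
  hourly_series(s$time, as.numeric(stats::residuals(fit)), units = s$units)
}

#' Subsample a series to a coarser sampling frequency
#'
#' Keeps every k-th slot (no interpolation, timestamps preserved), as used for
#' the 4-, 6- and 12-hourly correlation analyses. With a 559-slot hourly grid
#' and `k = 12`, 47 slots remain.
#'
#' @inheritParams trend_test
#' @param every_k_hours integer subsampling factor, >= 1 (in units of the
#'   series step).
#' @param anchor 0-based index of the first retained slot (default 0; the
#'   phase of the coarse grid).
#' @return An [hourly_series] with step `every_k_hours` times the input step.
#' @export
subsample <- function(s, every_k_hours, anchor = 0L) {
  stopifnot(inherits(s, "hourly_series"))
  k <- every_k_hours
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != round(k))
    stop("'every_k_hours' must be an integer >= 1", call. = FALSE)
  anchor <- as.integer(anchor)
  keep <- which(((seq_along(s$values) - 1L) - anchor) %% k == 0 &
                  (seq_along(s$values) - 1L) >= anchor)
  hourly_series(s$time[keep], s$values[keep], units = s$units)
}
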