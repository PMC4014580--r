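#' Specification of a synthetic hourly series
#'
#' Describes one synthetic variable on the study's hourly grid: a base level,
#' an optional linear trend, a sum of sinusoidal components (tidal forcing at
#' 12.42 h and 24.84 h in the emulated design), AR(1) noise, an observation
#' family, and a count of missing slots. The defaults reproduce the emulated
#' sampling design: 559 hourly slots starting 2011-10-07 08:00 UTC with 23
#' missing slots.
#'
#' @param n_slots number of hourly slots (default 559).
#' @param start_time first timestamp (UTC; default 2011-10-07 08:00).
#' @param n_missing number of slots flagged missing, drawn uniformly without
#'   replacement (default 23); must be `< n_slots`.
#' @param base_level constant level of the latent signal.
#' @param trend_slope linear trend per hour.
#' @param periods list of `c(period_hours, amplitude)` sinusoidal components;
#'   amplitudes must be >= 0. Phases are drawn uniformly on `[0, 2*pi)` per
#'   component.
#' @param noise_sd innovation standard deviation of the AR(1) noise, >= 0.
#' @param ar1 AR(1) coefficient in `[0, 1)`; the process is initialised at its
#'   stationary variance `noise_sd^2 / (1 - ar1^2)`.
#' @param family `"gaussian"` (signal + noise observed directly) or
#'   `"poisson-count"` (Poisson counts with latent mean `max(signal, 0)`,
#'   appropriate for nonnegative faunal counts).
#' @param units unit label attached to generated series.
#' @param seed integer seed; identical spec + seed give identical output.
#' @return An object of class `series_spec`.
#' @seealso [generate_series()]
#' @export
series_spec <- function(n_slots = 559L,
                        start_time = as.POSIXct("2011-10-07 08:00:00", tz = "UTC"),
                        n_missing = 23L,
                        base_level = 0,
                        trend_slope = 0,
                        periods = list(),
                        noise_sd = 1,
                        ar1 = 0,
                        family = c("gaussian", "poisson-count"),
                        units = "",
                        seed = NULL) {
  family <- match.arg(family)
  n_slots <- as.integer(n_slots)
  n_missing <- as.integer(n_missing)
  if (is.na(n_slots) || n_slots < 1L) stop("'n_slots' must be >= 1", call. = FALSE)
  if (is.na(n_missing) || n_missing < 0L || n_missing >= n_slots)
    stop("'n_missing' must satisfy 0 <= n_missing < n_slots", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.numeric(ar1) || ar1 < 0 || ar1 >= 1) stop("'ar1' must be in [0, 1)", call. = FALSE)
  if (is.numeric(periods)) periods <- list(periods)
  for (p in periods) {
    if (length(p) != 2L || !is.numeric(p) || p[1L] <= 0)
      stop("each period component must be c(period_hours > 0, amplitude)", call. = FALSE)
    if (p[2L] < 0) stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (is.character(start_time)) start_time <- parse_utc(start_time)
  structure(
    list(n_slots = n_slots, start_time = start_time, n_missing = n_missing,
         base_level = base_level, trend_slope = trend_slope, periods = periods,
         noise_sd = noise_sd, ar1 = ar1, family = family, units = units,
         seed = seed),
    class = "series_spec"
  )
}

#' Generate a synthetic hourly series
#'
#' Realises a [series_spec()]: latent signal
#' `base + trend * t + sum(amp * sin(2*pi*t/period + phase))` (t = hours since
#' start), plus AR(1) noise, observed through the chosen family; then
#' `n_missing` slots are blanked uniformly at random. The RNG draw order is
#' fixed (phases, noise, counts, missing slots) so a seed pins the whole
#' realisation.
#'
#' @param spec a [series_spec()].
#' @return An [hourly_series] with exactly `spec$n_missing` missing slots.
#' @examples
#' sp <- series_spec(n_slots = 100, n_missing = 5,
#'                   periods = list(c(12.42, 2)), noise_sd = 1, seed = 1)
#' s <- generate_series(sp)
#' n_missing(s)
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  with_seed(spec$seed, {
    n <- spec$n_slots
    t_h <- seq_len(n) - 1
    signal <- spec$base_level + spec$trend_slope * t_h
    for (p in spec$periods) {
      phase <- stats::runif(1L, 0, 2 * pi)
      signal <- signal + p[2L] * sin(2 * pi * t_h / p[1L] + phase)
    }
    noise <- if (spec$noise_sd > 0) {
      e <- stats::rnorm(n, 0, spec$noise_sd)
      if (spec$ar1 > 0) {
        x <- numeric(n)
        x[1L] <- stats::rnorm(1L, 0, spec$noise_sd / sqrt(1 - spec$ar1^2))
        for (i in seq_len(n)[-1L]) x[i] <- spec$ar1 * x[i - 1L] + e[i]
        x
      } else e
    } else numeric(n)
    latent <- signal + noise
    values <- switch(spec$family,
      "gaussian" = latent,
      "poisson-count" = stats::rpois(n, pmax(latent, 0))
    )
    if (spec$n_missing > 0L)
      values[sample.int(n, spec$n_missing)] <- NA_real_
    hourly_series(seq(spec$start_time, by = 3600, length.out = n), values,
                  units = spec$units)
  })
}

#' Specification of a synthetic labelled point pattern
#'
#' Describes clustered point patterns for a set of taxa inside a video frame,
#' emulating per-frame pixel annotations of mobile fauna. Each taxon occupies
#' `n_clusters` home-range centres (drawn once per seed, shared across frames)
#' with isotropic Gaussian spread; per-taxon point counts are exact.
#'
#' @param frame_width,frame_height frame size in pixels, > 0.
#' @param taxa `data.frame` with columns `name`, `n_points`, `n_clusters`,
#'   `cluster_sd` (pixels).
#' @param seed integer seed.
#' @return An object of class `pattern_spec`.
#' @seealso [generate_point_pattern()]
#' @export
pattern_spec <- function(frame_width, frame_height, taxa, seed = NULL) {
  if (!is.numeric(frame_width) || !is.numeric(frame_height) ||
      frame_width <= 0 || frame_height <= 0)
    stop("frame dimensions must be positive", call. = FALSE)
  need <- c("name", "n_points", "n_clusters", "cluster_sd")
  if (!is.data.frame(taxa) || !all(need %in% names(taxa)))
    stop("'taxa' must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(taxa$n_points < 0) || any(taxa$n_clusters < 1) || any(taxa$cluster_sd < 0))
    stop("invalid taxa table: need n_points >= 0, n_clusters >= 1, cluster_sd >= 0",
         call. = FALSE)
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 taxa = taxa, seed = seed),
            class = "pattern_spec")
}

#' Generate labelled point patterns for one or more frames
#'
#' Realises a [pattern_spec()]: cluster centres per taxon are drawn uniformly
#' inside the frame once (stable "home ranges"), then each frame draws the
#' taxon's points around randomly chosen centres with the specified isotropic
#' spread, rejection-sampled to stay inside the frame. Taxa with
#' `n_points = 0` are absent from the output.
#'
#' @param spec a [pattern_spec()].
#' @param n_frames number of frames to generate (default 1).
#' @return `data.frame` with columns `frame`, `taxon`, `x`, `y` (pixels, with
#'   `0 <= x < width`, `0 <= y < height`).
#' @export
generate_point_pattern <- function(spec, n_frames = 1L) {
  stopifnot(inherits(spec, "pattern_spec"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) stop("'n_frames' must be >= 1", call. = FALSE)
  w <- spec$frame_width; h <- spec$frame_height
  with_seed(spec$seed, {
    centres <- lapply(seq_len(nrow(spec$taxa)), function(i) {
      k <- spec$taxa$n_clusters[i]
      cbind(x = stats::runif(k, 0, w), y = stats::runif(k, 0, h))
    })
    out <- vector("list", n_frames * nrow(spec$taxa))
    ii <- 0L
    for (f in seq_len(n_frames)) {
      for (i in seq_len(nrow(spec$taxa))) {
        np <- spec$taxa$n_points[i]
        if (np == 0L) next
        sd <- spec$taxa$cluster_sd[i]
        cen <- centres[[i]][sample.int(nrow(centres[[i]]), np, replace = TRUE), ,
                            drop = FALSE]
        x <- cen[, 1L] + stats::rnorm(np, 0, sd)
        y <- cen[, 2L] + stats::rnorm(np, 0, sd)
        bad <- which(x < 0 | x >= w | y < 0 | y >= h)
        while (length(bad)) {           # resample escapees around their centre
          x[bad] <- cen[bad, 1L] + stats::rnorm(length(bad), 0, sd)
          y[bad] <- cen[bad, 2L] + stats::rnorm(length(bad), 0, sd)
          bad <- which(x < 0 | x >= w | y < 0 | y >= h)
        }
        ii <- ii + 1L
        out[[ii]] <- data.frame(frame = f, taxon = spec$taxa$name[i], x = x, y = y)
      }
    }
    res <- do.call(rbind, out[seq_len(ii)])
    if (is.null(res)) res <- data.frame(frame = integer(), taxon = character(),
                                        x = numeric(), y = numeric())
    rownames(res) <- NULL
    res
  })
}

#' Write/read series tables as CSV
#'
#' Tabular interchange format: ISO-8601 UTC `time` column plus one column per
#' variable, empty cells for missing slots.
#'
#' @param series named list of [hourly_series] on a shared grid.
#' @param path output/input file path.
#' @return `write_series_csv()` returns `path` invisibly; `read_series_csv()`
#'   returns a named list of [hourly_series].
#' @export
write_series_csv <- function(series, path) {
  stopifnot(is.list(series), length(series) >= 1L,
            all(vapply(series, inherits, logical(1), "hourly_series")))
  tm <- series[[1L]]$time
  for (s in series) stopifnot(identical(as.numeric(s$time), as.numeric(tm)))
  df <- data.frame(time = format(tm, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  for (nm in names(series)) df[[nm]] <- series[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tm <- parse_utc(sub("Z$", "", sub("T", " ", df$time)))
  out <- lapply(df[-1L], function(v) hourly_series(tm, as.numeric(v)))
  names(out) <- names(df)[-1L]
  out
}

#' Write/read labelled point annotations as CSV
#'
#' @param points `data.frame` with columns `frame`, `taxon`, `x`, `y`.
#' @param path file path.
#' @export
write_points_csv <- function(points, path) {
  stopifnot(all(c("frame", "taxon", "x", "y") %in% names(points)))
  utils::write.csv(points[c("frame", "taxon", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
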