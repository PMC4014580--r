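#' Simulate a complete synthetic study bundle
#'
#' Generates every input the analysis pipeline consumes, with the statistical
#' structure the analyses assume, emulating a 23-day hourly vent-imagery
#' deployment: 559 hourly slots (2011-10-07 08:00 to 2011-10-30 14:00 UTC)
#' with 23 missing, semi-diurnal (12.42 h) and diurnal (24.84 h) tidal
#' forcing, linear trends and AR(1) noise in the temperature probes,
#' Poisson-like counts per taxon, and clustered point patterns for the three
#' mobile taxa. Per-frame abundances and probe levels follow the emulated
#' design's order of magnitude; see the package vignette for the rationale of
#' each default.
#'
#' @param seed integer master seed (per-variable seeds are derived from it).
#' @param n_slots,n_missing grid size and number of missing slots.
#' @param start_time first timestamp (UTC).
#' @return List with `counts` (named list of [hourly_series] per taxon),
#'   `temperature` (named list per probe), `points` (`data.frame` of labelled
#'   point annotations for the mobile taxa on the non-missing frames),
#'   `area_m2`, `frame_width`, `frame_height`, `pixel_area_cm2`.
#' @export
simulate_study <- function(seed = 1L, n_slots = 559L, n_missing = 23L,
                           start_time = as.POSIXct("2011-10-07 08:00:00",
                                                   tz = "UTC")) {
  seed <- as.integer(seed)
  mk <- function(k, ...) generate_series(
    series_spec(n_slots = n_slots, n_missing = n_missing,
                start_time = start_time, seed = seed * 100L + k, ...))
  # taxon counts: mean per-frame abundances of the emulated assemblage,
  # semi-diurnal forcing strongest in the sessile tubeworms
  counts <- list(
    tubeworms   = mk(1L, base_level = 30, periods = list(c(12.42, 6), c(24.84, 3)),
                     noise_sd = 3, ar1 = 0.3, family = "poisson-count",
                     units = "count"),
    polynoids   = mk(2L, base_level = 6, periods = list(c(12.42, 1.5)),
                     noise_sd = 1.5, ar1 = 0.3, family = "poisson-count",
                     units = "count"),
    pycnogonids = mk(3L, base_level = 20, trend_slope = 0.01,
                     periods = list(c(24.84, 3)), noise_sd = 2, ar1 = 0.3,
                     family = "poisson-count", units = "count"),
    buccinids   = mk(4L, base_level = 3, noise_sd = 1, ar1 = 0.2,
                     family = "poisson-count", units = "count"),
    zoarcids    = mk(5L, base_level = 0.04, noise_sd = 0,
                     family = "poisson-count", units = "count"))
  # probe temperatures: distinct base levels, probe-specific tidal amplitude
  # (one probe nearly arrhythmic), slight drifts, strong autocorrelation
  tspec <- list(
    T601 = list(base = 3.1, amp12 = 0.25, amp25 = 0.35, trend = -4e-4),
    T602 = list(base = 3.5, amp12 = 0.30, amp25 = 0.40, trend = 4e-4),
    T603 = list(base = 4.1, amp12 = 0.35, amp25 = 0.45, trend = 0),
    T604 = list(base = 10.9, amp12 = 0.03, amp25 = 0.05, trend = -1.5e-3),
    T605 = list(base = 2.5, amp12 = 0.10, amp25 = 0.30, trend = 3e-4))
  temperature <- lapply(seq_along(tspec), function(i) {
    p <- tspec[[i]]
    mk(10L + i, base_level = p$base, trend_slope = p$trend,
       periods = list(c(12.42, p$amp12), c(24.84, p$amp25)),
       noise_sd = 0.12, ar1 = 0.6, units = "degC")
  })
  names(temperature) <- names(tspec)
  # clustered, mutually segregated point patterns for the mobile taxa
  frames_used <- which(!is.na(counts$polynoids$values))
  pat <- pattern_spec(
    frame_width = 720, frame_height = 576,
    taxa = data.frame(name = c("polynoids", "pycnogonids", "buccinids"),
                      n_points = c(6L, 20L, 3L),
                      n_clusters = c(4L, 2L, 2L),
                      cluster_sd = c(60, 25, 35)),
    seed = seed * 100L + 50L)
  points <- generate_point_pattern(pat, n_frames = length(frames_used))
  points$frame <- frames_used[points$frame]
  list(counts = counts, temperature = temperature, points = points,
       area_m2 = 0.0355, frame_width = 720, frame_height = 576,
       pixel_area_cm2 = (20 / 720) * (18 / 576))   # filmed area ca. 20 x 18 cm
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields mirror the arguments of [run_study()].
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration of the study design: densities from counts,
#' stationarity screen and automatic detrending, Whittaker-Robinson
#' periodograms per taxon and per probe, permutation correlations at several
#' sampling frequencies with Holm correction, nearest-neighbour segregation
#' and heat-map binning of the point annotations, and variation partitioning
#' of the density matrix between forward-selected temperature probes and
#' forward-selected temporal eigenfunctions. Deterministic under a fixed
#' seed. Taxa with too many zero frames to support the statistics (e.g.
#' sporadic fish visitors) are excluded from correlations and variation
#' partitioning via `exclude` but still receive a periodogram.
#'
#' @param config named list (or [read_config()] output) with elements:
#'   `counts` (named list of [hourly_series], or a series CSV path),
#'   `temperature` (idem), `points` (`data.frame` or points CSV path,
#'   optional), `area_m2` (default 0.0355), `bin_area_cm2` (default 1.125),
#'   `pixel_area_cm2`, `frame_width`, `frame_height` (required with
#'   `points`), `frequencies` (default `c(1, 4, 6, 12)`), `alpha` (0.05),
#'   `n_perm` (999), `n_perm_select` (99), `exclude` (default `"zoarcids"`),
#'   `seed`, `out_dir` (optional: write CSV/JSON/PNG outputs there).
#' @return Object of class `vent_study`: list with `densities`,
#'   `periodograms`, `correlations`, `segregation`, `heatmap`, `varpart`,
#'   `selected` and `summary` (the machine-readable summary list that is also
#'   written as JSON when `out_dir` is set).
#' @export
run_study <- function(config) {
  cfg <- config
  alpha <- cfg$alpha %||% 0.05
  n_perm <- cfg$n_perm %||% 999L
  n_sel <- cfg$n_perm_select %||% 99L
  freqs <- cfg$frequencies %||% c(1, 4, 6, 12)
  seed <- cfg$seed %||% 1L
  exclude <- cfg$exclude %||% "zoarcids"
  stop_if_not_scalar_prob(alpha, "alpha")
  if (n_perm < 99L) stop("'n_perm' must be >= 99", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  counts <- if (is.character(cfg$counts)) read_series_csv(cfg$counts) else cfg$counts
  temperature <- if (is.character(cfg$temperature)) read_series_csv(cfg$temperature)
                 else cfg$temperature
  points <- if (is.character(cfg$points)) read_points_csv(cfg$points) else cfg$points
  if (is.null(counts) || is.null(temperature))
    stop("config must supply 'counts' and 'temperature'", call. = FALSE)

  densities <- stage("prep", lapply(counts, counts_to_density,
                                    area_m2 = cfg$area_m2 %||% 0.0355))

  periodograms <- stage("rhythm", {
    all_series <- c(densities, temperature)
    out <- lapply(seq_along(all_series), function(i)
      wr_periodogram(all_series[[i]], n_perm = n_perm, alpha = alpha,
                     detrend = "auto", seed = seed + i))
    names(out) <- names(all_series)
    out
  })

  keep <- setdiff(names(densities), exclude)
  correlations <- stage("association",
    correlation_matrix(densities[keep], env = temperature, frequencies = freqs,
                       n_perm = n_perm, seed = seed))

  segregation <- heatmap <- NULL
  if (!is.null(points) && nrow(points)) {
    segregation <- stage("spatial", nn_segregation(points))
    if (!is.null(cfg$pixel_area_cm2))
      heatmap <- stage("spatial", bin_points(
        points, cfg$frame_width, cfg$frame_height, cfg$pixel_area_cm2,
        bin_area_cm2 = cfg$bin_area_cm2 %||% 1.125))
  }

  vp <- stage("varpart", {
    Y <- do.call(cbind, lapply(densities[keep], function(s) {
      if (!trend_test(s)$stationary) s <- detrend(s)
      s$values
    }))
    colnames(Y) <- keep
    Xc <- do.call(cbind, lapply(temperature, `[[`, "values"))
    colnames(Xc) <- names(temperature)
    cc <- stats::complete.cases(cbind(Y, Xc))
    Y <- Y[cc, , drop = FALSE]; Xc <- Xc[cc, , drop = FALSE]
    tm <- as.numeric(densities[[1L]]$time[cc]) / 3600
    Wc <- dbmem(tm - tm[1L])
    sel_X <- forward_select(Y, Xc, alpha = alpha, n_perm = n_sel, seed = seed + 101L)
    sel_W <- forward_select(Y, unclass(Wc)[, , drop = FALSE], alpha = alpha,
                            n_perm = n_sel, seed = seed + 102L)
    list(fit = vent_varpart(
           Y,
           if (length(sel_X$selected)) Xc[, sel_X$selected, drop = FALSE] else NULL,
           if (length(sel_W$selected)) Wc[, sel_W$selected, drop = FALSE] else NULL,
           n_perm = n_perm, seed = seed + 103L),
         selected_X = sel_X$selected, selected_W = sel_W$selected)
  })

  summary <- list(
    n_slots = n_slots(densities[[1L]]),
    n_missing = n_missing(densities[[1L]]),
    significant_periods = lapply(periodograms, function(p)
      p$period[p$significant %in% TRUE]),
    detrended = vapply(periodograms, attr, logical(1), "detrended"),
    correlations = correlations,
    segregation = if (!is.null(segregation)) as.data.frame(segregation),
    varpart = c(vp$fit$fractions,
                list(p_values = as.list(vp$fit$p_values),
                     selected_X = vp$selected_X, selected_W = vp$selected_W)),
    alpha = alpha, n_perm = n_perm, seed = seed)

  res <- structure(
    list(densities = densities, periodograms = periodograms,
         correlations = correlations, segregation = segregation,
         heatmap = heatmap, varpart = vp$fit,
         selected = list(X = vp$selected_X, W = vp$selected_W),
         summary = summary),
    class = "vent_study")
  if (!is.null(cfg$out_dir)) write_study(res, cfg$out_dir)
  res
}

#' @export
print.vent_study <- function(x, ...) {
  cat("Vent community rhythm analysis\n")
  cat(sprintf("  grid: %d slots, %d missing\n", x$summary$n_slots,
              x$summary$n_missing))
  for (nm in names(x$periodograms)) {
    sig <- x$summary$significant_periods[[nm]]
    cat(sprintf("  %-12s significant periods (h): %s\n", nm,
                if (length(sig)) paste(utils::head(sig, 12L), collapse = " ")
                else "none"))
  }
  cat(sprintf("  correlations: %d tests across %d frequencies\n",
              nrow(x$correlations), length(unique(x$correlations$frequency))))
  if (!is.null(x$segregation))
    cat(sprintf("  segregation: %d taxa over %d frames\n",
                length(x$segregation$abundances), x$segregation$n_frames["total"]))
  f <- x$varpart$fractions
  cat(sprintf("  varpart: [a]=%.3f [b]=%.3f [c]=%.3f [d]=%.3f\n",
              f$a, f$b, f$c, f$d))
  invisible(x)
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  if (!is.null(res$segregation))
    utils::write.csv(as.data.frame(res$segregation),
                     file.path(out_dir, "segregation.csv"), row.names = FALSE)
  for (nm in names(res$periodograms))
    utils::write.csv(as.data.frame(res$periodograms[[nm]]),
                     file.path(out_dir, paste0("periodogram_", nm, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  grDevices::png(file.path(out_dir, "periodograms.png"), width = 1200,
                 height = 300 * length(res$periodograms))
  op <- graphics::par(mfrow = c(length(res$periodograms), 1))
  for (nm in names(res$periodograms))
    plot(res$periodograms[[nm]], main = nm)
  graphics::par(op)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "varpart.png"), width = 700, height = 500)
  plot(res$varpart, labels = c("temperature", "temporal eigenfunctions"))
  grDevices::dev.off()
  if (!is.null(res$heatmap)) {
    grDevices::png(file.path(out_dir, "heatmaps.png"), width = 1200, height = 450)
    plot(res$heatmap)
    grDevices::dev.off()
  }
  invisible(out_dir)
}
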