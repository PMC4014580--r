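#' Fold a series into a Buys-Ballot table
#'
#' Folding at candidate period `T` assigns the value at slot `i` (0-based) to
#' column `i mod T`; a periodic signal of period `T` concentrates variance in
#' the column means. Missing values never enter a column mean; a column whose
#' members are all missing has an undefined mean and is excluded from the
#' periodogram statistic.
#'
#' @param s an [hourly_series] or plain numeric vector (`NA` = missing).
#' @param period integer candidate period in slots, `2 <= period <= n/2`.
#' @return Object of class `buys_ballot`: list with `period`, `columns`
#'   (list of member values per column, `NA`s included), `column_means`
#'   (`NaN` where a column has no observed member) and `column_counts`.
#' @examples
#' fold(c(1, 2, 3, 4, 5, 6), 2)$column_means  # 3 4
#' @export
fold <- function(s, period) {
  v <- if (inherits(s, "hourly_series")) s$values else as.numeric(s)
  n <- length(v)
  period <- as.integer(period)
  if (is.na(period) || period < 2L || period > n %/% 2L)
    stop("'period' must be an integer in [2, n/2]", call. = FALSE)
  grp <- ((seq_len(n) - 1L) %% period) + 1L
  counts <- tabulate(grp[!is.na(v)], nbins = period)
  sums <- rep(0, period)
  ok <- !is.na(v)
  if (any(ok)) {
    rs <- rowsum(v[ok], grp[ok])
    sums[as.integer(rownames(rs))] <- rs
  }
  means <- ifelse(counts > 0L, sums / counts, NaN)
  structure(list(period = period,
                 columns = split(v, grp),
                 column_means = means,
                 column_counts = counts),
            class = "buys_ballot")
}

#' Whittaker-Robinson amplitude of a Buys-Ballot table
#'
#' The periodogram statistic: the standard deviation of the (defined) column
#' means of the table. A strong periodicity at the folding period produces
#' widely spread column means; pure noise produces nearly equal ones. The
#' default uses the sample (n-1) standard deviation; `sd_type = "population"`
#' is available for cross-checks against implementations that divide by n.
#'
#' @param table a [fold()] result.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Nonnegative amplitude.
#' @examples
#' wr_statistic(fold(c(1, 2, 3, 4, 5, 6), 2))  # sd of c(3, 4)
#' @export
wr_statistic <- function(table, sd_type = c("sample", "population")) {
  stopifnot(inherits(table, "buys_ballot"))
  sd_type <- match.arg(sd_type)
  m <- table$column_means[table$column_counts > 0L]
  if (length(m) < 2L) stop("need >= 2 defined column means", call. = FALSE)
  out <- stats::sd(m)
  if (sd_type == "population") out <- out * sqrt((length(m) - 1) / length(m))
  out
}

#' Whittaker-Robinson periodogram with permutation significance
#'
#' Scans integer candidate periods `2..t_max` (default `floor(n/2)`; with the
#' emulated 559-slot design, periods 2..279), computing the Buys-Ballot
#' amplitude at each and a one-sided permutation p-value: the observed
#' (non-missing) values are shuffled over the observed slots -- the missing
#' pattern stays fixed, preserving the information-loss structure -- and the
#' whole amplitude spectrum is recomputed per permutation. The p-value at each
#' period is `(1 + #permuted amplitudes >= observed) / (n_perm + 1)`.
#'
#' Interpretation caveat: the statistic also flags integer multiples
#' (harmonics) of a true period, because folding at a multiple reproduces the
#' periodic profile as well (see [harmonics()]).
#'
#' @param s an [hourly_series] or numeric vector; should be (trend-)stationary.
#'   `detrend = "auto"` screens with [trend_test()] and removes a significant
#'   linear trend first.
#' @param t_max largest candidate period (default `floor(n/2)`).
#' @param n_perm number of random permutations, >= 99 (default 999).
#' @param alpha per-period significance level (default 0.05). No correction
#'   across periods is applied by default; `correct = "holm"` is available.
#' @param detrend `"never"`, `"auto"` or `"always"`.
#' @param sd_type passed to [wr_statistic()].
#' @param correct `"none"` (default) or `"holm"` across periods.
#' @param seed integer seed for the permutations.
#' @param permutations optional integer matrix (one permutation of the
#'   observed values per row) replacing random shuffles; the supplied set is
#'   then treated as the complete null set (include the identity) and p-values
#'   are exact proportions -- used for exhaustive-enumeration checks.
#' @return Object of class `wr_periodogram`: a `data.frame` with columns
#'   `period`, `amplitude`, `p_value`, `significant`, plus attributes `n`,
#'   `n_missing`, `n_perm`, `alpha`, `detrended`.
#' @examples
#' sp <- series_spec(n_slots = 120, n_missing = 6,
#'                   periods = list(c(12, 2)), noise_sd = 1, seed = 7)
#' pg <- wr_periodogram(generate_series(sp), n_perm = 99, seed = 1)
#' head(summary(pg))
#' @export
wr_periodogram <- function(s, t_max = NULL, n_perm = 999L, alpha = 0.05,
                           detrend = c("never", "auto", "always"),
                           sd_type = c("sample", "population"),
                           correct = c("none", "holm"),
                           seed = NULL, permutations = NULL) {
  detrend <- match.arg(detrend)
  sd_type <- match.arg(sd_type)
  correct <- match.arg(correct)
  stop_if_not_scalar_prob(alpha, "alpha")
  if (!inherits(s, "hourly_series"))
    s <- hourly_series(seq(as.POSIXct("2000-01-01", tz = "UTC"),
                           by = 3600, length.out = length(s)), s)
  n <- n_slots(s)
  if (n < 4L) stop("series too short (n < 4)", call. = FALSE)
  detrended <- FALSE
  if (detrend == "always" || (detrend == "auto" && !trend_test(s)$stationary)) {
    s <- detrend(s)
    detrended <- TRUE
  }
  t_max <- as.integer(t_max %||% (n %/% 2L))
  if (t_max < 2L || t_max > n %/% 2L)
    stop("'t_max' must be in [2, n/2]", call. = FALSE)

  v <- s$values
  obs <- which(!is.na(v))
  m <- length(obs)
  vo <- v[obs]
  exact <- !is.null(permutations)
  if (exact) {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != m)
      stop("'permutations' must have one column per observed value", call. = FALSE)
    n_perm <- nrow(permutations)
    P <- matrix(vo[t(permutations)], nrow = m)   # m x n_perm, one shuffle per column
  } else {
    n_perm <- as.integer(n_perm)
    if (is.na(n_perm) || n_perm < 99L) stop("'n_perm' must be >= 99", call. = FALSE)
    P <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) vo[sample.int(m)], numeric(m)))
  }

  periods <- 2:t_max
  V <- cbind(vo, P)                       # col 1 = observed, rest = permutations
  amp_obs <- numeric(length(periods))
  p_val <- numeric(length(periods))
  grp_all <- (obs - 1L)                   # 0-based slot index of observed values
  for (j in seq_along(periods)) {
    Tt <- periods[j]
    grp <- (grp_all %% Tt) + 1L
    sums <- rowsum(V, grp)                # one row per non-empty column
    counts <- tabulate(grp, nbins = Tt)[counts_idx <- as.integer(rownames(sums))]
    k <- length(counts_idx)
    if (k < 2L) { amp_obs[j] <- NA_real_; p_val[j] <- NA_real_; next }
    means <- sums / counts
    mu <- colMeans(means)
    ss <- colSums(means * means) - k * mu * mu
    denom <- if (sd_type == "sample") k - 1L else k
    amps <- sqrt(pmax(ss, 0) / denom)
    amp_obs[j] <- amps[1L]
    tol <- 1e-8 * (1 + abs(amps[1L]))    # exact permutation ties, float-safe
    p_val[j] <- if (exact) mean(amps[-1L] >= amps[1L] - tol)
                else (1 + sum(amps[-1L] >= amps[1L] - tol)) / (n_perm + 1)
  }
  p_use <- if (correct == "holm") holm_adjust(p_val) else p_val
  out <- data.frame(period = periods, amplitude = amp_obs, p_value = p_val,
                    significant = !is.na(p_use) & p_use < alpha)
  if (correct == "holm") out$p_holm <- p_use
  structure(out, class = c("wr_periodogram", "data.frame"),
            n = n, n_missing = n - m, n_perm = n_perm, alpha = alpha,
            sd_type = sd_type, correct = correct, detrended = detrended)
}

#' Integer harmonics of a base period
#'
#' The Buys-Ballot amplitude also peaks at integer multiples of a true period
#' (folding at a multiple reproduces the periodic profile), so significant
#' periods at e.g. 12, 24, 36, 48 h are read as one semi-diurnal rhythm plus
#' harmonics rather than four independent rhythms.
#'
#' @param t_base base period (>= 2).
#' @param t_max largest period to report.
#' @return Integer multiples of `t_base` up to `t_max`.
#' @examples
#' harmonics(12, 50)  # 12 24 36 48
#' @export
harmonics <- function(t_base, t_max) {
  t_base <- as.integer(t_base)
  if (is.na(t_base) || t_base < 2L) stop("'t_base' must be >= 2", call. = FALSE)
  if (t_max < t_base) return(integer())
  seq.int(t_base, as.integer(t_max), by = t_base)
}

#' @export
print.wr_periodogram <- function(x, ...) {
  a <- attributes(x)
  if (is.null(a$n)) {           # subset lost the metadata: print as a table
    print(as.data.frame(unclass(x)))
    return(invisible(x))
  }
  cat(sprintf("Whittaker-Robinson periodogram: n = %d (%d missing), periods %d..%d\n",
              a$n, a$n_missing, min(x$period), max(x$period)))
  cat(sprintf("  %d permutations, alpha = %g%s%s\n", a$n_perm, a$alpha,
              if (a$detrended) ", linearly detrended" else "",
              if (a$correct == "holm") ", Holm-corrected" else ""))
  sig <- x$period[x$significant %in% TRUE]
  if (length(sig)) {
    cat("  significant periods (h):", paste(sig, collapse = " "), "\n")
  } else cat("  no significant periods\n")
  invisible(x)
}

#' @export
summary.wr_periodogram <- function(object, ...) {
  sig <- as.data.frame(unclass(object))[object$significant %in% TRUE, , drop = FALSE]
  out <- sig[order(-sig$amplitude), c("period", "amplitude", "p_value")]
  rownames(out) <- NULL
  out
}

#' Plot a Whittaker-Robinson periodogram
#'
#' Amplitude against candidate period; significant periods drawn as filled
#' black squares, as is conventional for these periodograms.
#'
#' @param x a [wr_periodogram()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.wr_periodogram <- function(x, ...) {
  graphics::plot(x$period, x$amplitude, type = "l", col = "grey40",
                 xlab = "Period (h)", ylab = "Amplitude (sd of column means)",
                 ...)
  sig <- x$significant %in% TRUE
  graphics::points(x$period[sig], x$amplitude[sig], pch = 15, col = "black")
  invisible(x)
}

#' Most prominent significant period in a band
#'
#' Convenience selector used when reading a periodogram: among the significant
#' periods inside `[band_min, band_max]`, the one of maximum amplitude (e.g.
#' band < 20 h isolates the semi-diurnal constituent from its harmonics).
#'
#' @param x a [wr_periodogram()] result.
#' @param band_min,band_max inclusive period band in hours.
#' @return The selected period, or `NA` if no significant period in the band.
#' @export
peak_period <- function(x, band_min = 2, band_max = Inf) {
  stopifnot(inherits(x, "wr_periodogram"))
  sel <- x$significant %in% TRUE & x$period >= band_min & x$period <= band_max
  if (!any(sel)) return(NA_integer_)
  x$period[sel][which.max(x$amplitude[sel])]
}
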