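#' Two-tailed permutation correlation test
#'
#' Pearson correlation over the mutually observed slots of two series, with a
#' two-tailed permutation test: one series is shuffled over the complete pairs
#' and `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`. The permutation
#' null makes no normality assumption; missing slots are never imputed and
#' the number of complete pairs actually used is reported.
#'
#' @param x,y [hourly_series] on the same grid, or plain numeric vectors of
#'   equal length.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param permutations optional integer matrix (one permutation of the
#'   complete pairs per row); the supplied set is treated as the complete null
#'   set (include the identity) and the p-value is an exact proportion.
#' @return List with `r`, `p_raw`, `n_used`, and `degenerate` (`TRUE` when a
#'   series has zero variance over the complete pairs, in which case `r` and
#'   `p_raw` are `NA`).
#' @examples
#' perm_cor(1:20, (1:20)^2, n_perm = 99, seed = 1)$r
#' @export
perm_cor <- function(x, y, n_perm = 999L, seed = NULL, permutations = NULL) {
  xv <- if (inherits(x, "hourly_series")) x$values else as.numeric(x)
  yv <- if (inherits(y, "hourly_series")) y$values else as.numeric(y)
  if (length(xv) != length(yv)) stop("series lengths differ", call. = FALSE)
  ok <- !is.na(xv) & !is.na(yv)
  m <- sum(ok)
  if (m < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  xc <- xv[ok] - mean(xv[ok])
  yc <- yv[ok] - mean(yv[ok])
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p_raw = NA_real_, n_used = m, degenerate = TRUE))
  r_obs <- sum(xc * yc) / (sx * sy)
  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    if (ncol(permutations) != m)
      stop("'permutations' must have one column per complete pair", call. = FALSE)
    Y <- matrix(yc[t(permutations)], nrow = m)
    r_perm <- as.numeric(crossprod(xc, Y)) / (sx * sy)
    p <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  } else {
    n_perm <- as.integer(n_perm)
    if (is.na(n_perm) || n_perm < 99L) stop("'n_perm' must be >= 99", call. = FALSE)
    Y <- with_seed(seed,
      vapply(seq_len(n_perm), function(i) yc[sample.int(m)], numeric(m)))
    r_perm <- as.numeric(crossprod(xc, Y)) / (sx * sy)
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  }
  list(r = r_obs, p_raw = p, n_used = m, degenerate = FALSE)
}

#' Holm step-down adjustment of p-values
#'
#' Family-wise error control over a family of tests: sort p-values ascending,
#' multiply the i-th smallest by `(m - i + 1)`, enforce monotonicity, cap at
#' 1. Adjusted values are returned in the original order and never fall below
#' the raw ones. `NA`s are propagated.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(p) {
  pp <- p[!is.na(p)]
  if (length(pp) && (any(pp <= 0) || any(pp > 1)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "holm")
}

#' Pairwise permutation correlations at multiple sampling frequencies
#'
#' Runs [perm_cor()] on every declared pair of columns at each requested
#' sampling frequency (the series are subsampled with [subsample()], never
#' interpolated), then applies the Holm correction within each frequency's
#' family of tests. Pairs are all unordered taxon pairs within `densities`
#' plus, if given, all taxon x environment pairs.
#'
#' @param densities named list of [hourly_series] (faunal densities) on a
#'   shared grid.
#' @param env optional named list of [hourly_series] (environmental series) on
#'   the same grid.
#' @param frequencies sampling steps in hours (default `c(1, 4, 6, 12)`).
#' @param n_perm permutations per test (default 999).
#' @param anchor subsampling anchor passed to [subsample()].
#' @param seed integer seed (per-test seeds are derived from it).
#' @return `data.frame` with columns `var1`, `var2`, `frequency`, `n_used`,
#'   `r`, `p_raw`, `p_holm`. Degenerate or failing pairs are skipped with a
#'   warning.
#' @export
correlation_matrix <- function(densities, env = NULL,
                               frequencies = c(1, 4, 6, 12),
                               n_perm = 999L, anchor = 0L, seed = NULL) {
  stopifnot(is.list(densities), length(densities) >= 1L)
  taxa <- names(densities)
  pairs <- if (length(taxa) >= 2L) utils::combn(taxa, 2L, simplify = FALSE) else list()
  if (!is.null(env))
    for (tx in taxa) for (ev in names(env)) pairs <- c(pairs, list(c(tx, ev)))
  if (!length(pairs)) stop("no pairs to test", call. = FALSE)
  all_series <- c(densities, env %||% list())
  rows <- list(); ri <- 0L
  for (fq in frequencies) {
    sub <- lapply(all_series, subsample, every_k_hours = fq, anchor = anchor)
    res <- vector("list", length(pairs))
    for (j in seq_along(pairs)) {
      pr <- pairs[[j]]
      subseed <- if (is.null(seed)) NULL else seed + 1000L * match(fq, frequencies) + j
      res[[j]] <- tryCatch(
        perm_cor(sub[[pr[1L]]], sub[[pr[2L]]], n_perm = n_perm, seed = subseed),
        error = function(e) {
          warning(sprintf("pair %s/%s at %g h skipped: %s", pr[1L], pr[2L], fq,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(res[[j]]) && isTRUE(res[[j]]$degenerate)) {
        warning(sprintf("pair %s/%s at %g h degenerate (zero variance)",
                        pr[1L], pr[2L], fq), call. = FALSE)
        res[j] <- list(NULL)
      }
    }
    keep <- !vapply(res, is.null, logical(1))
    if (!any(keep)) next
    praw <- vapply(res[keep], `[[`, numeric(1), "p_raw")
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      var1 = vapply(pairs[keep], `[`, character(1), 1L),
      var2 = vapply(pairs[keep], `[`, character(1), 2L),
      frequency = fq,
      n_used = vapply(res[keep], `[[`, numeric(1), "n_used"),
      r = vapply(res[keep], `[[`, numeric(1), "r"),
      p_raw = praw,
      p_holm = holm_adjust(praw))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
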