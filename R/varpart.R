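#' Temporal eigenfunctions (dbMEM) of a sampling design
#'
#' Distance-based Moran eigenvector maps on the one-dimensional time axis:
#' orthogonal, centred eigenfunctions that decompose the sampling design into
#' periodic-like components from the whole-series scale down to the sampling
#' step. Construction: Euclidean distance matrix of the retained time points
#' (hours); distances beyond a truncation threshold `t` -- by default the
#' largest gap between temporally adjacent retained slots, so the design
#' stays connected -- are replaced by `4 t`; principal-coordinate
#' decomposition of the centred, transformed matrix; the eigenvectors with
#' positive eigenvalues form the basis. On a regular complete grid these are
#' discrete sinusoids ordered from low to high frequency.
#'
#' @param times time points in hours (numeric) or `POSIXct`; >= 3 distinct
#'   values, increasing.
#' @param truncation optional threshold in hours (default: largest adjacent
#'   gap).
#' @return Object of class `dbmem_basis`: numeric matrix (rows = time points,
#'   columns `MEM1`, `MEM2`, ... with unit norm) with attributes
#'   `eigenvalues` and `truncation`.
#' @examples
#' B <- dbmem(0:9)
#' zapsmall(crossprod(B))  # identity: orthonormal basis
#' @export
dbmem <- function(times, truncation = NULL) {
  if (inherits(times, "POSIXct")) times <- as.numeric(times) / 3600
  times <- as.numeric(times)
  n <- length(times)
  if (n < 3L) stop("need >= 3 time points", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be increasing", call. = FALSE)
  gaps <- diff(times)
  if (all(gaps == 0)) stop("degenerate design: all time points equal", call. = FALSE)
  thr <- truncation %||% max(gaps)
  if (thr <= 0) stop("'truncation' must be > 0", call. = FALSE)
  D <- abs(outer(times, times, "-"))
  D[D > thr] <- 4 * thr
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  eg <- eigen(G, symmetric = TRUE)
  keep <- eg$values > max(abs(eg$values)) * 1e-9
  V <- eg$vectors[, keep, drop = FALSE]
  colnames(V) <- paste0("MEM", seq_len(ncol(V)))
  structure(V, eigenvalues = eg$values[keep], truncation = thr,
            class = c("dbmem_basis", "matrix", "array"))
}

#' @export
print.dbmem_basis <- function(x, ...) {
  cat(sprintf("<dbmem_basis> %d eigenfunctions over %d time points (truncation %.4g h)\n",
              ncol(x), nrow(x), attr(x, "truncation")))
  invisible(x)
}

# Canonical (multi-response) R2 of Y on X by least squares, with rank check.
# X = NULL means the intercept-only model (R2 = 0).
canonical_r2 <- function(Y, X = NULL) {
  Y <- as_num_matrix(Y, "Y")
  n <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response has zero variance", call. = FALSE)
  if (is.null(X) || NCOL(X) == 0L)
    return(list(r2 = 0, adj = 0, m = 0L, n = n, fitted = matrix(0, n, ncol(Y)),
                resid = Yc))
  X <- as_num_matrix(X, "X")
  if (nrow(X) != n) stop("'Y' and 'X' row counts differ", call. = FALSE)
  m <- ncol(X)
  if (m >= n - 1L) stop("need fewer predictors than n - 1", call. = FALSE)
  qx <- qr(cbind(`(Intercept)` = 1, X))
  if (qx$rank < m + 1L) {
    bad <- colnames(cbind(`(Intercept)` = 1, X))[qx$pivot[(qx$rank + 1L):(m + 1L)]]
    stop("singular design; collinear column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fit <- qr.fitted(qx, Yc)
  r2 <- sum(fit^2) / ss_tot
  list(r2 = r2, adj = 1 - (1 - r2) * (n - 1) / (n - m - 1), m = m, n = n,
       fitted = fit, resid = Yc - fit)
}

#' Adjusted canonical R-squared
#'
#' Proportion of the total variance of a (possibly multi-column) response
#' matrix explained by least squares on a predictor matrix, with Ezekiel's
#' adjustment `1 - (1 - R2) (n - 1) / (n - m - 1)`, which is unbiased (mean
#' zero) under the null for `m` predictors and `n` rows. This is the currency
#' in which variation-partitioning fractions are expressed.
#'
#' @param Y response matrix (rows = observations).
#' @param X predictor matrix; `NULL` for the intercept-only model.
#' @return Adjusted R-squared (may be slightly negative by construction).
#' @examples
#' adjusted_r2(matrix(1:10), matrix(1:10))  # 1
#' @export
adjusted_r2 <- function(Y, X) {
  canonical_r2(Y, X)$adj
}

# Partial pseudo-F of adding X to a model already containing Z (Z may be NULL),
# with a Freedman-Lane residual-permutation p-value.
partial_perm_test <- function(Y, X, Z = NULL, n_perm = 199L, seed = NULL) {
  Y <- as_num_matrix(Y, "Y")
  X <- as_num_matrix(X, "X")
  n <- nrow(Y)
  mZ <- if (is.null(Z)) 0L else ncol(as_num_matrix(Z, "Z"))
  mX <- ncol(X)
  red <- canonical_r2(Y, Z)
  stat <- function(Ystar) {
    r <- canonical_r2(Ystar, Z)
    f <- canonical_r2(Ystar, if (is.null(Z)) X else cbind(Z, X))
    ss_tot <- sum(sweep(Ystar, 2L, colMeans(Ystar))^2)
    rss_red <- (1 - r$r2) * ss_tot
    rss_full <- (1 - f$r2) * ss_tot
    ((rss_red - rss_full) / mX) / (rss_full / (n - 1 - mX - mZ))
  }
  f_obs <- stat(Y)
  base_fit <- red$fitted
  base_res <- red$resid
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat(base_fit + base_res[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  list(F = f_obs, p = (1 + sum(f_perm >= f_obs)) / (n_perm + 1))
}

#' Forward selection of predictors with the double stopping criterion
#'
#' Greedy forward selection for a (multi-column) response: at each step the
#' candidate with the largest partial contribution to the canonical R-squared
#' is tested by residual permutation; selection stops when the best
#' candidate's p-value reaches `alpha`, or -- second stopping rule -- once the
#' cumulative adjusted R-squared reaches that of the full all-candidates
#' model, which guards against accumulating spurious predictors; the
#' significant candidate that crosses the cap is kept and the scan stops
#' there.
#'
#' @param Y response matrix.
#' @param candidates candidate predictor matrix (named columns).
#' @param alpha entry threshold for the permutation p-value (default 0.05).
#' @param r2a_cap cumulative adjusted-R2 cap (default: adjusted R2 of the
#'   model with all candidates).
#' @param n_perm permutations per entry test (default 199).
#' @param seed integer seed.
#' @return List with `selected` (column names, possibly empty), `steps`
#'   (`data.frame` of the accepted steps: candidate, cumulative R2, cumulative
#'   adjusted R2, p), and `r2a_cap`.
#' @export
forward_select <- function(Y, candidates, alpha = 0.05, r2a_cap = NULL,
                           n_perm = 199L, seed = NULL) {
  Y <- as_num_matrix(Y, "Y")
  candidates <- as_num_matrix(candidates, "candidates")
  stop_if_not_scalar_prob(alpha, "alpha")
  r2a_cap <- r2a_cap %||% canonical_r2(Y, candidates)$adj
  selected <- character()
  steps <- list()
  repeat {
    remaining <- setdiff(colnames(candidates), selected)
    if (!length(remaining)) break
    cur <- if (length(selected)) candidates[, selected, drop = FALSE] else NULL
    r2_cur <- canonical_r2(Y, cur)$r2
    gains <- vapply(remaining, function(cn) {
      canonical_r2(Y, cbind(cur, candidates[, cn, drop = FALSE]))$r2 - r2_cur
    }, numeric(1))
    best <- remaining[which.max(gains)]
    cand_seed <- if (is.null(seed)) NULL else seed + length(selected)
    ts <- partial_perm_test(Y, candidates[, best, drop = FALSE], Z = cur,
                            n_perm = n_perm, seed = cand_seed)
    if (ts$p >= alpha) break
    new_mod <- canonical_r2(Y, candidates[, c(selected, best), drop = FALSE])
    selected <- c(selected, best)
    steps[[length(steps) + 1L]] <- data.frame(
      candidate = best, r2 = new_mod$r2, adj_r2 = new_mod$adj, p = ts$p)
    # second stopping rule: once the cumulative adjusted R2 reaches that of
    # the all-candidates model, further gains are indistinguishable from
    # overfitting; the (significant) crossing candidate is kept, then stop
    if (new_mod$adj > r2a_cap) break
  }
  list(selected = selected,
       steps = if (length(steps)) do.call(rbind, steps)
               else data.frame(candidate = character(), r2 = numeric(),
                               adj_r2 = numeric(), p = numeric()),
       r2a_cap = r2a_cap)
}

#' Variation-partitioning fractions from three adjusted R-squared values
#'
#' Given the adjusted R-squared of `Y ~ X` (`[a+b]`), of `Y ~ W` (`[b+c]`)
#' and of `Y ~ X + W` (`[a+b+c]`), returns the unique fractions
#' `a = [a+b+c] - [b+c]`, `c = [a+b+c] - [a+b]`, the joint fraction
#' `b = [a+b] + [b+c] - [a+b+c]` and the residual `d = 1 - [a+b+c]`.
#' Fractions are reported as computed -- slightly negative values are an
#' expected artefact of the adjustment and are never clipped.
#'
#' @param r2_ab,r2_bc,r2_abc adjusted R-squared of the two marginal models and
#'   the joint model.
#' @return Named list `a`, `b`, `c`, `d`.
#' @examples
#' varpart_fractions(0.289, 0.365, 0.289 + 0.365 - 0.194)$a  # 0.095
#' @export
varpart_fractions <- function(r2_ab, r2_bc, r2_abc) {
  list(a = r2_abc - r2_bc,
       b = r2_ab + r2_bc - r2_abc,
       c = r2_abc - r2_ab,
       d = 1 - r2_abc)
}

#' Variation partitioning of a response matrix between two predictor sets
#'
#' Partitions the variance of a multi-taxon response matrix `Y` between an
#' environmental predictor set `X` and a temporal predictor set `W`
#' (typically selected dbMEM eigenfunctions), in adjusted-R-squared currency:
#' the unique fractions `[a]` (X only) and `[c]` (W only), the jointly
#' explained fraction `[b]`, and the residual `[d]`. The testable fractions
#' (`[a+b]`, `[b+c]`, `[a+b+c]`, `[a]`, `[c]`) receive residual-permutation
#' p-values; `[b]` and `[d]` are not testable and are reported without one.
#' If one side is empty the partition degenerates accordingly (e.g. `W`
#' empty: `b = c = 0`, `a` = adjusted R2 of `Y ~ X`).
#'
#' @param Y response matrix (complete rows).
#' @param X,W predictor matrices on the same rows (either may be `NULL` or
#'   zero-column).
#' @param n_perm permutations for the fraction tests (default 999).
#' @param seed integer seed.
#' @return Object of class `vent_varpart`: list with `fractions` (a, b, c, d),
#'   `r2` (adjusted `[a+b]`, `[b+c]`, `[a+b+c]`), `p_values` (named:
#'   `ab`, `bc`, `abc`, `a`, `c`), `n`, and the predictor names.
#' @export
vent_varpart <- function(Y, X, W, n_perm = 999L, seed = NULL) {
  Y <- as_num_matrix(Y, "Y")
  X <- if (!is.null(X) && NCOL(X) > 0L) as_num_matrix(X, "X") else NULL
  W <- if (!is.null(W) && NCOL(W) > 0L) as_num_matrix(W, "W") else NULL
  if (anyNA(Y) || (!is.null(X) && anyNA(X)) || (!is.null(W) && anyNA(W)))
    stop("complete cases required; drop missing rows first", call. = FALSE)
  n <- nrow(Y)
  r2_ab <- canonical_r2(Y, X)$adj
  r2_bc <- canonical_r2(Y, W)$adj
  both <- if (is.null(X)) W else if (is.null(W)) X else cbind(X, W)
  r2_abc <- canonical_r2(Y, both)$adj
  fr <- varpart_fractions(r2_ab, r2_bc, r2_abc)
  if (is.null(X) || is.null(W)) {     # degenerate partition: one side absent
    fr$b <- 0
    if (is.null(X)) { fr$a <- 0; fr$c <- r2_bc } else { fr$c <- 0; fr$a <- r2_ab }
    message("degenerate partition: one predictor set is empty")
  }
  p <- c(ab = NA_real_, bc = NA_real_, abc = NA_real_, a = NA_real_, c = NA_real_)
  sd2 <- function(k) if (is.null(seed)) NULL else seed + k
  if (!is.null(X)) p["ab"] <- partial_perm_test(Y, X, NULL, n_perm, sd2(1L))$p
  if (!is.null(W)) p["bc"] <- partial_perm_test(Y, W, NULL, n_perm, sd2(2L))$p
  if (!is.null(both)) p["abc"] <- partial_perm_test(Y, both, NULL, n_perm, sd2(3L))$p
  if (!is.null(X) && !is.null(W)) {
    p["a"] <- partial_perm_test(Y, X, W, n_perm, sd2(4L))$p
    p["c"] <- partial_perm_test(Y, W, X, n_perm, sd2(5L))$p
  }
  if (any(unlist(fr) < 0))
    warning("negative fraction(s) reported unclipped (adjusted-R2 artefact)",
            call. = FALSE)
  structure(list(fractions = fr,
                 r2 = c(ab = r2_ab, bc = r2_bc, abc = r2_abc),
                 p_values = p, n = n,
                 X_names = colnames(X), W_names = colnames(W)),
            class = "vent_varpart")
}

#' @export
print.vent_varpart <- function(x, digits = 3, ...) {
  cat(sprintf("Variation partitioning (n = %d, adjusted R2)\n", x$n))
  cat(sprintf("  X: %s\n  W: %s\n",
              paste(x$X_names %||% "<empty>", collapse = ", "),
              paste(x$W_names %||% "<empty>", collapse = ", ")))
  f <- x$fractions
  tab <- data.frame(
    fraction = c("[a] X only", "[b] joint", "[c] W only", "[d] residual",
                 "[a+b] X", "[b+c] W", "[a+b+c] all"),
    adj_r2 = round(c(f$a, f$b, f$c, f$d, x$r2["ab"], x$r2["bc"], x$r2["abc"]), digits),
    p = c(signif(x$p_values["a"], 3), NA, signif(x$p_values["c"], 3), NA,
          signif(x$p_values["ab"], 3), signif(x$p_values["bc"], 3),
          signif(x$p_values["abc"], 3)))
  print(tab, row.names = FALSE, na.print = "")
  invisible(x)
}

#' Venn-style plot of a variation partition
#'
#' Two overlapping circles labelled with the unique fractions `[a]`, `[c]`,
#' the joint fraction `[b]` and the residual `[d]`.
#'
#' @param x a [vent_varpart()] result.
#' @param labels names for the two predictor sets.
#' @param ... ignored.
#' @export
plot.vent_varpart <- function(x, labels = c("X", "W"), ...) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 6), asp = 1)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(4 + 2.2 * cos(th), 3 + 2.2 * sin(th))
  graphics::lines(6 + 2.2 * cos(th), 3 + 2.2 * sin(th))
  f <- x$fractions
  pc <- function(v) sprintf("%.1f%%", 100 * v)
  graphics::text(3, 3, paste0("[a]\n", pc(f$a)))
  graphics::text(5, 3, paste0("[b]\n", pc(f$b)))
  graphics::text(7, 3, paste0("[c]\n", pc(f$c)))
  graphics::text(5, 0.5, paste0("residuals [d] = ", pc(f$d)))
  graphics::text(2.5, 5.4, labels[1L])
  graphics::text(7.5, 5.4, labels[2L])
  invisible(x)
}
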