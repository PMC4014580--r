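#' Bin labelled points into a heat-map grid
#'
#' Aggregates per-frame pixel annotations into square spatial bins for
#' heat-map display of where each taxon was observed. Bins are square with
#' side `ceiling(sqrt(bin_area_cm2 / pixel_area_cm2))` pixels, tiling from the
#' top-left origin; a point on a bin edge belongs to the bin with the smaller
#' index (left-closed, top-closed). The emulated design uses bins of
#' ~1.125 cm^2.
#'
#' @param points `data.frame` with columns `taxon`, `x`, `y` (pixels); a
#'   `frame` column, if present, is ignored (observations accumulate over
#'   frames).
#' @param frame_width,frame_height frame size in pixels.
#' @param pixel_area_cm2 area of one pixel in cm^2, > 0.
#' @param bin_area_cm2 nominal bin area in cm^2 (default 1.125).
#' @return Object of class `heatmap_grid`: list with `counts` (named list of
#'   `n_bins_y x n_bins_x` matrices, one per taxon), `bin_side_px`,
#'   `bin_area_cm2` (realised area of one bin) and the frame dimensions.
#' @export
bin_points <- function(points, frame_width, frame_height, pixel_area_cm2,
                       bin_area_cm2 = 1.125) {
  stopifnot(all(c("taxon", "x", "y") %in% names(points)))
  if (!is.numeric(pixel_area_cm2) || pixel_area_cm2 <= 0)
    stop("'pixel_area_cm2' must be > 0", call. = FALSE)
  if (bin_area_cm2 <= 0) stop("'bin_area_cm2' must be > 0", call. = FALSE)
  side <- ceiling(sqrt(bin_area_cm2 / pixel_area_cm2))
  nx <- ceiling(frame_width / side)
  ny <- ceiling(frame_height / side)
  taxa <- sort(unique(as.character(points$taxon)))
  counts <- lapply(taxa, function(tx) {
    p <- points[points$taxon == tx, , drop = FALSE]
    if (any(p$x < 0 | p$x >= frame_width | p$y < 0 | p$y >= frame_height))
      stop("points outside the frame", call. = FALSE)
    ix <- floor(p$x / side) + 1L
    iy <- floor(p$y / side) + 1L
    m <- matrix(0L, nrow = ny, ncol = nx)
    if (nrow(p)) {
      tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
      m <- matrix(as.integer(tab), nrow = ny, ncol = nx)
    }
    m
  })
  names(counts) <- taxa
  structure(list(counts = counts, bin_side_px = side,
                 bin_area_cm2 = side^2 * pixel_area_cm2,
                 frame_width = frame_width, frame_height = frame_height),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  d <- dim(x$counts[[1L]])
  cat(sprintf("<heatmap_grid> %d x %d bins of %d px (%.4g cm2 each)\n",
              d[1L], d[2L], x$bin_side_px, x$bin_area_cm2))
  for (nm in names(x$counts))
    cat(sprintf("  %s: %d observations\n", nm, sum(x$counts[[nm]])))
  invisible(x)
}

#' Plot a heat-map grid
#'
#' One panel per taxon; linear colour scale from dark blue (least frequented
#' bins) to dark red (most frequented).
#'
#' @param x a [bin_points()] result.
#' @param taxa taxa to plot (default all).
#' @param ... passed to [graphics::image()].
#' @export
plot.heatmap_grid <- function(x, taxa = names(x$counts), ...) {
  pal <- grDevices::colorRampPalette(
    c("darkblue", "blue", "cyan", "yellow", "orange", "red", "darkred"))(64)
  op <- graphics::par(mfrow = c(1, length(taxa)))
  on.exit(graphics::par(op))
  for (tx in taxa) {
    m <- x$counts[[tx]]
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE], col = pal,
                    axes = FALSE, main = tx, ...)
  }
  invisible(x)
}

#' Nearest-neighbour contingency table for one frame
#'
#' For every individual in a frame, finds its Euclidean nearest neighbour
#' (ties broken by lowest record index, deterministic on pixel-quantised
#' coordinates) and tabulates `N[A, B]` = number of individuals of taxon A
#' whose nearest neighbour belongs to taxon B. Row sums equal the taxon
#' abundances: every individual has exactly one nearest neighbour.
#'
#' @param points `data.frame` with columns `taxon`, `x`, `y`; >= 2 rows.
#' @param taxa taxon levels for the table (default: those present, sorted).
#' @return Integer matrix `N` with one row/column per taxon.
#' @examples
#' pts <- data.frame(taxon = c("A", "A", "B"), x = c(0, 1, 3), y = 0)
#' nn_contingency(pts)  # N_AA = 2, N_BA = 1
#' @export
nn_contingency <- function(points, taxa = NULL) {
  stopifnot(all(c("taxon", "x", "y") %in% names(points)))
  n <- nrow(points)
  if (n < 2L) stop("need >= 2 points", call. = FALSE)
  taxa <- taxa %||% sort(unique(as.character(points$taxon)))
  D <- as.matrix(stats::dist(cbind(points$x, points$y)))
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  tab <- table(factor(points$taxon, levels = taxa),
               factor(points$taxon[nn], levels = taxa))
  m <- matrix(as.integer(tab), nrow = length(taxa),
              dimnames = list(from = taxa, to = taxa))
  m
}

#' Expected nearest-neighbour counts under random labelling
#'
#' Expectations of the nearest-neighbour contingency counts when taxon labels
#' are assigned at random over the fixed point locations:
#' `E_AA = n_A (n_A - 1) / (N - 1)` and `E_AB = n_A n_B / (N - 1)` for
#' `A != B`, where `n_A` are the taxon abundances and `N` their total.
#'
#' @param abundances named vector of per-taxon abundances; total >= 2.
#' @return Matrix of expected counts, same layout as [nn_contingency()].
#' @examples
#' expected_counts(c(A = 3, B = 3))  # E_AA = 1.2, E_AB = 1.8
#' @export
expected_counts <- function(abundances) {
  n <- as.numeric(abundances)
  N <- sum(n)
  if (N < 2) stop("total abundance must be >= 2", call. = FALSE)
  E <- outer(n, n) / (N - 1)
  diag(E) <- n * (n - 1) / (N - 1)
  dimnames(E) <- list(from = names(abundances), to = names(abundances))
  E
}

#' Dixon segregation index from observed and expected neighbour odds
#'
#' Log odds-ratio of observed versus random-labelling nearest-neighbour
#' frequencies:
#' `S_AA = ln[(N_AA / (n_A - N_AA)) / ((n_A - 1) / (N - n_A))]` and, for
#' `A != B`, `S_AB = ln[(N_AB / (n_A - N_AB)) / (n_B / (N - 1 - n_B))]`.
#' `S_AA > 0` means taxon A is segregated (its neighbours are conspecific more
#' often than random labelling predicts); `S_AB < 0` means B is
#' under-represented among A's neighbours. Odds involving a zero count are
#' infinite and flagged.
#'
#' @param observed matrix from [nn_contingency()].
#' @param abundances per-taxon abundances (default: row sums of `observed`,
#'   which equal them by construction).
#' @return List with `S` (matrix), and `finite` (logical matrix, `FALSE`
#'   where an odds was degenerate).
#' @export
segregation_index <- function(observed, abundances = rowSums(observed)) {
  n <- as.numeric(abundances)
  if (!isTRUE(all.equal(as.numeric(rowSums(observed)), n)))
    stop("row sums of 'observed' must equal 'abundances'", call. = FALSE)
  N <- sum(n)
  k <- nrow(observed)
  odds_obs <- observed / (n - observed)                    # row-wise n_A
  odds_exp <- matrix(rep(n, each = k), nrow = k) / (N - 1 - matrix(rep(n, each = k), nrow = k))
  diag(odds_exp) <- (n - 1) / (N - n)
  S <- log(odds_obs / odds_exp)
  dimnames(S) <- dimnames(observed)
  list(S = S, finite = is.finite(S))
}

#' Pooled nearest-neighbour segregation analysis over frames
#'
#' Runs the nearest-neighbour contingency analysis independently in every
#' frame (each hourly image is a separate point pattern), sums observed and
#' expected counts over frames, and computes the segregation index S from the
#' pooled observed and pooled expected neighbour odds. For a single frame this
#' reduces exactly to [segregation_index()]. Frames with fewer than 2 points
#' are skipped with a warning.
#'
#' @param points `data.frame` with columns `frame`, `taxon`, `x`, `y`.
#' @param taxa taxon levels (default: all present, sorted).
#' @return Object of class `nn_segregation`: list with matrices `observed`,
#'   `expected`, `S`, `finite`, vector `abundances` (pooled), `n_frames`
#'   (used / total) and `N` (pooled point total).
#' @export
nn_segregation <- function(points, taxa = NULL) {
  stopifnot(all(c("frame", "taxon", "x", "y") %in% names(points)))
  taxa <- taxa %||% sort(unique(as.character(points$taxon)))
  k <- length(taxa)
  obs <- exp_ <- matrix(0, nrow = k, ncol = k, dimnames = list(from = taxa, to = taxa))
  ab <- stats::setNames(numeric(k), taxa)
  frames <- unique(points$frame)
  used <- 0L
  for (f in frames) {
    p <- points[points$frame == f, , drop = FALSE]
    if (nrow(p) < 2L) next
    used <- used + 1L
    nf <- table(factor(p$taxon, levels = taxa))
    obs <- obs + nn_contingency(p, taxa = taxa)
    exp_ <- exp_ + expected_counts(nf)
    ab <- ab + as.numeric(nf)
  }
  if (used == 0L) stop("no frame with >= 2 points", call. = FALSE)
  if (used < length(frames))
    warning(length(frames) - used, " frame(s) with < 2 points skipped", call. = FALSE)
  odds_obs <- obs / (ab - obs)          # pooled observed odds, row-wise n_A
  odds_exp <- exp_ / (ab - exp_)        # pooled expected odds
  S <- log(odds_obs / odds_exp)
  structure(list(observed = obs, expected = exp_, S = S,
                 finite = is.finite(S), abundances = ab,
                 n_frames = c(used = used, total = length(frames)),
                 N = sum(ab)),
            class = "nn_segregation")
}

#' @export
print.nn_segregation <- function(x, digits = 2, ...) {
  cat(sprintf("Nearest-neighbour segregation: %d taxa, %d points, %d/%d frames used\n",
              length(x$abundances), x$N, x$n_frames["used"], x$n_frames["total"]))
  print(as.data.frame(x, digits = digits))
  invisible(x)
}

#' @export
as.data.frame.nn_segregation <- function(x, digits = NULL, ...) {
  taxa <- names(x$abundances)
  grid <- expand.grid(to = taxa, from = taxa, stringsAsFactors = FALSE)
  ij <- cbind(match(grid$from, taxa), match(grid$to, taxa))
  out <- data.frame(from = grid$from, to = grid$to,
                    obs_count = x$observed[ij],
                    exp_count = x$expected[ij],
                    S = x$S[ij])
  if (!is.null(digits)) {
    out$exp_count <- round(out$exp_count, digits)
    out$S <- round(out$S, digits)
  }
  rownames(out) <- NULL
  out
}
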