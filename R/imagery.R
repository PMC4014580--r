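#' Percent cover from a binary mask
#'
#' Fraction of an image marked as covered (e.g. microbial mat marked white on
#' black during annotation), in percent. Input is a matrix of 0/1 or logical
#' values; a greyscale matrix is thresholded at the midpoint of its nominal
#' scale (0.5 on a 0..1 image, 127.5 on 0..255) with a message.
#'
#' @param mask numeric or logical matrix with at least one pixel.
#' @return Percent cover in `[0, 100]`.
#' @examples
#' coverage_percent(matrix(c(1, 0, 0, 0), 2))  # 25
#' @export
coverage_percent <- function(mask) {
  if (is.null(dim(mask))) stop("'mask' must be a matrix", call. = FALSE)
  if (length(mask) == 0L) stop("empty image", call. = FALSE)
  v <- as.numeric(mask)
  if (anyNA(v)) stop("mask contains NA pixels", call. = FALSE)
  uu <- unique(v)
  if (!all(uu %in% c(0, 1))) {
    mid <- if (max(v) <= 1) 0.5 else 127.5
    message("non-binary mask thresholded at ", mid)
    v <- as.numeric(v > mid)
  }
  100 * mean(v)
}

# Vectorised RGB (0..1) -> HSL (each 0..1)
rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, ifelse(l <= 0.5, d / (mx + mn), d / (2 - mx - mn)))
  h <- numeric(length(r))
  nz <- d > 0
  hm <- ifelse(mx == r, ((g - b) / d) %% 6,
        ifelse(mx == g, (b - r) / d + 2, (r - g) / d + 4))
  h[nz] <- hm[nz] / 6
  list(h = h, s = s, l = l)
}

#' Frame luminosity index on a 0-255 scale
#'
#' Scalar per-frame index used to track the progressive darkening of
#' long-duration video recordings (lens fouling, lighting decay). Per pixel
#' the RGB values are converted to hue, saturation and lightness, each scaled
#' 0-255. The default mode `"lightness"` averages the lightness channel only,
#' so an all-black frame scores exactly 0 and an all-white frame 255; mode
#' `"mean-hsl"` averages all three channels (an all-black frame then scores
#' <= 85 because hue and saturation are 0 but enter the mean). Both modes are
#' strictly increasing in uniform lightness changes.
#'
#' @param frame numeric array `height x width x 3` with values in 0..1 or
#'   0..255.
#' @param mode `"lightness"` (default) or `"mean-hsl"`.
#' @return Index in `[0, 255]`.
#' @examples
#' hsl_index(array(1, c(2, 2, 3)))  # 255 (pure white)
#' @export
hsl_index <- function(frame, mode = c("lightness", "mean-hsl")) {
  mode <- match.arg(mode)
  if (length(dim(frame)) != 3L || dim(frame)[3L] != 3L)
    stop("'frame' must be a height x width x 3 array", call. = FALSE)
  v <- frame
  if (max(v) > 1) v <- v / 255
  if (min(v) < 0 || max(v) > 1) stop("pixel values out of range", call. = FALSE)
  hsl <- rgb_to_hsl(as.numeric(v[, , 1L]), as.numeric(v[, , 2L]),
                    as.numeric(v[, , 3L]))
  if (mode == "lightness") 255 * mean(hsl$l)
  else 255 * mean((hsl$h + hsl$s + hsl$l) / 3)
}

#' Per-frame quality metrics for a recording
#'
#' Convenience wrapper computing [coverage_percent()] and/or [hsl_index()]
#' for lists of frames.
#'
#' @param masks optional named list of binary mask matrices.
#' @param frames optional named list of RGB arrays.
#' @param mode passed to [hsl_index()].
#' @return `data.frame` with columns `frame_id`, `coverage_percent`,
#'   `hsl_index` (NA where the input was not supplied).
#' @export
frame_metrics <- function(masks = NULL, frames = NULL,
                          mode = c("lightness", "mean-hsl")) {
  mode <- match.arg(mode)
  ids <- union(names(masks %||% list()), names(frames %||% list()))
  if (!length(ids)) stop("supply 'masks' and/or 'frames'", call. = FALSE)
  data.frame(
    frame_id = ids,
    coverage_percent = vapply(ids, function(i)
      if (!is.null(masks[[i]])) coverage_percent(masks[[i]]) else NA_real_,
      numeric(1)),
    hsl_index = vapply(ids, function(i)
      if (!is.null(frames[[i]])) hsl_index(frames[[i]], mode) else NA_real_,
      numeric(1)),
    row.names = NULL)
}
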