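#' Pearson's colocalization coefficient between two channels
#'
#' Product-moment correlation of per-pixel intensities over a region of
#' interest. To avoid background-dominated inflation, pixels where both
#' channels are at or below `floor` are excluded (the floor used is recorded
#' in the attributes).
#'
#' @param a,b Numeric matrices of identical dimension.
#' @param roi Optional logical matrix restricting the computation.
#' @param floor Background floor; pixels with `a <= floor & b <= floor` are
#'   dropped. Default 0 keeps every pixel with signal in either channel.
#' @return PCC in \[-1, 1\] with attributes `n_pixels` and `floor`.
#' @export
pearson_cc <- function(a, b, roi = NULL, floor = 0) {
  if (!all(dim(a) == dim(b))) stop("channel dimensions differ", call. = FALSE)
  use <- if (is.null(roi)) rep(TRUE, length(a)) else as.vector(roi)
  use <- use & (as.vector(a) > floor | as.vector(b) > floor)
  av <- as.vector(a)[use]; bv <- as.vector(b)[use]
  if (length(av) < 2) stop("fewer than 2 pixels in ROI", call. = FALSE)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero variance in a channel over the ROI", call. = FALSE)
  structure(stats::cor(av, bv), n_pixels = length(av), floor = floor)
}

#' Manders' colocalization coefficients M1 and M2
#'
#' `M1` is the fraction of channel-A intensity falling on pixels where
#' channel B exceeds its threshold; `M2` swaps the roles. Thresholds default
#' to Otsu's method per channel and are recorded in the result.
#'
#' @param a,b Numeric matrices of identical dimension.
#' @param t_a,t_b Channel thresholds; `NULL` for Otsu.
#' @return A list: `m1`, `m2` (each in \[0, 1\]), `t_a`, `t_b`, `n_pixels`.
#' @export
manders_mcc <- function(a, b, t_a = NULL, t_b = NULL) {
  if (!all(dim(a) == dim(b))) stop("channel dimensions differ", call. = FALSE)
  if (is.null(t_a)) t_a <- otsu_threshold(a)
  if (is.null(t_b)) t_b <- otsu_threshold(b)
  if (t_a < 0 || t_b < 0) stop("thresholds must be >= 0", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 || sb == 0)
    stop("a channel has zero total intensity", call. = FALSE)
  list(m1 = sum(a[b > t_b]) / sa, m2 = sum(b[a > t_a]) / sb,
       t_a = t_a, t_b = t_b, n_pixels = length(a))
}

#' Intensity line profile across a multi-channel image
#'
#' Samples every channel along the segment from `p0` to `p1` at `n_samples`
#' equally spaced points by bilinear interpolation.
#'
#' @param image A `projected_image`, a matrix (single channel), or a 3-D
#'   array (y, x, channel).
#' @param p0,p1 Endpoints as `c(y, x)` in pixel coordinates (inside the
#'   frame).
#' @param n_samples Number of sample points.
#' @return A data.frame with `distance_px` and one intensity column per
#'   channel.
#' @export
line_profile <- function(image, p0, p1, n_samples = 100) {
  arr <- if (inherits(image, "projected_image")) image$data else image
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  d <- dim(arr)
  if (any(c(p0, p1) < 1) || p0[1] > d[1] || p1[1] > d[1] ||
      p0[2] > d[2] || p1[2] > d[2])
    stop("endpoints outside the frame", call. = FALSE)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("degenerate (zero-length) segment", call. = FALSE)
  tt <- seq(0, 1, length.out = n_samples)
  yy <- p0[1] + tt * (p1[1] - p0[1])
  xx <- p0[2] + tt * (p1[2] - p0[2])
  chans <- if (inherits(image, "projected_image") && !is.null(image$channels))
    image$channels else paste0("ch", seq_len(d[3]))
  out <- data.frame(distance_px = tt * len)
  for (ci in seq_len(d[3]))
    out[[chans[ci]]] <- pracma::interp2(x = seq_len(d[2]), y = seq_len(d[1]),
                                        Z = arr[, , ci], xp = xx, yp = yy)
  out
}
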