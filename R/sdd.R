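#' Rescale raw intensities to the working range 1..255
#'
#' CT slices (or any grayscale raster) are affinely mapped so that the minimum
#' observed value becomes 1 and the maximum 255, then rounded:
#' `round(1 + 254 * (v - min) / (max - min))`.  All histogram machinery
#' operates on this fixed 255-level range.  A constant image has no usable
#' contrast; it is mapped to 255 everywhere and flagged with the attribute
#' `degenerate = TRUE` so the pipeline can return an empty result for it.
#'
#' @param image Numeric matrix of raw intensities (any range, e.g. 12-bit CT).
#' @return Integer matrix with values in `{1, ..., 255}`; possibly carrying
#'   attribute `degenerate`.
#' @export
#' @examples
#' rescale_intensities(matrix(c(0, 1000), 1))
rescale_intensities <- function(image) {
  if (length(image) == 0) stop("empty image")
  image <- as.matrix(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    out <- matrix(255L, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- round(1 + 254 * (image - lo) / (hi - lo))
  storage.mode(out) <- "integer"
  out
}

#' Max-normalized intensity histogram
#'
#' Counts pixels per intensity level 1..255 and divides by the count of the
#' most populated bin, so the histogram's maximum is exactly 1.  (This is a
#' max-normalization, not a probability normalization; the smoothed version
#' is therefore not a density.)
#'
#' @param image Integer matrix with intensities in `{1, ..., 255}`
#'   (see [rescale_intensities()]).
#' @return Numeric vector of length 255 with `max(values) == 1`.
#' @export
compute_histogram <- function(image) {
  v <- as.integer(image)
  if (any(v < 1L) || any(v > 255L)) stop("intensities must lie in 1..255")
  counts <- tabulate(v, nbins = 255L)
  counts / max(counts)
}

#' Band-limit a histogram with a low-pass DFT filter
#'
#' The length-255 discrete Fourier transform of the histogram is computed,
#' only the DC bin, the `W` lowest positive frequencies and their conjugate
#' mirrors are kept, and the spectrum is inverted.  The DC bin is retained so
#' the mean of the sequence is preserved; the output is real.  Applying the
#' same band-limit twice equals applying it once.
#'
#' @param h Numeric vector of length 255 (a histogram).
#' @param W Integer bandwidth, `1 <= W <= 127`.
#' @return Numeric vector of length 255 (smoothed histogram, may dip slightly
#'   below zero because of ringing).
#' @export
smooth_histogram <- function(h, W = 12L) {
  stopifnot(length(h) == 255L)
  W <- as.integer(W)
  if (is.na(W) || W < 1L || W > 127L) stop("W must lie in 1..127")
  f <- stats::fft(h)
  keep <- c(1L, seq_len(W) + 1L, 255L - seq_len(W) + 1L)
  f[setdiff(seq_len(255L), keep)] <- 0
  Re(stats::fft(f, inverse = TRUE)) / 255
}

#' Ordinary least-squares line fit
#'
#' Fits `y = a x + b` by the normal equations of the least-squares criterion.
#' This is the line model used for the one-sided window fits of the slope
#' difference distribution and for the rib-curve fit.
#'
#' @param x,y Numeric vectors of equal length (at least 2 points, at least
#'   2 distinct `x`).
#' @return Named numeric vector `c(slope = a, intercept = b)`.
#' @export
fit_line <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) stop("need >= 2 (x, y) pairs")
  if (length(unique(x)) < 2L) stop("need >= 2 distinct x values")
  xbar <- mean(x); ybar <- mean(y)
  a <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  c(slope = a, intercept = ybar - a * xbar)
}

#' Slope difference distribution of a smoothed histogram
#'
#' At every interior intensity `i` in `{1+N, ..., 255-N}` two lines are fit by
#' ordinary least squares: one through the `N` points `i-N+1, ..., i` (left
#' window) and one through the `N` points `i, ..., i+N-1` (right window).
#' The slope difference `s(i)` is the left slope minus the right slope, so
#' that at a class boundary (histogram valley: falling left arm, rising right
#' arm) `s` dips to a negative valley, while histogram modes appear as
#' positive peaks.  The valleys of `s` are the class-separating thresholds.
#'
#' @param h Numeric vector of length 255 (smoothed histogram).
#' @param N Integer one-sided window length, `2 <= N <= 100`.
#' @return Object of class `slope_difference`: list with `values`, the
#'   matching intensity `index` (`1+N .. 255-N`), and `window_N`.
#' @export
slope_difference <- function(h, N = 20L) {
  stopifnot(length(h) == 255L)
  N <- as.integer(N)
  if (is.na(N) || N < 2L || N > 100L) stop("N must lie in 2..100")
  idx <- (1L + N):(255L - N)
  x <- seq_len(N)                      # window abscissae (shift-invariant slope)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vals <- vapply(idx, function(i) {
    yl <- h[(i - N + 1L):i]
    yr <- h[i:(i + N - 1L)]
    (sum(xc * yl) - sum(xc * yr)) / denom
  }, numeric(1))
  structure(list(values = vals, index = idx, window_N = N),
            class = "slope_difference")
}

#' @exportS3Method base::print
print.slope_difference <- function(x, ...) {
  cat("Slope difference distribution (window N =", x$window_N, ")\n")
  cat("  defined on intensities", min(x$index), "..", max(x$index), "\n")
  cat("  range:", format(range(x$values), digits = 4), "\n")
  invisible(x)
}

#' Detect class-separating thresholds as valleys of the slope difference
#'
#' A discrete index `i` is a valley when `s(i) < 0`, `s(i) <= s(i-1)` and
#' `s(i) <= s(i+1)`; for a plateau of equal values the central index (floor of
#' the midpoint) is taken.  Indices at the ends of the valid range are never
#' valleys.  Valleys closer than `merge_distance` intensity levels are merged,
#' keeping the deeper one, to suppress double detections caused by the slight
#' ringing of band-limited histograms.
#'
#' @param s A `slope_difference` object.
#' @param merge_distance Minimum separation (intensity levels) between
#'   reported thresholds; closer valleys are merged keeping the deeper one.
#' @return Integer vector of threshold intensities, ascending (possibly empty
#'   when no valley exists), with attribute `depth` giving `s` at each one.
#' @export
find_thresholds <- function(s, merge_distance = 8L) {
  stopifnot(inherits(s, "slope_difference"))
  v <- s$values
  if (length(v) < 3L) return(integer(0))
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pos <- integer(0); depth <- numeric(0)
  for (k in seq_along(runs$values)[-c(1L, length(runs$values))]) {
    val <- runs$values[k]
    # the depth guard keeps floating-point noise on flat stretches from
    # registering as valleys
    if (val < -1e-12 && val < runs$values[k - 1L] && val < runs$values[k + 1L]) {
      centre <- (starts[k] + ends[k]) %/% 2L
      pos <- c(pos, s$index[centre])
      depth <- c(depth, val)
    }
  }
  if (length(pos) > 1L && merge_distance > 0L) {
    ord <- order(depth, pos)               # deepest first, ties by position
    kept <- integer(0)
    for (j in ord) {
      if (all(abs(pos[j] - pos[kept]) >= merge_distance)) kept <- c(kept, j)
    }
    keep_idx <- sort(kept)
    pos <- pos[keep_idx]; depth <- depth[keep_idx]
  }
  ord <- order(pos)
  structure(pos[ord], depth = depth[ord])
}

#' Assign anatomical roles T1..T4 to detected thresholds
#'
#' With the detected valleys sorted ascending, the lowest valley splits
#' background from body (`T2`) and the highest splits soft tissue from bone
#' (`T1`).  Among the classes bounded below by an interior valley, the most
#' populated one (histogram mass between its bounding valleys) is taken to be
#' the liver, so `T4` is its lower bounding valley and `T3` (adjacent organ)
#' is the next valley above.  Fallbacks: with 3 valleys `T3 = T1`; with 2
#' valleys `T3 = T4 = T2` (a single soft-tissue class).
#'
#' @param thresholds Integer vector of valley positions (ascending), as
#'   returned by [find_thresholds()].
#' @param smoothed Numeric length-255 smoothed histogram used for class mass.
#' @param case Optional adjacency-case label carried through to the result.
#' @return List with elements `T1`, `T2`, `T3`, `T4`, `valleys`, `case`.
#' @export
assign_threshold_roles <- function(thresholds, smoothed, case = NULL) {
  v <- sort(as.integer(thresholds))
  M <- length(v)
  if (M < 2L) stop("insufficient pixel classes")
  stopifnot(length(smoothed) == 255L)
  T2 <- v[1L]; T1 <- v[M]
  if (M == 2L) {
    T3 <- T2; T4 <- T2
  } else {
    mass <- function(a, b) if (b - a < 2L) 0 else sum(smoothed[(a + 1L):(b - 1L)])
    cand <- 2L:(M - 1L)                       # classes [v_j, v_{j+1}], j interior
    masses <- vapply(cand, function(j) mass(v[j], v[j + 1L]), numeric(1))
    jstar <- cand[which.max(masses)]
    T4 <- v[jstar]
    T3 <- if (jstar + 1L <= M - 1L) v[jstar + 1L] else T1
  }
  list(T1 = T1, T2 = T2, T3 = T3, T4 = T4, valleys = v, case = case)
}

#' Threshold an image
#'
#' @param image Integer matrix with intensities in `{1, ..., 255}`.
#' @param threshold Intensity `T` in `1..255`.
#' @return Integer 0/1 mask, 1 where `image >= T`.
#' @export
binarize <- function(image, threshold) {
  threshold <- as.numeric(threshold)
  if (is.na(threshold) || threshold < 1 || threshold > 255) {
    stop("threshold must lie in 1..255")
  }
  out <- (image >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}
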