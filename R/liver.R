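#' Segment the liver under the anatomical constraints
#'
#' A pixel is liver when its intensity reaches `T4` and none of the three
#' constraint masks (rib-curve exclusion, body ring, merged adjacent organ)
#' claims it.  The result is always a subset of the plain threshold mask.
#'
#' @param image Integer matrix with intensities in 1..255.
#' @param t4 Liver threshold.
#' @param constraints A `constraint_masks` object from [build_constraints()],
#'   or any list with 0/1 masks `curve_excluded`, `ring`, `stomach`.
#' @return Integer 0/1 liver mask (uncleaned).
#' @export
segment_liver <- function(image, t4, constraints) {
  m <- binarize(image, t4)
  stopifnot(all(dim(constraints$curve_excluded) == dim(m)),
            all(dim(constraints$ring) == dim(m)),
            all(dim(constraints$stomach) == dim(m)))
  out <- m * (1L - constraints$curve_excluded) * (1L - constraints$ring) *
    (1L - constraints$stomach)
  storage.mode(out) <- "integer"
  out
}

#' Clean a raw liver mask
#'
#' Clique-energy denoising, morphological filtering, then retention of the
#' largest blob.  Raises "no liver found in slice" if nothing survives.
#'
#' @param mask Integer 0/1 mask.
#' @param config Configuration list.
#' @return Integer 0/1 mask with a single connected component.
#' @export
clean_liver <- function(mask, config = default_config()) {
  m <- minimize_energy(mask, config[["mrf.beta"]], config[["mrf.max_sweeps"]])
  m <- morphological_filter(m, config[["morph.n_f"]])
  if (!any(m == 1L)) stop("no liver found in slice")
  keep_largest_component(m)
}

#' Extract the ordered outer boundary of a mask
#'
#' Moore-neighbour tracing on the 8-connected outer boundary, starting from
#' the top-left-most foreground pixel.  The traversal is normalized to
#' counter-clockwise in image coordinates (positive shoelace area with
#' `x = col`, `y = row`).  Every vertex is a boundary pixel of the mask and
#' the contour encloses all foreground of the component.
#'
#' @param mask Integer 0/1 mask with exactly one non-empty 8-connected
#'   component.
#' @return Object of class `contour`: numeric matrix with columns
#'   `(row, col)`, attribute `closed = TRUE`.
#' @export
extract_boundary <- function(mask) {
  labels <- label_components(mask)
  n_comp <- max(labels)
  if (n_comp == 0L) stop("empty mask")
  if (n_comp > 1L) stop("mask must contain a single component")
  fg <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(fg) == 1L) {
    return(as_contour(matrix(as.numeric(fg), 1L, 2L)))
  }
  # start: top-left-most foreground pixel (min row, then min col)
  ord <- order(fg[, 1L], fg[, 2L])
  start <- fg[ord[1L], ]
  U <- nrow(mask); V <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= U && c >= 1L && c <= V && mask[r, c] == 1L
  # clockwise-ordered 8-neighbourhood offsets starting at west
  offs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                 ncol = 2L, byrow = TRUE)
  max_pts <- 4L * nrow(fg) + 8L
  path <- matrix(0, max_pts, 2L)
  path[1L, ] <- start
  n_pts <- 1L
  p <- start
  b <- start + c(0L, -1L)                     # backtrack: pixel west of start
  first_from <- NULL; first_to <- NULL
  repeat {
    d <- b - p
    k0 <- which(offs[, 1L] == d[1L] & offs[, 2L] == d[2L])
    q <- NULL
    for (step in seq_len(8L)) {
      k <- (k0 + step - 1L) %% 8L + 1L
      r <- p[1L] + offs[k, 1L]; c <- p[2L] + offs[k, 2L]
      if (inside(r, c)) {
        q <- c(r, c)
        prev_k <- (k0 + step - 2L) %% 8L + 1L
        b_new <- p + offs[prev_k, ]
        break
      }
    }
    if (is.null(q)) break                     # no neighbour (defensive)
    if (!is.null(first_from) &&
        all(p == first_from) && all(q == first_to)) break  # loop closed
    if (is.null(first_from)) { first_from <- p; first_to <- q }
    n_pts <- n_pts + 1L
    path[n_pts, ] <- q
    p <- q
    b <- b_new
    if (n_pts >= max_pts) break               # defensive bound
  }
  pts <- path[seq_len(n_pts), , drop = FALSE]
  if (n_pts > 1L && all(pts[n_pts, ] == pts[1L, ])) {
    pts <- pts[-n_pts, , drop = FALSE]        # trailing return to the start
  }
  as_contour(orient_ccw(pts))
}

as_contour <- function(m) {
  m <- as.matrix(m)
  colnames(m) <- c("row", "col")
  structure(m, closed = TRUE, class = c("contour", class(m)))
}

#' @exportS3Method base::print
print.contour <- function(x, ...) {
  cat("Closed contour with", nrow(x), "vertices\n")
  invisible(x)
}

signed_area <- function(pts) {
  x <- pts[, 2L]; y <- pts[, 1L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

orient_ccw <- function(pts) {
  if (nrow(pts) >= 3L && signed_area(pts) < 0) {
    pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  }
  pts
}

#' Penalized-spline smoothing of a contour
#'
#' Minimizes `(1 - alpha) * sum((B_s - B)^2) + alpha * integral(B_s'')^2`
#' per coordinate, discretizing the curvature integral with second
#' differences on the vertex parameterization (periodic for closed contours).
#' `alpha = 0` returns the input exactly; `alpha` is kept below 1 because the
#' curvature-only objective degenerates (it shrinks closed curves).  A closed
#' circle is a near-fixed point: its coordinates are single-frequency
#' harmonics that the periodic penalty barely attenuates.
#'
#' @param contour A `contour` (closed, >= 4 vertices) or plain `(row, col)`
#'   matrix with `closed = FALSE` for open polylines.
#' @param alpha Smoothing factor in `[0, 1)`; default 0.5.
#' @param closed Treat the vertex sequence as periodic (default taken from
#'   the contour's `closed` attribute, else `TRUE`).
#' @return Smoothed contour of the same vertex count.
#' @export
smooth_contour <- function(contour, alpha = 0.5, closed = NULL) {
  if (is.null(closed)) closed <- isTRUE(attr(contour, "closed")) || is.null(attr(contour, "closed"))
  if (is.na(alpha) || alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  pts <- unclass(contour)
  attr(pts, "closed") <- NULL
  if (alpha == 0) return(as_contour(pts))
  n <- nrow(pts)
  if (closed && n < 4L) stop("closed contour needs >= 4 vertices")
  out <- apply(pts, 2L, function(y) {
    if (closed) whittaker_periodic(y, alpha) else whittaker_open(y, alpha)
  })
  res <- as_contour(out)
  attr(res, "closed") <- closed
  res
}

# periodic Whittaker smoother: circulant second-difference penalty solved in
# the Fourier domain (exact)
whittaker_periodic <- function(y, alpha) {
  n <- length(y)
  lam <- 2 * cos(2 * pi * (seq_len(n) - 1L) / n) - 2
  gain <- (1 - alpha) / ((1 - alpha) + alpha * lam^2)
  Re(stats::fft(stats::fft(y) * gain, inverse = TRUE)) / n
}

# open-curve Whittaker smoother: banded normal equations
whittaker_open <- function(y, alpha) {
  n <- length(y)
  if (n < 3L) return(y)
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  A <- (1 - alpha) * Matrix::Diagonal(n) + alpha * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, (1 - alpha) * y))
}

#' Segment one CT slice end to end
#'
#' Full per-slice chain: intensity rescaling, histogram, DFT smoothing, slope
#' difference distribution, valley detection, threshold-role assignment,
#' constraint construction, constrained liver thresholding, cleaning, and
#' boundary extraction plus spline smoothing.  Deterministic.  Any failure
#' (degenerate slice, too few valleys, no bones, empty liver) yields a
#' flagged empty result instead of an error, so stack processing can skip or
#' interpolate the slice.
#'
#' @param image Numeric matrix (raw intensities; rescaled internally).
#' @param config Configuration list (see [default_config()]).
#' @return Object of class `slice_result`: list with `liver` (0/1 mask or
#'   `NULL`), `boundary`, `boundary_smoothed` (contours or `NULL`),
#'   `thresholds`, `valleys`, `constraints`, `empty` flag and `flags`
#'   (character log of what failed, if anything).
#' @export
process_slice <- function(image, config = default_config()) {
  config <- merge_config(config)
  flags <- character(0)
  empty_result <- function(flags) {
    structure(list(liver = NULL, boundary = NULL, boundary_smoothed = NULL,
                   thresholds = NULL, valleys = integer(0), constraints = NULL,
                   empty = TRUE, flags = flags, dim = dim(image)),
              class = "slice_result")
  }
  img <- rescale_intensities(image)
  if (isTRUE(attr(img, "degenerate"))) {
    return(empty_result("degenerate slice (constant intensity)"))
  }
  if (isTRUE(config[["anatomy.orientation_flip"]])) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  }
  h <- compute_histogram(img)
  hs <- smooth_histogram(h, config[["sdd.bandwidth_W"]])
  s <- slope_difference(hs, config[["sdd.window_N"]])
  valleys <- find_thresholds(s, config[["sdd.valley_merge_distance"]])
  if (length(valleys) < 2L) {
    return(empty_result(sprintf("only %d valley(s) detected", length(valleys))))
  }
  roles <- assign_threshold_roles(valleys, hs, case = config[["case"]])
  res <- tryCatch({
    constraints <- build_constraints(img, roles, config)
    liver_raw <- segment_liver(img, roles$T4, constraints)
    liver <- clean_liver(liver_raw, config)
    boundary <- extract_boundary(liver)
    smoothed <- if (nrow(boundary) >= 4L) {
      smooth_contour(boundary, config[["spline.alpha"]])
    } else {
      boundary
    }
    if (isTRUE(config[["anatomy.orientation_flip"]])) {
      V <- ncol(img)
      liver <- liver[, rev(seq_len(V)), drop = FALSE]
      boundary[, 2L] <- V + 1L - boundary[, 2L]
      smoothed[, 2L] <- V + 1L - smoothed[, 2L]
    }
    structure(list(liver = liver, boundary = boundary,
                   boundary_smoothed = smoothed, thresholds = roles,
                   valleys = valleys, constraints = constraints,
                   empty = FALSE, flags = flags, dim = dim(image)),
              class = "slice_result")
  }, error = function(e) empty_result(conditionMessage(e)))
  res
}

#' @exportS3Method base::print
print.slice_result <- function(x, ...) {
  if (x$empty) {
    cat("Empty slice result:", paste(x$flags, collapse = "; "), "\n")
  } else {
    t <- x$thresholds
    cat("Liver slice segmentation\n")
    cat(sprintf("  thresholds: T1=%d (bones) T2=%d (body) T3=%d (organ) T4=%d (liver)\n",
                t$T1, t$T2, t$T3, t$T4))
    cat(sprintf("  liver area: %d px; boundary: %d vertices\n",
                sum(x$liver), nrow(x$boundary)))
  }
  invisible(x)
}

#' @exportS3Method base::plot
plot.slice_result <- function(x, image = NULL, ...) {
  if (x$empty) {
    graphics::plot.new()
    graphics::title("empty slice result")
    return(invisible(x))
  }
  m <- if (!is.null(image)) image else x$liver
  graphics::image(t(m)[, nrow(m):1], col = gray.colors(64), axes = FALSE, ...)
  b <- x$boundary_smoothed
  U <- nrow(m); V <- ncol(m)
  graphics::lines((b[, 2L] - 1) / (V - 1), 1 - (b[, 1L] - 1) / (U - 1),
                  col = "red", lwd = 2)
  invisible(x)
}

#' Segment every slice of a stack
#'
#' @param slices List of numeric matrices (one per slice, equal shapes).
#' @param config Configuration list.
#' @return List of `slice_result`, one per slice.
#' @export
process_stack <- function(slices, config = default_config()) {
  lapply(slices, process_slice, config = config)
}
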