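#' Diamond (4-connected disk) structuring element
#'
#' The radius-1 element is the 5-pixel "plus"; radius `r` is the L1 ball of
#' radius `r` (the Minkowski composition of `r` radius-1 elements), which is a
#' diamond, not a Euclidean disk.  Contains the origin and is symmetric under
#' negation.
#'
#' @param radius Non-negative integer radius.
#' @return 0/1 matrix of size `(2 * radius + 1)` squared.
#' @export
se_diamond <- function(radius = 1L) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  d <- outer(abs(seq.int(-radius, radius)), abs(seq.int(-radius, radius)), "+")
  out <- (d <= radius) * 1L
  storage.mode(out) <- "integer"
  out
}

pad_mask <- function(mask, r) {
  U <- nrow(mask); V <- ncol(mask)
  out <- matrix(0L, U + 2L * r, V + 2L * r)
  out[(r + 1L):(r + U), (r + 1L):(r + V)] <- mask
  out
}

crop_mask <- function(mask, r, U, V) {
  mask[(r + 1L):(r + U), (r + 1L):(r + V), drop = FALSE]
}

#' Binary erosion / dilation with background outside the frame
#'
#' Standard set-definition binary morphology: erosion keeps the translations
#' `z` with `B_z` entirely inside the foreground; dilation keeps those where
#' the reflected element hits it.  Pixels outside the image count as
#' background for both operations (the mask is zero-padded before the kernel
#' pass), so foreground touching the frame erodes away rather than being
#' propped up by the border.
#'
#' @param mask Integer 0/1 matrix.
#' @param se Structuring element (0/1 matrix of odd size, see [se_diamond()]).
#' @return Integer 0/1 matrix of the same size as `mask`.
#' @export
erode_mask <- function(mask, se = se_diamond(1L)) {
  check_binary(mask)
  r <- (nrow(se) - 1L) %/% 2L
  p <- pad_mask(mask, r)
  e <- EBImage::erode(p, se)
  out <- crop_mask(as.matrix(e), r, nrow(mask), ncol(mask))
  storage.mode(out) <- "integer"
  out
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, se = se_diamond(1L)) {
  check_binary(mask)
  r <- (nrow(se) - 1L) %/% 2L
  p <- pad_mask(mask, r)
  d <- EBImage::dilate(p, se)
  out <- crop_mask(as.matrix(d), r, nrow(mask), ncol(mask))
  storage.mode(out) <- "integer"
  out
}

#' Morphological filter: repeated erosion then repeated dilation
#'
#' `n_f` erosions with the radius-1 diamond followed by `n_f` dilations — an
#' opening by the radius-`n_f` diamond.  Every blob whose maximal inscribed
#' diamond radius is below `n_f` is removed, including small blobs attached
#' to larger structures; surviving foreground is never grown beyond the
#' input.
#'
#' @param mask Integer 0/1 matrix.
#' @param n_f Non-negative repetition count (default 8).
#' @return Filtered integer 0/1 mask.
#' @export
morphological_filter <- function(mask, n_f = 8L) {
  n_f <- as.integer(n_f)
  stopifnot(n_f >= 0L)
  out <- mask
  se <- se_diamond(1L)
  for (i in seq_len(n_f)) out <- erode_mask(out, se)
  for (i in seq_len(n_f)) out <- dilate_mask(out, se)
  out
}

#' Morphological merge: repeated dilation then repeated erosion
#'
#' The opposite of [morphological_filter()]: `n_m` dilations followed by
#' `n_m` erosions — a closing by the radius-`n_m` diamond.  Parts of a split
#' organ separated by a sufficiently small gap become one component; original
#' foreground is never removed.
#'
#' @param mask Integer 0/1 matrix.
#' @param n_m Non-negative repetition count (default 16).
#' @return Merged integer 0/1 mask.
#' @export
morphological_merge <- function(mask, n_m = 16L) {
  n_m <- as.integer(n_m)
  stopifnot(n_m >= 0L)
  # pad by n_m so dilation has room to round outward before the erosions,
  # keeping the closing exact near the frame
  U <- nrow(mask); V <- ncol(mask)
  out <- pad_mask(mask, n_m)
  se <- se_diamond(1L)
  for (i in seq_len(n_m)) out <- dilate_mask(out, se)
  for (i in seq_len(n_m)) out <- erode_mask(out, se)
  out <- crop_mask(out, n_m, U, V)
  storage.mode(out) <- "integer"
  out
}

#' Label 8-connected components
#'
#' Deterministic labelling: components are numbered by the row-major scan
#' order of their first pixel.
#'
#' @param mask Integer 0/1 matrix.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask) {
  check_binary(mask)
  label_components_cpp(mask)
}

#' Per-component statistics
#'
#' @param labels Integer label matrix from [label_components()].
#' @return Data frame with `label`, `area`, `centroid_row`, `centroid_col`
#'   (centroids are arithmetic means of pixel coordinates).
#' @export
component_stats <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  rows <- row(labels); cols <- col(labels)
  out <- data.frame(
    label = ids,
    area = vapply(ids, function(i) sum(labels == i), numeric(1)),
    centroid_row = vapply(ids, function(i) mean(rows[labels == i]), numeric(1)),
    centroid_col = vapply(ids, function(i) mean(cols[labels == i]), numeric(1))
  )
  out
}

#' Keep only the largest connected component
#'
#' Area ties are broken in favour of the component whose first pixel comes
#' earliest in row-major order (top-left-most).
#'
#' @param mask Integer 0/1 matrix with at least one foreground pixel.
#' @return Integer 0/1 mask of the largest blob.
#' @export
keep_largest_component <- function(mask) {
  labels <- label_components(mask)
  if (max(labels) == 0L) stop("no component")
  areas <- tabulate(labels[labels > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # labels are assigned in row-major scan order, but R matrices scan
    # column-major; pick the tied label whose first row-major pixel is smallest
    first_rm <- vapply(best, function(b) {
      w <- which(labels == b)
      min((w - 1L) %% nrow(labels) * ncol(labels) + (w - 1L) %/% nrow(labels))
    }, numeric(1))
    best <- best[which.min(first_rm)]
  }
  out <- (labels == best) * 1L
  storage.mode(out) <- "integer"
  out
}
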