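#' Segment spine and ribs
#'
#' Bones are the brightest class; thresholding at `T1` yields the rib blobs
#' along the flank and the spine near the posterior centre.
#'
#' @param image Integer matrix with intensities in 1..255.
#' @param t1 Bone threshold (from [assign_threshold_roles()]).
#' @return Integer 0/1 mask.
#' @export
segment_bones <- function(image, t1) binarize(image, t1)

#' Split bone blobs into flank ribs and the spine
#'
#' Blobs whose centroid column lies left of `split_col` (after any
#' orientation normalization) form the rib class; among the remaining blobs
#' the largest is the spine.  `split_col` is normally the body centroid
#' column, which is robust to where exactly the spine sits.
#'
#' @param bones Integer 0/1 bone mask with at least two blobs.
#' @param split_col Column separating the rib flank from the centre.
#' @return List with data frames `ribs` and `spine` (see [component_stats()])
#'   and masks `rib_mask`, `spine_mask`.
#' @export
classify_bone_blobs <- function(bones, split_col) {
  labels <- label_components(bones)
  if (max(labels) < 2L) stop("insufficient bone blobs")
  st <- component_stats(labels)
  # blobs "around the center" belong with the spine class, so the rib class
  # only takes blobs clearly left of the split
  tol <- 0.02 * ncol(bones)
  is_rib <- st$centroid_col < split_col - tol
  if (!any(is_rib)) stop("no rib blobs left of the split column")
  if (all(is_rib)) stop("no spine candidate right of the split column")
  ribs <- st[is_rib, , drop = FALSE]
  centre <- st[!is_rib, , drop = FALSE]
  spine <- centre[which.max(centre$area), , drop = FALSE]
  rib_mask <- matrix(as.integer(labels %in% ribs$label), nrow(bones), ncol(bones))
  spine_mask <- (labels == spine$label) * 1L
  storage.mode(spine_mask) <- "integer"
  list(ribs = ribs, spine = spine, rib_mask = rib_mask, spine_mask = spine_mask)
}

#' Fit the rib separating curve
#'
#' Least-squares quadratic `col = c2 * row^2 + c1 * row + c0` through the rib
#' centroids and the spine centroid.  The curve runs down the flank and
#' separates the liver from body-wall tissue of the same intensity.
#'
#' @param centroids Numeric matrix with columns `(row, col)`; at least 3
#'   points with at least 3 distinct rows.
#' @return Object of class `rib_curve`: named numeric `c(c2, c1, c0)`.
#' @export
fit_rib_curve <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 3L || length(unique(centroids[, 1L])) < 3L) {
    stop("need >= 3 centroids with >= 3 distinct rows")
  }
  r <- centroids[, 1L]; cc <- centroids[, 2L]
  fit <- stats::lm.fit(cbind(r^2, r, 1), cc)
  coefs <- fit$coefficients
  structure(c(c2 = unname(coefs[1L]), c1 = unname(coefs[2L]),
              c0 = unname(coefs[3L])), class = "rib_curve")
}

#' Evaluate a rib curve at given rows
#' @param curve A `rib_curve`.
#' @param rows Numeric vector of row coordinates.
#' @return Column coordinate of the curve at each row.
#' @export
curve_col <- function(curve, rows) {
  curve[["c2"]] * rows^2 + curve[["c1"]] * rows + curve[["c0"]]
}

#' Exclusion mask on the far side of the rib curve
#'
#' Marks (with 1) every pixel on the opposite side of the fitted curve from
#' `interior_point` — the side holding the body-wall tissue that may share
#' the liver's intensity.  The liver is kept where this mask is 0.  Pixels
#' exactly on the curve count as interior.  The body centroid is the natural
#' interior reference: it always lies deep inside the frame, whereas the
#' spine centroid is itself a fit point of the curve and so sits on it.
#'
#' @param curve A `rib_curve`.
#' @param dim Integer vector `c(rows, cols)` of the frame.
#' @param interior_point Numeric `c(row, col)` on the liver side.
#' @return Integer 0/1 mask.
#' @export
curve_exclusion_mask <- function(curve, dim, interior_point) {
  U <- dim[1L]; V <- dim[2L]
  f <- curve_col(curve, seq_len(U))
  delta <- outer(-f, seq_len(V), "+")          # col - f(row)
  ref <- interior_point[2L] - curve_col(curve, interior_point[1L])
  if (ref == 0) ref <- 1
  out <- (delta * ref < 0) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Segment the body
#'
#' Threshold at `T2` then clean with the morphological filter: the body is by
#' far the largest structure, so the opening removes satellite blobs and
#' leaves a smooth body mask.
#'
#' @param image Integer matrix with intensities in 1..255.
#' @param t2 Body threshold.
#' @param n_f Morphological filter repetitions (default 8).
#' @return Integer 0/1 mask.
#' @export
segment_body <- function(image, t2, n_f = 8L) {
  morphological_filter(binarize(image, t2), n_f)
}

#' Average rib width
#'
#' The width of a blob is twice its maximal inscribed diamond radius, i.e.
#' twice the number of radius-1 erosions needed to make it vanish.  `N_c`,
#' the rounded mean width over the rib blobs, sets the thickness of the body
#' ring constraint.
#'
#' @param rib_mask Integer 0/1 mask of the rib blobs (>= 1 blob).
#' @return Integer `N_c`.
#' @export
estimate_rib_width <- function(rib_mask) {
  labels <- label_components(rib_mask)
  n <- max(labels)
  if (n < 1L) stop("no rib blobs")
  widths <- vapply(seq_len(n), function(i) {
    m <- (labels == i) * 1L
    storage.mode(m) <- "integer"
    d <- 0L
    while (any(m == 1L)) {
      m <- erode_mask(m)
      d <- d + 1L
    }
    2 * d
  }, numeric(1))
  as.integer(round(mean(widths)))
}

#' Body ring constraint
#'
#' The filtered body eroded by the radius-`n_c` diamond (as `n_c` repeats of
#' the radius-1 element) is subtracted from the body, leaving a ring of
#' thickness at most `n_c` along the body margin.  The ring covers body-wall
#' tissue adjacent to the liver without covering the liver itself.
#'
#' @param body Integer 0/1 body mask.
#' @param n_c Ring thickness (average rib width, see [estimate_rib_width()]).
#' @return Integer 0/1 ring mask, a subset of `body`.
#' @export
ring_constraint <- function(body, n_c) {
  n_c <- as.integer(n_c)
  stopifnot(n_c >= 0L)
  eroded <- body
  se <- se_diamond(1L)
  for (i in seq_len(n_c)) eroded <- erode_mask(eroded, se)
  out <- body * (1L - eroded)
  storage.mode(out) <- "integer"
  out
}

#' Segment and merge the adjacent organ (stomach pipeline)
#'
#' Threshold at `T3`, denoise by clique-energy minimization, remove the
#' bones, apply the morphological filter, keep only components whose centroid
#' column lies strictly beyond the spine centroid column, and merge the split
#' parts with the morphological closing.  An empty result is valid: it simply
#' deactivates the organ constraint (the adjacent organ may be absent or
#' indistinguishable from the liver in a given slice).
#'
#' @param image Integer matrix with intensities in 1..255.
#' @param t3 Adjacent-organ threshold.
#' @param bones Integer 0/1 bone mask.
#' @param spine_col Spine centroid column.
#' @param config Configuration list (see [default_config()]).
#' @return Integer 0/1 merged organ mask (possibly empty).
#' @export
segment_stomach <- function(image, t3, bones, spine_col,
                            config = default_config()) {
  m <- binarize(image, t3)
  m <- minimize_energy(m, config[["mrf.beta"]], config[["mrf.max_sweeps"]])
  m <- m * (1L - bones)
  storage.mode(m) <- "integer"
  m <- morphological_filter(m, config[["morph.n_f"]])
  if (!any(m == 1L)) return(m)
  labels <- label_components(m)
  st <- component_stats(labels)
  keep <- st$label[st$centroid_col > spine_col]
  if (length(keep) == 0L) return(matrix(0L, nrow(m), ncol(m)))
  m <- matrix(as.integer(labels %in% keep), nrow(m), ncol(m))
  morphological_merge(m, config[["morph.n_m"]])
}

#' Build the three anatomical constraint masks for a slice
#'
#' Runs the bone / body / organ sub-pipelines and assembles the rib-curve
#' exclusion mask, the body ring and the merged adjacent-organ mask.  The
#' liver is later segmented at `T4` restricted to pixels where all three
#' masks are 0.
#'
#' @param image Integer matrix with intensities in 1..255.
#' @param roles Threshold roles from [assign_threshold_roles()].
#' @param config Configuration list.
#' @return List of class `constraint_masks`: `curve_excluded`, `ring`,
#'   `stomach` (all 0/1 masks), plus `curve`, `bones`, `body`, `n_c` and the
#'   bone classification for inspection.
#' @export
build_constraints <- function(image, roles, config = default_config()) {
  bones <- segment_bones(image, roles$T1)
  body <- segment_body(image, roles$T2, config[["morph.n_f"]])
  if (!any(body == 1L)) stop("empty body mask")
  body_centroid <- c(mean(row(body)[body == 1L]), mean(col(body)[body == 1L]))
  split_col <- config[["anatomy.rib_split"]]
  if (identical(split_col, "auto")) split_col <- body_centroid[2L]
  cls <- classify_bone_blobs(bones, split_col)
  cent <- rbind(as.matrix(cls$ribs[, c("centroid_row", "centroid_col")]),
                as.matrix(cls$spine[, c("centroid_row", "centroid_col")]))
  curve <- fit_rib_curve(cent)
  curve_excluded <- curve_exclusion_mask(curve, dim(image), body_centroid)
  n_c <- estimate_rib_width(cls$rib_mask)
  ring <- ring_constraint(body, n_c)
  stomach <- segment_stomach(image, roles$T3, bones,
                             cls$spine$centroid_col[1L], config)
  structure(list(curve_excluded = curve_excluded, ring = ring,
                 stomach = stomach, curve = curve, bones = bones,
                 body = body, n_c = n_c, bone_classes = cls,
                 body_centroid = body_centroid),
            class = "constraint_masks")
}
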