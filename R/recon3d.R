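#' Resample a closed contour to equally spaced points
#'
#' Vertices are placed at equal arc-length intervals along the closed
#' polygonal contour, so the spacing between adjacent sampled points is
#' nearly constant (the community convention is 200 points per slice
#' boundary).  The total perimeter is preserved to within the polygonal
#' discretization.
#'
#' @param contour A `contour` or `(row, col)` matrix (closed polyline).
#' @param n_points Number of output points (default 200).
#' @return `contour` with `n_points` vertices.
#' @export
resample_contour <- function(contour, n_points = 200L) {
  pts <- unclass(as.matrix(contour))
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 3L)
  closed_pts <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed_pts)^2))
  L <- sum(seg)
  if (!is.finite(L) || L <= 0) stop("degenerate contour: zero perimeter")
  cum <- c(0, cumsum(seg))
  targets <- (seq_len(n_points) - 1L) * L / n_points
  out <- cbind(stats::approx(cum, closed_pts[, 1L], xout = targets)$y,
               stats::approx(cum, closed_pts[, 2L], xout = targets)$y)
  as_contour(out)
}

#' Align start indices and orientation across stacked contours
#'
#' All contours are first oriented consistently (counter-clockwise).  Then,
#' walking down the stack, each contour's vertex numbering is cyclically
#' rotated so that the summed squared distance between its vertices and the
#' same-index vertices of the previous (already aligned) contour is minimal.
#' After alignment, index `n` traces a coherent curve in the stacking
#' direction instead of spiralling.
#'
#' @param contours List of contours with the same vertex count.
#' @return List of aligned contours.
#' @export
align_contours <- function(contours) {
  stopifnot(length(contours) >= 2L)
  n <- nrow(contours[[1L]])
  contours <- lapply(contours, function(cc) {
    stopifnot(nrow(cc) == n)
    as_contour(orient_ccw(unclass(as.matrix(cc))))
  })
  out <- vector("list", length(contours))
  out[[1L]] <- contours[[1L]]
  for (k in 2L:length(contours)) {
    prev <- unclass(out[[k - 1L]])
    cur <- unclass(contours[[k]])
    costs <- vapply(seq_len(n) - 1L, function(r) {
      idx <- (seq_len(n) - 1L + r) %% n + 1L
      sum((cur[idx, ] - prev)^2)
    }, numeric(1))
    r <- which.min(costs) - 1L
    idx <- (seq_len(n) - 1L + r) %% n + 1L
    out[[k]] <- as_contour(cur[idx, , drop = FALSE])
  }
  out
}

#' Build the surface point grid from per-slice boundaries
#'
#' Resamples each available boundary to `n_points` vertices, aligns start
#' indices down the stack, converts to physical coordinates
#' (`x = col * pixel_spacing`, `y = row * pixel_spacing`,
#' `z = (slice - 1) * slice_spacing`) and fills slices without a boundary
#' (failed segmentations) by linear interpolation of each aligned point
#' trajectory between the nearest valid neighbours.  Leading or trailing
#' missing slices are dropped.
#'
#' @param boundaries List of contours or `NULL` per slice.
#' @param n_points Points per boundary (default 200).
#' @param pixel_spacing,slice_spacing Physical spacings in mm (default 1).
#' @return Numeric array `[n_slices, n_points, 3]` (x, y, z) of class
#'   `surface_grid`.
#' @export
surface_grid <- function(boundaries, n_points = 200L,
                         pixel_spacing = 1, slice_spacing = 1) {
  stopifnot(pixel_spacing > 0, slice_spacing > 0)
  present <- !vapply(boundaries, is.null, logical(1))
  first <- which(present)[1L]
  last <- rev(which(present))[1L]
  if (is.na(first) || sum(present) < 2L) stop("need >= 2 valid boundaries")
  keep <- first:last
  boundaries <- boundaries[keep]
  present <- present[keep]
  res <- lapply(boundaries[present], resample_contour, n_points = n_points)
  res <- align_contours(res)
  m_total <- length(boundaries)
  grid <- array(NA_real_, c(m_total, n_points, 3L))
  zs <- (keep - 1L) * slice_spacing
  j <- 0L
  for (m in seq_len(m_total)) {
    if (present[m]) {
      j <- j + 1L
      cc <- unclass(res[[j]])
      grid[m, , 1L] <- cc[, 2L] * pixel_spacing
      grid[m, , 2L] <- cc[, 1L] * pixel_spacing
      grid[m, , 3L] <- zs[m]
    }
  }
  if (any(!present)) {
    ms <- which(present)
    for (n in seq_len(n_points)) {
      for (d in 1:2) {
        grid[!present, n, d] <-
          stats::approx(zs[ms], grid[ms, n, d], xout = zs[!present])$y
      }
    }
    grid[!present, , 3L] <- zs[!present]
  }
  structure(grid, class = "surface_grid")
}

#' Smooth the stacked point trajectories along z
#'
#' Each of the `n_points` aligned vertex trajectories (one point per slice)
#' is replaced by its penalized-spline fit with fidelity weight `1 - alpha`
#' and curvature weight `alpha` (open-curve second-difference penalty along
#' the stacking index).  `alpha = 0` is the exact identity; trajectories
#' already linear in z are unchanged for any `alpha`.
#'
#' @param grid A `surface_grid` array `[m, n, 3]` with `m >= 4`.
#' @param alpha Smoothing factor in `[0, 1)`; default 0.5.
#' @return Smoothed `surface_grid`.
#' @export
smooth_z_curves <- function(grid, alpha = 0.5) {
  stopifnot(length(dim(grid)) == 3L, dim(grid)[3L] == 3L)
  if (dim(grid)[1L] < 4L) stop("need >= 4 slices in the stack")
  if (is.na(alpha) || alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (alpha == 0) return(grid)
  out <- grid
  for (n in seq_len(dim(grid)[2L])) {
    for (d in 1:2) {                          # z coordinates stay fixed
      out[, n, d] <- whittaker_open(grid[, n, d], alpha)
    }
  }
  structure(out, class = "surface_grid")
}

#' Triangle mesh over a surface point grid
#'
#' Connects the `[m, n]` grid with triangles, periodic in `n`, optionally
#' capping the first and last rings with triangle fans around their
#' centroids so the mesh is watertight.
#'
#' @param grid A `surface_grid`.
#' @param caps Close the ends (default `TRUE`).
#' @return Object of class `surface_mesh`: list with `vertices` (V x 3) and
#'   `faces` (F x 3 vertex indices, 1-based).
#' @export
build_mesh <- function(grid, caps = TRUE) {
  m <- dim(grid)[1L]; n <- dim(grid)[2L]
  stopifnot(m >= 2L, n >= 3L)
  verts <- matrix(aperm(grid, c(2L, 1L, 3L)), m * n, 3L)  # vertex (i,j) at (i-1)*n + j
  vid <- function(i, j) (i - 1L) * n + ((j - 1L) %% n) + 1L
  faces <- vector("list", (m - 1L) * n * 2L)
  f <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq_len(n)) {
      a <- vid(i, j); b2 <- vid(i, j + 1L)
      c2 <- vid(i + 1L, j + 1L); d2 <- vid(i + 1L, j)
      faces[[f + 1L]] <- c(a, b2, c2)
      faces[[f + 2L]] <- c(a, c2, d2)
      f <- f + 2L
    }
  }
  faces <- do.call(rbind, faces)
  if (caps) {
    c_bot <- colMeans(grid[1L, , ])
    c_top <- colMeans(grid[m, , ])
    verts <- rbind(verts, c_bot, c_top)
    ib <- nrow(verts) - 1L; it <- nrow(verts)
    bot <- t(vapply(seq_len(n),
                    function(j) c(ib, vid(1L, j + 1L), vid(1L, j)),
                    numeric(3)))
    top <- t(vapply(seq_len(n),
                    function(j) c(it, vid(m, j), vid(m, j + 1L)),
                    numeric(3)))
    faces <- rbind(faces, bot, top)
  }
  rownames(verts) <- NULL
  structure(list(vertices = verts, faces = faces), class = "surface_mesh")
}

#' @exportS3Method base::print
print.surface_mesh <- function(x, ...) {
  cat("Surface mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  invisible(x)
}

#' Enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes
#' `det(v1, v2, v3) / 6` over the faces, absolute value.
#'
#' @param mesh A `surface_mesh`.
#' @return Volume (in the cube of the coordinate unit).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  det6 <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  abs(sum(det6)) / 6
}

#' Write a mesh to PLY (ASCII) or OBJ
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path; format chosen by extension (`.ply` or `.obj`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property float x", "property float y", "property float z",
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    vl <- apply(v, 1L, function(p) paste(format(p, trim = TRUE), collapse = " "))
    fl <- apply(f - 1L, 1L, function(p) paste(c(3L, p), collapse = " "))
    writeLines(c(header, vl, fl), path)
  } else if (ext == "obj") {
    vl <- apply(v, 1L, function(p) paste("v", paste(format(p, trim = TRUE), collapse = " ")))
    fl <- apply(f, 1L, function(p) paste("f", paste(p, collapse = " ")))
    writeLines(c(vl, fl), path)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' Reconstruct the 3D liver surface from per-slice results
#'
#' Convenience wrapper: collects the smoothed boundaries of a list of
#' [process_slice()] results (or plain contours), resamples to `n_points`,
#' aligns, stacks with physical spacing, smooths the z trajectories and
#' builds the mesh.
#'
#' @param results List of `slice_result` objects or contours.
#' @param n_points Points per boundary (default 200).
#' @param alpha z-direction smoothing factor (default 0.5).
#' @param pixel_spacing,slice_spacing Physical spacings in mm.
#' @param caps Close the mesh ends (default TRUE).
#' @return Object of class `liver_surface`: list with `grid` and `mesh`.
#' @export
reconstruct_surface <- function(results, n_points = 200L, alpha = 0.5,
                                pixel_spacing = 1, slice_spacing = 1,
                                caps = TRUE) {
  boundaries <- lapply(results, function(r) {
    if (inherits(r, "slice_result")) {
      if (r$empty) NULL else r$boundary_smoothed
    } else {
      r
    }
  })
  if (sum(!vapply(boundaries, is.null, logical(1))) < 4L) {
    stop("need >= 4 slices with a liver boundary")
  }
  grid <- surface_grid(boundaries, n_points, pixel_spacing, slice_spacing)
  grid <- smooth_z_curves(grid, alpha)
  mesh <- build_mesh(grid, caps = caps)
  structure(list(grid = grid, mesh = mesh), class = "liver_surface")
}

#' @exportS3Method base::print
print.liver_surface <- function(x, ...) {
  d <- dim(x$grid)
  cat("Reconstructed liver surface:", d[1L], "slices x", d[2L], "boundary points\n")
  cat("  enclosed volume:", format(mesh_volume(x$mesh), digits = 6), "\n")
  invisible(x)
}
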