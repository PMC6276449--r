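#' Read a slice stack from disk
#'
#' Supported inputs: a directory of grayscale PNG or TIFF slices (sorted
#' lexicographically; spacing defaults to 1 mm with a warning), or a NIfTI
#' volume (`.nii` / `.nii.gz`, iterated along the third axis with spacings
#' read from the header).  All slices must share one shape.
#'
#' @param path Directory of slice images or a NIfTI file.
#' @return List with `slices` (list of numeric matrices), `pixel_spacing`
#'   and `slice_spacing` (mm).
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF slices found in ", path)
    slices <- lapply(files, read_slice_image)
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
      stop("inconsistent slice shapes")
    }
    warning("no spacing metadata in image directory; assuming 1 mm")
    return(list(slices = slices, pixel_spacing = 1, slice_spacing = 1))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    spac <- RNifti::pixdim(vol)
    slices <- lapply(seq_len(dim(vol)[3L]), function(k) vol[, , k])
    return(list(slices = slices,
                pixel_spacing = if (length(spac) >= 1L) spac[1L] else 1,
                slice_spacing = if (length(spac) >= 3L) spac[3L] else 1))
  }
  stop("unsupported input: ", path)
}

read_slice_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  if (length(dim(img)) == 3L) img <- img[, , 1L]    # first channel of RGB(A)
  img * 65535                                       # undo [0,1] normalization
}

#' Write binary masks as 0/255 PNG slices
#'
#' @param masks List of 0/1 matrices.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_masks <- function(masks, dir, prefix = "mask") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks))
  for (k in seq_along(masks)) {
    paths[k] <- file.path(dir, sprintf("%s_%04d.png", prefix, k))
    png::writePNG(masks[[k]] * 1.0, paths[k])
  }
  invisible(paths)
}

#' Read 0/255 PNG masks back as 0/1 matrices
#'
#' @param paths PNG files written by [write_masks()].
#' @return List of integer 0/1 matrices.
#' @export
read_masks <- function(paths) {
  lapply(paths, function(p) {
    m <- (png::readPNG(p) > 0.5) * 1L
    storage.mode(m) <- "integer"
    m
  })
}

#' Write / read per-slice contours as CSV
#'
#' Long format with columns `slice_index`, `vertex_index`, `row`, `col`.
#' The round trip reproduces the vertices exactly.
#'
#' @param contours List of contours (or `NULL` for failed slices).
#' @param path CSV path.
#' @return `write_contours` returns `path` invisibly; `read_contours`
#'   returns a list of contours indexed by slice.
#' @export
write_contours <- function(contours, path) {
  rows <- list()
  for (k in seq_along(contours)) {
    cc <- contours[[k]]
    if (is.null(cc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      slice_index = k, vertex_index = seq_len(nrow(cc)),
      row = cc[, 1L], col = cc[, 2L])
  }
  if (length(rows) == 0L) stop("no contours to write")
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path)
  out <- vector("list", max(df$slice_index))
  for (k in unique(df$slice_index)) {
    sub <- df[df$slice_index == k, ]
    sub <- sub[order(sub$vertex_index), ]
    out[[k]] <- as_contour(cbind(sub$row, sub$col))
  }
  out
}

#' Write an evaluation / run report as JSON
#'
#' @param report Named list (e.g. a `metrics_report`).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
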