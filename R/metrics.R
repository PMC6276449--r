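#' Dice coefficient
#'
#' @param pred,truth 0/1 masks or volumes of the same shape.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  inter <- sum(pred == 1L & truth == 1L)
  denom <- sum(pred == 1L) + sum(truth == 1L)
  if (denom == 0) return(1)
  2 * inter / denom
}

#' Volumetric overlap metrics
#'
#' Community-standard definitions:
#' `VOE = 100 * (1 - |A ∩ B| / |A ∪ B|)` and
#' `RVD = 100 * (|A| - |B|) / |B|`, with `A` the prediction and `B` the
#' ground truth.
#'
#' @param pred,truth 0/1 masks or volumes of the same shape; `truth` must be
#'   non-empty.
#' @return Named list `voe_percent`, `rvd_percent`.
#' @export
volume_metrics <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  nB <- sum(truth == 1L)
  if (nB == 0) stop("empty ground truth")
  nA <- sum(pred == 1L)
  inter <- sum(pred == 1L & truth == 1L)
  union <- nA + nB - inter
  list(voe_percent = 100 * (1 - inter / union),
       rvd_percent = 100 * (nA - nB) / nB)
}

border_voxels <- function(mask) {
  mask <- as.array(mask)
  dims <- dim(mask)
  idx <- lapply(dims, function(d) seq_len(d) + 1L)
  pad <- array(0L, dims + 2L)
  pad <- do.call(`[<-`, c(list(pad), idx, list(mask)))
  is_border <- array(FALSE, dims)
  for (d in seq_along(dims)) {
    for (s in c(-1L, 1L)) {
      sh <- idx
      sh[[d]] <- sh[[d]] + s
      nb <- do.call(`[`, c(list(pad), sh, list(drop = FALSE)))
      is_border <- is_border | (nb == 0L)
    }
  }
  which(mask == 1L & is_border, arr.ind = TRUE)
}

#' Symmetric surface distance metrics
#'
#' Border voxels (foreground voxels with at least one face-adjacent
#' background voxel; voxels on the array frame count as border) of both
#' masks are extracted, scaled to physical coordinates, and all nearest
#' distances from each surface to the other are pooled.  ASD is their mean,
#' RMSD the root mean square and MSSD the maximum — so
#' `ASD <= RMSD <= MSSD` always holds and the metrics are symmetric in the
#' two masks.
#'
#' @param pred,truth Non-empty 0/1 masks or volumes of the same shape.
#' @param spacing Physical voxel spacing per dimension in mm (recycled).
#' @return Named list `asd_mm`, `rmsd_mm`, `mssd_mm`.
#' @export
surface_metrics <- function(pred, truth, spacing = 1) {
  stopifnot(all(dim(pred) == dim(truth)))
  if (sum(pred == 1L) == 0 || sum(truth == 1L) == 0) stop("empty mask")
  nd <- length(dim(as.array(pred)))
  spacing <- rep_len(spacing, nd)
  a <- border_voxels(pred); b <- border_voxels(truth)
  a <- sweep(matrix(as.numeric(a), nrow(a)), 2L, spacing, `*`)
  b <- sweep(matrix(as.numeric(b), nrow(b)), 2L, spacing, `*`)
  d_ab <- min_distances_cpp(a, b)
  d_ba <- min_distances_cpp(b, a)
  all_d <- c(d_ab, d_ba)
  list(asd_mm = mean(all_d),
       rmsd_mm = sqrt(mean(all_d^2)),
       mssd_mm = max(all_d))
}

#' Full evaluation report for a segmentation
#'
#' @param pred,truth 0/1 masks or volumes of the same shape.
#' @param spacing Physical voxel spacing per dimension in mm.
#' @return Object of class `metrics_report`: list with `voe_percent`,
#'   `rvd_percent`, `asd_mm`, `rmsd_mm`, `mssd_mm`, `dice`.
#' @export
evaluate_segmentation <- function(pred, truth, spacing = 1) {
  vm <- volume_metrics(pred, truth)
  sm <- surface_metrics(pred, truth, spacing)
  structure(c(vm, sm, list(dice = dice_coefficient(pred, truth))),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("VOE %.2f%%  RVD %+.2f%%  ASD %.3f mm  RMSD %.3f mm  MSSD %.3f mm  Dice %.4f\n",
              x$voe_percent, x$rvd_percent, x$asd_mm, x$rmsd_mm, x$mssd_mm, x$dice))
  invisible(x)
}
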