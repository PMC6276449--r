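#' Calibrate the SDD parameters by grid search
#'
#' Runs the full per-slice segmentation for every `(W, N)` cell of the grid
#' and returns the pair maximizing the mean Dice coefficient against the
#' supplied ground-truth liver masks.  A slice whose segmentation fails
#' contributes Dice 0.  Deterministic: ties are broken by grid order
#' (`W` outer, `N` inner), so the first maximal cell wins.
#'
#' @param images List of slices (numeric matrices).
#' @param truths List of 0/1 ground-truth liver masks (same length).
#' @param W_grid,N_grid Integer vectors of candidate bandwidths / windows.
#' @param config Base configuration; `sdd.bandwidth_W` / `sdd.window_N` are
#'   overridden per cell.
#' @return List with `bandwidth_W`, `window_N`, `mean_dice` and the full
#'   `grid` data frame of scores.
#' @export
calibrate_sdd <- function(images, truths, W_grid = c(8L, 12L, 16L),
                          N_grid = c(10L, 20L, 30L),
                          config = default_config()) {
  if (length(images) == 0L || length(images) != length(truths)) {
    stop("need a non-empty labeled set of equal length")
  }
  grid <- expand.grid(N = as.integer(N_grid), W = as.integer(W_grid))[, c("W", "N")]
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg[["sdd.bandwidth_W"]] <- grid$W[g]
    cfg[["sdd.window_N"]] <- grid$N[g]
    dices <- vapply(seq_along(images), function(i) {
      res <- process_slice(images[[i]], cfg)
      if (res$empty) 0 else dice_coefficient(res$liver, truths[[i]])
    }, numeric(1))
    scores[g] <- mean(dices)
  }
  best <- which.max(scores)
  list(bandwidth_W = grid$W[best], window_N = grid$N[best],
       mean_dice = scores[best], grid = cbind(grid, mean_dice = scores))
}
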