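#' Default pipeline configuration
#'
#' Returns the flat named list of tunable parameters used throughout the
#' per-slice segmentation chain and the 3D reconstruction.  The defaults are
#' the calibrated working point of the method: histogram smoothing bandwidth
#' `sdd.bandwidth_W = 12` DFT bins, one-sided line-fit window
#' `sdd.window_N = 20` intensity levels, Ising penalty `mrf.beta = 1`,
#' morphological filter/merge repetition counts `morph.n_f = 8` and
#' `morph.n_m = 16`, and boundary smoothing factor `spline.alpha = 0.5`.
#'
#' @return Named list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg[["sdd.bandwidth_W"]]
default_config <- function() {
  list(
    `sdd.bandwidth_W`           = 12L,
    `sdd.window_N`              = 20L,
    `sdd.valley_merge_distance` = 8L,
    `mrf.beta`                  = 1.0,
    `mrf.max_sweeps`            = 20L,
    `morph.n_f`                 = 8L,
    `morph.n_m`                 = 16L,
    `spline.alpha`              = 0.5,
    `anatomy.orientation_flip`  = FALSE,
    `anatomy.rib_split`         = "auto",
    `recon.n_points`            = 200L,
    `recon.alpha`               = 0.5,
    `case`                      = "auto"
  )
}

#' Load / save a pipeline configuration
#'
#' Configurations are stored as flat JSON objects.  Unknown keys are rejected
#' so that typos in config files surface immediately; omitted keys fall back
#' to [default_config()].
#'
#' @param path Path of a JSON configuration file.
#' @param config Named list as returned by [default_config()].
#' @return `load_config` returns the merged configuration list;
#'   `save_config` returns `path` invisibly.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  config <- merge_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Merge user settings over the default configuration
#'
#' @param config Named list of overrides (possibly empty).
#' @return Full configuration list.
#' @export
merge_config <- function(config = list()) {
  base <- default_config()
  if (length(config) == 0) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  for (key in intersect(names(base), names(config))) {
    int_keys <- c("sdd.bandwidth_W", "sdd.window_N", "sdd.valley_merge_distance",
                  "mrf.max_sweeps", "morph.n_f", "morph.n_m", "recon.n_points")
    base[[key]] <- if (key %in% int_keys) as.integer(config[[key]]) else config[[key]]
  }
  base
}
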