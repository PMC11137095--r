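# Pipeline configuration: nested defaults, YAML overlay.

#' Default pipeline configuration
#'
#' Blocks mirror the pipeline stages. `fps`: patch size at the highest
#' magnification (512 px as in routine 20x/40x work) and the
#' threshold/morphology/marker parameters of [fps_config()]. `attention`:
#' minimum attention level `alpha` (0.1) and the fill color for suppressed
#' pixels. `ips`: minimum spacing `delta` (3, patch-grid units), distance
#' metric, per-patient cap. `wsid`: decision threshold `delta` (0.5) and
#' whether the classifier consumes the cleaned raster (default) or the raw
#' patch. `eval`: positive class for metrics.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    fps = c(list(patch_size = 512L), unclass(fps_config())),
    attention = list(alpha = 0.1, fill = c(255, 255, 255)),
    ips = list(delta = 3, metric = "euclidean", max_n = 50L),
    wsid = list(delta = 0.5, use_cleaned = TRUE),
    eval = list(positive_class = "MSI-High")
  )
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read a YAML configuration, overlaying the defaults
#'
#' @param path YAML file with any subset of the blocks of
#'   [default_config()].
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}
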