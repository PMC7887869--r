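#' Pipeline configuration
#'
#' Collects the switchable techniques of the identification pipeline. The
#' defaults reproduce the best-performing strategy (all five techniques on:
#' manual crop, resize to 150 px, histogram equalization, keypoint
#' concatenation, gender filter). The application order
#' crop -> resize -> histogram equalization is fixed and not configurable.
#'
#' @param use_crop Apply the manual ROI crop.
#' @param use_resize Resize to a fixed ear width.
#' @param target_width Ear width in pixels after resizing (default 150).
#' @param use_hist_eq Apply histogram equalization.
#' @param use_concatenation Combine descriptors from multiple images of the
#'   same subject into one composite identity vector.
#' @param use_gender_filter Narrow the gallery to records matching the
#'   probe's gender label before scoring.
#' @param top_k Length of the ranked candidate list (default 10).
#' @param seed Integer seed for any stochastic component.
#' @param backend Descriptor backend name (see [descriptor_backend()]).
#' @param label Optional human-readable strategy name.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(use_crop = TRUE, use_resize = TRUE, target_width = 150L,
                            use_hist_eq = TRUE, use_concatenation = TRUE,
                            use_gender_filter = TRUE, top_k = 10L, seed = 1L,
                            backend = "ghist", label = NULL) {
  target_width <- as.integer(target_width)
  top_k <- as.integer(top_k)
  if (is.na(target_width) || target_width < 8L) stop("target_width must be >= 8")
  if (is.na(top_k) || top_k < 1L) stop("top_k must be >= 1")
  cfg <- structure(
    list(use_crop = isTRUE(use_crop), use_resize = isTRUE(use_resize),
         target_width = target_width, use_hist_eq = isTRUE(use_hist_eq),
         use_concatenation = isTRUE(use_concatenation),
         use_gender_filter = isTRUE(use_gender_filter),
         top_k = top_k, seed = as.integer(seed), backend = backend),
    class = "pipeline_config"
  )
  cfg$label <- if (is.null(label)) strategy_label(cfg) else label
  cfg
}

strategy_label <- function(config) {
  parts <- c(
    if (config$use_crop) "crop",
    if (config$use_resize) sprintf("resize%d", config$target_width),
    if (config$use_hist_eq) "he",
    if (config$use_concatenation) "concat",
    if (config$use_gender_filter) "gender"
  )
  if (length(parts) == 0L) "none" else paste(parts, collapse = "+")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config %s> top_k=%d backend=%s hash=%s\n",
              x$label, x$top_k, x$backend, config_hash(x)))
  invisible(x)
}

#' Preprocessing/backend fingerprint
#'
#' Hash over every setting that changes extracted descriptors: the
#' preprocessing flags and target width plus the backend identity and
#' version. Galleries and descriptor caches are keyed by this fingerprint so
#' descriptors produced under different regimes are never mixed.
#'
#' @param config A [pipeline_config()].
#' @return A character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  be <- descriptor_backend(config$backend)
  digest::digest(list(
    use_crop = config$use_crop, use_resize = config$use_resize,
    target_width = config$target_width, use_hist_eq = config$use_hist_eq,
    backend = be$name, backend_version = be$version
  ))
}
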