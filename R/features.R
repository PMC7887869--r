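#' Descriptor set ("vector map")
#'
#' The identity representation of one or more ear images: an `n x 128` matrix
#' of keypoint descriptors. Rows are kept in a canonical order (by keypoint
#' x, y, scale, then lexicographically by descriptor values) so that caching,
#' serialization and concatenation are reproducible regardless of the order a
#' backend emits keypoints in.
#'
#' @param descriptors Numeric `n x 128` matrix (n may be 0).
#' @param source_images Character vector of image identifiers.
#' @param subject_id Subject the descriptors belong to, or `NA`.
#' @param keypoints Optional `n x 3` matrix (x, y, scale) used for canonical
#'   ordering; zero-filled when a backend does not report locations.
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(descriptors, source_images = character(),
                           subject_id = NA_character_, keypoints = NULL) {
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) == 0L) {
    descriptors <- matrix(numeric(0), 0L, 128L)
  }
  if (ncol(descriptors) != 128L) stop("descriptors must have exactly 128 columns")
  if (any(descriptors < 0)) stop("descriptor components must be non-negative")
  if (is.null(keypoints)) keypoints <- matrix(0, nrow(descriptors), 3L)
  keypoints <- as.matrix(keypoints)
  stopifnot(nrow(keypoints) == nrow(descriptors), ncol(keypoints) == 3L)
  dimnames(descriptors) <- NULL
  dimnames(keypoints) <- NULL
  ord <- canonical_order(keypoints, descriptors)
  structure(
    list(descriptors = descriptors[ord, , drop = FALSE],
         keypoints = keypoints[ord, , drop = FALSE],
         source_images = as.character(source_images),
         subject_id = as.character(subject_id)),
    class = "descriptor_set"
  )
}

canonical_order <- function(keypoints, descriptors) {
  if (nrow(descriptors) == 0L) return(integer(0))
  keys <- c(lapply(seq_len(3L), function(j) keypoints[, j]),
            lapply(seq_len(128L), function(j) descriptors[, j]))
  do.call(order, keys)
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set n=%d subject=%s images=%d>\n",
              nrow(x$descriptors), x$subject_id, length(x$source_images)))
  invisible(x)
}

#' Number of descriptors in a set
#' @param set A [descriptor_set()].
#' @return Integer count.
#' @export
n_descriptors <- function(set) nrow(set$descriptors)

#' Is a descriptor set unmatchable (empty)?
#' @param set A [descriptor_set()].
#' @return `TRUE` when the set holds no descriptors.
#' @export
is_unmatchable <- function(set) n_descriptors(set) == 0L

# ---- backend registry --------------------------------------------------------

backend_registry <- new.env(parent = emptyenv())

#' Descriptor backends
#'
#' Keypoint descriptor extraction is pluggable behind a small contract: a
#' backend is a list with `name`, `version` and `extract(pixels)` returning a
#' list with `descriptors` (`n x 128`) and `keypoints` (`n x 3`: x, y, scale).
#' The built-in `"ghist"` backend detects keypoints as local extrema of a
#' multi-scale difference-of-Gaussians response and encodes each as a 4x4
#' spatial grid of 8-bin gradient-orientation histograms (128 values), with
#' the usual unit-normalisation, 0.2 clipping and 8-bit quantisation. It is
#' fully deterministic: the same pixels always give the same descriptors.
#'
#' @param name Backend name.
#' @param backend For `register_descriptor_backend()`, the backend list.
#' @return `descriptor_backend()` returns the backend list.
#' @export
descriptor_backend <- function(name = "ghist") {
  be <- backend_registry[[name]]
  if (is.null(be)) stop(sprintf("unknown descriptor backend '%s'", name))
  be
}

#' @rdname descriptor_backend
#' @export
register_descriptor_backend <- function(name, backend) {
  stopifnot(is.list(backend), is.function(backend$extract),
            is.character(backend$version))
  backend$name <- name
  backend_registry[[name]] <- backend
  invisible(backend)
}

instrument <- new.env(parent = emptyenv())
instrument$extractions <- 0L

#' Extraction instrumentation counter
#'
#' Counts invocations of the descriptor backend since the last reset. Used to
#' verify that cached reruns skip feature extraction entirely.
#'
#' @return `extraction_count()` returns the current count.
#' @export
extraction_count <- function() instrument$extractions

#' @rdname extraction_count
#' @export
reset_extraction_count <- function() {
  instrument$extractions <- 0L
  invisible(NULL)
}

#' Extract keypoint descriptors from a preprocessed image
#'
#' Runs the configured backend on the image and returns its descriptors in
#' canonical order. A contrast-free image (e.g. a constant frame) yields an
#' empty, unmatchable set rather than an error; the caller decides whether
#' that is fatal.
#'
#' @param image A grayscale [ear_image()].
#' @param backend Backend name (default `"ghist"`).
#' @return A [descriptor_set()].
#' @export
extract_descriptors <- function(image, backend = "ghist") {
  stopifnot(inherits(image, "ear_image"))
  if (!is_grayscale(image)) stop("extract_descriptors expects a grayscale image")
  be <- descriptor_backend(backend)
  instrument$extractions <- instrument$extractions + 1L
  res <- be$extract(image$pixels)
  src <- if (is.na(image$source)) character() else image$source
  descriptor_set(res$descriptors, source_images = src,
                 subject_id = image$subject_id, keypoints = res$keypoints)
}

#' Concatenate descriptor sets into a composite identity vector
#'
#' Stacks the descriptor rows of several sets from the same subject into one
#' composite. Keypoints that appear only under one capture angle or lighting
#' tend to find no close neighbour in other images and are diluted, while
#' constant keypoints are retained, improving the signal-to-noise ratio of
#' the identity representation. The result is re-sorted canonically, so
#' concatenation is associative and order-insensitive.
#'
#' @param sets A list of [descriptor_set()] objects sharing one subject.
#' @return A composite [descriptor_set()] with `n = sum(n_i)`.
#' @export
concatenate_descriptors <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "descriptor_set")))
  ids <- unique(stats::na.omit(vapply(sets, function(s) s$subject_id, character(1))))
  if (length(ids) > 1L) {
    stop(sprintf("cannot concatenate descriptors from different subjects: %s",
                 paste(ids, collapse = ", ")))
  }
  descriptor_set(
    do.call(rbind, lapply(sets, function(s) s$descriptors)),
    source_images = unlist(lapply(sets, function(s) s$source_images)),
    subject_id = if (length(ids)) ids else NA_character_,
    keypoints = do.call(rbind, lapply(sets, function(s) s$keypoints))
  )
}
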