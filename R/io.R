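# Reading images, manifests and ROI sidecars.

#' Read an ear photograph
#'
#' Reads a PNG or JPEG file into an [ear_image()]. Colour images are kept in
#' colour (conversion to grayscale is the first pipeline stage); an alpha
#' channel, if present, is dropped.
#'
#' @param path Image file path.
#' @param subject_id,gender,side,capture_index Capture metadata; see
#'   [ear_image()].
#' @return An [ear_image()] whose `source` is `path`.
#' @export
read_ear_image <- function(path, subject_id = NA_character_,
                           gender = NA_character_,
                           side = "unspecified", capture_index = 1L) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' (PNG and JPEG are supported)", ext))
  )
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3L]
    raw <- if (nc >= 3L) raw[, , 1:3, drop = FALSE] else raw[, , 1L]
  }
  px <- quantize8(raw * 255)
  if (length(dim(raw)) == 3L) {
    px <- array(px, dim = dim(raw))
  }
  ear_image(px, subject_id = subject_id, gender = gender, side = side,
            capture_index = capture_index, source = path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `image_path`, `subject_id`, `gender`,
#' `side`, `capture_index` — one row per capture.
#'
#' @param path Manifest CSV path.
#' @return A validated `data.frame`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  need <- c("image_path", "subject_id", "gender", "side", "capture_index")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop(sprintf("manifest is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  m$capture_index <- as.integer(m$capture_index)
  m
}

#' Read an ROI sidecar
#'
#' A CSV with columns `image_path`, `x0`, `y0`, `x1`, `y1` giving the manual
#' crop for each image in 0-based, half-open pixel coordinates.
#'
#' @param path ROI CSV path.
#' @return A named list of [crop_roi()] keyed by `image_path`.
#' @export
read_rois <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "x0", "y0", "x1", "y1")
  missing <- setdiff(need, names(r))
  if (length(missing)) {
    stop(sprintf("ROI sidecar is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  rois <- lapply(seq_len(nrow(r)), function(i) {
    crop_roi(r$x0[i], r$y0[i], r$x1[i], r$y1[i])
  })
  names(rois) <- r$image_path
  rois
}

load_manifest_images <- function(manifest, image_dir = NULL) {
  paths <- manifest$image_path
  if (!is.null(image_dir)) paths <- file.path(image_dir, paths)
  imgs <- lapply(seq_len(nrow(manifest)), function(i) {
    if (!file.exists(paths[i])) {
      stop(sprintf("image file '%s' (manifest row %d) does not exist", paths[i], i))
    }
    read_ear_image(paths[i], subject_id = manifest$subject_id[i],
                   gender = manifest$gender[i], side = manifest$side[i],
                   capture_index = manifest$capture_index[i])
  })
  names(imgs) <- manifest$image_path
  imgs
}
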