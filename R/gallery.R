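#' Identity gallery
#'
#' A gallery is the searchable database of enrolled subjects. Every record
#' carries the subject's ID, gender label and composite vector map; raw
#' pixels are never stored, so possession of a gallery does not reveal what
#' anyone's ear looks like. All records in a gallery share one
#' preprocessing/backend fingerprint — regimes are never mixed.
#'
#' @param config The [pipeline_config()] the gallery is built under.
#' @return An empty `ear_gallery`.
#' @export
ear_gallery <- function(config = pipeline_config()) {
  structure(
    list(records = list(), config = config, config_hash = config_hash(config)),
    class = "ear_gallery"
  )
}

#' @export
print.ear_gallery <- function(x, ...) {
  cat(sprintf("<ear_gallery %d subjects, regime %s (%s)>\n",
              length(x$records), x$config$label, x$config_hash))
  invisible(x)
}

#' Number of enrolled subjects
#' @param gallery An [ear_gallery()].
#' @return Integer count.
#' @export
n_subjects <- function(gallery) length(gallery$records)

#' Enroll a subject into a gallery
#'
#' Each image is preprocessed and descriptor-extracted (consulting the cache
#' first), and the resulting vector maps are concatenated into one composite
#' identity vector when concatenation is enabled. Enrollment is write-once:
#' re-enrolling an existing subject ID is a conflict error. Descriptor
#' values are quantised to 32-bit float precision at enrollment so that the
#' persisted store round-trips bit-exactly.
#'
#' @param gallery An [ear_gallery()].
#' @param subject_id Unique subject identifier.
#' @param gender Gender label or `NA`.
#' @param images List of raw [ear_image()] captures (>= 1).
#' @param rois List of [crop_roi()] parallel to `images` (or `NULL` when
#'   cropping is disabled).
#' @param cache Optional [descriptor_cache()].
#' @return The gallery with the new record added.
#' @export
enroll_subject <- function(gallery, subject_id, gender, images, rois = NULL,
                           cache = NULL) {
  stopifnot(inherits(gallery, "ear_gallery"), length(images) >= 1L)
  subject_id <- as.character(subject_id)
  if (subject_id %in% names(gallery$records)) {
    stop(sprintf("enrollment conflict: subject '%s' is already enrolled", subject_id))
  }
  config <- gallery$config
  if (config$use_crop && is.null(rois)) {
    stop("gallery regime uses cropping but no ROIs were provided")
  }
  sets <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    img$subject_id <- subject_id
    sets[[i]] <- extract_cached(img, config, roi = rois[[i]], cache = cache)
  }
  sets <- Filter(Negate(is_unmatchable), sets)
  if (length(sets) == 0L) {
    stop(sprintf("subject '%s' is unenrollable: no image yielded descriptors",
                 subject_id))
  }
  if (config$use_concatenation) {
    if (length(sets) == 1L) {
      warning(sprintf(
        "concatenation enabled but subject '%s' has a single usable image; enrolling a single-image record",
        subject_id))
    }
    composite <- concatenate_descriptors(sets)
  } else {
    composite <- sets[[1L]]
  }
  composite$descriptors <- matrix(float32(composite$descriptors),
                                  nrow(composite$descriptors), 128L)
  record <- list(subject_id = subject_id, gender = as.character(gender),
                 composite = composite,
                 enrolled_from = composite$source_images,
                 config_hash = gallery$config_hash)
  gallery$records[[subject_id]] <- record
  gallery
}

# ---- persistence -------------------------------------------------------------

#' Persist / load a gallery as a single SQLite file
#'
#' The store holds only vector maps and metadata, never pixels. Descriptors
#' are written as 32-bit floats row-major, and `load_gallery(save_gallery(g))`
#' reproduces `g` bit-exactly. Writing is atomic (temp file then rename).
#' Loading with a `config` whose fingerprint differs from the stored one is
#' an explicit error, never a silent reuse.
#'
#' @param gallery An [ear_gallery()].
#' @param path SQLite file path.
#' @param config Optional [pipeline_config()] the caller expects the store
#'   to match.
#' @return `load_gallery()` returns the reconstructed [ear_gallery()];
#'   `save_gallery()` returns `path` invisibly.
#' @export
save_gallery <- function(gallery, path) {
  stopifnot(inherits(gallery, "ear_gallery"))
  tmp <- paste0(path, ".tmp")
  if (file.exists(tmp)) unlink(tmp)
  con <- DBI::dbConnect(RSQLite::SQLite(), tmp)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)")
  DBI::dbExecute(con, paste(
    "CREATE TABLE subjects (subject_id TEXT PRIMARY KEY, gender TEXT,",
    "n INTEGER, enrolled_from TEXT, desc BLOB, kp BLOB)"))
  cfg_txt <- rawToChar(serialize(gallery$config, NULL, ascii = TRUE))
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('config_hash', ?)",
                 params = list(gallery$config_hash))
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('config', ?)",
                 params = list(cfg_txt))
  DBI::dbExecute(con, "INSERT INTO meta VALUES ('format_version', '1')")
  for (r in gallery$records) {
    DBI::dbExecute(
      con,
      "INSERT INTO subjects VALUES (?, ?, ?, ?, ?, ?)",
      params = list(
        r$subject_id, r$gender, n_descriptors(r$composite),
        paste(r$enrolled_from, collapse = "\n"),
        list(writeBin(as.numeric(t(r$composite$descriptors)), raw(), size = 4L)),
        list(writeBin(as.numeric(t(r$composite$keypoints)), raw()))
      )
    )
  }
  DBI::dbDisconnect(con)
  on.exit()
  if (file.exists(path)) unlink(path)
  if (!file.rename(tmp, path)) stop("failed to move gallery store into place")
  invisible(path)
}

#' @rdname save_gallery
#' @export
load_gallery <- function(path, config = NULL) {
  if (!file.exists(path)) stop(sprintf("gallery store '%s' does not exist", path))
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  tabs <- DBI::dbListTables(con)
  if (!all(c("meta", "subjects") %in% tabs)) {
    stop(sprintf("'%s' is not a gallery store (corrupt or wrong file)", path))
  }
  meta <- DBI::dbGetQuery(con, "SELECT key, value FROM meta")
  mval <- function(k) meta$value[match(k, meta$key)]
  stored_hash <- mval("config_hash")
  stored_config <- unserialize(charToRaw(mval("config")))
  if (!is.null(config) && config_hash(config) != stored_hash) {
    stop(sprintf(
      "gallery regime mismatch: store was built under %s but %s was requested",
      stored_hash, config_hash(config)))
  }
  g <- ear_gallery(stored_config)
  rows <- DBI::dbGetQuery(con, "SELECT * FROM subjects ORDER BY subject_id")
  for (i in seq_len(nrow(rows))) {
    n <- rows$n[i]
    desc <- matrix(readBin(rows$desc[[i]], "double", n = n * 128L, size = 4L),
                   nrow = n, ncol = 128L, byrow = TRUE)
    kp <- matrix(readBin(rows$kp[[i]], "double", n = n * 3L),
                 nrow = n, ncol = 3L, byrow = TRUE)
    src <- if (nzchar(rows$enrolled_from[i])) {
      strsplit(rows$enrolled_from[i], "\n", fixed = TRUE)[[1L]]
    } else character()
    composite <- descriptor_set(desc, source_images = src,
                                subject_id = rows$subject_id[i], keypoints = kp)
    g$records[[rows$subject_id[i]]] <- list(
      subject_id = rows$subject_id[i], gender = rows$gender[i],
      composite = composite, enrolled_from = src, config_hash = stored_hash)
  }
  g
}
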