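# Shared fixtures and independent oracles.

# Independent brute-force oracle for the average nearest-neighbour squared
# Euclidean score: plain double loop, no shared code with the implementation.
brute_nn_score <- function(P, E) {
  total <- 0
  for (i in seq_len(nrow(P))) {
    best <- Inf
    for (j in seq_len(nrow(E))) {
      d <- sum((P[i, ] - E[j, ])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total / nrow(P)
}

random_descriptors <- function(n) {
  matrix(stats::runif(n * 128, 0, 255), n, 128)
}

random_set <- function(n, subject_id = NA_character_) {
  descriptor_set(random_descriptors(n), subject_id = subject_id)
}

make_record <- function(subject_id, gender, set) {
  list(subject_id = subject_id, gender = gender, composite = set,
       enrolled_from = character(), config_hash = "test")
}

gray_image <- function(values, nrow, ncol, ...) {
  ear_image(matrix(as.integer(values), nrow, ncol), ...)
}

const_image <- function(v, w = 24L, h = 24L, ...) {
  gray_image(rep(v, w * h), h, w, ...)
}

# A descriptor backend whose single descriptor encodes the top-left pixel
# value, so that evaluation outcomes can be scripted exactly: the distance
# between a probe and a gallery record is just the squared difference of the
# constant intensities their images were built from.
register_descriptor_backend("stub-const", list(
  version = "1",
  extract = function(pixels) {
    list(descriptors = matrix(c(pixels[1, 1], rep(0, 127)), 1, 128),
         keypoints = matrix(0, 1, 3))
  }
))

stub_config <- function(...) {
  pipeline_config(use_crop = FALSE, use_resize = FALSE, use_hist_eq = FALSE,
                  use_concatenation = FALSE, use_gender_filter = FALSE,
                  backend = "stub-const", ...)
}

# Scripted cohort: subject i enrolls a constant image of intensity enroll[i]
# and probes a constant image of intensity probe[i].
scripted_cohort <- function(enroll, probe, genders = NULL, dir = tempfile("scripted")) {
  n <- length(enroll)
  if (is.null(genders)) genders <- rep("F", n)
  dir.create(dir)
  manifest <- NULL
  for (i in seq_len(n)) {
    sid <- sprintf("P%02d", i)
    for (k in 1:2) {
      v <- if (k == 1L) enroll[i] else probe[i]
      fname <- sprintf("%s_c%d.png", sid, k)
      png::writePNG(matrix(v / 255, 16, 16), file.path(dir, fname))
      manifest <- rbind(manifest, data.frame(
        image_path = fname, subject_id = sid, gender = genders[i],
        side = "left", capture_index = k, stringsAsFactors = FALSE))
    }
  }
  list(dir = dir, manifest = manifest)
}

# Small real-image cohort shared across gallery/cache/synthetic tests;
# generated once per test run.
mini_cohort_env <- new.env()
mini_cohort <- function() {
  if (is.null(mini_cohort_env$co)) {
    spec <- synthetic_cohort_spec(n_subjects = 4, images_per_subject = 4,
                                  image_width = 200, image_height = 400,
                                  seed = 7)
    mini_cohort_env$co <- generate_cohort(spec, file.path(tempdir(), "minicohort"))
  }
  mini_cohort_env$co
}
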