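test_that("grayscale conversion applies BT.601 luma with half-up rounding", {
  red <- ear_image(array(c(255L, 0L, 0L), c(1L, 1L, 3L)))
  expect_equal(to_grayscale(red)$pixels, matrix(76L, 1, 1))
  grey <- ear_image(array(c(100L, 100L, 100L), c(1L, 1L, 3L)))
  expect_equal(to_grayscale(grey)$pixels, matrix(100L, 1, 1))
  g <- gray_image(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_identical(to_grayscale(g), g)  # grayscale passes through unchanged
  expect_error(ear_image(array(0L, c(2, 2, 2))), "matrix|array")
})

test_that("crop obeys half-open bounds and rejects out-of-range ROIs", {
  img <- gray_image(seq_len(100) %% 256, 10, 10)
  expect_identical(crop_image(img, crop_roi(0, 0, 10, 10))$pixels, img$pixels)
  big <- gray_image(rep(7L, 2000 * 1000), 1000, 2000)
  out <- crop_image(big, crop_roi(500, 100, 1700, 900))
  expect_equal(c(image_width(out), image_height(out)), c(1200, 800))
  expect_error(crop_image(img, crop_roi(5, 5, 15, 8)), "invalid ROI")
  expect_error(crop_roi(3, 3, 3, 8), "invalid ROI")
  sub <- crop_image(img, crop_roi(2, 1, 5, 4))
  expect_identical(sub$pixels, img$pixels[2:4, 3:5])
})

test_that("crop preserves capture metadata", {
  img <- gray_image(1:100 %% 256, 10, 10, subject_id = "Z9", gender = "M",
                    side = "right", capture_index = 3L)
  out <- crop_image(img, crop_roi(1, 1, 9, 9))
  expect_equal(out[c("subject_id", "gender", "side", "capture_index")],
               img[c("subject_id", "gender", "side", "capture_index")])
})

test_that("resize sets the target width and keeps proportions", {
  big <- gray_image(rep(128L, 2000 * 1000), 1000, 2000)
  out <- resize_to_width(big, 150)
  expect_equal(c(image_width(out), image_height(out)), c(150, 75))
  same <- gray_image(rep(5L, 150 * 80), 80, 150)
  expect_identical(resize_to_width(same, 150), same)
  half <- resize_to_width(gray_image(rep(9L, 300 * 100), 100, 300), 150)
  expect_equal(c(image_width(half), image_height(half)), c(150, 50))
})

test_that("resize preserves aspect ratio within half-pixel rounding and averages when shrinking", {
  set.seed(11)
  for (dims in list(c(37, 95), c(120, 61), c(400, 203))) {
    h <- dims[1]; w <- dims[2]
    tw <- sample(c(9L, 25L, 150L), 1)
    out <- resize_to_width(gray_image(sample(0:255, h * w, TRUE), h, w), tw)
    expect_equal(image_width(out), tw)
    expect_lte(abs(image_height(out) - h * tw / w), 0.5)
  }
  # exact 2x shrink is plain 2x2 block averaging
  px <- matrix(c(0L, 0L, 100L, 100L,
                 0L, 0L, 100L, 100L), 2, 4, byrow = TRUE)
  out <- resize_to_width(ear_image(px), 2)
  expect_equal(out$pixels, matrix(c(0L, 100L), 1, 2))
})

test_that("histogram equalization matches the worked cdf examples", {
  two <- equalize_histogram(gray_image(c(10L, 20L), 1, 2))
  expect_equal(sort(as.vector(two$pixels)), c(0L, 255L))
  flat <- const_image(42L)
  expect_identical(equalize_histogram(flat), flat)
  four <- equalize_histogram(gray_image(c(0L, 0L, 128L, 255L), 1, 4))
  expect_equal(as.vector(four$pixels), c(85L, 85L, 170L, 255L))
})

test_that("histogram equalization mapping is monotone over all 256 levels", {
  img <- gray_image(0:255, 16, 16)
  out <- equalize_histogram(img)
  lut <- out$pixels[order(img$pixels)]
  expect_true(all(diff(lut) >= 0))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  # and on a skewed random image, tracking each level's mapped value
  set.seed(3)
  px <- matrix(pmin(255L, as.integer(stats::rpois(900, 40))), 30, 30)
  eq <- equalize_histogram(ear_image(px))$pixels
  m <- tapply(as.vector(eq), as.vector(px), unique)
  expect_true(all(lengths(m) == 1L))  # one output level per input level
  expect_true(all(diff(unlist(m)) >= 0))
})

test_that("preprocess applies enabled stages in the fixed order", {
  set.seed(21)
  img <- gray_image(sample(0:255, 2000 * 1000, TRUE), 1000, 2000)
  all_off <- pipeline_config(use_crop = FALSE, use_resize = FALSE,
                             use_hist_eq = FALSE)
  expect_identical(preprocess_image(img, all_off), to_grayscale(img))

  crop_resize <- pipeline_config(use_hist_eq = FALSE)
  out <- preprocess_image(img, crop_resize, crop_roi(100, 100, 1600, 900))
  expect_equal(image_width(out), 150)

  # resize + HE without a crop is a legal strategy and runs on the full frame
  no_crop <- pipeline_config(use_crop = FALSE)
  out2 <- preprocess_image(img, no_crop)
  expect_equal(image_width(out2), 150)
  manual <- equalize_histogram(resize_to_width(img, 150))
  expect_identical(out2$pixels, manual$pixels)

  expect_error(preprocess_image(img, pipeline_config()), "ROI")
})

test_that("preprocessing stages are deterministic", {
  set.seed(5)
  img <- gray_image(sample(0:255, 5000, TRUE), 50, 100)
  cfg <- pipeline_config(use_crop = TRUE, target_width = 40)
  roi <- crop_roi(3, 5, 90, 44)
  expect_identical(preprocess_image(img, cfg, roi), preprocess_image(img, cfg, roi))
})
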