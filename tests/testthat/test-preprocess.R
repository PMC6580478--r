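# Preprocessing: grayscale conversion, aperture-ring detection, fixed crops
# and resizing.

test_that("grayscale conversion applies channel weights and rescales", {
  white <- array(1, dim = c(40, 40, 3))
  expect_equal(to_grayscale_single(white)$pixels, matrix(1, 40, 40))

  red <- array(0, dim = c(40, 40, 3))
  red[, , 1] <- 1
  expect_equal(to_grayscale_single(red)$pixels, matrix(0.299, 40, 40),
               tolerance = 1e-12)

  gray <- matrix(runif(40 * 40), 40, 40)
  expect_equal(to_grayscale_single(gray)$pixels, gray)

  counts <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  expect_equal(to_grayscale_single(counts)$pixels, counts / 255)

  expect_error(to_grayscale_single(array(1, dim = c(40, 40, 2))),
               class = "format_error")
  expect_error(to_grayscale_single(array(1, dim = c(40, 40, 3)),
                                   channel_weights = c(1, 1)),
               class = "format_error")
})

test_that("aperture auto-crop recovers the generator's interior within 2 px", {
  truth <- aperture_interior_bbox()
  seed <- 71
  errs <- numeric(0)
  for (s in 1:25) {
    for (v in 1:2) {
      img <- render_capture(sample_ear_shape(s, seed), donut_capture_model(),
                            v, seed)
      cr <- auto_crop_aperture(img)
      errs <- c(errs, max(abs(cr$provenance$crop_bbox - truth)))
    }
  }
  expect_lte(max(errs), 2)
})

test_that("auto-crop is idempotent and signals when no ring exists", {
  img <- render_capture(sample_ear_shape(1, 9), donut_capture_model(), 1, 9)
  once <- auto_crop_aperture(img)
  twice <- auto_crop_aperture(once)
  expect_identical(once$pixels, twice$pixels)

  no_ring <- render_capture(sample_ear_shape(1, 9),
                            capture_model("freehand"), 1, 9)
  expect_error(auto_crop_aperture(no_ring), class = "ring_detection_error")
})

test_that("fixed crop honors the window contract exactly", {
  img <- render_capture(sample_ear_shape(1, 9), capture_model("freehand"),
                        1, 9)
  full <- fixed_crop(img, crop_spec(480, 360))
  expect_identical(full$pixels, img$pixels)

  small <- fixed_crop(img, crop_spec(100, 80))
  expect_equal(dim(small$pixels), c(100L, 80L))

  expect_error(fixed_crop(img, crop_spec(481, 360)), class = "invalid_crop")
  expect_error(fixed_crop(img, crop_spec(100, 80, anchor = c(470, 350))),
               class = "invalid_crop")

  # a centre crop smaller than the ear excludes recorded ear pixels
  bb <- img$provenance$ear_bbox
  tight <- fixed_crop(img, crop_spec(100, 100))
  cb <- tight$provenance$crop_bbox
  expect_true(bb[1] < cb[1] || bb[2] > cb[2] || bb[3] < cb[3] || bb[4] > cb[4])
})

test_that("resize preserves aspect ratio and is lossy but mild", {
  img <- render_capture(sample_ear_shape(2, 9), capture_model("freehand"),
                        1, 9)
  expect_identical(resize_image(img, 480)$pixels, img$pixels)

  half <- resize_image(img, 240)
  expect_equal(dim(half$pixels), c(240L, 180L))

  back <- earsift:::resize_bilinear_cpp(half$pixels, 480L, 360L)
  mad <- mean(abs(back - img$pixels))
  expect_gt(mad, 0)
  expect_lt(mad, 0.05)

  expect_error(resize_image(img, 16), class = "invalid_argument")
})
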