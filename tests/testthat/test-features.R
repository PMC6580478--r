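# Feature layer: scale-space construction, keypoint detection, descriptor
# invariances, backend dispatch and serialization.

test_that("constant images yield zero DoG planes and no keypoints", {
  flat <- matrix(0.5, 64, 64)
  pyr <- build_scale_space(flat)
  for (oct in pyr$octaves) {
    for (d in oct$dog) expect_lt(max(abs(d)), 1e-12)
  }
  expect_equal(nrow(detect_keypoints(pyr)), 0)
  fs <- extract_features(flat, "native")
  expect_equal(nrow(fs$descriptors), 0)
})

test_that("a bright blob is a DoG extremum at its location", {
  m <- matrix(0.2, 96, 96)
  rr <- matrix(0:95, 96, 96)
  cc <- t(rr)
  m <- m + 0.6 * exp(-((rr - 48)^2 + (cc - 40)^2) / (2 * 4^2))
  pyr <- build_scale_space(m)
  # brute-force argmax over every DoG plane of every octave
  best <- c(val = -Inf, row = NA, col = NA)
  for (oct in pyr$octaves) {
    for (d in oct$dog) {
      i <- which.max(abs(d))
      if (abs(d[i]) > best["val"]) {
        rc <- arrayInd(i, dim(d))
        best <- c(val = abs(d[i]), row = (rc[1] - 1) * oct$factor,
                  col = (rc[2] - 1) * oct$factor)
      }
    }
  }
  expect_lt(abs(best["row"] - 48), 3)
  expect_lt(abs(best["col"] - 40), 3)
  kp <- detect_keypoints(pyr)
  expect_gt(nrow(kp), 0)
  d2 <- sqrt((kp$row - 48)^2 + (kp$col - 40)^2)
  expect_lt(min(d2), 2)
})

test_that("doubling base sigma moves a fixed blob's extremum down one octave", {
  m <- matrix(0.2, 128, 128)
  rr <- matrix(0:127, 128, 128)
  cc <- t(rr)
  m <- m + 0.6 * exp(-((rr - 64)^2 + (cc - 64)^2) / (2 * 8^2))
  argmax_octave <- function(base_sigma) {
    pyr <- build_scale_space(m, feature_params(base_sigma = base_sigma))
    best <- c(-Inf, NA)
    for (o in seq_along(pyr$octaves)) {
      for (d in pyr$octaves[[o]]$dog) {
        v <- max(abs(d))
        if (v > best[1]) best <- c(v, o)
      }
    }
    best[2]
  }
  o1 <- argmax_octave(1.6)
  o2 <- argmax_octave(3.2)
  expect_equal(o2, o1 - 1)
})

test_that("straight step edges do not survive the edge-response filter", {
  m <- matrix(0.2, 96, 96)
  m[, 49:96] <- 0.8
  m <- earsift:::gaussian_blur_cpp(m, 1)
  kp <- detect_keypoints(build_scale_space(m))
  expect_equal(nrow(kp), 0)
})

test_that("keypoints transform covariantly under 90-degree rotation", {
  m <- textured_patch(17, size = 96)
  mr <- t(m)[ncol(m):1, ]
  kp <- detect_keypoints(build_scale_space(m))
  kpr <- detect_keypoints(build_scale_space(mr))
  expect_gt(nrow(kp), 10)
  # counts agree up to rare floating-point tie flips at thresholds
  expect_lte(abs(nrow(kp) - nrow(kpr)), max(2, ceiling(0.05 * nrow(kp))))
  # map original (row, col) -> rotated frame: (n-1-col, row)
  n <- nrow(m)
  mapped_r <- n - 1 - kp$col
  mapped_c <- kp$row
  d <- vapply(seq_len(nrow(kp)), function(i) {
    min(sqrt((kpr$row - mapped_r[i])^2 + (kpr$col - mapped_c[i])^2))
  }, numeric(1))
  expect_gte(mean(d <= 1), 0.9)
})

test_that("descriptors are unit norm and invariant to global gain", {
  patch <- textured_patch(23, size = 128)
  kp <- detect_keypoints(build_scale_space(patch))
  expect_gt(nrow(kp), 10)

  # the same scene at gain 0.6 and brightened by 1.5x (no clipping)
  dim_fs <- compute_descriptors(patch * 0.6, kp)
  bright_fs <- compute_descriptors(patch * 0.9, kp)
  expect_equal(ncol(dim_fs$descriptors), 128)
  expect_equal(sqrt(rowSums(dim_fs$descriptors^2)),
               rep(1, nrow(dim_fs$descriptors)), tolerance = 1e-9)
  expect_true(all(dim_fs$descriptors >= 0))
  expect_equal(nrow(dim_fs$descriptors), nrow(bright_fs$descriptors))
  expect_lt(max(abs(dim_fs$descriptors - bright_fs$descriptors)), 1e-3)
})

test_that("descriptors of rotation-matched keypoints stay close", {
  m <- textured_patch(31, size = 128)
  mr <- t(m)[ncol(m):1, ]
  f <- extract_features(m, "native")
  fr <- extract_features(mr, "native")
  n <- nrow(m)
  mapped_r <- n - 1 - f$keypoints$col
  mapped_c <- f$keypoints$row
  # this rotation shifts gradient orientations by exactly -90 degrees
  expected_ori <- (f$keypoints$orientation - 90) %% 360
  dists <- c()
  for (i in seq_len(nrow(f$keypoints))) {
    d2 <- sqrt((fr$keypoints$row - mapped_r[i])^2 +
                 (fr$keypoints$col - mapped_c[i])^2)
    dori <- abs(((fr$keypoints$orientation - expected_ori[i] + 180) %% 360) - 180)
    cand <- which(d2 <= 1.5 & dori <= 15)
    if (length(cand)) {
      j <- cand[which.min(d2[cand])]
      dists <- c(dists, sqrt(sum((f$descriptors[i, ] - fr$descriptors[j, ])^2)))
    }
  }
  expect_gt(length(dists), 5)
  expect_lt(stats::median(dists), 0.35)

  # and the two images match under the ratio test
  expect_gt(match_descriptors(f, fr)$n_matches, 0.5 * nrow(f$keypoints))
})

test_that("backend dispatch is deterministic and rejects unknown labels", {
  m <- textured_patch(3, size = 64)
  a <- extract_features(m, "native")
  b <- extract_features(m, "native")
  expect_identical(a$descriptors, b$descriptors)
  expect_error(extract_features(m, "magic"))
})

test_that("feature sets round-trip through the columnar text cache", {
  m <- textured_patch(5, size = 64)
  fs <- extract_features(m, "native")
  path <- tempfile(fileext = ".csv")
  write_feature_set(fs, path)
  back <- read_feature_set(path)
  expect_equal(back$keypoints$row, fs$keypoints$row, tolerance = 1e-12)
  expect_equal(back$descriptors, fs$descriptors, tolerance = 1e-12)
})

test_that("images too small for the pyramid are rejected", {
  expect_error(build_scale_space(matrix(0.5, 16, 16)),
               class = "configuration_error")
  expect_error(build_scale_space(matrix(0.5, 40, 40),
                                 feature_params(n_octaves = 6)),
               class = "configuration_error")
})
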