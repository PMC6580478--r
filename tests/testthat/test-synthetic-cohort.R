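# Synthetic cohort generator: determinism, subject distinctness, the
# standardized-vs-freehand contrast at the pixel level, and manifest contracts.

test_that("ear shapes are deterministic per (subject, seed) and distinct across subjects", {
  expect_identical(sample_ear_shape(1, 42), sample_ear_shape(1, 42))
  s1 <- sample_ear_shape(1, 42)
  s2 <- sample_ear_shape(2, 42)
  expect_false(identical(s1[-1], s2[-1]))

  # pairwise distinct shape-parameter vectors across a cohort
  vecs <- t(sapply(1:20, function(s) {
    sh <- sample_ear_shape(s, 7)
    c(sh$helix_axes, sh$antihelix_offset, sh$concha_center, sh$concha_radius,
      sh$lobe_extent, sh$tragus_size)
  }))
  expect_equal(nrow(unique(round(vecs, 6))), 20)
})

test_that("shape invariants hold across seeds", {
  for (seed in c(1, 99, 2024)) {
    for (s in c(1, 13)) {
      sh <- sample_ear_shape(s, seed)
      expect_true(all(unlist(sh[c("helix_axes", "antihelix_offset",
                                  "concha_radius", "lobe_extent",
                                  "tragus_size")]) > 0))
      expect_lt(sh$antihelix_offset, min(sh$helix_axes))
    }
  }
  expect_error(sample_ear_shape(0, 1), class = "invalid_argument")
})

test_that("standardized capture freezes every nuisance except sensor noise", {
  sh <- sample_ear_shape(3, 11)
  v1 <- render_capture(sh, donut_capture_model(), 1, 11)
  v2 <- render_capture(sh, donut_capture_model(), 2, 11)
  d <- abs(v1$pixels - v2$pixels)
  # two independent N(0, 0.01) noise fields: difference sd ~ 0.014
  expect_lt(mean(d), 0.03)
  expect_lt(max(d), 0.15)
  p1 <- v1$provenance$capture
  p2 <- v2$provenance$capture
  expect_equal(p1$rotation, 0)
  expect_equal(p1$translation, c(0, 0))
  expect_equal(p1$scale, 1)
  expect_equal(p1[c("rotation", "translation", "scale", "gamma")],
               p2[c("rotation", "translation", "scale", "gamma")])
})

test_that("freehand capture redraws geometric nuisances per visit", {
  sh <- sample_ear_shape(3, 11)
  v1 <- render_capture(sh, freehand_capture_model(), 1, 11)
  v2 <- render_capture(sh, freehand_capture_model(), 2, 11)
  p1 <- v1$provenance$capture
  p2 <- v2$provenance$capture
  expect_false(p1$rotation == p2$rotation)
  expect_false(all(p1$translation == p2$translation))
  expect_false(p1$scale == p2$scale)
})

test_that("rendering is deterministic and zero occlusion is an identity", {
  sh <- sample_ear_shape(2, 5)
  a <- render_capture(sh, freehand_capture_model(), 1, 5)
  b <- render_capture(sh, freehand_capture_model(), 1, 5)
  expect_identical(a$pixels, b$pixels)

  no_occl <- capture_model("freehand", rotation_range = c(-15, 15),
                           scale_range = c(0.8, 1.2),
                           occlusion_fraction_range = c(0, 0))
  x <- render_capture(sh, no_occl, 1, 5)
  y <- render_capture(sh, no_occl, 1, 5, occlusion = FALSE)
  expect_identical(x$pixels, y$pixels)
})

test_that("capture models that could push the ear out of frame are rejected", {
  expect_error(capture_model("bad", translation_range = c(-0.6, 0.6)),
               class = "invalid_capture_model")
  expect_error(capture_model("bad", scale_range = c(0, 1)),
               class = "invalid_capture_model")
  expect_error(capture_model("bad", occlusion_fraction_range = c(0, 1.5)),
               class = "invalid_capture_model")
})

test_that("a subject's standardized pair is more alike than their freehand pair", {
  man <- fixture_cohort()
  dir <- attr(man, "dir")
  for (s in unique(man$subject_id)) {
    px <- lapply(c("donut", "freehand"), function(cond) {
      lapply(1:2, function(v) {
        row <- man[man$subject_id == s & man$condition == cond &
                     man$visit == v, ]
        png::readPNG(file.path(dir, row$file_path))
      })
    })
    donut_diff <- mean(abs(px[[1]][[1]] - px[[1]][[2]]))
    free_diff <- mean(abs(px[[2]][[1]] - px[[2]][[2]]))
    expect_lt(donut_diff, free_diff)
  }
})

test_that("raw-pixel nearest neighbors recover identity under standardized capture", {
  n <- 20
  seed <- 29
  v1 <- list(); v2 <- list()
  for (s in seq_len(n)) {
    sh <- sample_ear_shape(s, seed)
    can <- earsift:::render_canonical_ear(sh)
    v1[[s]] <- render_capture(sh, donut_capture_model(), 1, seed,
                              canonical = can)$pixels
    v2[[s]] <- render_capture(sh, donut_capture_model(), 2, seed,
                              canonical = can)$pixels
  }
  hits <- vapply(seq_len(n), function(s) {
    d <- vapply(v1, function(g) mean((v2[[s]] - g)^2), numeric(1))
    which.min(d) == s
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("generate_cohort writes a complete, reproducible image set", {
  man <- fixture_cohort()
  expect_s3_class(man, "cohort_manifest")
  expect_equal(nrow(man), 24)
  expect_true(all(table(man$subject_id) == 4))
  expect_false(anyDuplicated(paste(man$subject_id, man$visit,
                                   man$condition)) > 0)
  paths <- file.path(attr(man, "dir"), man$file_path)
  expect_true(all(file.exists(paths)))

  # regenerating two subjects elsewhere reproduces those bytes exactly
  dir2 <- file.path(tempdir(), "earsift_regen")
  man2 <- generate_cohort(2, cohort_seed = 313, out_dir = dir2)
  for (i in seq_len(nrow(man2))) {
    f_new <- file.path(dir2, man2$file_path[i])
    f_old <- file.path(attr(man, "dir"), man2$file_path[i])
    expect_identical(unname(tools::md5sum(f_new)),
                     unname(tools::md5sum(f_old)))
  }
  expect_error(generate_cohort(1, cohort_seed = 1, out_dir = tempdir()),
               class = "invalid_argument")
})
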