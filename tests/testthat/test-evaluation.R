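# Identification evaluation: direction results, report averaging, the
# score-matrix audit trail, and the crop-sensitivity sweep contracts.

test_that("probes identical to the gallery identify perfectly", {
  gallery <- lapply(1:5, function(s) {
    random_feature_set(10, seed = 40 + s, subject_id = s, visit = 1L)
  })
  probes <- lapply(1:5, function(s) {
    fs <- gallery[[s]]
    fs$key$visit <- 2L
    fs
  })
  d <- identify_direction(gallery, probes)
  expect_equal(d$top1_correct, 5L)
  expect_equal(d$top10_correct, 5L)
  expect_true(d$top10_correct >= d$top1_correct)
})

test_that("the top-10 criterion clamps to small galleries", {
  gallery <- lapply(1:2, function(s) {
    random_feature_set(8, seed = 60 + s, subject_id = s, visit = 1L)
  })
  probes <- lapply(1:2, function(s) {
    random_feature_set(8, seed = 80 + s, subject_id = s, visit = 2L)
  })
  d <- identify_direction(gallery, probes)
  # with 2 gallery images, "within top 10" degenerates to "present at all"
  expect_equal(d$top10_correct, d$n_probes)
})

test_that("probe subjects missing from the gallery are reported", {
  gallery <- lapply(1:3, function(s) {
    random_feature_set(5, seed = s, subject_id = s, visit = 1L)
  })
  probes <- list(random_feature_set(5, seed = 9, subject_id = 7L, visit = 2L))
  expect_error(identify_direction(gallery, probes),
               class = "manifest_inconsistency")
})

test_that("report rates average the two directional proportions", {
  man <- fixture_cohort()
  rep <- identification_report(man, "donut")
  d <- rep$direction_results
  p1 <- c(d[[1]]$top1_correct / d[[1]]$n_probes,
          d[[2]]$top1_correct / d[[2]]$n_probes)
  p10 <- c(d[[1]]$top10_correct / d[[1]]$n_probes,
           d[[2]]$top10_correct / d[[2]]$n_probes)
  expect_equal(rep$top1_rate, 100 * mean(p1))
  expect_equal(rep$top10_rate, 100 * mean(p10))
  expect_gte(rep$top10_rate, rep$top1_rate)
  # averaging is symmetric in the two directions
  expect_equal(mean(rev(p1)), mean(p1))
  fixture_cache$donut_report <- rep
})

test_that("exported score matrices re-sort to the reported counts", {
  man <- fixture_cohort()
  rep <- fixture_cache$donut_report
  if (is.null(rep)) rep <- identification_report(man, "donut")
  for (d in rep$direction_results) {
    path <- tempfile(fileext = ".csv")
    write_score_matrix(d, path)
    sm <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    # independent re-sorter: parse subject ids out of the key strings
    gal_subj <- as.integer(sub("^s(\\d+)_.*$", "\\1", colnames(sm)))
    top1 <- 0L; topk <- 0L
    k_eff <- min(10, ncol(sm))
    for (i in seq_len(nrow(sm))) {
      probe_subj <- as.integer(sub("^s(\\d+)_.*$", "\\1", rownames(sm)[i]))
      ord <- order(-sm[i, ], gal_subj)
      if (gal_subj[ord[1]] == probe_subj) top1 <- top1 + 1L
      if (probe_subj %in% gal_subj[ord[seq_len(k_eff)]]) topk <- topk + 1L
    }
    expect_equal(top1, d$top1_correct)
    expect_equal(topk, d$top10_correct)
  }
})

test_that("sensitivity sweep validates its grid and differentiates rates", {
  man <- fixture_cohort()
  expect_error(sensitivity_sweep(man, "freehand", "length", c(200, 200)),
               class = "invalid_argument")
  expect_error(sensitivity_sweep(man, "freehand", "length", c(250)),
               class = "invalid_argument")

  curve <- sensitivity_sweep(man, "freehand", "length",
                             values = c(160, 300), fixed_other = 300)
  expect_equal(nrow(curve), 2)
  expect_true(is.na(curve$slope[1]))
  expect_equal(curve$slope[2],
               diff(curve$top1_rate) / diff(curve$crop_value))
  expect_true(all(curve$top1_rate >= 0 & curve$top1_rate <= 100))
  # the flag fires exactly when |slope| exceeds the percent-per-pixel threshold
  expect_equal(curve$sensitive[2], abs(curve$slope[2]) > 1)
})

test_that("a sweep point larger than the image is rejected", {
  man <- fixture_cohort()
  expect_error(sensitivity_sweep(man, "freehand", "length",
                                 values = c(300, 500), fixed_other = 300),
               class = "invalid_crop")
})
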