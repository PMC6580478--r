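# Descriptor matching and gallery ranking against independent brute-force
# oracles.

test_that("a probe matched against itself hits the self-match ceiling", {
  fs <- random_feature_set(12, seed = 1)
  ps <- match_descriptors(fs, fs)
  expect_equal(ps$n_matches, 12)
})

test_that("empty feature sets yield zero matches", {
  fs <- random_feature_set(5, seed = 2)
  empty <- feature_set(fs$keypoints[0, ], matrix(numeric(0), 0, 128),
                       key = list(subject_id = 9L, visit = 1L,
                                  condition = "donut"))
  expect_equal(match_descriptors(fs, empty)$n_matches, 0)
  expect_equal(match_descriptors(empty, fs)$n_matches, 0)
  expect_error(match_descriptors(fs, fs, ratio_threshold = 1.2),
               class = "invalid_argument")
})

test_that("match counts equal the brute-force oracle on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    np <- sample(2:20, 1)
    ng <- sample(2:20, 1)
    P <- random_unit_descriptors(np, seed * 101)
    G <- random_unit_descriptors(ng, seed * 101 + 1)
    fp <- feature_set(data.frame(row = seq_len(np), col = 1, scale = 1.6,
                                 orientation = 0, octave = 1L,
                                 scale_index = 1, response = 1), P,
                      key = list(subject_id = 1L, visit = 2L,
                                 condition = "donut"))
    fg <- feature_set(data.frame(row = seq_len(ng), col = 1, scale = 1.6,
                                 orientation = 0, octave = 1L,
                                 scale_index = 1, response = 1), G,
                      key = list(subject_id = 2L, visit = 1L,
                                 condition = "donut"))
    for (ratio in c(0.6, 0.75, 0.9)) {
      expect_equal(match_descriptors(fp, fg, ratio)$n_matches,
                   oracle_match_count(P, G, ratio),
                   info = sprintf("seed=%d ratio=%.2f", seed, ratio))
    }
  }
})

test_that("gallery ranking equals the brute-force oracle on seeded instances", {
  for (seed in 1:5) {
    gallery <- lapply(1:12, function(s) {
      random_feature_set(sample(3:15, 1), seed = seed * 1000 + s,
                         subject_id = s, visit = 1L)
    })
    probe <- random_feature_set(10, seed = seed * 1000 + 99, subject_id = 3L,
                                visit = 2L)
    rk <- rank_gallery(probe, gallery)
    orc <- oracle_rank(probe, gallery, 0.75)
    expect_equal(rk$subject_id, orc$subject_id)
    expect_equal(rk$n_matches, orc$n_matches)
  }
})

test_that("a gallery containing the probe itself ranks it first", {
  gallery <- lapply(1:6, function(s) {
    random_feature_set(10, seed = 500 + s, subject_id = s, visit = 1L)
  })
  rk <- rank_gallery(gallery[[4]], gallery)
  expect_equal(rk$subject_id[1], 4L)
  expect_equal(rk$n_matches[1], 10)
})

test_that("degenerate all-tied galleries fall back to the deterministic tie-break", {
  empty_fs <- function(s, v) {
    feature_set(data.frame(row = numeric(0), col = numeric(0),
                           scale = numeric(0), orientation = numeric(0),
                           octave = integer(0), scale_index = numeric(0),
                           response = numeric(0)),
                matrix(numeric(0), 0, 128),
                key = list(subject_id = s, visit = v, condition = "donut"))
  }
  gallery <- lapply(c(5L, 2L, 9L, 1L), empty_fs, v = 1L)
  probe <- random_feature_set(5, seed = 1, subject_id = 1L, visit = 2L)
  rk <- rank_gallery(probe, gallery)
  expect_equal(rk$n_matches, rep(0, 4))
  expect_equal(rk$subject_id, c(1L, 2L, 5L, 9L))
})

test_that("ranking is invariant to gallery input order", {
  gallery <- lapply(1:8, function(s) {
    random_feature_set(8, seed = 700 + s, subject_id = s, visit = 1L)
  })
  probe <- random_feature_set(8, seed = 799, subject_id = 5L, visit = 2L)
  rk1 <- rank_gallery(probe, gallery)
  rk2 <- rank_gallery(probe, rev(gallery))
  expect_equal(rk1$gallery_key, rk2$gallery_key)
  expect_equal(rk1$n_matches, rk2$n_matches)
})

test_that("duplicate gallery keys are rejected", {
  g <- random_feature_set(5, seed = 1, subject_id = 1L, visit = 1L)
  expect_error(rank_gallery(g, list(g, g)), class = "malformed_gallery")
})
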