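# Shared fixtures: a small cached synthetic cohort, textured patches for
# feature tests, random feature sets, and independent brute-force oracles for
# the matching layer.

fixture_cache <- new.env(parent = emptyenv())

# Small paired-visit cohort generated once per test run.
fixture_cohort <- function(n = 6L, seed = 313L) {
  key <- sprintf("cohort_%d_%d", n, seed)
  if (is.null(fixture_cache[[key]])) {
    dir <- file.path(tempdir(), sprintf("earsift_fixture_%d_%d", n, seed))
    fixture_cache[[key]] <- generate_cohort(n, cohort_seed = seed,
                                            out_dir = dir)
  }
  fixture_cache[[key]]
}

# Two-scale random texture with full dynamic range — generic imagery for
# feature-layer tests with structure at both fine and coarse scales.
textured_patch <- function(seed, size = 128L) {
  set.seed(seed)
  fine <- earsift:::gaussian_blur_cpp(matrix(rnorm(size * size), size, size),
                                      1.5)
  coarse <- earsift:::gaussian_blur_cpp(matrix(rnorm(size * size), size, size),
                                        4)
  m <- 0.6 * fine / sd(fine) + 0.4 * coarse / sd(coarse)
  (m - min(m)) / (max(m) - min(m))
}

random_unit_descriptors <- function(n, seed) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n * 128)), n, 128)
  m / sqrt(rowSums(m^2))
}

random_feature_set <- function(n, seed, subject_id = 1L, visit = 1L,
                               condition = "donut") {
  desc <- random_unit_descriptors(n, seed)
  kp <- data.frame(row = seq_len(n), col = seq_len(n), scale = 1.6,
                   orientation = 0, octave = 1L, scale_index = 1,
                   response = 1)
  feature_set(kp, desc, key = list(subject_id = as.integer(subject_id),
                                   visit = as.integer(visit),
                                   condition = condition))
}

# Independent brute-force oracle for the ratio-test match count: explicit
# O(n * m) loop with a full sort, no shared code with the implementation.
oracle_match_count <- function(P, G, ratio) {
  np <- nrow(P); ng <- nrow(G)
  if (np == 0 || ng == 0) return(0L)
  cand_i <- integer(0); cand_j <- integer(0); cand_d <- numeric(0)
  for (i in seq_len(np)) {
    d <- numeric(ng)
    for (j in seq_len(ng)) d[j] <- sqrt(sum((P[i, ] - G[j, ])^2))
    ord <- sort(d, index.return = TRUE)
    d1 <- ord$x[1]; j1 <- ord$ix[1]
    d2 <- if (ng >= 2) ord$x[2] else Inf
    if (d2 > 0 && d1 / d2 < ratio) {
      cand_i <- c(cand_i, i); cand_j <- c(cand_j, j1); cand_d <- c(cand_d, d1)
    }
  }
  if (length(cand_i) == 0) return(0L)
  used <- rep(FALSE, ng)
  n_acc <- 0L
  for (k in order(cand_d, cand_i)) {
    if (!used[cand_j[k]]) {
      used[cand_j[k]] <- TRUE
      n_acc <- n_acc + 1L
    }
  }
  n_acc
}

# Independent oracle ranking: recompute every pair score with the oracle
# above and sort with the documented tie-break (subject then visit).
oracle_rank <- function(probe, gallery, ratio) {
  scores <- vapply(gallery, function(g) {
    oracle_match_count(probe$descriptors, g$descriptors, ratio)
  }, integer(1))
  subj <- vapply(gallery, function(g) as.integer(g$key$subject_id), integer(1))
  vis <- vapply(gallery, function(g) as.integer(g$key$visit), integer(1))
  ord <- order(-scores, subj, vis)
  data.frame(subject_id = subj[ord], visit = vis[ord],
             n_matches = scores[ord])
}
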