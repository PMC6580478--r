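# Descriptor matching and gallery ranking. An image pair's score is the
# number of accepted descriptor correspondences: Lowe ratio test
# (nearest / second-nearest Euclidean distance below the threshold) with
# one-to-one enforcement by greedy acceptance in ascending nearest-distance
# order. Note the ratio test is directional — pair scores are not symmetric;
# the evaluation layer runs both directions explicitly.

#' Match descriptors between a probe and one gallery image
#'
#' For each probe descriptor, the nearest and second-nearest gallery
#' descriptors by Euclidean distance are found; the correspondence is
#' accepted iff \code{nearest / second_nearest < ratio_threshold}.
#' One-to-one correspondence is enforced greedily in ascending
#' nearest-distance order. When probe and gallery are the same image
#' (identical keys), the second-nearest distance excludes the
#' identical-index descriptor, so the self-match ceiling equals the
#' descriptor count.
#'
#' @param probe,gallery_image [feature_set()]s.
#' @param ratio_threshold Ratio-test threshold in (0, 1).
#' @return A list of class \code{pair_score}: \code{probe_key},
#'   \code{gallery_key}, \code{n_matches}, and a \code{matches} data frame
#'   (\code{probe_idx}, \code{gallery_idx}, \code{distance}, \code{ratio}).
#' @export
match_descriptors <- function(probe, gallery_image, ratio_threshold = 0.75) {
  if (ratio_threshold <= 0 || ratio_threshold >= 1) {
    stop_earsift("ratio_threshold must lie strictly between 0 and 1",
                 "invalid_argument")
  }
  pk <- if (length(probe$key)) probe$key else NULL
  gk <- if (length(gallery_image$key)) gallery_image$key else NULL
  same_image <- !is.null(pk) && !is.null(gk) && identical(pk, gk)

  np <- nrow(probe$descriptors)
  ng <- nrow(gallery_image$descriptors)
  empty <- data.frame(probe_idx = integer(0), gallery_idx = integer(0),
                      distance = numeric(0), ratio = numeric(0))
  result <- function(matches) {
    structure(list(probe_key = pk, gallery_key = gk,
                   n_matches = nrow(matches), matches = matches),
              class = "pair_score")
  }
  if (np == 0 || ng == 0) return(result(empty))

  P <- probe$descriptors
  G <- gallery_image$descriptors
  d2 <- outer(rowSums(P^2), rep(1, ng)) +
    outer(rep(1, np), rowSums(G^2)) - 2 * tcrossprod(P, G)
  d2[d2 < 0] <- 0

  nn_idx <- integer(np)
  nn_d <- numeric(np)
  ratio <- numeric(np)
  for (i in seq_len(np)) {
    row <- d2[i, ]
    j1 <- which.min(row)
    d1 <- row[j1]
    row2 <- row
    if (same_image && i <= ng) {
      row2[i] <- Inf    # second-nearest excludes the identical-index descriptor
      if (j1 == i) { j1 <- which.min(row2); d1 <- row2[j1] }
      # for the self-pair the nearest IS the identical index
      j1 <- if (row[i] <= d1) i else j1
      d1 <- min(row[i], d1)
    }
    row2[j1] <- Inf
    d2nd <- min(row2)
    nn_idx[i] <- j1
    nn_d[i] <- sqrt(d1)
    ratio[i] <- if (d2nd > 0) sqrt(d1) / sqrt(d2nd) else Inf
  }
  accepted <- which(is.finite(ratio) & ratio < ratio_threshold)
  if (length(accepted) == 0) return(result(empty))

  ord <- accepted[order(nn_d[accepted], accepted)]
  used <- logical(ng)
  keep <- integer(0)
  for (i in ord) {
    j <- nn_idx[i]
    if (!used[j]) {
      used[j] <- TRUE
      keep <- c(keep, i)
    }
  }
  result(data.frame(probe_idx = keep, gallery_idx = nn_idx[keep],
                    distance = nn_d[keep], ratio = ratio[keep]))
}

#' Rank a gallery for one probe
#'
#' Scores the probe against every gallery image with [match_descriptors()]
#' and returns the full descending ranking by match count, ties broken
#' deterministically by ascending subject id then visit (keys, not input
#' positions, so the ranking is invariant to gallery order).
#'
#' @param probe A [feature_set()].
#' @param gallery Non-empty list of [feature_set()]s with unique keys.
#' @param ratio_threshold Ratio-test threshold.
#' @return A data frame of class \code{ranked_matches}: \code{rank},
#'   \code{gallery_key}, \code{subject_id}, \code{visit}, \code{n_matches},
#'   with the probe key in attribute \code{probe_key}.
#' @export
rank_gallery <- function(probe, gallery, ratio_threshold = 0.75) {
  if (length(gallery) == 0) {
    stop_earsift("gallery must be non-empty", "invalid_argument")
  }
  keys <- vapply(gallery, function(g) {
    format_image_key(g$key$subject_id, g$key$visit, g$key$condition)
  }, character(1))
  if (anyDuplicated(keys)) {
    stop_earsift("gallery contains duplicate image keys", "malformed_gallery")
  }
  n_matches <- vapply(gallery, function(g) {
    match_descriptors(probe, g, ratio_threshold)$n_matches
  }, numeric(1))
  subject_id <- vapply(gallery, function(g) as.integer(g$key$subject_id),
                       integer(1))
  visit <- vapply(gallery, function(g) as.integer(g$key$visit), integer(1))
  ord <- order(-n_matches, subject_id, visit)
  out <- data.frame(rank = seq_along(ord), gallery_key = keys[ord],
                    subject_id = subject_id[ord], visit = visit[ord],
                    n_matches = n_matches[ord], stringsAsFactors = FALSE)
  attr(out, "probe_key") <- probe$key
  class(out) <- c("ranked_matches", "data.frame")
  out
}
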