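# Closed-set identification evaluation: bidirectional top-1/top-10 rates per
# capture condition, and the crop-sensitivity sweep. One direction enrolls one
# visit's images as the gallery and queries the other visit's images as
# probes; the reported rate is the average of the two directions.

#' Identify probes against a gallery (one direction)
#'
#' Ranks every probe against the gallery; a probe is top-1 correct when the
#' rank-1 gallery image belongs to the probe's subject, and top-k correct when
#' the subject appears within the first \code{min(k, |gallery|)} ranks.
#'
#' @param gallery List of [feature_set()]s, one image per subject.
#' @param probes List of [feature_set()]s covering the same subjects.
#' @param ratio_threshold Ratio-test threshold.
#' @param top_k Depth of the secondary criterion (10, as reported).
#' @return A list of class \code{direction_result}: \code{gallery_visit},
#'   \code{n_probes}, \code{top1_correct}, \code{top10_correct}, and the
#'   integer \code{score_matrix} (probe rows x gallery columns).
#' @export
identify_direction <- function(gallery, probes, ratio_threshold = 0.75,
                               top_k = 10L) {
  g_subjects <- sort(vapply(gallery, function(g) as.integer(g$key$subject_id),
                            integer(1)))
  p_subjects <- vapply(probes, function(p) as.integer(p$key$subject_id),
                       integer(1))
  if (anyDuplicated(g_subjects)) {
    stop_earsift("gallery must hold one image per subject",
                 "manifest_inconsistency")
  }
  missing <- setdiff(p_subjects, g_subjects)
  if (length(missing)) {
    stop_earsift(sprintf("probe subjects absent from gallery: %s",
                         paste(missing, collapse = ", ")),
                 "manifest_inconsistency")
  }
  k_eff <- min(top_k, length(gallery))
  top1 <- 0L
  topk <- 0L
  score <- matrix(0L, length(probes), length(gallery))
  g_keys <- vapply(gallery, function(g)
    format_image_key(g$key$subject_id, g$key$visit, g$key$condition),
    character(1))
  p_keys <- vapply(probes, function(p)
    format_image_key(p$key$subject_id, p$key$visit, p$key$condition),
    character(1))
  dimnames(score) <- list(p_keys, g_keys)
  for (i in seq_along(probes)) {
    rk <- rank_gallery(probes[[i]], gallery, ratio_threshold)
    score[i, rk$gallery_key] <- as.integer(rk$n_matches)
    subj <- p_subjects[i]
    if (rk$subject_id[1] == subj) top1 <- top1 + 1L
    if (subj %in% rk$subject_id[seq_len(k_eff)]) topk <- topk + 1L
  }
  structure(list(
    gallery_visit = as.integer(gallery[[1]]$key$visit),
    n_probes = length(probes),
    top1_correct = top1,
    top10_correct = topk,
    score_matrix = score
  ), class = "direction_result")
}

load_condition_features <- function(manifest, condition_name, visit,
                                    crop = "auto", params = feature_params(),
                                    target_long_side = 256L,
                                    fallback_spec = default_ear_crop(),
                                    ratio_threshold = 0.75) {
  dir <- attr(manifest, "dir")
  rows <- manifest[manifest$condition == condition_name &
                     manifest$visit == visit, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_earsift(sprintf("manifest has no %s visit-%d images", condition_name,
                         visit), "manifest_inconsistency")
  }
  rows <- rows[order(rows$subject_id), , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    path <- file.path(dir, rows$file_path[i])
    img <- read_ear_png(path, subject_id = rows$subject_id[i],
                        visit = rows$visit[i], condition = rows$condition[i])
    pre <- preprocess_for_condition(img, condition_name, crop = crop,
                                    target_long_side = target_long_side,
                                    fallback_spec = fallback_spec)
    extract_features(pre, backend = "native", params = params)
  })
}

#' Bidirectional identification report for one capture condition
#'
#' Runs preprocessing, feature extraction and gallery ranking in both
#' directions (visit-1 gallery / visit-2 probes, then swapped) and averages
#' the two directional proportions into the reported top-1 and top-10 rates
#' (percentages). Per-direction integer counts are always retained alongside
#' the averages.
#'
#' @param manifest A cohort manifest (see [generate_cohort()],
#'   [read_manifest()]).
#' @param condition_name Condition to evaluate.
#' @param crop \code{"auto"} (aperture crop for standardized capture, default
#'   fixed crop otherwise) or a [crop_spec()].
#' @param params A [feature_params()].
#' @param ratio_threshold Ratio-test threshold.
#' @param target_long_side Common long side after preprocessing.
#' @param fallback_spec Fixed [crop_spec()] used for freehand images and as
#'   the aperture-detection fallback.
#' @return A list of class \code{identification_report}: the condition, both
#'   \code{direction_results}, \code{top1_rate} and \code{top10_rate}
#'   (percent), and the provenance of the run (parameters, crop).
#' @export
identification_report <- function(manifest, condition_name, crop = "auto",
                                  params = feature_params(),
                                  ratio_threshold = 0.75,
                                  target_long_side = 256L,
                                  fallback_spec = default_ear_crop()) {
  validate_manifest(manifest)
  feats <- lapply(1:2, function(v) {
    load_condition_features(manifest, condition_name, v, crop = crop,
                            params = params,
                            target_long_side = target_long_side,
                            fallback_spec = fallback_spec)
  })
  d1 <- identify_direction(feats[[1]], feats[[2]], ratio_threshold)
  d2 <- identify_direction(feats[[2]], feats[[1]], ratio_threshold)
  p1 <- c(d1$top1_correct / d1$n_probes, d2$top1_correct / d2$n_probes)
  p10 <- c(d1$top10_correct / d1$n_probes, d2$top10_correct / d2$n_probes)
  structure(list(
    condition_name = condition_name,
    direction_results = list(d1, d2),
    top1_rate = 100 * mean(p1),
    top10_rate = 100 * mean(p10),
    n_subjects = d1$n_probes,
    provenance = list(params = params, crop = crop,
                      ratio_threshold = ratio_threshold,
                      target_long_side = target_long_side)
  ), class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("Identification report — condition '%s' (%d subjects)\n",
              x$condition_name, x$n_subjects))
  for (d in x$direction_results) {
    cat(sprintf("  gallery visit %d: top-1 %d/%d, top-10 %d/%d\n",
                d$gallery_visit, d$top1_correct, d$n_probes,
                d$top10_correct, d$n_probes))
  }
  cat(sprintf("  averaged top-1 rate:  %.1f%%\n", x$top1_rate))
  cat(sprintf("  averaged top-10 rate: %.1f%%\n", x$top10_rate))
  invisible(x)
}

#' Crop-sensitivity sweep
#'
#' Re-runs the identification report over a strictly increasing grid of crop
#' sizes along one dimension (length = rows or width = columns), holding the
#' other dimension fixed, and differentiates the resulting top-1 accuracy
#' with respect to crop size. A sweep point is flagged sensitive when the
#' magnitude of the adjacent finite-difference slope exceeds
#' \code{sensitive_threshold} (percentage points of accuracy per pixel).
#'
#' @param manifest A cohort manifest.
#' @param condition_name Condition to sweep.
#' @param dimension \code{"length"} or \code{"width"}.
#' @param values Strictly increasing crop sizes, pixels (at least 2).
#' @param fixed_other Fixed size of the other dimension, pixels.
#' @param params A [feature_params()].
#' @param ratio_threshold Ratio-test threshold.
#' @param target_long_side Common long side after preprocessing.
#' @param sensitive_threshold Slope-magnitude threshold, percent per pixel.
#' @return A data frame of class \code{sensitivity_curve}: \code{crop_value},
#'   \code{top1_rate}, \code{slope} (\code{NA} for the first point),
#'   \code{sensitive}.
#' @export
sensitivity_sweep <- function(manifest, condition_name,
                              dimension = c("length", "width"),
                              values, fixed_other = 300L,
                              params = feature_params(),
                              ratio_threshold = 0.75,
                              target_long_side = 256L,
                              sensitive_threshold = 1) {
  dimension <- match.arg(dimension)
  if (length(values) < 2 || any(diff(values) <= 0)) {
    stop_earsift("values must contain at least 2 strictly increasing sizes",
                 "invalid_argument")
  }
  rates <- vapply(values, function(v) {
    spec <- if (dimension == "length") {
      crop_spec(length = v, width = fixed_other)
    } else {
      crop_spec(length = fixed_other, width = v)
    }
    identification_report(manifest, condition_name, crop = spec,
                          params = params, ratio_threshold = ratio_threshold,
                          target_long_side = target_long_side)$top1_rate
  }, numeric(1))
  slope <- c(NA_real_, diff(rates) / diff(values))
  out <- data.frame(crop_value = values, top1_rate = rates, slope = slope,
                    sensitive = !is.na(slope) & abs(slope) > sensitive_threshold)
  attr(out, "swept_dimension") <- dimension
  attr(out, "fixed_other") <- fixed_other
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Export a direction's score matrix as CSV
#'
#' The audit artifact for a run: integer match counts with probe rows and
#' gallery columns, re-sortable by independent scripts to recompute the
#' identification rates.
#'
#' @param direction A \code{direction_result} from [identify_direction()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_matrix <- function(direction, path) {
  write.csv(as.data.frame(direction$score_matrix), path, row.names = TRUE)
  invisible(path)
}
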