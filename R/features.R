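# Scale-invariant feature extraction. Native implementation of the canonical
# SIFT recipe: Gaussian scale-space pyramid, difference-of-Gaussians extrema
# with quadratic sub-pixel refinement, contrast and edge-response filtering,
# gradient-orientation-histogram orientation assignment, and 4x4x8
# gradient-histogram descriptors (clamped at 0.2, renormalized to unit norm).
# A "reference" backend dispatches to an external extractor with matched
# parameters for drift audits.

#' Feature-extraction parameters
#'
#' Defaults follow the canonical published algorithm: 4 octaves, 3 scales per
#' octave, base sigma 1.6 (input assumed pre-blurred at 0.5), contrast
#' threshold 0.03 on \code{[0, 1]} intensities, principal-curvature edge ratio
#' 10, descriptor clamp ceiling 0.2. \code{max_features} caps extraction at
#' the strongest keypoints by DoG response to bound matching cost.
#'
#' @param n_octaves,scales_per_octave Pyramid geometry.
#' @param base_sigma Blur of the first pyramid level, pixels.
#' @param assumed_blur Blur assumed present in the input image, pixels.
#' @param contrast_threshold Minimum refined |DoG| response.
#' @param edge_ratio Maximum principal-curvature ratio.
#' @param refine Logical; quadratic sub-pixel refinement of extrema.
#' @param orientation_bins Bins in the orientation histogram.
#' @param descriptor_clamp Per-entry ceiling before renormalization.
#' @param max_features Cap on keypoints kept per image (strongest first).
#' @return A list of class \code{feature_params}.
#' @export
feature_params <- function(n_octaves = 4L, scales_per_octave = 3L,
                           base_sigma = 1.6, assumed_blur = 0.5,
                           contrast_threshold = 0.03, edge_ratio = 10,
                           refine = TRUE, orientation_bins = 36L,
                           descriptor_clamp = 0.2, max_features = 250L) {
  structure(list(
    n_octaves = as.integer(n_octaves),
    scales_per_octave = as.integer(scales_per_octave),
    base_sigma = base_sigma, assumed_blur = assumed_blur,
    contrast_threshold = contrast_threshold, edge_ratio = edge_ratio,
    refine = isTRUE(refine), orientation_bins = as.integer(orientation_bins),
    descriptor_clamp = descriptor_clamp,
    max_features = as.integer(max_features)
  ), class = "feature_params")
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "ear_image")) image$pixels else image
}

#' Build a Gaussian / difference-of-Gaussians scale-space pyramid
#'
#' Per octave, \code{scales_per_octave + 3} Gaussian planes at sigmas
#' \code{base_sigma * 2^(i / scales_per_octave)} and the
#' \code{scales_per_octave + 2} adjacent differences; octaves downsample by 2.
#'
#' @param image An [ear_image()] or numeric matrix with long side >= 32.
#' @param params A [feature_params()].
#' @return A list of class \code{dog_pyramid}; each octave holds \code{gauss}
#'   and \code{dog} plane lists plus its downsampling factor.
#' @export
build_scale_space <- function(image, params = feature_params()) {
  m <- as_pixel_matrix(image)
  if (max(dim(m)) < 32) {
    stop_earsift("image long side must be at least 32 pixels",
                 "configuration_error")
  }
  if (min(dim(m)) / 2^(params$n_octaves - 1) < 8) {
    stop_earsift("image too small for the requested number of octaves",
                 "configuration_error")
  }
  s <- params$scales_per_octave
  k <- 2^(1 / s)
  base <- gaussian_blur_cpp(m, sqrt(max(0, params$base_sigma^2 -
                                          params$assumed_blur^2)))
  octaves <- vector("list", params$n_octaves)
  for (o in seq_len(params$n_octaves)) {
    gauss <- vector("list", s + 3)
    gauss[[1]] <- base
    for (i in seq_len(s + 2)) {
      sig_prev <- params$base_sigma * k^(i - 1)
      sig_next <- params$base_sigma * k^i
      gauss[[i + 1]] <- gaussian_blur_cpp(gauss[[i]],
                                          sqrt(sig_next^2 - sig_prev^2))
    }
    dog <- vector("list", s + 2)
    for (i in seq_len(s + 2)) dog[[i]] <- gauss[[i + 1]] - gauss[[i]]
    octaves[[o]] <- list(gauss = gauss, dog = dog, factor = 2^(o - 1))
    base <- downsample2_cpp(gauss[[s + 1]]) # the plane at 2 * base_sigma
  }
  structure(list(octaves = octaves, params = params, dim = dim(m)),
            class = "dog_pyramid")
}

# Orientation peaks (>= 80% of max) with parabolic interpolation; returns
# angles in degrees [0, 360).
orientation_peaks <- function(hist) {
  n <- length(hist)
  mx <- max(hist)
  if (mx <= 0) return(0)
  angles <- numeric(0)
  for (i in seq_len(n)) {
    l <- hist[if (i == 1) n else i - 1]
    r <- hist[if (i == n) 1 else i + 1]
    v <- hist[i]
    if (v > l && v > r && v >= 0.8 * mx) {
      denom <- l - 2 * v + r
      off <- if (abs(denom) > 1e-12) 0.5 * (l - r) / denom else 0
      ang <- ((i - 1 + off + 0.5) * 360 / n) %% 360
      angles <- c(angles, ang)
    }
  }
  if (length(angles) == 0) angles <- 0
  angles
}

#' Detect scale-space keypoints
#'
#' 3x3x3 local extrema of the DoG stack, filtered by absolute contrast and
#' edge response, sub-pixel refined, with orientations assigned from the
#' dominant peaks of a 36-bin Gaussian-weighted gradient-orientation
#' histogram (secondary peaks at >= 80\% of the maximum duplicate the
#' keypoint).
#'
#' @param pyramid A [build_scale_space()] result.
#' @return A data frame with one row per oriented keypoint: \code{row},
#'   \code{col} (0-based, input-image frame), \code{scale} (absolute sigma,
#'   pixels), \code{orientation} (degrees, \code{[0, 360)}), \code{octave},
#'   \code{scale_index} (continuous, octave frame), \code{response}.
#' @export
detect_keypoints <- function(pyramid) {
  stopifnot(inherits(pyramid, "dog_pyramid"))
  params <- pyramid$params
  s <- params$scales_per_octave
  out <- list()
  for (o in seq_along(pyramid$octaves)) {
    oct <- pyramid$octaves[[o]]
    ext <- detect_extrema_cpp(oct$dog, params$contrast_threshold,
                              params$edge_ratio, params$refine)
    if (nrow(ext) == 0) next
    for (i in seq_len(nrow(ext))) {
      s_cont <- ext$s[i]
      sigma_oct <- params$base_sigma * 2^(s_cont / s)
      plane_idx <- max(1L, min(s + 3L, as.integer(round(s_cont)) + 1L))
      hist <- orientation_hist_cpp(oct$gauss[[plane_idx]], ext$row[i],
                                   ext$col[i], sigma_oct,
                                   params$orientation_bins)
      for (ang in orientation_peaks(hist)) {
        out[[length(out) + 1L]] <- data.frame(
          row = ext$row[i] * oct$factor,
          col = ext$col[i] * oct$factor,
          scale = sigma_oct * oct$factor,
          orientation = ang,
          octave = o,
          scale_index = s_cont,
          response = ext$response[i]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), scale = numeric(0),
                      orientation = numeric(0), octave = integer(0),
                      scale_index = numeric(0), response = numeric(0)))
  }
  kp <- do.call(rbind, out)
  if (nrow(kp) > params$max_features) {
    kp <- kp[order(-kp$response, kp$row, kp$col), ][seq_len(params$max_features), ]
  }
  # deterministic ordering regardless of detection order
  kp <- kp[order(kp$octave, kp$scale_index, kp$row, kp$col, kp$orientation), ]
  rownames(kp) <- NULL
  kp
}

#' Feature set
#'
#' Keypoints and their descriptors for one image, with the image's identity
#' key. Descriptor rows are unit-norm 128-vectors parallel to keypoint rows;
#' both may be empty for a featureless image.
#'
#' @param keypoints Keypoint data frame (see [detect_keypoints()]).
#' @param descriptors Numeric matrix, \code{nrow(keypoints)} x 128.
#' @param key Named list with \code{subject_id}, \code{visit},
#'   \code{condition}.
#' @param n_dropped Count of keypoints dropped for border proximity.
#' @return An object of class \code{feature_set}.
#' @export
feature_set <- function(keypoints, descriptors, key = list(), n_dropped = 0L) {
  stopifnot(nrow(keypoints) == nrow(descriptors))
  structure(list(keypoints = keypoints, descriptors = descriptors,
                 key = key, n_dropped = as.integer(n_dropped)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set %s: %d keypoints, %d dropped at border>\n",
              if (length(x$key)) format_image_key(x$key$subject_id,
                                                  x$key$visit,
                                                  x$key$condition) else "?",
              nrow(x$keypoints), x$n_dropped))
  invisible(x)
}

#' Compute descriptors for detected keypoints
#'
#' Per keypoint: a 4x4 spatial grid of 8-bin gradient-orientation histograms,
#' sampled from the keypoint's pyramid plane in its scale- and
#' orientation-aligned frame with Gaussian spatial weighting and trilinear
#' scatter, clamped at the configured ceiling and renormalized to unit norm.
#' Keypoints whose sampling window leaves the image are dropped (counted, not
#' an error).
#'
#' @param image An [ear_image()] or matrix (used to rebuild the pyramid when
#'   \code{pyramid} is not supplied).
#' @param keypoints A [detect_keypoints()] data frame.
#' @param params A [feature_params()].
#' @param pyramid Optional pre-built [build_scale_space()] pyramid.
#' @return A [feature_set()].
#' @export
compute_descriptors <- function(image, keypoints, params = feature_params(),
                                pyramid = NULL) {
  if (is.null(pyramid)) pyramid <- build_scale_space(image, params)
  key <- if (inherits(image, "ear_image")) {
    list(subject_id = image$subject_id, visit = image$visit,
         condition = image$condition)
  } else {
    list()
  }
  if (nrow(keypoints) == 0) {
    return(feature_set(keypoints, matrix(numeric(0), 0, 128), key = key))
  }
  s <- params$scales_per_octave
  desc <- matrix(NA_real_, nrow(keypoints), 128)
  keep <- logical(nrow(keypoints))
  for (i in seq_len(nrow(keypoints))) {
    o <- keypoints$octave[i]
    oct <- pyramid$octaves[[o]]
    s_cont <- keypoints$scale_index[i]
    sigma_oct <- params$base_sigma * 2^(s_cont / s)
    plane_idx <- max(1L, min(s + 3L, as.integer(round(s_cont)) + 1L))
    d <- descriptor_cpp(oct$gauss[[plane_idx]],
                        keypoints$row[i] / oct$factor,
                        keypoints$col[i] / oct$factor,
                        sigma_oct, keypoints$orientation[i],
                        params$descriptor_clamp)
    if (length(d) == 128) {
      desc[i, ] <- d
      keep[i] <- TRUE
    }
  }
  feature_set(keypoints[keep, , drop = FALSE],
              desc[keep, , drop = FALSE], key = key,
              n_dropped = sum(!keep))
}

#' Extract scale-invariant features from an image
#'
#' Dispatches to the native extractor or to the external reference extractor
#' with matched parameters; the output type is identical either way. The
#' native path is fully deterministic.
#'
#' @param image An [ear_image()] or numeric matrix.
#' @param backend \code{"native"} or \code{"reference"}.
#' @param params A [feature_params()].
#' @return A [feature_set()].
#' @export
extract_features <- function(image, backend = c("native", "reference"),
                             params = feature_params()) {
  backend <- match.arg(backend)
  if (backend == "reference") {
    return(extract_reference(image, params))
  }
  pyr <- build_scale_space(image, params)
  kp <- detect_keypoints(pyr)
  compute_descriptors(image, kp, params, pyramid = pyr)
}

#' Write / read a feature set as columnar text
#'
#' One row per keypoint: \code{row}, \code{col}, \code{scale},
#' \code{orientation} and the 128 descriptor values — the cache format used
#' between pipeline stages.
#'
#' @param fs A [feature_set()].
#' @param path Output path.
#' @return \code{write_feature_set}: the path, invisibly;
#'   \code{read_feature_set}: a [feature_set()] (keypoint geometry columns
#'   only).
#' @export
write_feature_set <- function(fs, path) {
  tab <- cbind(fs$keypoints[, c("row", "col", "scale", "orientation")],
               as.data.frame(fs$descriptors))
  names(tab) <- c("row", "col", "scale", "orientation",
                  sprintf("d%03d", seq_len(128)))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  tab <- read.csv(path, colClasses = "numeric")
  kp <- tab[, c("row", "col", "scale", "orientation"), drop = FALSE]
  desc <- as.matrix(tab[, -(1:4), drop = FALSE])
  dimnames(desc) <- NULL
  feature_set(kp, desc)
}
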