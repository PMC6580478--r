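# Preprocessing: grayscale conversion, aperture-ring auto-crop, fixed crop,
# and aspect-preserving resize. Everything downstream of preprocessing shares
# one long-side length so feature extraction cost is bounded.

#' Convert a raster to a single-channel intensity image
#'
#' Accepts a 1-channel matrix or a 3-channel (or RGBA, alpha dropped) array,
#' returns intensities in \code{[0, 1]}. 3-channel input is reduced with the
#' given channel weights (ITU-R BT.601 luma by default); 1-channel input
#' passes through weight-free. Integer-scaled input (max > 1) is rescaled by
#' 255.
#'
#' @param raster Numeric matrix (grayscale) or h x w x 3/4 array.
#' @param channel_weights Length-3 weights for R, G, B.
#' @param subject_id,visit,condition Metadata attached to the result.
#' @return An [ear_image()].
#' @export
to_grayscale_single <- function(raster, channel_weights = c(0.299, 0.587, 0.114),
                                subject_id = NA_integer_, visit = NA_integer_,
                                condition = NA_character_) {
  if (is.matrix(raster)) {
    gray <- raster
  } else if (is.array(raster) && length(dim(raster)) == 3 &&
             dim(raster)[3] %in% c(3L, 4L)) {
    if (length(channel_weights) != 3) {
      stop_earsift("channel_weights must have length 3", "format_error")
    }
    gray <- channel_weights[1] * raster[, , 1] +
      channel_weights[2] * raster[, , 2] +
      channel_weights[3] * raster[, , 3]
  } else if (is.array(raster) && length(dim(raster)) == 3 && dim(raster)[3] == 1L) {
    gray <- raster[, , 1]
  } else {
    stop_earsift("raster must be 1-, 3- or 4-channel", "format_error")
  }
  if (max(gray) > 1 + 1e-9) gray <- gray / 255
  ear_image(clamp01(gray), subject_id = subject_id, visit = visit,
            condition = condition)
}

#' Crop window specification
#'
#' A fixed crop window: \code{length} rows (vertical extent, corresponding to
#' ear length) by \code{width} columns (horizontal extent, corresponding to
#' ear width), centered on \code{anchor} (a 0-based (row, col) point) or on
#' the frame center when \code{anchor = "auto"}.
#'
#' @param length,width Window extent in pixels, strictly positive.
#' @param anchor Numeric (row, col) center, or \code{"auto"}.
#' @return An object of class \code{crop_spec}.
#' @export
crop_spec <- function(length, width, anchor = "auto") {
  if (length <= 0 || width <= 0) {
    stop_earsift("crop length and width must be strictly positive",
                 "invalid_crop")
  }
  if (!identical(anchor, "auto") &&
      (!is.numeric(anchor) || length(anchor) != 2)) {
    stop_earsift("anchor must be \"auto\" or a (row, col) point", "invalid_crop")
  }
  structure(list(length = as.integer(length), width = as.integer(width),
                 anchor = anchor),
            class = "crop_spec")
}

#' Automatically crop to the interior of the device aperture ring
#'
#' Detects the dark annulus the capture device leaves in the frame
#' (thresholding at \code{dark_fraction} of the mean intensity, taking the
#' largest connected dark component and requiring it to enclose a hole) and
#' returns the bounding box of the enclosed interior, so the ear occupies a
#' consistent region regardless of frame content outside the device.
#'
#' Output carries a provenance flag; calling this on an already-cropped image
#' returns it unchanged. An image without a detectable ring signals a
#' \code{ring_detection_error}; callers may fall back to [fixed_crop()].
#'
#' @param image An [ear_image()].
#' @param dark_fraction Threshold as a fraction of mean intensity.
#' @param min_interior_fraction Minimum enclosed-hole area as a fraction of
#'   the component bounding box, below which no ring is declared.
#' @return The cropped [ear_image()].
#' @export
auto_crop_aperture <- function(image, dark_fraction = 0.25,
                               min_interior_fraction = 0.25) {
  if (isTRUE(image$provenance$aperture_cropped)) {
    return(image)
  }
  m <- image$pixels
  mask <- m < dark_fraction * mean(m)
  if (!any(mask)) {
    stop_earsift("no dark aperture ring detected", "ring_detection_error")
  }
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)

  # holes: background regions not connected to the image border
  bg_lab <- label_components_cpp(!comp)
  border_labels <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                            bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- !comp & !(bg_lab %in% border_labels)
  dim(hole) <- dim(comp)
  if (!any(hole)) {
    stop_earsift("largest dark component does not enclose an interior (no annulus)",
                 "ring_detection_error")
  }
  ci <- which(comp, arr.ind = TRUE)
  bbox_area <- (diff(range(ci[, 1])) + 1) * (diff(range(ci[, 2])) + 1)
  if (sum(hole) < min_interior_fraction * bbox_area) {
    stop_earsift("enclosed interior too small for an aperture ring",
                 "ring_detection_error")
  }
  hi <- which(hole, arr.ind = TRUE)
  r0 <- min(hi[, 1]); r1 <- max(hi[, 1])
  c0 <- min(hi[, 2]); c1 <- max(hi[, 2])

  out <- image
  out$pixels <- m[r0:r1, c0:c1, drop = FALSE]
  out$provenance$aperture_cropped <- TRUE
  out$provenance$crop_offset <- c(r0, c0) - 1 # 0-based offset of the window
  out$provenance$crop_bbox <- c(r0, r1, c0, c1) - 1
  out
}

#' Fixed-window crop
#'
#' Extracts the \code{length x width} window centered at the spec's anchor
#' (frame center for \code{anchor = "auto"}); no resampling. A window that
#' does not fit inside the image signals an \code{invalid_crop} error.
#'
#' @param image An [ear_image()].
#' @param spec A [crop_spec()].
#' @return The cropped [ear_image()].
#' @export
fixed_crop <- function(image, spec) {
  stopifnot(inherits(spec, "crop_spec"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  if (spec$length > h || spec$width > w) {
    stop_earsift("crop window exceeds image bounds", "invalid_crop")
  }
  anchor <- if (identical(spec$anchor, "auto")) c((h - 1) / 2, (w - 1) / 2) else spec$anchor
  r0 <- round(anchor[1] - spec$length / 2) + 1
  c0 <- round(anchor[2] - spec$width / 2) + 1
  r1 <- r0 + spec$length - 1
  c1 <- c0 + spec$width - 1
  if (r0 < 1 || c0 < 1 || r1 > h || c1 > w) {
    stop_earsift("crop window exceeds image bounds", "invalid_crop")
  }
  out <- image
  out$pixels <- image$pixels[r0:r1, c0:c1, drop = FALSE]
  out$provenance$crop_offset <- c(r0, c0) - 1
  out$provenance$crop_bbox <- c(r0, r1, c0, c1) - 1
  out
}

#' Aspect-preserving bilinear resize
#'
#' Resizes so the long side equals \code{target_long_side}, preserving the
#' aspect ratio, with bilinear interpolation.
#'
#' @param image An [ear_image()].
#' @param target_long_side Target long-side length in pixels (at least 32).
#' @return The resized [ear_image()].
#' @export
resize_image <- function(image, target_long_side = 256L) {
  if (target_long_side < 32) {
    stop_earsift("target_long_side must be at least 32", "invalid_argument")
  }
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  long <- max(h, w)
  if (long == target_long_side) {
    return(image)
  }
  sc <- target_long_side / long
  nh <- if (h >= w) as.integer(target_long_side) else max(32L, as.integer(round(h * sc)))
  nw <- if (w > h) as.integer(target_long_side) else max(32L, as.integer(round(w * sc)))
  out <- image
  out$pixels <- clamp01(resize_bilinear_cpp(image$pixels, nh, nw))
  out$provenance$resize_scale <- c(nh / h, nw / w)
  out
}

#' Default ear-sized crop window
#'
#' The fixed crop used for freehand images (and as the aperture-detection
#' fallback): a frame-centered window sized to the cohort's mean ear at
#' standard scale and position — 260 rows by 170 columns, from mean helix
#' semi-axes of 125 x 82.5 px. Crop length corresponds to ear length and
#' crop width to ear width, so an ear displaced or rescaled by freehand
#' capture is partially clipped, while a standardized, centered ear fits.
#'
#' @return A [crop_spec()].
#' @export
default_ear_crop <- function() {
  crop_spec(length = 260, width = 170, anchor = "auto")
}

# Standard preprocessing for one image of a condition: aperture auto-crop for
# standardized capture (falling back to the fixed spec if no ring is found),
# fixed crop for freehand capture, then resize to the common long side.
preprocess_for_condition <- function(image, condition, crop = "auto",
                                     target_long_side = 256L,
                                     fallback_spec = default_ear_crop()) {
  cropped <- if (inherits(crop, "crop_spec")) {
    fixed_crop(image, crop)
  } else if (identical(condition, "donut")) {
    tryCatch(auto_crop_aperture(image),
             ring_detection_error = function(e) fixed_crop(image, fallback_spec))
  } else {
    fixed_crop(image, fallback_spec)
  }
  resize_image(cropped, target_long_side)
}
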