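#' Ear image container
#'
#' The unit flowing through the pipeline: a single-channel intensity grid in
#' \code{[0, 1]} together with its identity metadata (subject, visit, capture
#' condition) and any provenance the producing step recorded (drawn capture
#' nuisance parameters, ground-truth ear bounding box, aperture geometry,
#' crop offsets). Coordinates are row/col, 0-based, origin top-left.
#'
#' @param pixels Numeric matrix of intensities in \code{[0, 1]}.
#' @param subject_id Integer subject identifier (or \code{NA}).
#' @param visit Visit number, 1 or 2 (or \code{NA}).
#' @param condition Capture-condition label, e.g. \code{"donut"} or
#'   \code{"freehand"} (or \code{NA}).
#' @param provenance Named list of auxiliary facts recorded by the producer.
#' @return An object of class \code{ear_image}.
#' @export
ear_image <- function(pixels, subject_id = NA_integer_, visit = NA_integer_,
                      condition = NA_character_, provenance = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_earsift("pixels must be a numeric matrix", "format_error")
  }
  if (nrow(pixels) < 32 || ncol(pixels) < 32) {
    stop_earsift("ear images must be at least 32x32 pixels", "format_error")
  }
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop_earsift("intensities must lie in [0, 1]", "format_error")
  }
  structure(
    list(
      pixels = pixels,
      subject_id = as.integer(subject_id),
      visit = as.integer(visit),
      condition = as.character(condition),
      provenance = provenance
    ),
    class = "ear_image"
  )
}

#' @export
print.ear_image <- function(x, ...) {
  cat(sprintf(
    "<ear_image %dx%d subject=%s visit=%s condition=%s>\n",
    nrow(x$pixels), ncol(x$pixels),
    ifelse(is.na(x$subject_id), "?", x$subject_id),
    ifelse(is.na(x$visit), "?", x$visit),
    ifelse(is.na(x$condition), "?", x$condition)
  ))
  invisible(x)
}

#' @export
dim.ear_image <- function(x) dim(x$pixels)

image_key <- function(img) {
  format_image_key(img$subject_id, img$visit, img$condition)
}

#' Read an ear image from a PNG file
#'
#' Reads a PNG (grayscale or RGB), converts it to a single-channel intensity
#' grid via [to_grayscale_single()], and attaches identity metadata.
#'
#' @param path Path to a PNG file.
#' @param subject_id,visit,condition Identity metadata to attach.
#' @return An [ear_image()].
#' @export
read_ear_png <- function(path, subject_id = NA_integer_, visit = NA_integer_,
                         condition = NA_character_) {
  if (!file.exists(path)) {
    stop_earsift(sprintf("image file not found: %s", path), "io_error")
  }
  raster <- png::readPNG(path)
  to_grayscale_single(raster, subject_id = subject_id, visit = visit,
                      condition = condition)
}
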