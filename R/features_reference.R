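# Reference feature backend: scikit-image's SIFT run out of process with
# parameters matched to the native extractor (upsampling disabled, same
# pyramid geometry and thresholds). Used as an independent audit of the
# native implementation, never as the pipeline path.

reference_backend_cache <- new.env(parent = emptyenv())

#' Is the reference feature backend available?
#'
#' Checks once per session for a `python` interpreter with scikit-image.
#'
#' @return Logical scalar.
#' @export
reference_backend_available <- function() {
  if (!is.null(reference_backend_cache$ok)) {
    return(reference_backend_cache$ok)
  }
  ok <- nzchar(Sys.which("python"))
  if (ok) {
    status <- suppressWarnings(system2(
      "python", c("-c", shQuote("import skimage.feature")),
      stdout = FALSE, stderr = FALSE
    ))
    ok <- identical(status, 0L)
  }
  reference_backend_cache$ok <- ok
  ok
}

extract_reference <- function(image, params = feature_params()) {
  if (!reference_backend_available()) {
    stop_earsift("reference backend requires python with scikit-image",
                 "backend_error")
  }
  m <- as_pixel_matrix(image)
  script <- system.file("python", "skimage_sift.py", package = "earsift")
  in_txt <- tempfile(fileext = ".txt")
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(in_txt, out_csv)), add = TRUE)
  utils::write.table(m, in_txt, row.names = FALSE, col.names = FALSE)
  status <- system2("python", c(
    shQuote(script), shQuote(in_txt), shQuote(out_csv),
    params$n_octaves, params$scales_per_octave,
    params$base_sigma, params$contrast_threshold / params$scales_per_octave,
    params$edge_ratio
  ), stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L) || !file.exists(out_csv)) {
    stop_earsift("reference backend failed", "backend_error")
  }
  key <- if (inherits(image, "ear_image")) {
    list(subject_id = image$subject_id, visit = image$visit,
         condition = image$condition)
  } else {
    list()
  }
  info <- file.info(out_csv)
  if (is.na(info$size) || info$size == 0) {
    kp <- data.frame(row = numeric(0), col = numeric(0), scale = numeric(0),
                     orientation = numeric(0), octave = integer(0),
                     scale_index = numeric(0), response = numeric(0))
    return(feature_set(kp, matrix(numeric(0), 0, 128), key = key))
  }
  tab <- utils::read.csv(out_csv, header = FALSE)
  kp <- data.frame(row = tab[[1]], col = tab[[2]], scale = tab[[3]],
                   orientation = tab[[4]], octave = NA_integer_,
                   scale_index = NA_real_, response = NA_real_)
  desc <- as.matrix(tab[, 5:132, drop = FALSE])
  dimnames(desc) <- NULL
  if (nrow(kp) > params$max_features) {
    keep <- seq_len(params$max_features)
    kp <- kp[keep, , drop = FALSE]
    desc <- desc[keep, , drop = FALSE]
  }
  feature_set(kp, desc, key = key)
}
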