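# Synthetic paired-visit ear-image cohort.
#
# Emulates a field study in which each subject contributes four images of the
# same (left) ear: two "visits" under a standardized capture device that fixes
# scale, rotation, centering, lighting and occlusion (and leaves a dark
# aperture ring in the frame that downstream auto-cropping keys on), and two
# visits of unstandardized freehand capture where all of those nuisances are
# randomized. Ears are procedural — helix / antihelix / concha / lobe / tragus
# curves plus subject-specific texture — not photorealistic: the pipeline only
# needs high-contrast structure that is stable within subject and variable
# between subjects.

DEFAULT_FRAME <- c(480L, 360L)
APERTURE_INNER_RADIUS <- 150
APERTURE_OUTER_RADIUS <- 172
SKIN_BASE <- 0.72
MAX_ABS_TRANSLATION <- 0.35

#' Capture-condition model
#'
#' Describes the distribution of capture nuisances for one condition. Every
#' range is an ordered (min, max) pair; a degenerate range (min == max) pins
#' the nuisance. The standardized ("donut") condition pins rotation,
#' translation, scale, illumination and occlusion and renders the device's
#' dark aperture annulus; the freehand condition randomizes all of them.
#'
#' @param condition_name Condition label, e.g. \code{"donut"} or
#'   \code{"freehand"}.
#' @param rotation_range In-plane rotation, degrees (min, max).
#' @param translation_range Translation as a fraction of the frame per axis
#'   (min, max); absolute values above 0.35 are rejected because they could
#'   push the entire ear out of frame.
#' @param scale_range Unitless scale multiplier (min, max).
#' @param illumination_gradient_strength Peak linear illumination gradient as
#'   a fraction of dynamic range (min, max), direction drawn uniformly.
#' @param gamma_range Gamma jitter (min, max).
#' @param occlusion_fraction_range Fraction of ear area covered by dark
#'   hair-like strokes (min, max), each in \code{[0, 1]}.
#' @param aperture_ring Logical; render the dark device-aperture annulus.
#' @param sensor_noise_sd Additive Gaussian sensor noise, intensity units.
#' @return An object of class \code{capture_model}.
#' @export
capture_model <- function(condition_name,
                          rotation_range = c(0, 0),
                          translation_range = c(0, 0),
                          scale_range = c(1, 1),
                          illumination_gradient_strength = c(0, 0),
                          gamma_range = c(1, 1),
                          occlusion_fraction_range = c(0, 0),
                          aperture_ring = FALSE,
                          sensor_noise_sd = 0.01) {
  ranges <- list(
    rotation_range = rotation_range,
    translation_range = translation_range,
    scale_range = scale_range,
    illumination_gradient_strength = illumination_gradient_strength,
    gamma_range = gamma_range,
    occlusion_fraction_range = occlusion_fraction_range
  )
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop_earsift(sprintf("%s must be an ordered (min, max) pair", nm),
                   "invalid_capture_model")
    }
  }
  if (any(occlusion_fraction_range < 0) || any(occlusion_fraction_range > 1)) {
    stop_earsift("occlusion fractions must lie in [0, 1]",
                 "invalid_capture_model")
  }
  if (any(illumination_gradient_strength < 0) ||
      any(illumination_gradient_strength > 1)) {
    stop_earsift("illumination gradient strengths must lie in [0, 1]",
                 "invalid_capture_model")
  }
  if (max(abs(translation_range)) > MAX_ABS_TRANSLATION) {
    stop_earsift(sprintf(
      "translation range beyond +/-%.2f of the frame could push the ear out of frame",
      MAX_ABS_TRANSLATION
    ), "invalid_capture_model")
  }
  if (any(scale_range <= 0)) {
    stop_earsift("scale multipliers must be strictly positive",
                 "invalid_capture_model")
  }
  if (sensor_noise_sd < 0) {
    stop_earsift("sensor_noise_sd must be non-negative", "invalid_capture_model")
  }
  structure(
    c(list(condition_name = as.character(condition_name)), ranges,
      list(aperture_ring = isTRUE(aperture_ring),
           sensor_noise_sd = sensor_noise_sd)),
    class = "capture_model"
  )
}

#' Default standardized-capture model
#'
#' All geometric and photometric nuisances pinned; the device's dark aperture
#' annulus is rendered so the auto-crop can find it. Only sensor noise
#' distinguishes a subject's two visits.
#'
#' @param sensor_noise_sd Additive sensor noise standard deviation.
#' @return A [capture_model()].
#' @export
donut_capture_model <- function(sensor_noise_sd = 0.01) {
  capture_model("donut", aperture_ring = TRUE, sensor_noise_sd = sensor_noise_sd)
}

#' Default freehand-capture model
#'
#' Wide nuisance ranges emulating uncontrolled field capture: rotation within
#' 15 degrees, translation within 15\% of the frame, scale 0.75-1.30,
#' illumination gradients up to 40\% of dynamic range, gamma 0.8-1.25 and
#' hair-like occlusion covering up to 25\% of the ear.
#'
#' @param sensor_noise_sd Additive sensor noise standard deviation.
#' @return A [capture_model()].
#' @export
freehand_capture_model <- function(sensor_noise_sd = 0.01) {
  capture_model(
    "freehand",
    rotation_range = c(-15, 15),
    translation_range = c(-0.15, 0.15),
    scale_range = c(0.75, 1.30),
    illumination_gradient_strength = c(0, 0.40),
    gamma_range = c(0.80, 1.25),
    occlusion_fraction_range = c(0, 0.25)
  )
}

#' Sample a subject's ear shape
#'
#' Draws the anatomical parameters of one subject's ear from fixed
#' distributions, deterministically for a given (subject, cohort seed) pair.
#' The distributions are wide enough that different subjects render visibly
#' different structure — the premise a capture-standardization study tests.
#'
#' @param subject_id Positive integer subject identifier.
#' @param cohort_seed Integer seed of the cohort.
#' @param frame Frame dimensions (rows, cols) the shape must fit at unit scale.
#' @return An object of class \code{ear_shape}.
#' @export
sample_ear_shape <- function(subject_id, cohort_seed, frame = DEFAULT_FRAME) {
  if (!is.numeric(subject_id) || length(subject_id) != 1 || subject_id < 1) {
    stop_earsift("subject_id must be a positive integer", "invalid_argument")
  }
  subject_id <- as.integer(subject_id)
  centre <- (frame - 1) / 2
  stream <- derive_stream(cohort_seed, subject_id, salt = 0L)
  shape <- with_stream(stream, {
    list(
      subject_id = subject_id,
      helix_axes = c(runif(1, 110, 140), runif(1, 70, 95)),
      antihelix_offset = runif(1, 18, 34),
      concha_center = c(centre[1] + runif(1, 5, 35),
                        centre[2] - runif(1, 0, 20)),
      concha_radius = runif(1, 24, 42),
      lobe_extent = runif(1, 30, 55),
      tragus_size = runif(1, 8, 16),
      texture_seed = sample.int(MOD31 - 1L, 1L)
    )
  })
  stopifnot(
    all(shape$helix_axes > 0),
    shape$antihelix_offset < min(shape$helix_axes),
    shape$helix_axes[1] < frame[1] / 2,
    shape$helix_axes[2] < frame[2] / 2
  )
  structure(shape, class = "ear_shape")
}

# Render the subject's canonical (nuisance-free) ear into the frame:
# helix/antihelix ellipse strokes, concha bowl and rim, lobe and tragus arcs,
# subject-specific macro blobs and fine texture. Deterministic per shape.
render_canonical_ear <- function(shape, frame = DEFAULT_FRAME) {
  h <- frame[1]; w <- frame[2]
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  rr <- matrix(seq_len(h) - 1, h, w)
  ccm <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)

  tex <- with_stream(shape$texture_seed, {
    list(
      fine = matrix(rnorm(h * w), h, w),
      mottle = matrix(rnorm(h * w), h, w),
      blobs = data.frame(
        r = runif(30, cr - shape$helix_axes[1], cr + shape$helix_axes[1]),
        c = runif(30, cc - shape$helix_axes[2], cc + shape$helix_axes[2]),
        rad = runif(30, 3, 9),
        amp = runif(30, -0.18, 0.18)
      )
    )
  })
  fine <- gaussian_blur_cpp(tex$fine, 2.0)
  fine <- fine / sd(fine)
  mottle <- gaussian_blur_cpp(tex$mottle, 12)
  mottle <- mottle / sd(mottle)

  a <- shape$helix_axes[1]; b <- shape$helix_axes[2]
  en <- sqrt(((rr - cr) / a)^2 + ((ccm - cc) / b)^2)
  wn <- 4 / sqrt(a * b) # ~4 px stroke width in normalized ellipse units
  helix <- exp(-((en - 1) / wn)^2)

  a2 <- a - shape$antihelix_offset; b2 <- b - shape$antihelix_offset
  en2 <- sqrt(((rr - cr) / a2)^2 + ((ccm - cc) / b2)^2)
  antihelix <- exp(-((en2 - 1) / wn)^2) * (rr < shape$concha_center[1])

  dcon <- sqrt((rr - shape$concha_center[1])^2 + (ccm - shape$concha_center[2])^2)
  concha_bowl <- exp(-(dcon / shape$concha_radius)^2 * 1.2)
  concha_rim <- exp(-((dcon - shape$concha_radius) / 2.5)^2)

  lobe_c <- c(cr + 0.78 * a, cc - 0.15 * b)
  dlobe <- sqrt((rr - lobe_c[1])^2 + (ccm - lobe_c[2])^2)
  lobe <- exp(-((dlobe - shape$lobe_extent / 2) / 3)^2)

  trag_c <- c(shape$concha_center[1] + 0.2 * shape$concha_radius,
              shape$concha_center[2] - shape$concha_radius - shape$tragus_size)
  dtr <- sqrt((rr - trag_c[1])^2 + (ccm - trag_c[2])^2)
  tragus <- exp(-((dtr - shape$tragus_size) / 2.5)^2)

  ear_mask <- en < 1.04
  blob_map <- matrix(0, h, w)
  for (i in seq_len(nrow(tex$blobs))) {
    bl <- tex$blobs[i, ]
    r0 <- max(1, floor(bl$r - 3 * bl$rad)); r1 <- min(h, ceiling(bl$r + 3 * bl$rad))
    c0 <- max(1, floor(bl$c - 3 * bl$rad)); c1 <- min(w, ceiling(bl$c + 3 * bl$rad))
    if (r0 > r1 || c0 > c1) next
    sub_r <- rr[r0:r1, c0:c1]; sub_c <- ccm[r0:r1, c0:c1]
    d2 <- (sub_r - bl$r)^2 + (sub_c - bl$c)^2
    blob_map[r0:r1, c0:c1] <- blob_map[r0:r1, c0:c1] + bl$amp * exp(-d2 / (2 * bl$rad^2))
  }

  img <- SKIN_BASE + 0.05 * mottle + (0.08 * fine + blob_map) * ear_mask
  img <- img - 0.50 * helix - 0.38 * antihelix - 0.33 * concha_bowl -
    0.30 * concha_rim - 0.32 * lobe - 0.30 * tragus
  img <- pmin(pmax(img, 0.02), 0.98)

  idx <- which(ear_mask, arr.ind = TRUE)
  bbox <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])) - 1 # 0-based
  list(pixels = img, ear_mask = ear_mask, ear_bbox = bbox)
}

# Dark hair stroke along a line segment; modifies img/mask on a local window.
draw_stroke <- function(img, stroke_mask, p0, tilt_deg, len, halfw,
                        hair_value = 0.12) {
  h <- nrow(img); w <- ncol(img)
  a <- tilt_deg * pi / 180
  dirv <- c(cos(a), sin(a)) # mostly downward (+row)
  p1 <- p0 + len * dirv
  r0 <- max(1, floor(min(p0[1], p1[1]) - halfw - 2) + 1)
  r1 <- min(h, ceiling(max(p0[1], p1[1]) + halfw + 2) + 1)
  c0 <- max(1, floor(min(p0[2], p1[2]) - halfw - 2) + 1)
  c1 <- min(w, ceiling(max(p0[2], p1[2]) + halfw + 2) + 1)
  if (r0 > r1 || c0 > c1) return(list(img = img, stroke_mask = stroke_mask))
  rs <- matrix(r0:r1 - 1, r1 - r0 + 1, c1 - c0 + 1)
  cs <- matrix(c0:c1 - 1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
  drm <- rs - p0[1]; dcm <- cs - p0[2]
  t <- pmin(len, pmax(0, drm * dirv[1] + dcm * dirv[2]))
  dist <- sqrt((drm - t * dirv[1])^2 + (dcm - t * dirv[2])^2)
  m <- pmax(0, 1 - (dist / halfw)^2)
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] * (1 - m) + hair_value * m
  stroke_mask[r0:r1, c0:c1] <- stroke_mask[r0:r1, c0:c1] | (m > 0.3)
  list(img = img, stroke_mask = stroke_mask)
}

#' Render one captured image of a subject's ear
#'
#' Renders the subject's canonical ear and applies, in order: scale, in-plane
#' rotation, translation (each drawn from the capture model for this
#' (subject, visit, condition) tuple), a linear illumination gradient with
#' random direction, gamma jitter, hair-like occlusion strokes covering the
#' drawn fraction of ear area, the dark device-aperture annulus when the model
#' requests it, and finally additive sensor noise. Fully reproducible from
#' \code{(shape, model, visit, cohort_seed)}.
#'
#' @param shape An [sample_ear_shape()] result.
#' @param model A [capture_model()].
#' @param visit Visit number, 1 or 2.
#' @param cohort_seed Integer cohort seed.
#' @param canonical Optional precomputed canonical render (internal reuse).
#' @param frame Frame dimensions (rows, cols).
#' @param occlusion Logical; set \code{FALSE} to skip occlusion rendering
#'   (the drawn occlusion fraction is still consumed so the remaining random
#'   stream is unchanged).
#' @return An [ear_image()] whose \code{provenance} records the drawn capture
#'   parameters, the warped ear bounding box, and the aperture geometry.
#' @export
render_capture <- function(shape, model, visit, cohort_seed, canonical = NULL,
                           frame = DEFAULT_FRAME, occlusion = TRUE) {
  if (!inherits(model, "capture_model")) {
    stop_earsift("model must be a capture_model", "invalid_capture_model")
  }
  if (!visit %in% c(1, 2)) {
    stop_earsift("visit must be 1 or 2", "invalid_argument")
  }
  if (is.null(canonical)) canonical <- render_canonical_ear(shape, frame)
  h <- frame[1]; w <- frame[2]
  cr <- (h - 1) / 2; cc <- (w - 1) / 2
  stream <- derive_stream(cohort_seed, shape$subject_id, as.integer(visit),
                          condition_code(model$condition_name), salt = 1L)

  with_stream(stream, {
    rot <- runif(1, model$rotation_range[1], model$rotation_range[2])
    tr_frac <- runif(2, model$translation_range[1], model$translation_range[2])
    sc <- runif(1, model$scale_range[1], model$scale_range[2])
    illum_s <- runif(1, model$illumination_gradient_strength[1],
                     model$illumination_gradient_strength[2])
    illum_dir <- runif(1, 0, 2 * pi)
    gam <- runif(1, model$gamma_range[1], model$gamma_range[2])
    occl_frac <- runif(1, model$occlusion_fraction_range[1],
                       model$occlusion_fraction_range[2])

    # backward-mapped affine: p_in = ctr + R^{-1} (p_out - ctr - t) / s
    th <- rot * pi / 180
    ct <- cos(th); st <- sin(th)
    tvec <- tr_frac * c(h, w)
    minv <- matrix(0, 2, 3)
    minv[1, 1] <- ct / sc;  minv[1, 2] <- st / sc
    minv[2, 1] <- -st / sc; minv[2, 2] <- ct / sc
    off <- c(cr, cc) + tvec
    minv[1, 3] <- cr - (minv[1, 1] * off[1] + minv[1, 2] * off[2])
    minv[2, 3] <- cc - (minv[2, 1] * off[1] + minv[2, 2] * off[2])
    img <- warp_affine_cpp(canonical$pixels, minv, h, w, SKIN_BASE)
    mask <- warp_affine_cpp(canonical$ear_mask + 0, minv, h, w, 0) > 0.5

    rr <- matrix(seq_len(h) - 1, h, w)
    ccm <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)

    if (illum_s > 0) {
      u <- (cos(illum_dir) * (rr - cr) + sin(illum_dir) * (ccm - cc)) /
        (0.5 * sqrt(h^2 + w^2))
      img <- img * (1 + illum_s * u)
    }
    img <- clamp01(img)^gam

    n_strokes <- 0L
    if (occl_frac > 0 && isTRUE(occlusion) && any(mask)) {
      target <- occl_frac * sum(mask)
      stroke_mask <- matrix(FALSE, h, w)
      idx <- which(mask, arr.ind = TRUE)
      bb <- c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])) - 1
      for (k in seq_len(80)) {
        p0 <- c(runif(1, bb[1] - 15, bb[1] + 0.3 * (bb[2] - bb[1])),
                runif(1, bb[3], bb[4]))
        tilt <- runif(1, -30, 30)
        halfw <- runif(1, 2.5, 5)
        res <- draw_stroke(img, stroke_mask, p0, tilt, len = h, halfw = halfw)
        img <- res$img; stroke_mask <- res$stroke_mask
        n_strokes <- n_strokes + 1L
        if (sum(stroke_mask & mask) >= target) break
      }
    }

    aperture <- NULL
    if (isTRUE(model$aperture_ring)) {
      dring <- sqrt((rr - cr)^2 + (ccm - cc)^2)
      m <- pmax(0, pmin(1, (dring - APERTURE_INNER_RADIUS) / 1.5)) -
        pmax(0, pmin(1, (dring - APERTURE_OUTER_RADIUS) / 1.5))
      img <- img * (1 - m) + 0.02 * m
      aperture <- list(center = c(cr, cc),
                       inner_radius = APERTURE_INNER_RADIUS,
                       outer_radius = APERTURE_OUTER_RADIUS)
    }

    if (model$sensor_noise_sd > 0) {
      img <- img + matrix(rnorm(h * w, 0, model$sensor_noise_sd), h, w)
    }
    img <- clamp01(img)

    ear_bbox <- if (any(mask)) {
      idx <- which(mask, arr.ind = TRUE)
      c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])) - 1
    } else {
      rep(NA_real_, 4)
    }

    ear_image(
      img, subject_id = shape$subject_id, visit = visit,
      condition = model$condition_name,
      provenance = list(
        capture = list(rotation = rot, translation = tr_frac, scale = sc,
                       illumination_strength = illum_s,
                       illumination_direction = illum_dir, gamma = gam,
                       occlusion_fraction = occl_frac, n_strokes = n_strokes),
        ear_bbox = ear_bbox,
        aperture = aperture,
        frame = frame
      )
    )
  })
}

#' Generate a synthetic paired-visit cohort
#'
#' Writes \code{4 * n_subjects} PNG files (two visits under each of the two
#' capture conditions per subject) plus a manifest CSV, all a pure function of
#' \code{(n_subjects, models, cohort_seed)}.
#'
#' @param n_subjects Number of subjects (at least 2).
#' @param donut_model,freehand_model [capture_model()]s for the standardized
#'   and freehand conditions.
#' @param cohort_seed Integer cohort seed.
#' @param out_dir Output directory (created if needed).
#' @return A \code{cohort_manifest}: a data frame with columns
#'   \code{subject_id}, \code{visit}, \code{condition}, \code{file_path}
#'   (paths relative to \code{out_dir}), carrying attributes \code{dir} and
#'   \code{cohort_seed}.
#' @export
generate_cohort <- function(n_subjects, donut_model = donut_capture_model(),
                            freehand_model = freehand_capture_model(),
                            cohort_seed = 1L, out_dir) {
  if (n_subjects < 2) {
    stop_earsift("a cohort needs at least 2 subjects", "invalid_argument")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_earsift(sprintf("cannot create output directory: %s", out_dir),
                 "io_error")
  }
  models <- list(donut = donut_model, freehand = freehand_model)
  rows <- vector("list", 4L * n_subjects)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    shape <- sample_ear_shape(s, cohort_seed)
    canonical <- render_canonical_ear(shape)
    for (cond in names(models)) {
      for (v in 1:2) {
        img <- render_capture(shape, models[[cond]], v, cohort_seed,
                              canonical = canonical)
        fname <- sprintf("s%03d_v%d_%s.png", s, v, cond)
        png::writePNG(img$pixels, file.path(out_dir, fname))
        i <- i + 1L
        rows[[i]] <- data.frame(subject_id = s, visit = v, condition = cond,
                                file_path = fname, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- new_cohort_manifest(manifest, dir = out_dir,
                                  cohort_seed = cohort_seed)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Ground-truth aperture interior bounding box
#'
#' The bounding box (0-based, \code{c(rmin, rmax, cmin, cmax)}) of the pixels
#' strictly inside the rendered aperture annulus, used to audit the automatic
#' ring-detection crop.
#'
#' @param frame Frame dimensions (rows, cols).
#' @return Numeric length-4 vector.
#' @export
aperture_interior_bbox <- function(frame = DEFAULT_FRAME) {
  cr <- (frame[1] - 1) / 2; cc <- (frame[2] - 1) / 2
  r <- APERTURE_INNER_RADIUS
  c(ceiling(cr - r), floor(cr + r), ceiling(cc - r), floor(cc + r))
}
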