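# Cohort manifest I/O and validation. A manifest is a data frame with one row
# per image (subject_id, visit, condition, file_path) and exactly four rows
# per subject: two visits under each of the two capture conditions.

new_cohort_manifest <- function(df, dir = ".", cohort_seed = NA_integer_) {
  df <- df[, c("subject_id", "visit", "condition", "file_path")]
  df$subject_id <- as.integer(df$subject_id)
  df$visit <- as.integer(df$visit)
  df$condition <- as.character(df$condition)
  df$file_path <- as.character(df$file_path)
  rownames(df) <- NULL
  structure(df, dir = dir, cohort_seed = cohort_seed,
            class = c("cohort_manifest", "data.frame"))
}

#' Validate a cohort manifest
#'
#' Checks the required columns, uniqueness of (subject, visit, condition)
#' triples, and the four-records-per-subject invariant (two visits under each
#' condition), reporting every offending subject by id.
#'
#' @param manifest A manifest data frame.
#' @param check_files Logical; also require every referenced image file to
#'   exist under the manifest's directory.
#' @return The manifest, invisibly, or an error describing the violations.
#' @export
validate_manifest <- function(manifest, check_files = FALSE) {
  required <- c("subject_id", "visit", "condition", "file_path")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    stop_earsift(sprintf("manifest is missing columns: %s",
                         paste(missing_cols, collapse = ", ")),
                 "manifest_inconsistency")
  }
  key <- paste(manifest$subject_id, manifest$visit, manifest$condition)
  if (anyDuplicated(key)) {
    stop_earsift(sprintf("duplicate (subject, visit, condition) triples: %s",
                         paste(unique(key[duplicated(key)]), collapse = "; ")),
                 "manifest_inconsistency")
  }
  bad <- vapply(split(manifest, manifest$subject_id), function(sub) {
    !(nrow(sub) == 4 &&
        all(sort(paste(sub$condition, sub$visit)) ==
              sort(c("donut 1", "donut 2", "freehand 1", "freehand 2"))))
  }, logical(1))
  if (any(bad)) {
    stop_earsift(sprintf("incomplete image sets for subject(s): %s",
                         paste(names(bad)[bad], collapse = ", ")),
                 "manifest_inconsistency")
  }
  if (check_files) {
    paths <- file.path(attr(manifest, "dir") %||% ".", manifest$file_path)
    gone <- paths[!file.exists(paths)]
    if (length(gone)) {
      stop_earsift(sprintf("missing image files: %s",
                           paste(utils::head(gone, 5), collapse = ", ")),
                   "manifest_inconsistency")
    }
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort manifest CSV
#'
#' The CSV carries the header
#' \code{subject_id,visit,condition,file_path}; file paths are relative to
#' the CSV's directory. Reading validates the cohort invariants.
#'
#' @param manifest A cohort manifest.
#' @param path CSV path.
#' @return \code{write_manifest}: the path, invisibly;
#'   \code{read_manifest}: a validated \code{cohort_manifest}.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(as.data.frame(manifest)[, c("subject_id", "visit", "condition",
                                        "file_path")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param cohort_seed Optional seed recorded on the returned manifest.
#' @export
read_manifest <- function(path, cohort_seed = NA_integer_) {
  if (!file.exists(path)) {
    stop_earsift(sprintf("manifest not found: %s", path), "io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  m <- new_cohort_manifest(df, dir = dirname(path), cohort_seed = cohort_seed)
  validate_manifest(m)
  m
}
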