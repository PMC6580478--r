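# Internal helpers: seeded random streams, key formatting, config hashing.

MOD31 <- 2147483647

# Deterministic per-image stream id from the cohort seed and the image's
# identity tuple (Horner mix, kept below 2^31 so set.seed() accepts it).
derive_stream <- function(cohort_seed, subject_id = 0L, visit = 0L,
                          condition = 0L, salt = 0L) {
  x <- abs(as.numeric(cohort_seed)) %% MOD31
  for (d in c(subject_id, visit, condition, salt)) {
    x <- (x * 31 + as.numeric(d)) %% MOD31
  }
  as.integer(x)
}

condition_code <- function(condition_name) {
  match(condition_name, c("donut", "freehand"))
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_stream <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

format_image_key <- function(subject_id, visit, condition) {
  sprintf("s%03d_v%d_%s", as.integer(subject_id), as.integer(visit), condition)
}

# dim-preserving clamp (pmin/pmax with a scalar first arg drop attributes)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Short stable hash of a configuration
#'
#' djb2-style string hash used to stamp run outputs so artifacts can be
#' traced back to the exact parameter set that produced them.
#'
#' @param x An R object (deparsed before hashing) or a single string.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(x) {
  if (!is.character(x) || length(x) != 1L) {
    x <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  }
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

stop_earsift <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "earsift_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}
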