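CASCADE_ARCHIVE_VERSION <- 1L

#' Save a trained cascade to a versioned archive
#'
#' The archive is an RDS file carrying a format version, a digest of the
#' schema it was trained under, the generation order, the fitted
#' question-model banks and the training provenance (seed, backend, per-step
#' record counts).
#'
#' @param model a `synthq_cascade`
#' @param path destination file (conventionally `.rds`)
#' @return `path`, invisibly
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "synthq_cascade"))
  payload <- list(
    version = CASCADE_ARCHIVE_VERSION,
    schema_digest = schema_digest(model$schema),
    model = model
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Load a cascade archive
#' @param path archive written by [save_cascade()]
#' @return a `synthq_cascade`
#' @export
load_cascade <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  payload <- readRDS(path)
  if (!identical(payload$version, CASCADE_ARCHIVE_VERSION)) {
    stop("unsupported cascade archive version: ", payload$version,
         call. = FALSE)
  }
  if (!identical(payload$schema_digest, schema_digest(payload$model$schema))) {
    stop("cascade archive is corrupt: schema digest mismatch", call. = FALSE)
  }
  payload$model
}

# digest of the schema's structural content
schema_digest <- function(schema) {
  parts <- unlist(lapply(schema$questionnaires, function(q) {
    c(q$name, q$questions, q$answer_min, q$answer_max,
      vapply(q$subscales, function(s)
        paste(s$name, s$subject, paste(s$items, collapse = ","),
              sep = ";"), ""))
  }))
  text_digest(parts)
}
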