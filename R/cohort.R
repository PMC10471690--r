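#' Cohort tables
#'
#' A `synthq_cohort` holds one row per patient and one integer column per
#' questionnaire item, in schema block order, together with a per-record,
#' per-questionnaire presence indicator. Missingness is block-level: a record
#' either answered a questionnaire completely (a validated register) or the
#' whole block is missing. Partially answered blocks are rejected at load
#' time, or dropped to missing under the `"drop-partial"` policy.
#'
#' @name synthq_cohort
#' @keywords internal
NULL

new_cohort <- function(values, present, record_ids, schema) {
  structure(
    list(values = values, present = present,
         record_ids = record_ids, schema = schema),
    class = "synthq_cohort"
  )
}

#' Validate a raw answers table against a schema
#'
#' @param table data.frame with columns `<prefix>_q<index>` (e.g. `sf36_q1`)
#'   and optionally `record_id`; empty/`NA` cells mark missing answers. A
#'   questionnaire block may be absent from the header entirely, in which case
#'   it is missing for every record.
#' @param schema a `synthq_schema`
#' @param policy `"reject"` (default) errors on partial blocks or out-of-rank
#'   values; `"drop-partial"` masks the offending block to missing instead.
#' @param quiet suppress the per-questionnaire validation summary
#' @return a `synthq_cohort`
#' @export
validate_cohort <- function(table, schema, policy = c("reject", "drop-partial"),
                            quiet = FALSE) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(table))
  cols <- item_columns(schema)
  extra <- setdiff(names(table), c("record_id", cols))
  if (length(extra) > 0) {
    stop("unknown column(s) in cohort table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  record_ids <- if ("record_id" %in% names(table)) {
    as.character(table$record_id)
  } else {
    as.character(seq_len(n))
  }
  values <- matrix(NA_integer_, nrow = n, ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (cn in intersect(cols, names(table))) {
    v <- table[[cn]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    values[, cn] <- as.integer(v)
  }
  qnames <- questionnaire_names(schema)
  present <- matrix(FALSE, nrow = n, ncol = length(qnames),
                    dimnames = list(NULL, qnames))
  for (q in schema$questionnaires) {
    idx <- block_columns(schema, q$name)
    block <- values[, idx, drop = FALSE]
    n_answered <- rowSums(!is.na(block))
    complete <- n_answered == q$questions
    partial <- n_answered > 0 & !complete
    in_rank <- is.na(block) | (block >= q$answer_min & block <= q$answer_max)
    bad_rank <- rowSums(!in_rank) > 0
    if (policy == "reject") {
      if (any(bad_rank)) {
        cell <- which(!in_rank, arr.ind = TRUE)[1, ]
        stop(sprintf(
          "out-of-rank value in %s: record '%s', column '%s' = %d (allowed %d..%d)",
          q$name, record_ids[cell[1]], cols[idx][cell[2]],
          block[cell[1], cell[2]], q$answer_min, q$answer_max), call. = FALSE)
      }
      if (any(partial)) {
        stop(sprintf(
          "partial %s block for record '%s' (%d of %d items answered)",
          q$name, record_ids[which(partial)[1]],
          n_answered[which(partial)[1]], q$questions), call. = FALSE)
      }
      keep <- complete
    } else {
      keep <- complete & !bad_rank
      dropped <- sum((partial | (complete & bad_rank)))
      if (!quiet && dropped > 0) {
        message(sprintf("%s: dropped %d partial/out-of-rank block(s)",
                        q$name, dropped))
      }
    }
    present[, q$name] <- keep
    values[!keep, idx] <- NA_integer_
    if (!quiet) {
      message(sprintf("%s: %d of %d records kept", q$name, sum(keep), n))
    }
  }
  new_cohort(values, present, record_ids, schema)
}

#' Read a cohort CSV
#'
#' @inheritParams validate_cohort
#' @param path CSV file with the `<prefix>_q<index>` column convention
#' @return a `synthq_cohort`
#' @export
read_cohort_csv <- function(path, schema, policy = "reject", quiet = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  validate_cohort(df, schema, policy = policy, quiet = quiet)
}

#' Write a cohort to CSV
#' @param cohort a `synthq_cohort`
#' @param path destination CSV
#' @return `path`, invisibly
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- data.frame(record_id = cohort$record_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(cohort$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Extract one questionnaire's item block
#' @param cohort a `synthq_cohort`
#' @param qname questionnaire name
#' @param complete_only keep only records whose block is present
#' @return integer matrix (with `NA` rows unless `complete_only`)
#' @export
cohort_block <- function(cohort, qname, complete_only = FALSE) {
  idx <- block_columns(cohort$schema, qname)
  m <- cohort$values[, idx, drop = FALSE]
  if (complete_only) m <- m[cohort$present[, qname], , drop = FALSE]
  m
}

#' Score all subscales of a cohort
#'
#' Each subscale score is the sum of its member items (the instruments'
#' published subscales are monotone aggregates; a plain sum preserves the
#' ordering information the correlation graph relies on). Records whose
#' questionnaire block is missing get `NA` scores for that questionnaire's
#' subscales. Columns follow the schema's subscale ordering.
#'
#' @param cohort a `synthq_cohort`
#' @param schema optional schema override (defaults to the cohort's)
#' @return numeric matrix, records x subscales
#' @export
score_subscales <- function(cohort, schema = cohort$schema) {
  st <- subscale_table(schema)
  out <- matrix(NA_real_, nrow = nrow(cohort$values), ncol = nrow(st),
                dimnames = list(NULL, st$subscale))
  for (k in seq_len(nrow(st))) {
    q <- schema$questionnaires[[st$questionnaire[k]]]
    s <- q$subscales[[which(vapply(q$subscales, `[[`, "", "name") ==
                              st$subscale[k])]]
    idx <- block_columns(schema, q$name)[s$items]
    rows <- cohort$present[, q$name]
    if (any(rows)) {
      out[rows, k] <- rowSums(cohort$values[rows, idx, drop = FALSE])
    }
  }
  out
}

#' @export
print.synthq_cohort <- function(x, ...) {
  cat("<synthq_cohort>", nrow(x$values), "records x", ncol(x$values),
      "items\n")
  counts <- colSums(x$present)
  for (q in names(counts)) {
    cat(sprintf("  %-9s %d complete register(s)\n", q, counts[q]))
  }
  invisible(x)
}
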