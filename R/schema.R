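#' Questionnaire schemas for the six ME/CFS instruments
#'
#' A `synthq_schema` encodes the structure of a battery of self-administered
#' questionnaires: how many items each instrument has, the ordered set of
#' integer answers every item admits (its answer rank), whether the instrument
#' carries a single total score, and the named subscales with their item
#' membership and thematic subject area (Physic, Anxiety, Sleep quality, ...).
#'
#' The bundled default describes the six instruments used in specialised
#' ME/CFS units: SF-36 (36 items, answers 1..6), HAD (14 items, 0..3),
#' SCL 90 R (90 items, 0..4), FIS8 (8 items, 0..4), FIS40 (40 items, 0..4)
#' and PSQI (34 items, 0..3) -- 222 items and 38 subscales in total.
#'
#' @name synthq_schema
#' @keywords internal
NULL

QUESTIONNAIRE_PREFIXES <- c(
  "SF-36" = "sf36", "HAD" = "had", "SCL 90 R" = "scl90r",
  "FIS8" = "fis8", "FIS40" = "fis40", "PSQI" = "psqi"
)

new_subscale <- function(name, subject, items) {
  list(name = name, subject = subject, items = as.integer(items))
}

new_questionnaire <- function(name, questions, answer_min, answer_max,
                              has_total, subscales, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- unname(QUESTIONNAIRE_PREFIXES[name])
    if (is.na(prefix)) prefix <- gsub("[^a-z0-9]", "", tolower(name))
  }
  list(
    name = name, prefix = prefix, questions = as.integer(questions),
    answer_min = as.integer(answer_min), answer_max = as.integer(answer_max),
    has_total = isTRUE(has_total), subscales = subscales
  )
}

validate_schema <- function(schema) {
  stopifnot(is.list(schema$questionnaires), length(schema$questionnaires) >= 1)
  nms <- vapply(schema$questionnaires, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("schema error: duplicated questionnaire name '",
         nms[duplicated(nms)][1], "'", call. = FALSE)
  }
  for (q in schema$questionnaires) {
    if (q$questions < 1) {
      stop("schema error: questionnaire '", q$name,
           "' has a non-positive question count", call. = FALSE)
    }
    if (q$answer_min >= q$answer_max) {
      stop("schema error: questionnaire '", q$name,
           "' has an empty answer rank", call. = FALSE)
    }
    for (s in q$subscales) {
      if (length(s$items) == 0) {
        stop("schema error: subscale '", s$name, "' of '", q$name,
             "' has no member items", call. = FALSE)
      }
      if (any(s$items < 1L | s$items > q$questions)) {
        stop("schema error: subscale '", s$name, "' of '", q$name,
             "' references item indices outside 1..", q$questions,
             call. = FALSE)
      }
      if (is.null(s$subject) || !nzchar(s$subject)) {
        stop("schema error: subscale '", s$name, "' of '", q$name,
             "' is missing its subject label", call. = FALSE)
      }
    }
  }
  sub_names <- unlist(lapply(schema$questionnaires,
                             function(q) vapply(q$subscales, `[[`, "", "name")))
  if (anyDuplicated(sub_names)) {
    stop("schema error: duplicated subscale name '",
         sub_names[duplicated(sub_names)][1], "'", call. = FALSE)
  }
  invisible(schema)
}

new_schema <- function(questionnaires, subscale_order = NULL) {
  names(questionnaires) <- vapply(questionnaires, `[[`, "", "name")
  if (is.null(subscale_order)) subscale_order <- names(questionnaires)
  schema <- structure(
    list(questionnaires = questionnaires, subscale_order = subscale_order),
    class = "synthq_schema"
  )
  validate_schema(schema)
  schema
}

#' Names of the questionnaires in a schema, in block (column) order
#' @param schema a `synthq_schema`
#' @return character vector of questionnaire names
#' @export
questionnaire_names <- function(schema) {
  vapply(schema$questionnaires, `[[`, "", "name")
}

#' Total number of items across all questionnaires
#' @param schema a `synthq_schema`
#' @return integer item count (222 for the bundled default)
#' @export
n_items <- function(schema) {
  sum(vapply(schema$questionnaires, `[[`, 0L, "questions"))
}

#' Flat table of all subscales in a schema
#'
#' Rows follow the schema's subscale ordering (for the bundled default, the
#' instrument order SF-36, HAD, FIS40, FIS8, PSQI, SCL 90 R, items listed
#' within each instrument), which is also the column order of
#' [score_subscales()] and the node order of the correlation graph.
#'
#' @param schema a `synthq_schema`
#' @return data.frame with columns `subscale`, `questionnaire`, `subject`,
#'   `n_items`
#' @export
subscale_table <- function(schema) {
  rows <- list()
  for (qname in schema$subscale_order) {
    q <- schema$questionnaires[[qname]]
    for (s in q$subscales) {
      rows[[length(rows) + 1L]] <- data.frame(
        subscale = s$name, questionnaire = q$name, subject = s$subject,
        n_items = length(s$items), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Number of subscales in a schema
#' @param schema a `synthq_schema`
#' @return integer (38 for the bundled default)
#' @export
n_subscales <- function(schema) {
  sum(vapply(schema$questionnaires, function(q) length(q$subscales), 0L))
}

#' Column names of a cohort matrix under a schema
#' @param schema a `synthq_schema`
#' @return character vector `<prefix>_q<index>` in block order
#' @export
item_columns <- function(schema) {
  unlist(lapply(schema$questionnaires, function(q) {
    paste0(q$prefix, "_q", seq_len(q$questions))
  }), use.names = FALSE)
}

# column index range of one questionnaire block within the full item matrix
block_columns <- function(schema, qname) {
  offset <- 0L
  for (q in schema$questionnaires) {
    if (q$name == qname) return(offset + seq_len(q$questions))
    offset <- offset + q$questions
  }
  stop("unknown questionnaire '", qname, "'", call. = FALSE)
}

#' The bundled default schema (six ME/CFS instruments)
#'
#' Encodes the six questionnaires with their published item counts and answer
#' ranks, and 38 subscales (10 SF-36, 3 HAD, 12 SCL 90 R, 1 FIS8, 4 FIS40,
#' 8 PSQI) each tagged with a subject area. The published instruments do not
#' disclose a machine-readable item-to-subscale map, so the default assigns
#' contiguous item blocks whose sizes are consistent with each instrument's
#' structure; composite subscales (SF-36 component scores, questionnaire
#' totals, the SCL 90 R global indices) aggregate the union of their parts.
#' Users with the licensed instrument keys can supply the exact mapping via
#' [load_schema()].
#'
#' @return a `synthq_schema`
#' @export
default_schema <- function() {
  sf36 <- new_questionnaire(
    "SF-36", 36, 1, 6, FALSE,
    list(
      new_subscale("Physic function (PF)", "Physic", 1:10),
      new_subscale("Rol physic (RP)", "Physic", 11:14),
      new_subscale("Body pain (BP)", "Pain", 15:16),
      new_subscale("General health (GH)", "General health", 17:21),
      new_subscale("Vitality (VT)", "Vitality", 22:25),
      new_subscale("Social function (SF)", "Social", 26:27),
      new_subscale("Rol emotional (RE)", "Emotional", 28:30),
      new_subscale("Mental health (MH)", "Mental", 31:36),
      new_subscale("Physical component score (PCS)", "Physic", 1:21),
      new_subscale("Mental component score (MCS)", "Mental", 22:36)
    )
  )
  had <- new_questionnaire(
    "HAD", 14, 0, 3, TRUE,
    list(
      new_subscale("Total anxiety", "Anxiety", 1:7),
      new_subscale("Total depression", "Depression", 8:14),
      new_subscale("Total HAD", "Depression", 1:14)
    )
  )
  scl <- new_questionnaire(
    "SCL 90 R", 90, 0, 4, FALSE,
    list(
      new_subscale("Somatizations (SOM)", "Mental", 1:10),
      new_subscale("Obsessions (OBS)", "Mental", 11:20),
      new_subscale("Interpersonal sensitivity (SI)", "Mental", 21:30),
      new_subscale("Depression (DEP)", "Depression", 31:40),
      new_subscale("Anxiety (ANS)", "Anxiety", 41:50),
      new_subscale("Hostility (HOS)", "Anxiety", 51:60),
      new_subscale("Phobic anxiety (FOB)", "Anxiety", 61:70),
      new_subscale("Paranoid (PAR)", "Mental", 71:80),
      new_subscale("Psychoticism (SIC)", "Mental", 81:90),
      new_subscale("Severity global index (GSI)", "Mental", 1:90),
      new_subscale("Positive symptoms (PST)", "Mental", 1:90),
      new_subscale("Symptomatic discomfort Index (PSDI)", "Mental", 1:90)
    )
  )
  fis8 <- new_questionnaire(
    "FIS8", 8, 0, 4, TRUE,
    list(new_subscale("FIS8", "Physic", 1:8))
  )
  fis40 <- new_questionnaire(
    "FIS40", 40, 0, 4, TRUE,
    list(
      new_subscale("Physic dim", "Physic", 1:13),
      new_subscale("Cognitive dim", "Cognitive", 14:26),
      new_subscale("Social dim", "Social", 27:40),
      new_subscale("Total FIS40", "Physic", 1:40)
    )
  )
  psqi <- new_questionnaire(
    "PSQI", 34, 0, 3, TRUE,
    list(
      new_subscale("Component 1", "Sleep quality", 1:5),
      new_subscale("Component 2", "Sleep quality", 6:10),
      new_subscale("Component 3", "Sleep quality", 11:15),
      new_subscale("Component 4", "Sleep quality", 16:20),
      new_subscale("Component 5", "Sleep quality", 21:25),
      new_subscale("Component 6", "Sleep quality", 26:30),
      new_subscale("Component 7", "Sleep quality", 31:34),
      new_subscale("Total PSQI", "Sleep quality", 1:34)
    )
  )
  new_schema(
    list(sf36, had, scl, fis8, fis40, psqi),
    subscale_order = c("SF-36", "HAD", "FIS40", "FIS8", "PSQI", "SCL 90 R")
  )
}

#' Load a questionnaire schema
#'
#' Reads a schema from a structured-text file (JSON or YAML) with top-level
#' key `questionnaires`, each entry carrying `name`, `questions`,
#' `answer_min`, `answer_max`, `has_total` and a list of `subscales`
#' (`name`, `subject`, `items`). The string `"bundled-default"` returns the
#' built-in six-instrument schema.
#'
#' @param path file path, or `"bundled-default"`
#' @return a `synthq_schema`
#' @export
load_schema <- function(path = "bundled-default") {
  if (identical(path, "bundled-default")) return(default_schema())
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(raw$questionnaires)) {
    stop("schema error: file lacks a 'questionnaires' key", call. = FALSE)
  }
  qs <- lapply(raw$questionnaires, function(q) {
    for (key in c("name", "questions", "answer_min", "answer_max")) {
      if (is.null(q[[key]])) {
        stop("schema error: questionnaire entry missing '", key, "'",
             call. = FALSE)
      }
    }
    subs <- lapply(q$subscales, function(s) {
      if (is.null(s$name) || is.null(s$subject) || is.null(s$items)) {
        stop("schema error: subscale of '", q$name,
             "' missing name/subject/items", call. = FALSE)
      }
      new_subscale(s$name, s$subject, unlist(s$items))
    })
    new_questionnaire(q$name, q$questions, q$answer_min, q$answer_max,
                      isTRUE(q$has_total), subs, prefix = q$prefix)
  })
  order <- if (!is.null(raw$subscale_order)) unlist(raw$subscale_order) else NULL
  new_schema(qs, subscale_order = order)
}

#' Write a schema to a JSON or YAML file
#' @param schema a `synthq_schema`
#' @param path destination (`.json`, `.yaml` or `.yml`)
#' @return `path`, invisibly
#' @export
write_schema <- function(schema, path) {
  out <- list(
    questionnaires = lapply(unname(schema$questionnaires), function(q) {
      list(
        name = q$name, prefix = q$prefix, questions = q$questions,
        answer_min = q$answer_min, answer_max = q$answer_max,
        has_total = q$has_total,
        subscales = lapply(q$subscales, function(s) {
          list(name = s$name, subject = s$subject, items = as.integer(s$items))
        })
      )
    }),
    subscale_order = schema$subscale_order
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.synthq_schema <- function(x, ...) {
  cat("<synthq_schema>", length(x$questionnaires), "questionnaires,",
      n_items(x), "items,", n_subscales(x), "subscales\n")
  for (q in x$questionnaires) {
    cat(sprintf("  %-9s %3d items, answers {%d..%d}, %d subscale(s)\n",
                q$name, q$questions, q$answer_min, q$answer_max,
                length(q$subscales)))
  }
  invisible(x)
}
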