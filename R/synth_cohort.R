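#' Synthetic cohort specifications
#'
#' The hospital cohort behind the six-questionnaire battery is not publicly
#' released, so the package ships a seeded generator of correlated ordinal
#' cohorts with planted subject-level structure. Each record draws a latent
#' trait vector `z` (one coordinate per subject area, zero-mean unit-variance
#' Gaussian with a chosen correlation matrix); each item's latent value is
#' `lambda * z[subject(item)] + sqrt(1 - lambda^2) * eps` with independent
#' standard-normal noise, discretised onto the item's answer rank by
#' equal-probability quantile thresholds (or user-supplied category
#' probabilities). Block-level missingness is applied per (record,
#' questionnaire) by a seeded Bernoulli draw.
#'
#' @param n_records number of records to generate
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bitwise
#' @param subject_corr correlation matrix over subject areas, with dimnames
#'   naming the subjects; `NULL` means independent subjects
#' @param lambda item loading on its subject trait, in `[0, 1]`; either a
#'   scalar or a named vector of per-questionnaire overrides (unnamed default
#'   0.8)
#' @param item_subject_map named character vector mapping item columns (e.g.
#'   `sf36_q31`) to subject labels, overriding the default (the subject of the
#'   first subscale containing the item)
#' @param retention named per-questionnaire fraction of records whose block is
#'   present; scalar recycled
#' @param item_probs named list mapping item columns to category probability
#'   vectors, overriding the uniform default (to emulate imbalanced answers)
#' @return a `synthq_cohort_spec`
#' @export
cohort_spec <- function(n_records, seed = 0, subject_corr = NULL,
                        lambda = 0.8, item_subject_map = NULL,
                        retention = 1, item_probs = NULL) {
  stopifnot(n_records >= 1, all(lambda >= 0), all(lambda <= 1),
            all(retention > 0), all(retention <= 1))
  structure(
    list(n_records = as.integer(n_records), seed = as.integer(seed),
         subject_corr = subject_corr, lambda = lambda,
         item_subject_map = item_subject_map, retention = retention,
         item_probs = item_probs),
    class = "synthq_cohort_spec"
  )
}

# subject of each item column: first subscale containing it, else a
# questionnaire-specific filler subject (items outside any subscale)
default_item_subjects <- function(schema) {
  out <- character(0)
  for (q in schema$questionnaires) {
    subj <- rep(paste0(q$name, " (unscaled)"), q$questions)
    for (s in rev(q$subscales)) subj[s$items] <- s$subject
    # rev(): the FIRST subscale listing an item wins
    names(subj) <- paste0(q$prefix, "_q", seq_len(q$questions))
    out <- c(out, subj)
  }
  out
}

resolve_lambda <- function(lambda, qnames) {
  lam <- rep(if (is.null(names(lambda))) lambda[1] else 0.8, length(qnames))
  names(lam) <- qnames
  if (!is.null(names(lambda))) {
    known <- intersect(names(lambda), qnames)
    lam[known] <- lambda[known]
  }
  lam
}

#' Generate a synthetic cohort
#'
#' Draws a correlated ordinal cohort from a [cohort_spec()] under a schema.
#' Fully reproducible: the same spec (including seed) yields a bitwise
#' identical cohort.
#'
#' @param spec a `synthq_cohort_spec`
#' @param schema a `synthq_schema`
#' @return a `synthq_cohort`
#' @export
generate_cohort <- function(spec, schema = default_schema()) {
  stopifnot(inherits(spec, "synthq_cohort_spec"))
  qnames <- questionnaire_names(schema)
  subj_map <- default_item_subjects(schema)
  if (!is.null(spec$item_subject_map)) {
    unknown <- setdiff(names(spec$item_subject_map), names(subj_map))
    if (length(unknown) > 0) {
      stop("item_subject_map names unknown item(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    subj_map[names(spec$item_subject_map)] <- spec$item_subject_map
  }
  subjects <- sort(unique(unname(subj_map)))
  S <- spec$subject_corr
  if (is.null(S)) {
    S <- diag(length(subjects))
    dimnames(S) <- list(subjects, subjects)
  }
  if (is.null(dimnames(S)[[1]])) {
    stop("subject_corr must carry subject names as dimnames", call. = FALSE)
  }
  missing_subj <- setdiff(subjects, rownames(S))
  if (length(missing_subj) > 0) {
    stop("subject_corr lacks subject(s): ",
         paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  S <- S[subjects, subjects, drop = FALSE]
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("subject_corr is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  lam <- resolve_lambda(spec$lambda, qnames)
  retention <- spec$retention
  if (is.null(names(retention))) {
    retention <- stats::setNames(rep(retention[1], length(qnames)), qnames)
  } else {
    full <- stats::setNames(rep(1, length(qnames)), qnames)
    full[intersect(names(retention), qnames)] <-
      retention[intersect(names(retention), qnames)]
    retention <- full
  }

  n <- spec$n_records
  cols <- item_columns(schema)
  with_seed(spec$seed, {
    # eigendecomposition square root: tolerant of semi-definite matrices
    ev2 <- eigen(S, symmetric = TRUE)
    rootS <- ev2$vectors %*% diag(sqrt(pmax(ev2$values, 0)),
                                  nrow = length(ev2$values)) %*% t(ev2$vectors)
    z <- matrix(stats::rnorm(n * length(subjects)), n) %*% rootS
    colnames(z) <- subjects
    eps <- matrix(stats::rnorm(n * length(cols)), n)
    values <- matrix(NA_integer_, n, length(cols),
                     dimnames = list(NULL, cols))
    j <- 0L
    for (q in schema$questionnaires) {
      K <- q$answer_max - q$answer_min + 1L
      l <- lam[q$name]
      for (i in seq_len(q$questions)) {
        j <- j + 1L
        u <- l * z[, subj_map[cols[j]]] + sqrt(1 - l^2) * eps[, j]
        p <- spec$item_probs[[cols[j]]] %||% rep(1 / K, K)
        if (length(p) != K || abs(sum(p) - 1) > 1e-8) {
          stop("item_probs for ", cols[j], " must be ", K,
               " probabilities summing to 1", call. = FALSE)
        }
        thr <- stats::qnorm(cumsum(p)[-K])
        values[, j] <- q$answer_min + findInterval(u, thr)
      }
    }
    present <- matrix(FALSE, n, length(qnames),
                      dimnames = list(NULL, qnames))
    for (qn in qnames) {
      present[, qn] <- stats::runif(n) < retention[qn]
      values[!present[, qn], block_columns(schema, qn)] <- NA_integer_
    }
    new_cohort(values, present, as.character(seq_len(n)), schema)
  })
}

#' A cohort specification emulating the hospital battery
#'
#' Plants subject-level correlations so that the subscale correlation graph of
#' a generated cohort reproduces the qualitative structure observed on the
#' real register data: SF-36 subscales cover all three HAD nodes but only a
#' minority of SCL 90 R nodes (its anxiety/depression dimensions and global
#' indices), while HAD covers all twelve SCL 90 R nodes; the fatigue scales
#' hang off the physical-function cluster;
#' the sleep-quality trait is nearly uncoupled so PSQI is close to isolated.
#' Under the greedy coverage ordering this yields the cascade
#' SF-36, HAD, SCL 90 R, FIS8, FIS40, PSQI.
#'
#' Per-questionnaire retention fractions mirror the relative register counts
#' of the real battery (PSQI lowest). SF-36 mental-health items are mapped to
#' the Emotional trait: on real data the SF-36 mental items track HAD far more
#' closely than the SCL 90 R psychopathology dimensions, and a single shared
#' Mental trait cannot express that asymmetry.
#'
#' @param n_records cohort size (default 2000)
#' @param seed integer seed
#' @return a `synthq_cohort_spec`
#' @export
default_paper_like_spec <- function(n_records = 2000, seed = 0) {
  subjects <- c("Physic", "Pain", "General health", "Vitality", "Social",
                "Emotional", "Mental", "Anxiety", "Depression", "Cognitive",
                "Sleep quality")
  S <- matrix(0.45, 11, 11, dimnames = list(subjects, subjects))
  physical <- c("Physic", "Pain", "General health", "Vitality", "Social")
  S[physical, physical] <- 0.80
  S["Mental", "Anxiety"] <- S["Anxiety", "Mental"] <- 0.80
  S["Mental", "Depression"] <- S["Depression", "Mental"] <- 0.80
  S["Anxiety", "Depression"] <- S["Depression", "Anxiety"] <- 0.85
  S["Emotional", "Anxiety"] <- S["Anxiety", "Emotional"] <- 0.75
  S["Emotional", "Depression"] <- S["Depression", "Emotional"] <- 0.75
  S["Emotional", physical] <- S[physical, "Emotional"] <- 0.55
  S["Mental", c(physical, "Emotional")] <- 0.40
  S[c(physical, "Emotional"), "Mental"] <- 0.40
  S["Cognitive", ] <- S[, "Cognitive"] <- 0.35
  S["Sleep quality", ] <- S[, "Sleep quality"] <- 0.20
  diag(S) <- 1
  mh_items <- paste0("sf36_q", 31:36)
  cohort_spec(
    n_records = n_records, seed = seed, subject_corr = S, lambda = 0.8,
    item_subject_map = stats::setNames(rep("Emotional", length(mh_items)),
                                       mh_items),
    retention = c("SF-36" = 0.930, "HAD" = 0.927, "SCL 90 R" = 0.936,
                  "FIS8" = 0.816, "FIS40" = 0.937, "PSQI" = 0.777)
  )
}
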