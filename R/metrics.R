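#' Per-label classification report
#'
#' Computes the confusion-matrix summary used throughout the validation:
#' per-label precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and their
#' harmonic mean F1 (0 when undefined), label supports, overall accuracy (the
#' fraction of exact matches), the macro average, and the support-weighted
#' average.
#'
#' @param y_true vector of true labels
#' @param y_pred vector of predicted labels, same length
#' @param labels optional label universe (defaults to the union of observed
#'   values, sorted)
#' @return a `synthq_classification_report`: list with `per_label`
#'   (data.frame: label, precision, recall, f1, support), `accuracy`, `macro`
#'   and `weighted` rows, and `n`
#' @export
classification_report <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length", call. = FALSE)
  }
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% labels)) {
    stop("labels must cover all observed values", call. = FALSE)
  }
  per <- data.frame(label = labels, precision = 0, recall = 0, f1 = 0,
                    support = 0L)
  for (k in seq_along(labels)) {
    l <- labels[k]
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[k, c("precision", "recall", "f1", "support")] <-
      c(prec, rec, f1, tp + fn)
  }
  n <- length(y_true)
  wts <- per$support / n
  structure(
    list(
      per_label = per,
      accuracy = mean(y_true == y_pred),
      macro = c(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1)),
      weighted = c(precision = sum(wts * per$precision),
                   recall = sum(wts * per$recall),
                   f1 = sum(wts * per$f1)),
      n = n
    ),
    class = "synthq_classification_report"
  )
}

#' @export
print.synthq_classification_report <- function(x, digits = 2, ...) {
  cat(sprintf("%-12s %9s %9s %9s %9s\n", "", "precision", "recall",
              "f1-score", "support"))
  for (k in seq_len(nrow(x$per_label))) {
    p <- x$per_label[k, ]
    cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", as.character(p$label),
                digits, p$precision, digits, p$recall, digits, p$f1,
                as.integer(p$support)))
  }
  cat(sprintf("%-12s %9s %9s %9.*f %9d\n", "accuracy", "", "",
              digits, x$accuracy, x$n))
  cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", "macro avg",
              digits, x$macro["precision"], digits, x$macro["recall"],
              digits, x$macro["f1"], x$n))
  cat(sprintf("%-12s %9.*f %9.*f %9.*f %9d\n", "weighted avg",
              digits, x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"], x$n))
  invisible(x)
}

#' Signed mean error of questionnaire totals
#'
#' `100 * (sum(synthetic) - sum(real)) / sum(real)`: the percentage by which
#' the synthetic block's overall answer mass deviates from the real block's.
#' Negative values mean the generator under-scores the questionnaire.
#'
#' @param real records x items block of real answers
#' @param synthetic same-shape block of synthetic answers
#' @return signed percentage (scalar); `NA` with a warning when the real block
#'   sums to zero
#' @export
mean_error <- function(real, synthetic) {
  real <- as.matrix(real); synthetic <- as.matrix(synthetic)
  if (!all(dim(real) == dim(synthetic))) {
    stop("real and synthetic blocks differ in shape", call. = FALSE)
  }
  denom <- sum(real)
  if (denom == 0) {
    warning("real block sums to zero; mean error undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * (sum(synthetic) - denom) / denom
}

#' Sum-series t-test between real and synthetic blocks
#'
#' The utility check for one questionnaire: each item's answers are summed
#' over records, giving one series per block (length = number of items); a
#' two-sided two-sample Welch t-test then asks whether the real and synthetic
#' sum series could share a mean. Identical series give p = 1 by convention;
#' two exactly constant but unequal series give p = 0 with a warning. A paired
#' t-test on the per-item differences is available via `paired = TRUE`.
#'
#' @param real records x items block (>= 2 items)
#' @param synthetic same-shape block
#' @param paired use a paired t-test instead of Welch
#' @return p-value
#' @export
sum_ttest <- function(real, synthetic, paired = FALSE) {
  real <- as.matrix(real); synthetic <- as.matrix(synthetic)
  if (!all(dim(real) == dim(synthetic))) {
    stop("real and synthetic blocks differ in shape", call. = FALSE)
  }
  if (ncol(real) < 2) stop("need at least 2 items", call. = FALSE)
  a <- colSums(real)
  b <- colSums(synthetic)
  if (isTRUE(all.equal(a, b))) return(1.0)
  constant <- stats::var(a) < 1e-12 && stats::var(b) < 1e-12
  if (paired) constant <- stats::var(a - b) < 1e-12
  if (constant) {
    if (abs(mean(a) - mean(b)) < 1e-12) return(1.0)
    warning("zero-variance series with unequal means; p = 0 by convention",
            call. = FALSE)
    return(0.0)
  }
  stats::t.test(a, b, paired = paired)$p.value
}

#' Evaluate a trained cascade against real data
#'
#' Regenerates the five synthetic blocks from the cohort's real input
#' questionnaire and compares each step's synthetic block with the real one on
#' the records where both are available. Per step, all (record, question)
#' decisions are pooled into one confusion matrix: accuracy is the pooled
#' fraction of exact matches, and precision/recall/F1 are macro averages over
#' the pooled labels. The signed mean error and the sum-series t-test p-value
#' complete the row.
#'
#' @param model a `synthq_cascade`
#' @param cohort a `synthq_cohort` holding real blocks for comparison
#' @param mode prediction mode passed to [generate_battery()]
#' @param seed integer seed
#' @return a `synthq_evaluation`: data.frame with one row per step (columns
#'   step, target, n_records, accuracy, precision, recall, f1, mean_error,
#'   t_p), with per-step classification reports attached as the `"reports"`
#'   attribute
#' @export
evaluate_cascade <- function(model, cohort, mode = "argmax", seed = 0) {
  schema <- model$schema
  start <- model$order[1]
  rows <- which(cohort$present[, start])
  if (length(rows) == 0) stop("no records with the input questionnaire",
                              call. = FALSE)
  input <- cohort$values[rows, block_columns(schema, start), drop = FALSE]
  synth <- generate_battery(model, input, mode = mode, seed = seed)
  out <- data.frame()
  reports <- list()
  for (k in seq_along(model$steps)) {
    target <- model$steps[[k]]$target_questionnaire
    q <- schema$questionnaires[[target]]
    have <- cohort$present[rows, target]
    real_block <- cohort$values[rows[have], block_columns(schema, target),
                                drop = FALSE]
    syn_block <- synth[have, paste0(q$prefix, "_q", seq_len(q$questions)),
                       drop = FALSE]
    y_true <- as.vector(real_block)
    y_pred <- as.vector(syn_block)
    rep_k <- classification_report(y_true, y_pred)
    reports[[target]] <- rep_k
    out <- rbind(out, data.frame(
      step = k, target = target, n_records = sum(have),
      accuracy = rep_k$accuracy,
      precision = unname(rep_k$macro["precision"]),
      recall = unname(rep_k$macro["recall"]),
      f1 = unname(rep_k$macro["f1"]),
      mean_error = mean_error(real_block, syn_block),
      t_p = sum_ttest(real_block, syn_block),
      stringsAsFactors = FALSE
    ))
  }
  structure(out, reports = reports, class = c("synthq_evaluation",
                                              "data.frame"))
}

#' Write an evaluation report to CSV
#' @param report a `synthq_evaluation`
#' @param path destination CSV
#' @return `path`, invisibly
#' @export
write_evaluation_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Render an evaluation as a text table
#' @param report a `synthq_evaluation`
#' @return character vector of lines (one header, one per metric row)
#' @export
format_evaluation <- function(report) {
  metrics <- c("accuracy", "precision", "recall", "f1", "mean_error", "t_p")
  labels <- c("Accuracy", "Precision", "Recall", "F1 score", "Mean error",
              "t-student")
  header <- sprintf("%-12s %s", "Metrics",
                    paste(sprintf("STEP %d (%s)", report$step, report$target),
                          collapse = "  "))
  lines <- vapply(seq_along(metrics), function(m) {
    vals <- report[[metrics[m]]]
    txt <- if (metrics[m] == "mean_error") {
      sprintf("%16.2f%%", vals)
    } else {
      sprintf("%17.2f", vals)
    }
    sprintf("%-12s %s", labels[m], paste(txt, collapse = "  "))
  }, "")
  c(header, lines)
}

#' @export
print.synthq_evaluation <- function(x, ...) {
  cat(format_evaluation(x), sep = "\n")
  invisible(x)
}
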