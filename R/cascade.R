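#' Balanced class weights for an answer vector
#'
#' For each observed label `i`, the weight is `n / (classes * count_i)`,
#' where `n` is the number of valid registers, `classes` the number of
#' distinct observed labels, and `count_i` the support of label `i`. Rare
#' answers therefore receive proportionally larger penalty multipliers during
#' training, countering the strong answer-category imbalance seen in these
#' questionnaires (a single observed class gets weight 1).
#'
#' @param labels non-empty vector of integer answers
#' @return named numeric vector of weights, one per observed label (sorted)
#' @export
compute_class_weights <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) stop("labels must be non-empty", call. = FALSE)
  counts <- table(labels)
  n <- length(labels)
  w <- n / (length(counts) * as.numeric(counts))
  stats::setNames(w, names(counts))
}

#' Hyperparameter bundles
#'
#' Container for the training knobs a backend may honour. The `"mlp"` backend
#' uses all fields; the `"multinomial"` default uses `iterations`,
#' `learning_rate` and `l2`; `"xgboost"` uses `nrounds`, `max_depth`, `eta`.
#'
#' @param layers number of hidden layers (informational; `neurons` governs)
#' @param neurons integer vector, hidden neurons per layer
#' @param dropout_layers how many leading hidden layers get dropout
#' @param epochs maximum training epochs
#' @param patience early-stopping patience (epochs without improvement of the
#'   validation macro recall)
#' @param monitor monitored quantity (only `"val_recall"` is implemented)
#' @param validation_fraction stratified validation split fraction
#' @param ... further backend-specific fields (e.g. `iterations`,
#'   `learning_rate`, `nrounds`, `dropout_rate`)
#' @return a named list of class `synthq_hyperparams`
#' @export
hyperparams <- function(layers = NULL, neurons = NULL, dropout_layers = NULL,
                        epochs = NULL, patience = NULL,
                        monitor = "val_recall", validation_fraction = 0.2,
                        ...) {
  structure(
    list(layers = layers, neurons = neurons, dropout_layers = dropout_layers,
         epochs = epochs, patience = patience, monitor = monitor,
         validation_fraction = validation_fraction, ...),
    class = "synthq_hyperparams"
  )
}

#' Published per-step network configurations
#'
#' The five cascade steps were tuned separately on the register data; these
#' are the shipped configurations (hidden layers, dropout layers, epoch
#' budget, early-stopping patience on validation macro recall).
#'
#' @return list of five [hyperparams()] objects, one per step
#' @export
default_step_hyperparams <- function() {
  list(
    hyperparams(layers = 4, neurons = c(400, 400, 200, 100),
                dropout_layers = 2, epochs = 4000, patience = 400),
    hyperparams(layers = 3, neurons = c(1500, 1500, 750),
                dropout_layers = 2, epochs = 3000, patience = 300),
    hyperparams(layers = 4, neurons = c(1000, 1000, 500, 250),
                dropout_layers = 3, epochs = 3000, patience = 300),
    hyperparams(layers = 4, neurons = c(1000, 1000, 500, 250),
                dropout_layers = 3, epochs = 3000, patience = 300),
    hyperparams(layers = 4, neurons = c(500, 500, 250, 100),
                dropout_layers = 2, epochs = 3000, patience = 400)
  )
}

#' Build the cascade step specifications
#'
#' Step `k` takes the concatenated item blocks of `order[1..k]` as features
#' and predicts every item of `order[k + 1]`. Under the default schema and
#' order the feature dimensions are 36, 50, 140, 148 and 188, and the target
#' dimensions 14, 90, 8, 40 and 34.
#'
#' @param schema a `synthq_schema`
#' @param order permutation of the schema's questionnaires; the first entry is
#'   the input questionnaire
#' @param step_hyperparams optional list of per-step [hyperparams()]
#' @return list of step specs (`step_index`, `input_questionnaires`,
#'   `target_questionnaire`, `input_dim`, `target_dim`, `hyperparams`)
#' @export
make_steps <- function(schema, order = NULL, step_hyperparams = NULL) {
  qnames <- questionnaire_names(schema)
  if (is.null(order)) order <- qnames
  if (!setequal(order, qnames) || length(order) != length(qnames)) {
    stop("order must be a permutation of the schema's questionnaires",
         call. = FALSE)
  }
  n_steps <- length(order) - 1L
  if (is.null(step_hyperparams) && n_steps == 5L) {
    step_hyperparams <- default_step_hyperparams()
  }
  qcount <- function(qn) schema$questionnaires[[qn]]$questions
  lapply(seq_len(n_steps), function(k) {
    inputs <- order[seq_len(k)]
    target <- order[k + 1L]
    list(
      step_index = k,
      input_questionnaires = inputs,
      target_questionnaire = target,
      input_dim = sum(vapply(inputs, qcount, 0L)),
      target_dim = qcount(target),
      hyperparams = if (!is.null(step_hyperparams)) step_hyperparams[[k]]
                    else hyperparams()
    )
  })
}

new_question_model <- function(item, labels, weights, kind, fit, constant = NULL) {
  list(item = item, observed_labels = labels, class_weights = weights,
       backend_kind = kind, fit = fit, constant = constant)
}

predict_question <- function(qm, features, mode = "argmax", seed = 0) {
  n <- nrow(features)
  if (!is.null(qm$constant)) return(rep(qm$constant, n))
  scores <- predict_scores(qm$fit, features)
  labels <- qm$observed_labels
  if (mode == "argmax") {
    labels[max.col(scores, ties.method = "first")]
  } else {
    probs <- scores / rowSums(scores)
    with_seed(seed, {
      u <- stats::runif(n)
      cum <- t(apply(probs, 1, cumsum))
      labels[rowSums(u > cum) + 1L]
    })
  }
}

#' Train one cascade step
#'
#' Fits one class-weighted classifier per target item. Training records are
#' the step's complete cases: records whose real target block and all real
#' input blocks are present. Features are the real input questionnaire block
#' concatenated with the synthetic outputs of the previous steps
#' (`prior_synthetic`), mirroring generation-time conditions; pass the real
#' prior blocks instead for a teacher-forcing ablation.
#'
#' @param spec one element of [make_steps()]
#' @param cohort a `synthq_cohort`
#' @param prior_synthetic matrix of previous steps' synthetic outputs, aligned
#'   to the cohort's records (`NULL` for step 1)
#' @param backend backend kind (see [fit_backend()])
#' @param seed integer seed
#' @param min_records minimum training records (default 30)
#' @param quiet suppress the per-step training summary
#' @return list with the fitted question-model bank, the training row indices
#'   and the per-question summary
#' @export
train_step <- function(spec, cohort, prior_synthetic = NULL,
                       backend = "multinomial", seed = 0, min_records = 30,
                       quiet = FALSE) {
  schema <- cohort$schema
  rows <- cohort$present[, spec$target_questionnaire]
  for (qn in spec$input_questionnaires) rows <- rows & cohort$present[, qn]
  rows <- which(rows)
  if (length(rows) < min_records) {
    stop("step ", spec$step_index, " has ", length(rows),
         " complete training records (minimum ", min_records, ")",
         call. = FALSE)
  }
  base <- cohort$values[rows, block_columns(schema, spec$input_questionnaires[1]),
                        drop = FALSE]
  features <- if (is.null(prior_synthetic)) {
    base
  } else {
    stopifnot(nrow(prior_synthetic) == nrow(cohort$values))
    cbind(base, prior_synthetic[rows, , drop = FALSE])
  }
  if (ncol(features) != spec$input_dim) {
    stop("step ", spec$step_index, " features have ", ncol(features),
         " columns; expected ", spec$input_dim, call. = FALSE)
  }
  q <- schema$questionnaires[[spec$target_questionnaire]]
  target <- cohort$values[rows, block_columns(schema, q$name), drop = FALSE]
  rank <- seq(q$answer_min, q$answer_max)
  hp <- spec$hyperparams
  hp$answer_rank <- rank
  bank <- vector("list", q$questions)
  summary <- data.frame(item = seq_len(q$questions), n_labels = NA_integer_,
                        train_accuracy = NA_real_)
  for (i in seq_len(q$questions)) {
    y <- target[, i]
    labels <- sort(unique(y))
    if (length(labels) == 1L) {
      warning("step ", spec$step_index, " item ", i,
              " has a single observed class (", labels,
              "); using a constant predictor", call. = FALSE)
      bank[[i]] <- new_question_model(i, labels, c(1), backend, NULL,
                                      constant = labels)
      summary$n_labels[i] <- 1L
      summary$train_accuracy[i] <- 1
      next
    }
    weights <- compute_class_weights(y)
    fit <- fit_backend(backend, features, y, weights, hp,
                       seed = derive_seed(seed, spec$step_index, i))
    bank[[i]] <- new_question_model(i, labels, weights, backend, fit)
    pred <- predict_question(bank[[i]], features)
    summary$n_labels[i] <- length(labels)
    summary$train_accuracy[i] <- mean(pred == y)
  }
  if (!quiet) {
    message(sprintf(
      "step %d: %s -> %s, %d records, %d question models, mean train accuracy %.3f",
      spec$step_index, paste(spec$input_questionnaires, collapse = "+"),
      spec$target_questionnaire, length(rows), q$questions,
      mean(summary$train_accuracy)))
  }
  list(bank = bank, rows = rows, summary = summary)
}

#' Train the full cascade
#'
#' Trains the steps in order. After each step, synthetic outputs are produced
#' (deterministic argmax) for every record whose input questionnaire block is
#' present and concatenated into the next step's features, so each step is
#' trained under the same conditions it will see at generation time. The
#' per-step complete-case record counts shrink as more real blocks are
#' required, mirroring the register availability of the instruments.
#'
#' @param cohort a `synthq_cohort` containing all questionnaire blocks
#' @param schema optional schema override (defaults to the cohort's)
#' @param order generation order; `NULL` derives it from the cohort via
#'   [cascade_order()] on the thresholded correlation graph
#' @param config list of options: `backend` (default `"multinomial"`),
#'   `teacher_forcing` (use real prior blocks as training inputs), `tau`
#'   (graph threshold when deriving the order), `min_records`,
#'   `step_hyperparams`, `quiet`
#' @param seed integer seed
#' @return a `synthq_cascade` model
#' @export
train_cascade <- function(cohort, schema = cohort$schema, order = NULL,
                          config = list(), seed = 0) {
  backend <- config$backend %||% "multinomial"
  teacher_forcing <- isTRUE(config$teacher_forcing)
  quiet <- isTRUE(config$quiet)
  min_records <- config$min_records %||% 30
  if (is.null(order)) {
    scores <- score_subscales(cohort, schema)
    graph <- build_graph(pearson_matrix(scores), schema,
                         tau = config$tau %||% 0.5)
    order <- as.character(cascade_order(
      graph, start = questionnaire_names(schema)[1]))
    if (!quiet) {
      message("derived cascade order: ", paste(order, collapse = ", "))
    }
  }
  steps <- make_steps(schema, order, config$step_hyperparams)
  start <- order[1]
  gen_rows <- which(cohort$present[, start])
  base <- cohort$values[gen_rows, block_columns(schema, start), drop = FALSE]
  synth_full <- NULL   # aligned to all cohort records
  synth_gen <- NULL    # aligned to gen_rows
  banks <- vector("list", length(steps))
  counts <- integer(length(steps))
  for (k in seq_along(steps)) {
    spec <- steps[[k]]
    prior <- if (k == 1) {
      NULL
    } else if (teacher_forcing) {
      cols <- unlist(lapply(spec$input_questionnaires[-1], function(qn)
        block_columns(schema, qn)))
      cohort$values[, cols, drop = FALSE]
    } else {
      synth_full
    }
    trained <- train_step(spec, cohort, prior, backend = backend,
                          seed = derive_seed(seed, k),
                          min_records = min_records, quiet = quiet)
    banks[[k]] <- trained$bank
    counts[k] <- length(trained$rows)
    # feed forward: synthesize this step's block for all generatable records
    feat <- if (is.null(synth_gen)) base else cbind(base, synth_gen)
    block <- matrix(
      NA_integer_, nrow(cohort$values),
      schema$questionnaires[[spec$target_questionnaire]]$questions)
    pred <- vapply(trained$bank, function(qm)
      as.integer(predict_question(qm, feat, mode = "argmax")),
      integer(nrow(feat)))
    if (nrow(feat) == 1) pred <- matrix(pred, nrow = 1)
    block[gen_rows, ] <- pred
    synth_gen <- if (is.null(synth_gen)) pred else cbind(synth_gen, pred)
    synth_full <- if (is.null(synth_full)) block else cbind(synth_full, block)
  }
  cfg_digest <- text_digest(c(backend, paste(order, collapse = "|"),
                              as.character(seed), as.character(counts)))
  structure(
    list(schema = schema, order = order, steps = steps, banks = banks,
         provenance = list(seed = seed, backend = backend,
                           teacher_forcing = teacher_forcing,
                           step_records = counts, config_digest = cfg_digest)),
    class = "synthq_cascade"
  )
}

#' @export
print.synthq_cascade <- function(x, ...) {
  cat("<synthq_cascade>", length(x$steps), "steps,",
      sum(vapply(x$banks, length, 0L)), "question models, backend",
      x$provenance$backend, "\n")
  for (k in seq_along(x$steps)) {
    s <- x$steps[[k]]
    cat(sprintf("  step %d: %s (n=%d, dim %d) -> %s (%d)\n", k,
                paste(s$input_questionnaires, collapse = "+"),
                x$provenance$step_records[k], s$input_dim,
                s$target_questionnaire, s$target_dim))
  }
  invisible(x)
}

#' Generate synthetic questionnaire batteries
#'
#' Runs the trained cascade on a matrix of input-questionnaire responses and
#' returns the five synthetic blocks (186 columns under the default schema),
#' ordered by the schema's block order. `"argmax"` predicts each answer
#' deterministically; `"sample"` draws each answer from the classifier's
#' per-label scores under the given seed.
#'
#' @param model a `synthq_cascade`
#' @param input records x items matrix of the input questionnaire (complete
#'   rows, values within its answer rank); column names are ignored
#' @param mode `"argmax"` (default) or `"sample"`
#' @param seed integer seed (used by `"sample"` mode and stochastic backends)
#' @return integer matrix, records x total target items, columns named
#'   `<prefix>_q<index>`
#' @export
generate_battery <- function(model, input, mode = c("argmax", "sample"),
                             seed = 0) {
  mode <- match.arg(mode)
  schema <- model$schema
  start <- model$order[1]
  q0 <- schema$questionnaires[[start]]
  input <- as.matrix(input)
  if (ncol(input) != q0$questions) {
    stop("input must have ", q0$questions, " columns (the ", start,
         " items)", call. = FALSE)
  }
  if (anyNA(input)) stop("input rows must be complete", call. = FALSE)
  if (any(input < q0$answer_min | input > q0$answer_max)) {
    stop("input values outside the ", start, " answer rank {",
         q0$answer_min, "..", q0$answer_max, "}", call. = FALSE)
  }
  feat <- input
  out <- list()
  for (k in seq_along(model$steps)) {
    spec <- model$steps[[k]]
    if (ncol(feat) != spec$input_dim) {
      stop("model/schema mismatch at step ", k, call. = FALSE)
    }
    bank <- model$banks[[k]]
    block <- vapply(seq_along(bank), function(i)
      as.integer(predict_question(bank[[i]], feat, mode = mode,
                                  seed = derive_seed(seed, 7L, k, i))),
      integer(nrow(feat)))
    if (nrow(feat) == 1) block <- matrix(block, nrow = 1)
    q <- schema$questionnaires[[spec$target_questionnaire]]
    colnames(block) <- paste0(q$prefix, "_q", seq_len(q$questions))
    out[[spec$target_questionnaire]] <- block
    feat <- cbind(feat, block)
  }
  # assemble in schema block order (minus the input questionnaire)
  targets <- setdiff(questionnaire_names(schema), start)
  do.call(cbind, out[targets])
}
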