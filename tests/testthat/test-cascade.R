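test_that("class weights follow the balanced n/(classes*count) rule", {
  # the published HAD question 1 supports
  labels <- rep(0:3, times = c(66, 886, 807, 562))
  w <- compute_class_weights(labels)
  expect_equal(round(unname(w["2"]), 2), 0.72)
  expect_equal(round(unname(w["3"]), 2), 1.03)
  expect_equal(unname(w["0"]), 2321 / (4 * 66))
  # balanced supports give unit weights
  expect_equal(unname(compute_class_weights(rep(c("a", "b"), each = 50))),
               c(1, 1))
  # single observed class
  expect_equal(unname(compute_class_weights(rep(2, 17))), 1)
  # arbitrary supports equal brute-force evaluation of the formula
  set.seed(3)
  for (rep_i in 1:10) {
    y <- sample(0:4, 200, replace = TRUE, prob = runif(5))
    w <- compute_class_weights(y)
    for (l in names(w)) {
      expect_equal(unname(w[l]),
                   length(y) / (length(unique(y)) * sum(y == as.integer(l))))
    }
  }
  expect_error(compute_class_weights(integer(0)), "non-empty")
})

test_that("make_steps books the cascade dimensions correctly", {
  sch <- default_schema()
  steps <- make_steps(sch, paper_order)
  expect_length(steps, 5)
  expect_equal(vapply(steps, `[[`, 0L, "input_dim"),
               c(36L, 50L, 140L, 148L, 188L))
  expect_equal(vapply(steps, `[[`, 0L, "target_dim"),
               c(14L, 90L, 8L, 40L, 34L))
  expect_equal(steps[[2]]$target_questionnaire, "SCL 90 R")
  expect_equal(steps[[5]]$input_questionnaires,
               c("SF-36", "HAD", "SCL 90 R", "FIS8", "FIS40"))
  # per-step shipped hyperparameters attach in order
  expect_equal(steps[[1]]$hyperparams$neurons, c(400, 400, 200, 100))
  expect_equal(steps[[2]]$hyperparams$epochs, 3000)
  expect_error(make_steps(sch, c("HAD", "SF-36")), "permutation")
  toy_steps <- make_steps(toy_schema(), c("QA", "QB"))
  expect_length(toy_steps, 1)
  expect_equal(toy_steps[[1]]$input_dim, 2L)
})

test_that("backends honour the score contract on separable data", {
  set.seed(10)
  x <- matrix(rnorm(300), 150, 2)
  y <- ifelse(x[, 1] > 0, 1L, 0L)
  w <- compute_class_weights(y)
  for (kind in c("multinomial", "xgboost")) {
    fit <- fit_backend(kind, x, y, w, hyperparams(), seed = 1)
    s <- predict_scores(fit, x)
    expect_identical(colnames(s), c("0", "1"))
    expect_true(all(s >= 0))
    pred <- as.integer(colnames(s))[max.col(s, ties.method = "first")]
    expect_equal(mean(pred == y), 1.0)
  }
  expect_error(fit_backend("nope", x, y, w), "unknown backend")
})

test_that("the mlp backend trains with early stopping and is seed-stable", {
  set.seed(11)
  x <- matrix(rnorm(400), 200, 2)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] > 0, 1L, 0L)
  hp <- hyperparams(neurons = c(16, 8), dropout_layers = 1, epochs = 150,
                    patience = 40, learning_rate = 0.01)
  f1 <- fit_backend("mlp", x, y, compute_class_weights(y), hp, seed = 7)
  f2 <- fit_backend("mlp", x, y, compute_class_weights(y), hp, seed = 7)
  s1 <- predict_scores(f1, x)
  expect_identical(s1, predict_scores(f2, x))
  pred <- as.integer(colnames(s1))[max.col(s1, ties.method = "first")]
  expect_gt(mean(pred == y), 0.9)
  expect_gte(f1$val_recall, 0.8)
})

test_that("the rounded regressor rounds half away from zero and clamps", {
  x <- matrix(seq(0, 3, length.out = 40), ncol = 1)
  y <- as.integer(round(x[, 1]))
  hp <- hyperparams()
  hp$answer_rank <- 0:3
  fit <- fit_backend("regressor", x, y, compute_class_weights(y), hp)
  # near-perfect linear fit on y ~ x, so prediction at 2.6 is ~2.6 -> 3
  s <- predict_scores(fit, matrix(c(2.6, 4.2), ncol = 1))
  lab <- as.integer(colnames(s))
  pred <- lab[max.col(s, ties.method = "first")]
  expect_equal(pred[1], 3L)  # 2.6 rounds up
  expect_equal(pred[2], 3L)  # 4.2 clamps to the rank maximum
  expect_identical(colnames(s), as.character(0:3))
})

test_that("train_step fits one model per target item on complete cases", {
  sch <- toy_schema()
  set.seed(20)
  n <- 120
  qa1 <- sample(0:2, n, replace = TRUE)
  tab <- data.frame(
    qa_q1 = qa1, qa_q2 = sample(0:2, n, replace = TRUE),
    qb_q1 = ifelse(qa1 >= 1, 2L, 1L),  # deterministic in qa_q1
    qb_q2 = rep(3L, n)                 # constant
  )
  co <- suppressMessages(validate_cohort(tab, sch))
  spec <- make_steps(sch, c("QA", "QB"))[[1]]
  expect_warning(
    trained <- train_step(spec, co, NULL, quiet = TRUE),
    "single observed class"
  )
  expect_length(trained$bank, 2)
  expect_equal(trained$summary$train_accuracy, c(1, 1))
  expect_equal(trained$bank[[2]]$constant, 3L)
  # held-out prediction of the separable item is perfect
  new_x <- cbind(c(0, 1, 2, 0), c(1, 1, 1, 1))
  pred <- synthq:::predict_question(trained$bank[[1]], new_x)
  expect_equal(pred, c(1, 2, 2, 1))
  # too few records errors
  tiny <- suppressMessages(validate_cohort(tab[1:10, ], sch))
  expect_error(train_step(spec, tiny, NULL, quiet = TRUE), "minimum")
})

test_that("step 1 of the default battery trains 14 question models", {
  co <- generate_cohort(default_paper_like_spec(150, seed = 1))
  spec <- make_steps(default_schema(), paper_order)[[1]]
  trained <- train_step(spec, co, NULL, quiet = TRUE)
  expect_length(trained$bank, 14)
})

test_that("class weighting raises minority recall on 9:1 imbalanced data", {
  set.seed(30)
  n <- 600
  y <- rep(c(0L, 1L), times = c(540, 60))
  x <- matrix(rnorm(n, mean = y * 1.2), ncol = 1)  # overlapping classes
  w_bal <- compute_class_weights(y)
  w_flat <- stats::setNames(c(1, 1), c("0", "1"))
  recall1 <- function(w) {
    fit <- fit_backend("multinomial", x, y, w)
    s <- predict_scores(fit, x)
    pred <- as.integer(colnames(s))[max.col(s, ties.method = "first")]
    sum(pred == 1 & y == 1) / sum(y == 1)
  }
  expect_gte(recall1(w_bal), recall1(w_flat))
  expect_lt(recall1(w_flat), 1)  # the toy is genuinely non-separable
})

test_that("train_cascade builds 186 question models over 5 steps", {
  co <- generate_cohort(default_paper_like_spec(320, seed = 6))
  m <- suppressWarnings(
    train_cascade(co, order = paper_order, config = list(quiet = TRUE),
                  seed = 2))
  expect_s3_class(m, "synthq_cascade")
  expect_length(m$steps, 5)
  expect_equal(sum(vapply(m$banks, length, 0L)), 186L)
  expect_equal(m$order, paper_order)
  # record counts shrink (or stay equal) as steps require more real blocks
  expect_true(all(diff(m$provenance$step_records) <= 0))
})

test_that("a toy schema yields a one-step cascade", {
  sch <- toy_schema()
  tab <- toy_table(60, seed = 2)
  co <- suppressMessages(validate_cohort(tab, sch))
  m <- suppressWarnings(train_cascade(co, order = c("QA", "QB"),
                                      config = list(quiet = TRUE)))
  expect_length(m$steps, 1)
  out <- generate_battery(m, as.matrix(tab[1:5, 1:2]))
  expect_equal(dim(out), c(5L, 2L))
  expect_identical(colnames(out), c("qb_q1", "qb_q2"))
})

test_that("generated batteries stay within every item's answer rank", {
  co <- generate_cohort(default_paper_like_spec(320, seed = 6))
  m <- suppressWarnings(
    train_cascade(co, order = paper_order, config = list(quiet = TRUE),
                  seed = 2))
  sch <- default_schema()
  set.seed(40)
  inp <- matrix(sample(1:6, 1000 * 36, replace = TRUE), 1000)
  for (mode in c("argmax", "sample")) {
    out <- generate_battery(m, inp, mode = mode, seed = 3)
    expect_equal(ncol(out), 186)
    for (q in sch$questionnaires[-1]) {
      block <- out[, paste0(q$prefix, "_q", seq_len(q$questions))]
      expect_true(all(block >= q$answer_min & block <= q$answer_max))
    }
  }
  expect_error(generate_battery(m, inp[, 1:10]), "36 columns")
  bad <- inp[1:5, ]; bad[1, 1] <- 7L
  expect_error(generate_battery(m, bad), "answer rank")
  bad2 <- inp[1:5, ]; bad2[2, 3] <- NA
  expect_error(generate_battery(m, bad2), "complete")
})

test_that("cascade archives round-trip through save/load", {
  sch <- toy_schema()
  co <- suppressMessages(validate_cohort(toy_table(60, seed = 5), sch))
  m <- suppressWarnings(train_cascade(co, order = c("QA", "QB"),
                                      config = list(quiet = TRUE)))
  path <- tempfile(fileext = ".rds")
  save_cascade(m, path)
  back <- load_cascade(path)
  inp <- as.matrix(toy_table(10, seed = 6)[, 1:2])
  expect_identical(generate_battery(back, inp), generate_battery(m, inp))
  expect_identical(back$provenance, m$provenance)
  unlink(path)
  expect_error(load_cascade(tempfile()), "not found")
})
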