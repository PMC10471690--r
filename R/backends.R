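#' Classifier backend contract
#'
#' Every per-question model in the cascade is fitted through a pluggable
#' backend. A backend is identified by a kind string and must implement
#' `fit_backend(kind, x, y, class_weights, hyperparams, seed)`, returning an
#' object for which [predict_scores()] yields one non-negative score per
#' observed label (columns named by label, rows aligned to the input).
#'
#' Shipped backends:
#' \describe{
#'   \item{`"multinomial"`}{class-weighted multinomial logistic regression
#'     fitted by deterministic full-batch gradient descent (zero
#'     initialisation, momentum). The default: fast, seed-independent and
#'     bitwise reproducible.}
#'   \item{`"mlp"`}{a feed-forward network with ReLU hidden layers, dropout,
#'     class-weighted cross-entropy, Adam, and early stopping on validation
#'     macro recall, honouring the per-step hyperparameter tables.}
#'   \item{`"xgboost"`}{gradient-boosted trees via the xgboost package
#'     (optional; only available when xgboost is installed).}
#'   \item{`"regressor"`}{class-weighted linear least squares whose continuous
#'     prediction is rounded half away from zero and clamped to the item's
#'     answer rank; provided for the regression-versus-classification
#'     comparison, in which rounded regression shows much larger mean error.}
#' }
#'
#' @param kind backend kind string
#' @param x numeric feature matrix (records x features)
#' @param y integer label vector
#' @param class_weights named per-label weights (see
#'   [compute_class_weights()])
#' @param hyperparams a [hyperparams()] list (backends use the fields they
#'   understand); `NULL` for all-default settings
#' @param seed integer seed for stochastic backends
#' @return a fitted backend object
#' @export
fit_backend <- function(kind, x, y, class_weights, hyperparams = NULL,
                        seed = 0) {
  if (is.null(hyperparams)) {
    hyperparams <- structure(list(), class = "synthq_hyperparams")
  }
  fitter <- switch(kind,
    multinomial = fit_multinomial,
    mlp = fit_mlp,
    xgboost = fit_xgb,
    regressor = fit_regressor,
    stop("unknown backend kind '", kind, "'", call. = FALSE)
  )
  fitter(as.matrix(x), as.integer(y), class_weights, hyperparams, seed)
}

#' Per-label scores from a fitted backend
#' @param object a fitted backend object
#' @param x feature matrix
#' @return matrix records x observed labels, columns named by label
#' @export
predict_scores <- function(object, x) {
  UseMethod("predict_scores")
}

check_scores <- function(scores, object) {
  if (!identical(colnames(scores), as.character(object$labels))) {
    stop("backend contract violation: score columns ",
         paste(colnames(scores), collapse = ","), " do not match observed ",
         "labels ", paste(object$labels, collapse = ","), call. = FALSE)
  }
  scores
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

softmax <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

# ---- multinomial: weighted softmax regression, deterministic -----------

fit_multinomial <- function(x, y, class_weights, hp, seed) {
  labels <- sort(unique(y))
  K <- length(labels)
  std <- standardize_fit(x)
  xs <- cbind(1, standardize_apply(x, std))
  n <- nrow(xs); p <- ncol(xs)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(y, labels))] <- 1
  w <- unname(class_weights[as.character(y)])
  w <- w / mean(w)
  iters <- hp$iterations %||% 150L
  lr <- hp$learning_rate %||% 0.3
  l2 <- hp$l2 %||% 1e-4
  W <- matrix(0, p, K)
  V <- matrix(0, p, K)
  for (it in seq_len(iters)) {
    P <- softmax(xs %*% W)
    G <- crossprod(xs, (P - Y) * w) / n
    G[-1, ] <- G[-1, ] + l2 * W[-1, ]
    V <- 0.9 * V - lr * G
    W <- W + V
  }
  structure(list(labels = labels, W = W, std = std),
            class = c("synthq_multinomial", "synthq_backend"))
}

#' @export
predict_scores.synthq_multinomial <- function(object, x) {
  xs <- cbind(1, standardize_apply(as.matrix(x), object$std))
  s <- softmax(xs %*% object$W)
  colnames(s) <- as.character(object$labels)
  check_scores(s, object)
}

# ---- mlp: feed-forward net with val-recall early stopping --------------

macro_recall <- function(y_true, y_pred, labels) {
  mean(vapply(labels, function(l) {
    denom <- sum(y_true == l)
    if (denom == 0) return(NA_real_)
    sum(y_true == l & y_pred == l) / denom
  }, 0.0), na.rm = TRUE)
}

fit_mlp <- function(x, y, class_weights, hp, seed) {
  labels <- sort(unique(y))
  K <- length(labels)
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  n <- nrow(xs)
  neurons <- hp$neurons %||% c(32, 16)
  n_drop <- hp$dropout_layers %||% 0L
  drop_rate <- hp$dropout_rate %||% 0.2
  epochs <- hp$epochs %||% 200L
  patience <- hp$patience %||% 50L
  lr <- hp$learning_rate %||% 1e-3
  val_frac <- hp$validation_fraction %||% 0.2

  with_seed(seed, {
    # stratified validation split for the recall monitor
    val <- logical(n)
    for (l in labels) {
      idx <- which(y == l)
      n_val <- max(1L, floor(length(idx) * val_frac))
      if (length(idx) > 1) val[sample(idx, min(n_val, length(idx) - 1L))] <- TRUE
    }
    tr <- which(!val); va <- which(val)
    yt <- match(y, labels)
    Yt <- matrix(0, length(tr), K)
    Yt[cbind(seq_along(tr), yt[tr])] <- 1
    w <- unname(class_weights[as.character(y[tr])])
    w <- w / mean(w)

    sizes <- c(ncol(xs), neurons, K)
    L <- length(sizes) - 1L
    Ws <- lapply(seq_len(L), function(i) {
      matrix(stats::rnorm(sizes[i] * sizes[i + 1], sd = sqrt(2 / sizes[i])),
             sizes[i], sizes[i + 1])
    })
    bs <- lapply(seq_len(L), function(i) rep(0, sizes[i + 1]))
    mW <- lapply(Ws, function(W) W * 0); vW <- mW
    mb <- lapply(bs, function(b) b * 0); vb <- mb
    dropout_on <- seq_len(L - 1) <= n_drop

    forward <- function(X, training) {
      acts <- list(X)
      for (i in seq_len(L)) {
        z <- sweep(acts[[i]] %*% Ws[[i]], 2, bs[[i]], "+")
        if (i < L) {
          a <- pmax(z, 0)
          if (training && dropout_on[i]) {
            mask <- matrix(stats::runif(length(a)) > drop_rate,
                           nrow(a), ncol(a)) / (1 - drop_rate)
            a <- a * mask
          }
        } else {
          a <- softmax(z)
        }
        acts[[i + 1]] <- a
      }
      acts
    }

    best <- list(recall = -Inf, Ws = Ws, bs = bs, since = 0L)
    beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8; t_adam <- 0
    Xtr <- xs[tr, , drop = FALSE]
    Xva <- xs[va, , drop = FALSE]
    for (ep in seq_len(epochs)) {
      acts <- forward(Xtr, training = TRUE)
      P <- acts[[L + 1]]
      delta <- (P - Yt) * w / length(tr)
      t_adam <- t_adam + 1
      for (i in rev(seq_len(L))) {
        gW <- crossprod(acts[[i]], delta)
        gb <- colSums(delta)
        if (i > 1) {
          delta <- (delta %*% t(Ws[[i]])) * (acts[[i]] > 0)
        }
        mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gW
        vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gW^2
        mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gb
        vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gb^2
        mhW <- mW[[i]] / (1 - beta1^t_adam); vhW <- vW[[i]] / (1 - beta2^t_adam)
        mhb <- mb[[i]] / (1 - beta1^t_adam); vhb <- vb[[i]] / (1 - beta2^t_adam)
        Ws[[i]] <- Ws[[i]] - lr * mhW / (sqrt(vhW) + epsadam)
        bs[[i]] <- bs[[i]] - lr * mhb / (sqrt(vhb) + epsadam)
      }
      if (length(va) > 0) {
        Pv <- forward(Xva, training = FALSE)[[L + 1]]
        pred <- labels[max.col(Pv, ties.method = "first")]
        rec <- macro_recall(y[va], pred, labels)
      } else {
        rec <- 0
      }
      if (rec > best$recall + 1e-9) {
        best <- list(recall = rec, Ws = Ws, bs = bs, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) break
      }
    }
    structure(list(labels = labels, Ws = best$Ws, bs = best$bs, std = std,
                   val_recall = best$recall, sizes = sizes),
              class = c("synthq_mlp", "synthq_backend"))
  })
}

#' @export
predict_scores.synthq_mlp <- function(object, x) {
  a <- standardize_apply(as.matrix(x), object$std)
  L <- length(object$Ws)
  for (i in seq_len(L)) {
    z <- sweep(a %*% object$Ws[[i]], 2, object$bs[[i]], "+")
    a <- if (i < L) pmax(z, 0) else softmax(z)
  }
  colnames(a) <- as.character(object$labels)
  check_scores(a, object)
}

# ---- xgboost: gradient-boosted trees ------------------------------------

fit_xgb <- function(x, y, class_weights, hp, seed) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the 'xgboost' backend requires the xgboost package", call. = FALSE)
  }
  labels <- sort(unique(y))
  K <- length(labels)
  w <- unname(class_weights[as.character(y)])
  with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(data = x, label = match(y, labels) - 1L,
                                   weight = w, nthread = 1)
    params <- list(
      objective = if (K > 2) "multi:softprob" else "binary:logistic",
      max_depth = hp$max_depth %||% 4L,
      eta = hp$eta %||% 0.3,
      nthread = 1
    )
    if (K > 2) params$num_class <- K
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = hp$nrounds %||% 50L, verbose = 0)
    structure(list(labels = labels, booster = booster, K = K),
              class = c("synthq_xgb", "synthq_backend"))
  })
}

#' @export
predict_scores.synthq_xgb <- function(object, x) {
  d <- xgboost::xgb.DMatrix(data = as.matrix(x), nthread = 1)
  p <- stats::predict(object$booster, d)
  s <- if (object$K > 2) {
    if (is.matrix(p)) p else matrix(p, ncol = object$K, byrow = TRUE)
  } else {
    cbind(1 - p, p)
  }
  dimnames(s) <- NULL
  colnames(s) <- as.character(object$labels)
  check_scores(s, object)
}

# ---- regressor: rounded + clamped linear least squares ------------------

fit_regressor <- function(x, y, class_weights, hp, seed) {
  rank <- hp$answer_rank
  if (is.null(rank)) rank <- seq(min(y), max(y))
  w <- unname(class_weights[as.character(y)])
  std <- standardize_fit(x)
  xs <- cbind(1, standardize_apply(x, std))
  fit <- stats::lm.wfit(xs, as.numeric(y), w)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(labels = as.integer(rank), coef = coefs, std = std),
            class = c("synthq_regressor", "synthq_backend"))
}

#' @export
predict_scores.synthq_regressor <- function(object, x) {
  xs <- cbind(1, standardize_apply(as.matrix(x), object$std))
  yhat <- drop(xs %*% object$coef)
  lab <- object$labels
  pred <- pmin(pmax(round_half_away(yhat), min(lab)), max(lab))
  s <- matrix(0, length(pred), length(lab),
              dimnames = list(NULL, as.character(lab)))
  s[cbind(seq_along(pred), match(pred, lab))] <- 1
  check_scores(s, object)
}
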