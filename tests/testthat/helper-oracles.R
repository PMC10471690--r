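# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops and textbook formulas only.

# confusion-matrix metrics by explicit counting
oracle_report <- function(y_true, y_pred, labels = sort(unique(c(y_true, y_pred)))) {
  per <- list()
  for (l in labels) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(y_true)) {
      if (y_pred[i] == l && y_true[i] == l) tp <- tp + 1
      if (y_pred[i] == l && y_true[i] != l) fp <- fp + 1
      if (y_pred[i] != l && y_true[i] == l) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    per[[as.character(l)]] <- c(precision = prec, recall = rec, f1 = f1,
                                support = tp + fn)
  }
  acc <- sum(y_true == y_pred) / length(y_true)
  list(per_label = per, accuracy = acc)
}

# pairwise-complete Pearson r by the direct covariance formula
oracle_pearson <- function(x) {
  p <- ncol(x)
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      if (sum(ok) < 3) next
      a <- x[ok, i]; b <- x[ok, j]
      sa <- sqrt(sum((a - mean(a))^2)); sb <- sqrt(sum((b - mean(b))^2))
      if (sa == 0 || sb == 0) next
      r[i, j] <- sum((a - mean(a)) * (b - mean(b))) / (sa * sb)
    }
  }
  diag(r) <- 1
  r
}

# exhaustive re-execution of the stated greedy ordering rule on an adjacency
# matrix whose nodes are labelled with questionnaire names
oracle_greedy_order <- function(adj, node_q, start) {
  tests <- unique(node_q)
  selected <- start
  remaining <- setdiff(tests, start)
  while (length(remaining) > 0) {
    best <- NULL
    for (j in sort(remaining)) {
      tgt <- which(node_q == j)
      src <- which(node_q %in% selected)
      covered <- 0
      for (t in tgt) {
        if (any(adj[t, src])) covered <- covered + 1
      }
      cand <- list(test = j, coverage = covered / length(tgt),
                   covered = covered, size = length(tgt))
      better <- is.null(best) ||
        cand$coverage > best$coverage + 1e-12 ||
        (abs(cand$coverage - best$coverage) <= 1e-12 &&
           (cand$covered > best$covered ||
              (cand$covered == best$covered && cand$size < best$size)))
      if (better) best <- cand
    }
    selected <- c(selected, best$test)
    remaining <- setdiff(remaining, best$test)
  }
  selected
}

# independent implementation of the latent-trait ordinal generator: draws
# per-subject traits directly and discretises via the probability integral
# transform rather than quantile thresholds
oracle_latent_ordinal <- function(n, lambda, subject_of, answer_min, answer_max,
                                  seed) {
  set.seed(seed)
  subjects <- unique(subject_of)
  z <- sapply(subjects, function(s) rnorm(n))
  colnames(z) <- subjects
  K <- answer_max - answer_min + 1
  out <- matrix(NA_integer_, n, length(subject_of))
  for (j in seq_along(subject_of)) {
    u <- lambda * z[, subject_of[j]] + sqrt(1 - lambda^2) * rnorm(n)
    out[, j] <- answer_min + as.integer(cut(pnorm(u),
                                            breaks = seq(0, 1, length.out = K + 1),
                                            include.lowest = TRUE)) - 1L
  }
  out
}

# same generative formula over a whole battery with independent subject
# traits, one questionnaire block at a time
oracle_latent_ordinal_battery <- function(n, lambda, schema, subject_of, seed) {
  set.seed(seed)
  subjects <- unique(subject_of)
  z <- sapply(subjects, function(s) rnorm(n))
  colnames(z) <- subjects
  out <- matrix(NA_integer_, n, length(subject_of))
  j <- 0
  for (q in schema$questionnaires) {
    K <- q$answer_max - q$answer_min + 1
    for (i in seq_len(q$questions)) {
      j <- j + 1
      u <- lambda * z[, subject_of[j]] + sqrt(1 - lambda^2) * rnorm(n)
      out[, j] <- q$answer_min +
        as.integer(cut(pnorm(u), breaks = seq(0, 1, length.out = K + 1),
                       include.lowest = TRUE)) - 1L
    }
  }
  out
}

# Welch statistic and p-value straight from the textbook formulas
oracle_welch_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va / na + vb / nb)
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t_stat), df)
}
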