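test_that("pearson_matrix reproduces textbook Pearson behaviour", {
  set.seed(1)
  x <- matrix(rnorm(60), 20)
  dup <- cbind(x, x[, 1], -x[, 1])
  r <- pearson_matrix(dup)
  expect_equal(r[1, 4], 1.0)
  expect_equal(r[1, 5], -1.0)
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 5))
})

test_that("pairwise-complete correlations match the brute-force formula", {
  set.seed(2)
  n <- 200
  z <- rnorm(n)
  scores <- cbind(z + rnorm(n, sd = 0.3), z + rnorm(n, sd = 0.3),
                  rnorm(n), rnorm(n))
  scores[sample(n, 40), 2] <- NA
  scores[sample(n, 30), 4] <- NA
  expect_equal(unname(pearson_matrix(scores)), oracle_pearson(scores),
               tolerance = 1e-12)
})

test_that("thin and constant pairs yield missing correlations", {
  x <- matrix(rnorm(40), 10)
  x[1:8, 2] <- NA  # only 2 complete pairs with every other column
  expect_warning(r <- pearson_matrix(x), "fewer than 3")
  expect_true(all(is.na(r[2, -2])))
  expect_equal(r[2, 2], 1)
  y <- cbind(rnorm(10), rep(5, 10))
  ry <- pearson_matrix(y)
  expect_true(is.na(ry[1, 2]))
  g <- build_graph(ry[c(1, 2), c(1, 2)], toy_schema())
  expect_equal(nrow(g$edges), 0)
})

test_that("build_graph thresholds |r| and counts degrees", {
  sch <- default_schema()
  p <- n_subscales(sch)
  g0 <- build_graph(diag(p), sch)
  expect_equal(nrow(g0$nodes), 38)
  expect_equal(nrow(g0$edges), 0)
  g1 <- build_graph(matrix(1, p, p), sch)
  expect_equal(nrow(g1$edges), choose(38, 2))
  expect_equal(unique(g1$nodes$degree), 37L)
  expect_error(build_graph(diag(p), sch, tau = 0), "tau")
  expect_error(build_graph(diag(p), sch, tau = 1.5), "tau")
  expect_error(build_graph(diag(3), sch), "38 subscales")
})

test_that("graph edges equal brute-force thresholding of the oracle matrix", {
  sch <- default_schema()
  co <- generate_cohort(default_paper_like_spec(400, seed = 5), sch)
  scores <- score_subscales(co)
  oracle <- oracle_pearson(scores)
  g <- build_graph(pearson_matrix(scores), sch)
  st <- subscale_table(sch)
  expected <- list()
  for (i in seq_len(37)) {
    for (j in (i + 1):38) {
      if (!is.na(oracle[i, j]) && abs(oracle[i, j]) >= 0.5) {
        expected[[length(expected) + 1]] <- paste(st$subscale[i],
                                                  st$subscale[j], sep = "|")
      }
    }
  }
  got <- paste(g$edges$node_a, g$edges$node_b, sep = "|")
  expect_setequal(got, unlist(expected))
})

test_that("graph is invariant to record permutation and affine score maps", {
  sch <- default_schema()
  co <- generate_cohort(default_paper_like_spec(300, seed = 8), sch)
  scores <- score_subscales(co)
  g <- build_graph(pearson_matrix(scores), sch)
  perm <- sample(nrow(scores))
  g_perm <- build_graph(pearson_matrix(scores[perm, ]), sch)
  expect_equal(g_perm$edges[order(g_perm$edges$node_a, g_perm$edges$node_b), ],
               g$edges[order(g$edges$node_a, g$edges$node_b), ],
               tolerance = 1e-12, ignore_attr = TRUE)
  affine <- sweep(sweep(scores, 2, runif(38, 0.5, 3), "*"), 2,
                  runif(38, -5, 5), "+")
  g_aff <- build_graph(pearson_matrix(affine), sch)
  expect_identical(g_aff$edges[, 1:2], g$edges[, 1:2])
})

test_that("raising the threshold never adds edges", {
  sch <- default_schema()
  co <- generate_cohort(default_paper_like_spec(300, seed = 2), sch)
  r <- pearson_matrix(score_subscales(co))
  taus <- c(0.3, 0.5, 0.7, 0.9)
  sizes <- vapply(taus, function(tau) nrow(build_graph(r, sch, tau)$edges), 0)
  expect_true(all(diff(sizes) <= 0))
  edge_key <- function(tau) {
    e <- build_graph(r, sch, tau)$edges
    paste(e$node_a, e$node_b)
  }
  expect_true(all(edge_key(0.7) %in% edge_key(0.5)))
})

test_that("coverage counts adjacent target nodes", {
  sch <- default_schema()
  g <- build_graph(narrative_corr(sch), sch)
  expect_equal(graph_coverage(g, "SF-36", "HAD"), 1.0)
  expect_equal(graph_coverage(g, "SF-36", "SCL 90 R"), 4 / 12)
  expect_equal(graph_coverage(g, "HAD", "SCL 90 R"), 1.0)
  expect_equal(graph_coverage(g, "SF-36", "PSQI"), 0.0)
  expect_error(graph_coverage(g, "SF-36", "nope"), "unknown questionnaire")
  expect_error(graph_coverage(g, c("SF-36", "HAD"), "HAD"), "must not belong")
})

test_that("coverage equals a brute-force adjacency scan on random graphs", {
  sch <- default_schema()
  st <- subscale_table(sch)
  for (seed in 1:5) {
    set.seed(seed)
    p <- nrow(st)
    r <- matrix(runif(p * p, -1, 1), p)
    r <- (r + t(r)) / 2
    diag(r) <- 1
    g <- build_graph(r, sch, tau = 0.7)
    adj <- abs(r) >= 0.7
    diag(adj) <- FALSE
    from <- sample(unique(st$questionnaire), 2)
    to <- setdiff(unique(st$questionnaire), from)[1]
    tgt <- which(st$questionnaire == to)
    src <- which(st$questionnaire %in% from)
    manual <- mean(vapply(tgt, function(t) any(adj[t, src]), TRUE))
    expect_equal(graph_coverage(g, from, to), manual)
  }
})

test_that("cascade_order reproduces the narrated questionnaire order", {
  sch <- default_schema()
  g <- build_graph(narrative_corr(sch), sch)
  expect_equal(as.character(cascade_order(g)), paper_order)
  trail <- attr(cascade_order(g), "trail")
  expect_length(trail, 5)
})

test_that("cascade_order equals exhaustive greedy re-execution", {
  sch <- default_schema()
  st <- subscale_table(sch)
  for (seed in 1:8) {
    set.seed(100 + seed)
    p <- nrow(st)
    r <- matrix(0, p, p)
    pairs <- which(upper.tri(r))
    on <- sample(pairs, round(length(pairs) * 0.08))
    r[on] <- 0.9
    r <- r + t(r)
    diag(r) <- 1
    g <- build_graph(r, sch)
    adj <- abs(r) >= 0.5
    diag(adj) <- FALSE
    expect_equal(as.character(cascade_order(g, start = "SF-36")),
                 oracle_greedy_order(adj, st$questionnaire, "SF-36"))
  }
})

test_that("two-questionnaire graphs order trivially", {
  sch <- toy_schema()
  g <- build_graph(diag(2), sch)
  expect_equal(as.character(cascade_order(g, start = "QA")), c("QA", "QB"))
})

test_that("graph exports round-trip and carry attributes", {
  sch <- default_schema()
  g <- build_graph(narrative_corr(sch), sch)
  edges_path <- tempfile(fileext = ".csv")
  write_edge_list(g, edges_path)
  back <- utils::read.csv(edges_path)
  expect_equal(nrow(back), nrow(g$edges))
  expect_equal(back$r, g$edges$r)
  nodes_path <- tempfile(fileext = ".csv")
  write_node_table(g, nodes_path)
  nodes <- utils::read.csv(nodes_path)
  expect_equal(nrow(nodes), 38)
  gm <- tempfile(fileext = ".graphml")
  write_graphml(g, gm)
  ig <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::gorder(ig), 38)
  expect_equal(igraph::gsize(ig), nrow(g$edges))
  unlink(c(edges_path, nodes_path, gm))
  sg <- subject_graph(g)
  expect_true(all(sg$subject_a < sg$subject_b))
})
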