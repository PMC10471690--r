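#' Pairwise-complete Pearson correlation matrix of subscale scores
#'
#' Correlations are computed on the records where both subscales are present
#' (register counts differ per questionnaire, so complete-case deletion across
#' the whole battery would discard most of the data; a complete-case switch is
#' provided for comparison). Pairs with fewer than `min_n` pairwise-complete
#' records, and pairs involving a constant column, get `NA` and generate no
#' graph edge.
#'
#' @param scores records x subscales numeric matrix, possibly with `NA`
#' @param use `"pairwise"` (default) or `"complete"` case handling
#' @param min_n minimum pairwise-complete records per pair (default 3)
#' @return symmetric correlation matrix with unit diagonal; `NA` where
#'   undefined
#' @export
pearson_matrix <- function(scores, use = c("pairwise", "complete"), min_n = 3) {
  use <- match.arg(use)
  scores <- as.matrix(scores)
  if (use == "complete") {
    scores <- scores[stats::complete.cases(scores), , drop = FALSE]
  }
  obs <- !is.na(scores)
  n_pair <- crossprod(obs)
  suppressWarnings(
    r <- stats::cor(scores, use = "pairwise.complete.obs")
  )
  thin <- n_pair < min_n
  if (any(thin & upper.tri(thin))) {
    warning("some subscale pairs have fewer than ", min_n,
            " pairwise-complete records; their correlations are undefined",
            call. = FALSE)
  }
  r[thin] <- NA_real_
  diag(r) <- 1
  r
}

#' Build the thresholded correlation graph over subscales
#'
#' Nodes are all subscales of the schema; an undirected edge joins subscales
#' `i` and `j` whenever `|corr(i, j)| >= tau` (strong negative correlations
#' count as relationships too). Undefined correlations yield no edge.
#'
#' @param corr symmetric correlation matrix, columns in the schema's subscale
#'   order
#' @param schema a `synthq_schema`
#' @param tau edge threshold in `(0, 1]` (default 0.5, the conventional
#'   boundary of a moderate correlation)
#' @return a `synthq_graph`: list with `nodes` (data.frame: subscale,
#'   questionnaire, subject, degree) and `edges` (data.frame: node_a, node_b,
#'   r), plus the threshold
#' @export
build_graph <- function(corr, schema, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  nodes <- subscale_table(schema)
  p <- nrow(nodes)
  if (!all(dim(corr) == c(p, p))) {
    stop("correlation matrix is ", nrow(corr), "x", ncol(corr),
         " but the schema defines ", p, " subscales", call. = FALSE)
  }
  adj <- !is.na(corr) & abs(corr) >= tau
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(
    node_a = nodes$subscale[idx[, 1]],
    node_b = nodes$subscale[idx[, 2]],
    r = corr[idx],
    stringsAsFactors = FALSE
  )
  nodes$degree <- as.integer(rowSums(adj))
  structure(
    list(nodes = nodes, edges = edges, tau = tau),
    class = "synthq_graph"
  )
}

#' @export
print.synthq_graph <- function(x, ...) {
  cat("<synthq_graph>", nrow(x$nodes), "subscale nodes,",
      nrow(x$edges), sprintf("edges (|r| >= %g)\n", x$tau))
  invisible(x)
}

adjacency_lookup <- function(graph) {
  p <- nrow(graph$nodes)
  adj <- matrix(FALSE, p, p,
                dimnames = list(graph$nodes$subscale, graph$nodes$subscale))
  if (nrow(graph$edges) > 0) {
    ia <- match(graph$edges$node_a, graph$nodes$subscale)
    ib <- match(graph$edges$node_b, graph$nodes$subscale)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  adj
}

#' Coverage of one questionnaire's nodes by a set of questionnaires
#'
#' The fraction of `to_test`'s subscale nodes adjacent to at least one node
#' belonging to any questionnaire in `from_tests`. This is the relationship
#' strength that drives the cascade ordering: a test fully covered by the
#' already-selected tests is the natural next target.
#'
#' @param graph a `synthq_graph`
#' @param from_tests character vector of questionnaire names
#' @param to_test single questionnaire name, not in `from_tests`
#' @return fraction in `[0, 1]`
#' @export
graph_coverage <- function(graph, from_tests, to_test) {
  known <- unique(graph$nodes$questionnaire)
  bad <- setdiff(c(from_tests, to_test), known)
  if (length(bad) > 0) {
    stop("unknown questionnaire(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (to_test %in% from_tests) {
    stop("to_test must not belong to from_tests", call. = FALSE)
  }
  covered_nodes(graph, from_tests, to_test) /
    sum(graph$nodes$questionnaire == to_test)
}

covered_nodes <- function(graph, from_tests, to_test) {
  adj <- adjacency_lookup(graph)
  tgt <- graph$nodes$questionnaire == to_test
  src <- graph$nodes$questionnaire %in% from_tests
  if (!any(tgt)) return(0L)
  sum(apply(adj[tgt, src, drop = FALSE], 1, any))
}

#' Greedy cascade ordering of questionnaires
#'
#' Starting from the input questionnaire, repeatedly appends the unselected
#' questionnaire whose subscale nodes are best covered by the union of the
#' already-selected ones (the cascade feeds every previously generated block
#' into the next step, so the union is the relevant source set). Ties are
#' broken by (1) larger absolute number of covered nodes, (2) smaller own node
#' count, (3) questionnaire name; the trail of choices is attached as the
#' `"trail"` attribute.
#'
#' @param graph a `synthq_graph`
#' @param start name of the input questionnaire (default `"SF-36"`)
#' @return character vector: all questionnaires in generation order, starting
#'   with `start`
#' @export
cascade_order <- function(graph, start = "SF-36") {
  tests <- unique(graph$nodes$questionnaire)
  if (!start %in% tests) {
    stop("unknown start questionnaire '", start, "'", call. = FALSE)
  }
  selected <- start
  remaining <- setdiff(tests, start)
  trail <- list()
  while (length(remaining) > 0) {
    cand <- data.frame(
      test = remaining,
      coverage = vapply(remaining, function(j)
        graph_coverage(graph, selected, j), 0.0),
      covered = vapply(remaining, function(j)
        as.numeric(covered_nodes(graph, selected, j)), 0.0),
      size = vapply(remaining, function(j)
        sum(graph$nodes$questionnaire == j), 0L),
      stringsAsFactors = FALSE
    )
    ord <- order(-cand$coverage, -cand$covered, cand$size, cand$test)
    pick <- cand$test[ord[1]]
    trail[[length(trail) + 1L]] <- cand[ord, ]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(selected, trail = trail)
}

#' Export a graph as an edge-list CSV
#' @param graph a `synthq_graph`
#' @param path destination CSV (columns node_a, node_b, r)
#' @return `path`, invisibly
#' @export
write_edge_list <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' Export a graph's node attribute table as CSV
#' @param graph a `synthq_graph`
#' @param path destination CSV (columns subscale, questionnaire, subject,
#'   n_items, degree)
#' @return `path`, invisibly
#' @export
write_node_table <- function(graph, path) {
  utils::write.csv(graph$nodes, path, row.names = FALSE)
  invisible(path)
}

#' Convert to an igraph object
#' @param graph a `synthq_graph`
#' @return an undirected [igraph::igraph] with node attributes
#'   `questionnaire` and `subject` and edge attribute `r`
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes$subscale,
                          questionnaire = graph$nodes$questionnaire,
                          subject = graph$nodes$subject,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Export a graph in GraphML format
#' @param graph a `synthq_graph`
#' @param path destination `.graphml` file
#' @return `path`, invisibly
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Aggregate the subscale graph to subject areas
#'
#' Collapses subscale nodes sharing a subject label into one node; two
#' subjects are linked if any pair of their subscales is linked.
#'
#' @param graph a `synthq_graph`
#' @return data.frame of subject-level edges (subject_a, subject_b, n_links)
#' @export
subject_graph <- function(graph) {
  if (nrow(graph$edges) == 0) {
    return(data.frame(subject_a = character(0), subject_b = character(0),
                      n_links = integer(0)))
  }
  subj <- stats::setNames(graph$nodes$subject, graph$nodes$subscale)
  a <- subj[graph$edges$node_a]
  b <- subj[graph$edges$node_b]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  keep <- a != b
  if (!any(keep)) {
    return(data.frame(subject_a = character(0), subject_b = character(0),
                      n_links = integer(0)))
  }
  agg <- stats::aggregate(list(n_links = rep(1L, sum(keep))),
                          by = list(subject_a = a[keep], subject_b = b[keep]),
                          FUN = sum)
  agg[order(agg$subject_a, agg$subject_b), , drop = FALSE]
}
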