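# small schemas and cohorts built in code

# two questionnaires, two items each, for plumbing tests
toy_schema_list <- function() {
  list(
    questionnaires = list(
      list(name = "QA", prefix = "qa", questions = 2, answer_min = 0,
           answer_max = 2, has_total = TRUE,
           subscales = list(list(name = "QA total", subject = "Alpha",
                                 items = c(1, 2)))),
      list(name = "QB", prefix = "qb", questions = 2, answer_min = 1,
           answer_max = 3, has_total = TRUE,
           subscales = list(list(name = "QB total", subject = "Beta",
                                 items = c(1, 2))))
    )
  )
}

toy_schema <- function() {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(toy_schema_list(), path, auto_unbox = TRUE)
  on.exit(unlink(path))
  load_schema(path)
}

# complete data frame for the toy schema
toy_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    qa_q1 = sample(0:2, n, replace = TRUE),
    qa_q2 = sample(0:2, n, replace = TRUE),
    qb_q1 = sample(1:3, n, replace = TRUE),
    qb_q2 = sample(1:3, n, replace = TRUE)
  )
}

# a correlation matrix over the default schema's 38 subscales encoding the
# narrated inter-questionnaire relationships: SF-36 covers all HAD nodes and
# a minority of SCL 90 R; HAD covers all SCL 90 R; SCL 90 R touches FIS8;
# FIS8 touches all FIS40 nodes; PSQI is isolated
narrative_corr <- function(schema = default_schema()) {
  st <- subscale_table(schema)
  p <- nrow(st)
  C <- diag(p)
  dimnames(C) <- list(st$subscale, st$subscale)
  link <- function(a, b, r = 0.8) {
    C[a, b] <<- r; C[b, a] <<- r
  }
  sf <- st$subscale[st$questionnaire == "SF-36"]
  had <- st$subscale[st$questionnaire == "HAD"]
  scl <- st$subscale[st$questionnaire == "SCL 90 R"]
  fis40 <- st$subscale[st$questionnaire == "FIS40"]
  for (h in had) link("Mental health (MH)", h)
  scl_cov <- c("Depression (DEP)", "Anxiety (ANS)", "Hostility (HOS)",
               "Phobic anxiety (FOB)")
  for (s in scl_cov) link("Rol emotional (RE)", s, 0.55)
  for (s in scl) link("Total anxiety", s)
  link("Somatizations (SOM)", "FIS8", 0.6)
  link("Physic function (PF)", "FIS8", 0.7)
  for (f in setdiff(fis40, "Cognitive dim")) link("Physic function (PF)", f, 0.6)
  for (f in fis40) link("FIS8", f, 0.65)
  C
}

paper_order <- c("SF-36", "HAD", "SCL 90 R", "FIS8", "FIS40", "PSQI")

# column indices of one questionnaire block, recomputed from the column
# naming convention (independent of the package's internal bookkeeping)
block_idx <- function(schema, qname) {
  cols <- item_columns(schema)
  q <- schema$questionnaires[[qname]]
  match(paste0(q$prefix, "_q", seq_len(q$questions)), cols)
}

# three questionnaires x three subject blocks, non-overlapping 4-item
# subscales; with independent subjects the same-block pairs are the planted
# edges and cross-block correlations are zero
planted_block_schema <- function() {
  qs <- lapply(1:3, function(qi) {
    list(name = paste0("P", qi), prefix = paste0("p", qi), questions = 12,
         answer_min = 0, answer_max = 3, has_total = FALSE,
         subscales = lapply(1:3, function(si) {
           list(name = sprintf("P%d block %s", qi, LETTERS[si]),
                subject = paste("Block", LETTERS[si]),
                items = ((si - 1) * 4 + 1):(si * 4))
         }))
  })
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(questionnaires = qs), path, auto_unbox = TRUE)
  on.exit(unlink(path))
  load_schema(path)
}

# item -> subject mapping by "first subscale containing the item", rebuilt
# from the schema lists by plain loops
first_subscale_subjects <- function(schema) {
  out <- character(0)
  for (q in schema$questionnaires) {
    subj <- rep(paste0(q$name, "!none"), q$questions)
    for (i in seq_len(q$questions)) {
      for (s in q$subscales) {
        if (i %in% s$items) {
          subj[i] <- s$subject
          break
        }
      }
    }
    out <- c(out, subj)
  }
  out
}

# total-variation distance between two empirical label distributions
tv_distance <- function(a, b, levels) {
  pa <- tabulate(factor(a, levels = levels), nbins = length(levels)) / length(a)
  pb <- tabulate(factor(b, levels = levels), nbins = length(levels)) / length(b)
  0.5 * sum(abs(pa - pb))
}

toy_table_full_sf36 <- function(n = 3) {
  as.data.frame(matrix(2L, n, 36,
                       dimnames = list(NULL, paste0("sf36_q", 1:36))))
}
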