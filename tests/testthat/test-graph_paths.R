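triple_row <- function(src, styp, verb, tgt, ttyp, pmid = "1", sidx = 1L,
                       negated = FALSE) {
  data.frame(pmid = pmid, sentence_index = sidx, source_id = src,
             source_type = styp, verb = verb,
             polarity = "DECREASE", negated = negated, voice = "ACTIVE",
             target_id = tgt, target_type = ttyp, stringsAsFactors = FALSE)
}

test_that("parallel triples aggregate into one edge with summed support", {
  tr <- do.call(rbind, rep(list(
    triple_row("D1", "DRUG", "inhibit", "P1", "PROTEIN")), 3L))
  g <- build_graph(tr)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$support, 3L)
  expect_equal(g$edges$verbs, "inhibit")
})

test_that("drug whitelist drops out-of-list drugs with their edges", {
  tr <- rbind(triple_row("sorafenib", "DRUG", "inhibit", "P1", "PROTEIN"),
              triple_row("tamoxifen", "DRUG", "inhibit", "P2", "PROTEIN"))
  g <- build_graph(tr, drug_whitelist = "sorafenib")
  expect_equal(g$edges$source_id, "sorafenib")
})

test_that("negated triples are excluded from the graph by default", {
  tr <- rbind(triple_row("D1", "DRUG", "inhibit", "P1", "PROTEIN"),
              triple_row("D1", "DRUG", "block", "P1", "PROTEIN",
                         negated = TRUE))
  expect_equal(build_graph(tr)$edges$verbs, "inhibit")
  expect_equal(build_graph(tr, keep_negated = TRUE)$edges$verbs,
               "block|inhibit")
})

test_that("edge supports equal brute-force pair counts and sum to triple count", {
  syn <- generate_corpus(n_docs = 12, n_chains = 10, seed = 55)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  tr <- res$triples[!res$triples$negated, ]
  g <- res$graph
  expect_equal(sum(g$edges$support), nrow(tr))
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    expect_equal(e$support, sum(tr$source_id == e$source_id &
                                tr$target_id == e$target_id))
  }
})

test_that("path enumeration handles the toy two-edge graph", {
  tr <- rbind(triple_row("D1", "DRUG", "inhibit", "P1", "PROTEIN"),
              triple_row("P1", "PROTEIN", "inhibit", "S1", "SIDE_EFFECT"))
  g <- build_graph(tr)
  p1 <- enumerate_paths(g, 1L)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$drug, "D1")
  expect_equal(p1$p1, "P1")
  expect_equal(p1$side_effect, "S1")
  expect_equal(nrow(enumerate_paths(g, 2L)), 0L)
  expect_error(enumerate_paths(g, 4L), "1..3")
  expect_error(enumerate_paths(g, 0L), "1..3")
})

random_typed_graph <- function(n_drug, n_prot, n_se, p_edge, seed) {
  set.seed(seed)
  tr <- list()
  add <- function(a, at, b, bt) {
    tr[[length(tr) + 1L]] <<- triple_row(a, at, "inhibit", b, bt)
  }
  for (d in paste0("D", seq_len(n_drug)))
    for (p in paste0("P", seq_len(n_prot)))
      if (runif(1) < p_edge) add(d, "DRUG", p, "PROTEIN")
  for (p in paste0("P", seq_len(n_prot)))
    for (q in paste0("P", seq_len(n_prot)))
      if (p != q && runif(1) < p_edge) add(p, "PROTEIN", q, "PROTEIN")
  for (p in paste0("P", seq_len(n_prot)))
    for (s in paste0("S", seq_len(n_se)))
      if (runif(1) < p_edge) add(p, "PROTEIN", s, "SIDE_EFFECT")
  build_graph(do.call(rbind, tr))
}

test_that("enumeration equals the exhaustive igraph simple-path oracle", {
  for (seed in c(1, 2, 3)) {
    g <- random_typed_graph(5, 20, 5, 0.12, seed)
    e <- g$edges
    ig <- igraph::graph_from_data_frame(
      data.frame(from = paste(e$source_type, e$source_id),
                 to = paste(e$target_type, e$target_id)),
      vertices = data.frame(name = paste(g$nodes$type, g$nodes$id),
                            type = g$nodes$type))
    for (k in 1:3) {
      got <- enumerate_paths(g, k)
      got_keys <- if (nrow(got) == 0L) character(0) else apply(got, 1L, function(r)
        paste(c(r[["drug"]], r[["p1"]], r[["p2"]], r[["p3"]],
                r[["side_effect"]]), collapse = "/"))
      want_keys <- character(0)
      drugs <- g$nodes$id[g$nodes$type == "DRUG"]
      ses <- g$nodes$id[g$nodes$type == "SIDE_EFFECT"]
      for (d in drugs) for (s in ses) {
        sp <- igraph::all_simple_paths(
          ig, from = paste("DRUG", d), to = paste("SIDE_EFFECT", s),
          cutoff = k + 1L)
        for (pp in sp) {
          nm <- igraph::V(ig)$name[pp]
          if (length(nm) != k + 2L) next
          types <- sub(" .*", "", nm)
          if (!all(types == c("DRUG", rep("PROTEIN", k), "SIDE_EFFECT"))) next
          ids <- sub("^[A-Z_]+ ", "", nm)
          want_keys <- c(want_keys,
                         paste(c(ids[1:(k + 1L)],
                                 rep(NA_character_, 3L - k),
                                 ids[[k + 2L]]), collapse = "/"))
        }
      }
      expect_setequal(unname(got_keys), unique(want_keys))
    }
  }
})

test_that("enumeration order is deterministic and input-order invariant", {
  syn <- generate_corpus(n_docs = 10, n_chains = 8, seed = 77)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  tr <- res$triples
  set.seed(1)
  tr_shuffled <- tr[sample(nrow(tr)), ]
  g1 <- build_graph(tr)
  g2 <- build_graph(tr_shuffled)
  for (k in 1:3) {
    expect_identical(enumerate_paths(g1, k), enumerate_paths(g2, k))
  }
})

test_that("every returned path walks existing edges of the graph", {
  syn <- generate_corpus(n_docs = 10, n_chains = 10, seed = 91)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  e <- res$graph$edges
  ekeys <- paste(e$source_id, e$target_id)
  for (i in seq_len(nrow(res$paths_raw))) {
    nodes <- path_nodes(res$paths_raw[i, ])
    for (j in seq_len(length(nodes) - 1L)) {
      expect_true(paste(nodes[[j]], nodes[[j + 1L]]) %in% ekeys)
    }
  }
})

test_that("significance filtering removes effect-term endpoints and weak verbs", {
  bv <- toy_bioverbs()
  paths <- data.frame(
    depth = c(1L, 1L, 1L),
    drug = c("D1", "D2", "D3"), p1 = c("P1", "P2", "P3"),
    p2 = NA_character_, p3 = NA_character_,
    side_effect = c("SE1", "SE2", "SE3"),
    v1 = c("inhibit", "inhibit", "observe"),
    v2 = c("associate", "associate", "associate"),
    v3 = NA_character_, v4 = NA_character_, stringsAsFactors = FALSE)
  nm <- c(SE1 = "breast cancer", SE2 = "nausea", SE3 = "rash")
  out <- filter_significant(paths, bioverbs = bv, se_names = nm)
  # SE1 ends in an intended-effect name; D3's first edge is only associative
  expect_equal(out$drug, "D2")
  # terminal edge may be associative
  expect_equal(out$v2, "associate")
  # identity under empty screens
  out2 <- filter_significant(paths, effect_terms = character(0),
                             significant = function(v, terminal) TRUE)
  expect_equal(out2, paths)
})
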