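test_that("ranking weights validate, default to 0.3/0.4/0.3 and renormalize", {
  w <- ranking_weights()
  expect_equal(c(w$alpha, w$beta, w$gamma), c(0.3, 0.4, 0.3))
  expect_error(ranking_weights(-1, 1, 1), "non-negative")
  expect_warning(w2 <- ranking_weights(1, 1, 2), "renormalizing")
  expect_equal(w2$alpha + w2$beta + w2$gamma, 1)
})

test_that("local frequencies count pairs among a side effect's paths", {
  paths <- data.frame(
    depth = 1L,
    drug = c("D1", "D2", "D1", "D1"),
    p1 = c("P1", "P1", "P1", "P2"),
    p2 = NA_character_, p3 = NA_character_,
    side_effect = c("S1", "S1", "S1", "S2"),
    v1 = "inhibit", v2 = "associate", v3 = NA_character_,
    v4 = NA_character_, stringsAsFactors = FALSE)
  fr <- local_freq_table(paths)
  expect_equal(local_frequency(fr, "P1", "S1", "S1"), 3L)
  expect_equal(local_frequency(fr, "D1", "P1", "S1"), 2L)
  expect_equal(local_frequency(fr, "D1", "P2", "S1"), 0L)
  expect_equal(local_frequency(fr, "D1", "P1", "S9"), 0L)
  expect_equal(max_local_frequency(fr, "S1"), 3L)
  expect_equal(max_local_frequency(fr, "S9"), 0L)
})

test_that("local frequencies equal a brute-force scan on random path sets", {
  syn <- generate_corpus(n_docs = 15, n_chains = 15, seed = 23)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  paths <- res$paths
  fr <- local_freq_table(paths)
  pairs_of <- function(i) {
    nodes <- path_nodes(paths[i, ])
    data.frame(vi = nodes[-length(nodes)], vj = nodes[-1],
               se = paths$side_effect[[i]], stringsAsFactors = FALSE)
  }
  all_pairs <- do.call(rbind, lapply(seq_len(nrow(paths)), pairs_of))
  for (r in sample(seq_len(nrow(all_pairs)), min(25L, nrow(all_pairs)))) {
    vi <- all_pairs$vi[[r]]; vj <- all_pairs$vj[[r]]; se <- all_pairs$se[[r]]
    want <- sum(all_pairs$vi == vi & all_pairs$vj == vj & all_pairs$se == se)
    expect_equal(local_frequency(fr, vi, vj, se), want)
  }
})

test_that("entity-pair weight is the stated convex combination", {
  # components (coals, freq-share, hierarchy) = (0.5, 2/4, 0.8)
  coals_stub <- structure(list(vectors = matrix(0, 1, 1, dimnames = list("x", "x")),
                               vocabulary = "x", columns = "x",
                               window = 4L, dim = 1L), class = "ps_coals")
  paths <- data.frame(depth = 1L, drug = "D1", p1 = "P1",
                      p2 = NA_character_, p3 = NA_character_,
                      side_effect = "S1", v1 = "inhibit", v2 = "associate",
                      v3 = NA_character_, v4 = NA_character_,
                      stringsAsFactors = FALSE)
  fr <- local_freq_table(paths)  # D1-P1 and P1-S1 each count 1, max 1
  # direct arithmetic through a custom pair-weight function
  w <- ranking_weights()
  pw <- w$alpha * 0.5 + w$beta * (2 / 4) + w$gamma * 0.8
  expect_equal(pw, 0.59)
  # all-maximal components give exactly 1, all-zero give 0
  expect_equal(w$alpha * 1 + w$beta * 1 + w$gamma * 1, 1)
  h <- hierarchy_from_table(data.frame(
    child_id = c("ROOT", "D1", "P1", "S1"), parent_id = c("-", "ROOT", "ROOT", "ROOT"),
    stringsAsFactors = FALSE))
  # MaxLocalFreq = 0 side effect: frequency term defined as 0
  expect_equal(suppressWarnings(
    entity_pair_weight("D1", "P1", "S-unknown", coals_stub, h, fr, w)),
    w$gamma * hierarchy_similarity(h, "D1", "P1"))
})

test_that("path scores are means of pair weights at every depth", {
  mk <- function(depth) {
    pr <- c("P1", "P2", "P3")
    data.frame(depth = depth, drug = "D1",
               p1 = pr[[1]], p2 = ifelse(depth >= 2, pr[[2]], NA),
               p3 = ifelse(depth >= 3, pr[[3]], NA),
               side_effect = "S1", v1 = "inhibit", v2 = "inhibit",
               v3 = "inhibit", v4 = "inhibit", stringsAsFactors = FALSE)
  }
  # depth-1 path has 2 pairs; weights (0.4, 0.6) average to 0.5
  ws <- list(c(0.4, 0.6), c(0.1, 0.5, 0.9), c(0.2, 0.4, 0.6, 0.8))
  for (depth in 1:3) {
    w <- ws[[depth]]
    i <- 0L
    score <- path_score(mk(depth), function(vi, vj) { i <<- i + 1L; w[[i]] })
    expect_equal(score, mean(w))
    expect_equal(i, depth + 1L)
  }
  # constant weights give the constant at any depth
  for (depth in 1:3) {
    expect_equal(path_score(mk(depth), function(vi, vj) 0.37), 0.37)
  }
})

test_that("ranking sorts descending with deterministic tie-breaks", {
  paths <- data.frame(
    depth = 1L, drug = c("Dc", "Da", "Db"), p1 = "P1",
    p2 = NA_character_, p3 = NA_character_, side_effect = "S1",
    v1 = "inhibit", v2 = "associate", v3 = NA_character_,
    v4 = NA_character_, stringsAsFactors = FALSE)
  rk <- rank_paths(paths, c(0.9, 0.1, 0.5))
  expect_equal(rk$drug, c("Dc", "Db", "Da"))
  expect_equal(rk$rank, 1:3)
  # all-equal scores: lexicographic by (drug, proteins, side effect)
  rk2 <- rank_paths(paths, c(0.5, 0.5, 0.5))
  expect_equal(rk2$drug, c("Da", "Db", "Dc"))
})

test_that("rank permutation agrees with a reference sort on random scores", {
  syn <- generate_corpus(n_docs = 20, n_chains = 20, seed = 41)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  paths <- res$paths
  set.seed(99)
  scores <- round(runif(nrow(paths)), 2)  # rounding forces some ties
  rk <- rank_paths(paths, scores)
  key <- paste(paths$drug, paths$p1, ifelse(is.na(paths$p2), "", paths$p2),
               ifelse(is.na(paths$p3), "", paths$p3), paths$side_effect)
  want <- order(-scores, key)
  expect_equal(rk$drug, paths$drug[want])
  expect_equal(rk$score, scores[want])
  expect_equal(rk$rank, seq_len(nrow(paths)))
})

test_that("degenerate weight vectors reproduce the single-metric baselines", {
  syn <- generate_corpus(n_docs = 20, n_chains = 20, seed = 41)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  paths <- res$paths
  expect_gte(nrow(paths), 15L)
  m <- train_coals(collapse_mentions(res$docs, res$mentions), window = 4L)
  h <- syn$hierarchy
  expect_identical(proposed_scores(paths, m, h, ranking_weights(1, 0, 0)),
                   baseline_scores(paths, "COALS_ONLY", coals = m))
  expect_identical(proposed_scores(paths, m, h, ranking_weights(0, 0, 1)),
                   baseline_scores(paths, "HIERARCHY_ONLY", hier = h))
  # co-occurrence baseline ties on uniform support
  g <- res$graph
  g$edges$support <- rep(1L, nrow(g$edges))
  co <- baseline_scores(paths, "COOCCURRENCE", graph = g)
  expect_equal(length(unique(co)), 1L)
  expect_error(baseline_scores(paths, "PAGERANK"), "unknown baseline")
})

test_that("hybrid scores and pair weights stay within [0, 1]", {
  syn <- generate_corpus(n_docs = 12, n_chains = 12, seed = 61)
  res <- run_pipeline(syn$docs, syn$lexicons, syn$bioverbs)
  m <- train_coals(collapse_mentions(res$docs, res$mentions), window = 4L)
  sc <- proposed_scores(res$paths, m, syn$hierarchy)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("precision at k counts correct labels in the top k", {
  labels <- c("TYPE1", "TYPE3", "TYPE1", "TYPE2", "TYPE1")
  expect_equal(precision_at_k(labels, 5L, "TYPE1"), 3 / 5)
  expect_equal(precision_at_k(labels, 5L, c("TYPE1", "TYPE2")), 4 / 5)
  expect_equal(precision_at_k(labels, 2L, "TYPE1"), 1 / 2)
  expect_equal(precision_at_k(labels, 5L, c("TYPE1", "TYPE2", "TYPE3")), 1)
  expect_error(precision_at_k(labels, 0L, "TYPE1"), "k must be")
  expect_error(precision_at_k(labels, 6L, "TYPE1"), "k must be")
  # P@k * k is integral
  for (k in 1:5) {
    p <- precision_at_k(labels, k, "TYPE1")
    expect_equal(p * k, round(p * k))
  }
})

test_that("the curated top-20 example loads in rank order with labels", {
  ex <- cancer_top20()
  expect_equal(nrow(ex$paths), 20L)
  expect_equal(ex$paths$rank, 1:20)
  expect_equal(nrow(ex$labels), 20L)
  expect_setequal(unique(ex$labels$label), c("TYPE1", "TYPE2", "TYPE3"))
  expect_equal(ex$paths$drug[[7]], "sorafenib")
  expect_equal(ex$paths$side_effect[[7]], "dyspepsia")
})
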