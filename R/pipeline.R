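# End-to-end convenience wrapper: corpus -> mentions -> triples -> graph ->
# paths -> ranked paths.

#' Run the full mining pipeline
#'
#' Segments and tags the corpus, recognizes entity mentions, extracts
#' relation triples, builds the knowledge graph, enumerates paths for every
#' requested depth and applies the significance screen. Ranking is left to
#' the caller (it needs a trained COALS model and a hierarchy); see
#' [proposed_scores()] and [rank_paths()].
#'
#' @param docs list of `ps_document` (e.g. from [parse_medline_xml()]).
#' @param lexicons list of `ps_lexicon` keyed or not by type.
#' @param bioverbs a `ps_bioverbs`.
#' @param window distance rule bound (default 6).
#' @param depths protein depths to enumerate (default 1:3).
#' @param drug_whitelist optional drug canonical-id filter.
#' @param include_title mine titles (default TRUE).
#' @param keep_negated keep negated triples in the graph (default FALSE).
#' @param effect_terms intended-effect name screen for
#'   [filter_significant()]; `NULL` skips filtering entirely.
#' @param tagger optional `ps_tagger`; defaults to the rule tagger built
#'   from `bioverbs`.
#' @return list with `docs` (prepared), `mentions`, `triples`, `graph`,
#'   `paths` (all depths, filtered), `paths_raw` (unfiltered).
#' @export
run_pipeline <- function(docs, lexicons, bioverbs, window = 6L,
                         depths = 1:3, drug_whitelist = NULL,
                         include_title = TRUE, keep_negated = FALSE,
                         effect_terms = c("tumor", "tumour", "cancer",
                                          "carcinoma", "neoplasm"),
                         tagger = NULL) {
  if (is.null(tagger)) tagger <- ps_tagger("rule", bioverbs = bioverbs)
  docs <- prepare_corpus(docs, tagger, include_title = include_title)
  mentions <- match_corpus(docs, lexicons)
  triples <- extract_corpus_relations(docs, mentions, bioverbs,
                                      window = window)
  graph <- build_graph(triples, drug_whitelist = drug_whitelist,
                       keep_negated = keep_negated)
  paths_raw <- do.call(rbind, lapply(depths, enumerate_paths, graph = graph))
  if (is.null(paths_raw)) paths_raw <- .ps_empty_paths()
  se_lex <- Filter(function(l) l$entity_type == "SIDE_EFFECT", lexicons)
  se_names <- if (length(se_lex)) lexicon_names(se_lex[[1]]) else NULL
  paths <- if (is.null(effect_terms)) {
    paths_raw
  } else {
    filter_significant(paths_raw, effect_terms = effect_terms,
                       bioverbs = bioverbs, se_names = se_names)
  }
  list(docs = docs, mentions = mentions, triples = triples, graph = graph,
       paths = paths, paths_raw = paths_raw)
}
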