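# Rule/lexicon POS tagging and lemmatization.
#
# The pipeline only needs three coarse labels (VERB / NOUN / OTHER): relation
# extraction fires on bio-verbs, voice detection on be-auxiliaries and past
# participles. A deterministic suffix+lexicon tagger covers that without any
# model download; an adapter slot is kept for an external statistical tagger.

.ps_be_forms <- c("be", "is", "are", "was", "were", "been", "being", "am")
.ps_aux_forms <- c(.ps_be_forms, "do", "does", "did", "done",
                   "has", "have", "had", "having",
                   "can", "could", "may", "might", "will", "would",
                   "shall", "should", "must")

# irregular lemma table (small; extended as templates require)
.ps_irregular <- c(
  is = "be", are = "be", was = "be", were = "be", been = "be", being = "be",
  am = "be", does = "do", did = "do", done = "do", has = "have", had = "have",
  rose = "rise", risen = "rise", given = "give", gave = "give",
  shown = "show", showed = "show", known = "know", knew = "know",
  found = "find", led = "lead", became = "become", arose = "arise"
)

.ps_negation_cues <- c("not", "no", "never", "hardly", "scarcely",
                       "neither", "nor", "without")

#' Candidate lemmas for a token
#'
#' Applies the irregular table then inflectional suffix stripping
#' (`-ies/-es/-s`, `-ed/-d`, `-ing`, consonant doubling). The first candidate
#' found in a lexicon of interest is taken as the lemma; otherwise the
#' lowercased token itself.
#'
#' @param token character scalar.
#' @return character vector of candidate lemmas, most specific first.
#' @export
lemma_candidates <- function(token) {
  t <- tolower(token)
  cands <- character(0)
  if (t %in% names(.ps_irregular)) cands <- c(cands, unname(.ps_irregular[[t]]))
  if (grepl("ies$", t)) cands <- c(cands, sub("ies$", "y", t))
  if (grepl("(sh|ch|s|x|z)es$", t)) cands <- c(cands, sub("es$", "", t))
  if (grepl("[^s]s$", t)) cands <- c(cands, sub("s$", "", t))
  if (grepl("ed$", t) && nchar(t) > 3L) {
    stem <- sub("ed$", "", t)
    cands <- c(cands, stem, paste0(stem, "e"), sub("(.)\\1$", "\\1", stem))
  }
  if (grepl("ing$", t) && nchar(t) > 4L) {
    stem <- sub("ing$", "", t)
    cands <- c(cands, stem, paste0(stem, "e"), sub("(.)\\1$", "\\1", stem))
  }
  unique(c(cands, t))
}

#' Create a POS tagger
#'
#' The `"rule"` tagger is the offline default: a token is tagged `VERB` when
#' one of its lemma candidates is a bio-verb or an auxiliary, `OTHER` when it
#' is punctuation, a number, a negation cue or a short function word, and
#' `NOUN` otherwise. `"external"` is an adapter slot: supply `tag_fun(tokens)`
#' returning `list(lemmas=, pos=)` from a statistical tagger of your choice.
#'
#' @param name `"rule"` or `"external"`; anything else is a configuration
#'   error.
#' @param bioverbs a bio-verb lexicon from [load_bioverbs()] (rule tagger).
#' @param tag_fun function for the external adapter.
#' @return object of class `ps_tagger`.
#' @export
ps_tagger <- function(name = c("rule", "external"), bioverbs = NULL,
                      tag_fun = NULL) {
  if (!is.character(name) || !name[[1]] %in% c("rule", "external")) {
    stop("unknown tagger name: ", name[[1]])
  }
  name <- name[[1]]
  if (name == "external") {
    stopifnot(is.function(tag_fun))
    return(structure(list(name = name, tag_fun = tag_fun),
                     class = "ps_tagger"))
  }
  verb_lemmas <- if (is.null(bioverbs)) character(0) else names(bioverbs$polarity)
  function_words <- c("the", "a", "an", "of", "in", "on", "by", "to", "and",
                      "or", "with", "for", "that", "which", "this", "these",
                      "its", "their", "as", "at", "from", "into", "than",
                      "but", "both", "also", "very", "more", "most", "n't")
  tag_fun <- function(tokens) {
    n <- length(tokens)
    lemmas <- character(n)
    pos <- character(n)
    for (i in seq_len(n)) {
      tok <- tokens[[i]]
      low <- tolower(tok)
      cands <- lemma_candidates(tok)
      hit <- cands[cands %in% verb_lemmas]
      if (length(hit)) {
        lemmas[[i]] <- hit[[1]]
        pos[[i]] <- "VERB"
      } else if (low %in% .ps_aux_forms) {
        lemmas[[i]] <- if (low %in% names(.ps_irregular))
          unname(.ps_irregular[[low]]) else low
        pos[[i]] <- "VERB"
      } else if (grepl("^[[:punct:]]+$", tok) || grepl("^[0-9.]+$", tok) ||
                 low %in% .ps_negation_cues || low %in% function_words) {
        lemmas[[i]] <- low
        pos[[i]] <- "OTHER"
      } else {
        lemmas[[i]] <- low
        pos[[i]] <- "NOUN"
      }
    }
    list(lemmas = lemmas, pos = pos)
  }
  structure(list(name = name, tag_fun = tag_fun), class = "ps_tagger")
}

#' Tag one sentence
#'
#' Fills the `lemmas` and `pos` fields (parallel to `tokens`).
#'
#' @param sentence a `ps_sentence` with tokens populated.
#' @param tagger a `ps_tagger`.
#' @return the tagged sentence.
#' @export
tag_sentence <- function(sentence, tagger) {
  stopifnot(inherits(sentence, "ps_sentence"), inherits(tagger, "ps_tagger"))
  res <- tagger$tag_fun(sentence$tokens)
  stopifnot(length(res$lemmas) == length(sentence$tokens),
            length(res$pos) == length(sentence$tokens))
  sentence$lemmas <- res$lemmas
  sentence$pos <- res$pos
  sentence
}

#' Segment and tag every document of a corpus
#'
#' @param docs list of `ps_document`.
#' @param tagger a `ps_tagger`.
#' @param include_title mine titles as sentence 0 (default TRUE).
#' @return list of documents with tagged sentences.
#' @export
prepare_corpus <- function(docs, tagger, include_title = TRUE) {
  lapply(docs, function(d) {
    d <- segment_sentences(d, include_title = include_title)
    d$sentences <- lapply(d$sentences, tag_sentence, tagger = tagger)
    d
  })
}
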