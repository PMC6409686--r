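# Rule-based relation extraction: entity-verb-entity assertions with bio-verb
# filtering, negation and voice detection, and a token-distance window.
#
# Five rules fire per candidate pair of mentions in one sentence:
#   basic      - a bio-verb strictly between two entity mentions links them;
#   keyword    - the verb lemma must be in the bio-verb lexicon (with an
#                increase / decrease / neutral polarity class);
#   negation   - a negation cue near the verb flags the triple as negated;
#   distance   - at most `window` tokens may lie strictly between the spans;
#   direction  - active voice points left-to-right, passive reverses it.

.ps_allowed_pairs <- matrix(c("DRUG", "PROTEIN",
                              "PROTEIN", "PROTEIN",
                              "PROTEIN", "SIDE_EFFECT"),
                            ncol = 2L, byrow = TRUE,
                            dimnames = list(NULL, c("source", "target")))

.ps_participles <- c("given", "shown", "known", "found", "seen", "made",
                     "taken", "done", "kept", "held", "upregulated",
                     "downregulated")

#' Load the bio-verb lexicon
#'
#' TSV with header columns `lemma` and `polarity`
#' (INCREASE / DECREASE / NEUTRAL). Standing in for the curated list of
#' biomedical relation verbs; neutral covers associative verbs such as
#' "associate" or "observe" that mark a link without a direction of change.
#'
#' @param path TSV path.
#' @return object of class `ps_bioverbs` with a `polarity` lookup vector.
#' @export
load_bioverbs <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("lemma", "polarity") %in% names(tab))) {
    stop("bio-verb TSV must have columns lemma, polarity")
  }
  bioverbs_from_table(tab)
}

#' Build a bio-verb lexicon from a table
#'
#' @param tab data.frame with `lemma` and `polarity` columns.
#' @return a `ps_bioverbs`.
#' @export
bioverbs_from_table <- function(tab) {
  bad <- setdiff(unique(tab$polarity), c("INCREASE", "DECREASE", "NEUTRAL"))
  if (length(bad)) stop("unknown polarity label: ", paste(bad, collapse = ", "))
  lem <- tolower(trimws(tab$lemma))
  if (anyDuplicated(lem)) stop("duplicate bio-verb lemma")
  structure(list(polarity = stats::setNames(tab$polarity, lem)),
            class = "ps_bioverbs")
}

#' Polarity of a verb lemma
#'
#' @param bioverbs a `ps_bioverbs`.
#' @param lemma verb lemma (lowercase).
#' @return `"INCREASE"`, `"DECREASE"`, `"NEUTRAL"`, or `NA_character_` when
#'   the lemma is not a bio-verb.
#' @export
verb_polarity <- function(bioverbs, lemma) {
  p <- unname(bioverbs$polarity[lemma])
  ifelse(is.na(p), NA_character_, p)
}

#' Detect negation around a verb
#'
#' TRUE when a negation cue (`not`, `no`, `never`, `hardly`, `scarcely`,
#' `n't`, `neither`, `nor`, `without`) occurs within the 3 tokens preceding
#' the verb.
#'
#' @param sentence a tagged `ps_sentence`.
#' @param verb_index 1-based token position of the verb.
#' @return logical.
#' @export
detect_negation <- function(sentence, verb_index) {
  toks <- tolower(sentence$tokens)
  lo <- max(1L, verb_index - 3L)
  if (lo > verb_index - 1L) return(FALSE)
  win <- toks[lo:(verb_index - 1L)]
  any(win %in% .ps_negation_cues) || any(grepl("n't$", win))
}

.ps_is_participle <- function(token) {
  low <- tolower(token)
  grepl("ed$", low) || low %in% .ps_participles
}

#' Detect verb voice
#'
#' PASSIVE when a be/auxiliary form occurs within the 2 tokens preceding a
#' past-participle verb form ("A is activated by B", "A was inhibited by B");
#' otherwise ACTIVE.
#'
#' @param sentence a tagged `ps_sentence`.
#' @param verb_index 1-based token position of the verb.
#' @return `"ACTIVE"` or `"PASSIVE"`.
#' @export
detect_voice <- function(sentence, verb_index) {
  if (!.ps_is_participle(sentence$tokens[[verb_index]])) return("ACTIVE")
  lo <- max(1L, verb_index - 2L)
  if (lo > verb_index - 1L) return("ACTIVE")
  win <- tolower(sentence$tokens[lo:(verb_index - 1L)])
  if (any(win %in% .ps_aux_forms)) "PASSIVE" else "ACTIVE"
}

.ps_empty_triples <- function() {
  data.frame(pmid = character(0), sentence_index = integer(0),
             source_id = character(0), source_type = character(0),
             verb = character(0), polarity = character(0),
             negated = logical(0), voice = character(0),
             target_id = character(0), target_type = character(0),
             stringsAsFactors = FALSE)
}

.ps_pair_allowed <- function(src_type, tgt_type) {
  any(.ps_allowed_pairs[, "source"] == src_type &
      .ps_allowed_pairs[, "target"] == tgt_type)
}

#' Extract relation triples from one sentence
#'
#' For every ordered pair of non-overlapping mentions (m1 left of m2), every
#' bio-verb token strictly between the two spans yields one candidate triple,
#' provided the number of tokens strictly between the spans is at most
#' `window` (the distance rule; default 6). The direction is m1 -> m2 for an
#' active verb and m2 -> m1 for a passive one; the triple is kept only when
#' the directed type pair is drug->protein, protein->protein or
#' protein->side-effect. Negation is flagged, not dropped, so downstream
#' stages can decide disposal.
#'
#' @param sentence a tagged `ps_sentence`.
#' @param mentions mention data.frame for this sentence (from
#'   [match_entities()]).
#' @param bioverbs a `ps_bioverbs`.
#' @param window maximum tokens strictly between the two mention spans.
#' @return data.frame of triples.
#' @export
extract_relations <- function(sentence, mentions, bioverbs, window = 6L) {
  stopifnot(inherits(sentence, "ps_sentence"), window >= 1L)
  if (is.null(sentence$lemmas)) stop("sentence must be tagged first")
  if (is.null(mentions) || nrow(mentions) < 2L) return(.ps_empty_triples())
  m <- mentions[order(mentions$start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      gap_lo <- m$end[[i]] + 1L
      gap_hi <- m$start[[j]] - 1L
      gap_n <- gap_hi - gap_lo + 1L
      if (gap_n < 0L) next  # overlapping spans are never paired
      if (gap_n > window) next
      if (gap_n == 0L) next
      for (p in gap_lo:gap_hi) {
        lemma <- sentence$lemmas[[p]]
        pol <- unname(bioverbs$polarity[lemma])
        if (is.na(pol)) next
        voice <- detect_voice(sentence, p)
        if (voice == "ACTIVE") {
          src <- i; tgt <- j
        } else {
          src <- j; tgt <- i
        }
        if (!.ps_pair_allowed(m$entity_type[[src]], m$entity_type[[tgt]])) next
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = sentence$doc_pmid, sentence_index = sentence$index,
          source_id = m$canonical_id[[src]],
          source_type = m$entity_type[[src]],
          verb = lemma, polarity = pol,
          negated = detect_negation(sentence, p), voice = voice,
          target_id = m$canonical_id[[tgt]],
          target_type = m$entity_type[[tgt]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.ps_empty_triples())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract relations across a prepared corpus
#'
#' @param docs list of tagged `ps_document`.
#' @param mentions corpus-wide mention data.frame (from [match_corpus()]).
#' @inheritParams extract_relations
#' @return data.frame of triples for the whole corpus.
#' @export
extract_corpus_relations <- function(docs, mentions, bioverbs, window = 6L) {
  res <- list()
  for (d in docs) {
    for (s in d$sentences) {
      ms <- mentions[mentions$pmid == d$pmid &
                     mentions$sentence_index == s$index, , drop = FALSE]
      if (nrow(ms) < 2L) next
      tr <- extract_relations(s, ms, bioverbs, window = window)
      if (nrow(tr)) res[[length(res) + 1L]] <- tr
    }
  }
  if (!length(res)) return(.ps_empty_triples())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write triples to TSV
#'
#' @param triples triples data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(triples, path) {
  write.table(triples, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read triples from TSV
#'
#' @param path TSV written by [write_triples()].
#' @return triples data.frame.
#' @export
read_triples <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    fileEncoding = "UTF-8",
                    colClasses = c(negated = "logical",
                                   sentence_index = "integer"))
  tab$pmid <- as.character(tab$pmid)
  tab
}
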