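# Dictionary loading and n-gram exact-match entity recognition.
#
# Dictionaries are stand-ins for DrugBank (drugs), UniProt (proteins) and
# SIDER (side effects) exports: canonical id + name + synonyms. Mentions are
# found by exact matching of 1/2/3-token grams against the synonym index,
# case-folded by default.

.ps_entity_types <- c("DRUG", "PROTEIN", "SIDE_EFFECT")

#' Load an entity lexicon from TSV
#'
#' Expected columns (header required): `canonical_id`, `canonical_name`,
#' `synonyms` (pipe-separated; may be empty). The canonical name is always a
#' lookup key; every synonym maps to exactly one canonical id within a type —
#' on collision the first mapping wins and a warning is emitted. Synonym
#' merging (e.g. folding gastrin-17 / little gastrin 1 into one gastrin
#' entity) is expressed by listing all variants under one canonical id.
#'
#' @param path TSV path.
#' @param entity_type one of `"DRUG"`, `"PROTEIN"`, `"SIDE_EFFECT"`.
#' @param case_fold lowercase keys before indexing (default TRUE).
#' @return object of class `ps_lexicon`: entries table plus synonym index.
#' @export
load_lexicon <- function(path, entity_type, case_fold = TRUE) {
  entity_type <- match.arg(entity_type, .ps_entity_types)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", fileEncoding = "UTF-8")
  need <- c("canonical_id", "canonical_name", "synonyms")
  if (!all(need %in% names(tab))) {
    stop("lexicon TSV must have columns: ", paste(need, collapse = ", "))
  }
  lexicon_from_table(tab, entity_type, case_fold = case_fold)
}

#' Build a lexicon from an in-memory table
#'
#' @param tab data.frame with canonical_id / canonical_name / synonyms.
#' @inheritParams load_lexicon
#' @return a `ps_lexicon`.
#' @export
lexicon_from_table <- function(tab, entity_type, case_fold = TRUE) {
  entity_type <- match.arg(entity_type, .ps_entity_types)
  if (anyDuplicated(tab$canonical_id)) {
    stop("duplicate canonical_id in ", entity_type, " lexicon: ",
         tab$canonical_id[duplicated(tab$canonical_id)][1L])
  }
  index <- new.env(parent = emptyenv())
  fold <- if (case_fold) tolower else identity
  for (i in seq_len(nrow(tab))) {
    syns <- strsplit(tab$synonyms[[i]], "|", fixed = TRUE)[[1]]
    syns <- trimws(syns)
    if (any(!nzchar(syns))) {
      warning("empty synonym skipped for ", tab$canonical_id[[i]])
      syns <- syns[nzchar(syns)]
    }
    syns <- unique(c(trimws(tab$canonical_name[[i]]), syns))
    for (s in syns) {
      ntok <- length(ps_tokenize(s))
      if (ntok < 1L || ntok > 3L) {
        warning("synonym '", s, "' has ", ntok,
                " tokens; only 1-3 grams are matchable")
        if (ntok < 1L) next
      }
      key <- fold(paste(ps_tokenize(s), collapse = " "))
      if (!is.null(index[[key]])) {
        if (index[[key]] != tab$canonical_id[[i]]) {
          warning("synonym collision on '", s, "' in ", entity_type,
                  " lexicon; keeping first mapping ", index[[key]])
        }
        next
      }
      index[[key]] <- tab$canonical_id[[i]]
    }
  }
  structure(list(entries = tab, entity_type = entity_type,
                 index = index, case_fold = case_fold),
            class = "ps_lexicon")
}

#' @export
print.ps_lexicon <- function(x, ...) {
  cat(sprintf("<ps_lexicon %s: %d entries, %d keys>\n", x$entity_type,
              nrow(x$entries), length(ls(x$index))))
  invisible(x)
}

#' Canonical names of a lexicon
#'
#' Named character vector canonical_id -> canonical_name, used e.g. by
#' [filter_significant()] to test side-effect names for effect terms.
#'
#' @param lexicon a `ps_lexicon`.
#' @return named character vector.
#' @export
lexicon_names <- function(lexicon) {
  stats::setNames(lexicon$entries$canonical_name, lexicon$entries$canonical_id)
}

#' Save a lexicon back to TSV
#'
#' @param lexicon a `ps_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  write.table(lexicon$entries, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.ps_empty_mentions <- function() {
  data.frame(pmid = character(0), sentence_index = integer(0),
             canonical_id = character(0), entity_type = character(0),
             surface = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

#' Recognize entity mentions in a sentence
#'
#' Exact matching of 1/2/3-grams against the synonym indices, longest match
#' first, ties broken left-to-right; accepted spans are claimed so no two
#' mentions overlap. When the same span matches in several lexicons the
#' `type_priority` order decides (default PROTEIN > DRUG > SIDE_EFFECT).
#'
#' Token spans are 1-based and inclusive (`start:end`, length `end-start+1`).
#'
#' @param sentence a tokenized `ps_sentence`.
#' @param lexicons list of `ps_lexicon` (one per entity type).
#' @param type_priority character vector ordering types for same-span ties.
#' @return data.frame of mentions (pmid, sentence_index, canonical_id,
#'   entity_type, surface, start, end).
#' @export
match_entities <- function(sentence, lexicons,
                           type_priority = c("PROTEIN", "DRUG", "SIDE_EFFECT")) {
  stopifnot(inherits(sentence, "ps_sentence"))
  lexicons <- if (inherits(lexicons, "ps_lexicon")) list(lexicons) else lexicons
  types <- vapply(lexicons, `[[`, "", "entity_type")
  names(lexicons) <- types
  toks <- sentence$tokens
  n <- length(toks)
  if (n == 0L) return(.ps_empty_mentions())
  claimed <- logical(n)
  rows <- list()
  for (glen in 3:1) {
    if (glen > n) next
    for (s in seq_len(n - glen + 1L)) {
      e <- s + glen - 1L
      if (any(claimed[s:e])) next
      surface <- paste(toks[s:e], collapse = " ")
      hit_type <- NULL
      hit_id <- NULL
      for (ty in type_priority) {
        lex <- lexicons[[ty]]
        if (is.null(lex)) next
        key <- if (lex$case_fold) tolower(surface) else surface
        id <- lex$index[[key]]
        if (!is.null(id)) {
          hit_type <- ty
          hit_id <- id
          break
        }
      }
      if (!is.null(hit_id)) {
        claimed[s:e] <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          pmid = sentence$doc_pmid, sentence_index = sentence$index,
          canonical_id = hit_id, entity_type = hit_type,
          surface = surface, start = s, end = e, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.ps_empty_mentions())
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recognize mentions across a prepared corpus
#'
#' @param docs list of `ps_document` with sentences populated.
#' @inheritParams match_entities
#' @return data.frame of mentions for the whole corpus.
#' @export
match_corpus <- function(docs, lexicons,
                         type_priority = c("PROTEIN", "DRUG", "SIDE_EFFECT")) {
  res <- lapply(docs, function(d) {
    do.call(rbind, lapply(d$sentences, match_entities, lexicons = lexicons,
                          type_priority = type_priority))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(.ps_empty_mentions())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
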