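# Shared in-code fixtures: a toy verb lexicon, toy entity lexicons, and
# independent brute-force oracles used across test files.

toy_bioverbs <- function() {
  bioverbs_from_table(data.frame(
    lemma = c("inhibit", "block", "reduce", "abolish", "silence",
              "activate", "stimulate", "enhance", "induce", "increase",
              "associate", "observe"),
    polarity = c(rep("DECREASE", 5L), rep("INCREASE", 5L),
                 rep("NEUTRAL", 2L)),
    stringsAsFactors = FALSE))
}

toy_lexicons <- function() {
  list(
    DRUG = lexicon_from_table(data.frame(
      canonical_id = c("sorafenib", "tamoxifen"),
      canonical_name = c("sorafenib", "tamoxifen"),
      synonyms = c("", ""), stringsAsFactors = FALSE), "DRUG"),
    PROTEIN = lexicon_from_table(data.frame(
      canonical_id = c("p38", "gastrin"),
      canonical_name = c("p38", "gastrin"),
      synonyms = c("p38 map kinase", "g17|gastrin-17|little gastrin 1"),
      stringsAsFactors = FALSE), "PROTEIN"),
    SIDE_EFFECT = lexicon_from_table(data.frame(
      canonical_id = c("dyspepsia"),
      canonical_name = c("dyspepsia"),
      synonyms = c(""), stringsAsFactors = FALSE), "SIDE_EFFECT"))
}

tag_text <- function(text, bioverbs = toy_bioverbs(), pmid = "t1",
                     index = 0L) {
  s <- structure(list(doc_pmid = pmid, index = index, text = text,
                      tokens = ps_tokenize(text), lemmas = NULL, pos = NULL),
                 class = "ps_sentence")
  tag_sentence(s, ps_tagger("rule", bioverbs = bioverbs))
}

# Independent brute-force relation oracle: re-checks every (ordered pair,
# verb position) combination against the five rules, written as plain loops
# with no shared code path beyond the published cue lists.
oracle_relations <- function(sentence, mentions, bioverbs, window = 6L) {
  cues <- c("not", "no", "never", "hardly", "scarcely", "neither", "nor",
            "without")
  aux <- c("be", "is", "are", "was", "were", "been", "being", "am", "do",
           "does", "did", "done", "has", "have", "had", "having", "can",
           "could", "may", "might", "will", "would", "shall", "should",
           "must")
  allowed <- list(c("DRUG", "PROTEIN"), c("PROTEIN", "PROTEIN"),
                  c("PROTEIN", "SIDE_EFFECT"))
  m <- mentions[order(mentions$start), , drop = FALSE]
  out <- list()
  n <- nrow(m)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    between <- seq_len(length(sentence$tokens))
    between <- between[between > m$end[[i]] & between < m$start[[j]]]
    if (length(between) == 0L || length(between) > window) next
    for (p in between) {
      lem <- sentence$lemmas[[p]]
      pol <- verb_polarity(bioverbs, lem)
      if (is.na(pol)) next
      tok <- tolower(sentence$tokens[[p]])
      is_part <- grepl("ed$", tok) ||
        tok %in% c("given", "shown", "known", "found", "seen", "made",
                   "taken", "done", "kept", "held", "upregulated",
                   "downregulated")
      prev2 <- tolower(sentence$tokens[seq_len(length(sentence$tokens))])
      prev2 <- prev2[seq_len(p - 1L)]
      prev2 <- utils::tail(prev2, 2L)
      passive <- is_part && any(prev2 %in% aux)
      prev3 <- tolower(sentence$tokens[seq_len(p - 1L)])
      prev3 <- utils::tail(prev3, 3L)
      neg <- any(prev3 %in% cues) || any(grepl("n't$", prev3))
      if (passive) { si <- j; ti <- i } else { si <- i; ti <- j }
      ok <- any(vapply(allowed, function(a)
        a[[1]] == m$entity_type[[si]] && a[[2]] == m$entity_type[[ti]], TRUE))
      if (!ok) next
      out[[length(out) + 1L]] <- data.frame(
        source_id = m$canonical_id[[si]], verb = lem,
        target_id = m$canonical_id[[ti]],
        negated = neg, voice = if (passive) "PASSIVE" else "ACTIVE",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Exhaustive Wu-Palmer oracle: intersects full ancestor sets and maximizes
# 2*depth(c)/(depth(a)+depth(b)) over all common ancestors c.
oracle_wupalmer <- function(parent_map, root, a, b) {
  anc <- function(x) {
    out <- x
    while (x != root) {
      x <- parent_map[[x]]
      out <- c(out, x)
    }
    out
  }
  depth <- function(x) length(anc(x))
  if (a == b) return(1)
  common <- intersect(anc(a), anc(b))
  max(vapply(common, function(cc) 2 * depth(cc) / (depth(a) + depth(b)), 0))
}

# Direct COALS formula oracle: counts the ramped co-occurrences with plain
# loops and applies the correlation normalization cell by cell.
oracle_coals_vectors <- function(sentences, window = 4L) {
  vocab <- sort(unique(unlist(sentences)))
  n <- length(vocab)
  W <- matrix(0, n, n, dimnames = list(vocab, vocab))
  for (s in sentences) {
    for (i in seq_along(s)) for (j in seq_along(s)) {
      if (i == j) next
      d <- abs(i - j)
      if (d <= window) W[s[[i]], s[[j]]] <- W[s[[i]], s[[j]]] + (window + 1 - d)
    }
  }
  Tt <- sum(W)
  out <- W
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sum(W[i, ]); cc <- sum(W[, j])
    den <- sqrt(r * (Tt - r) * cc * (Tt - cc))
    v <- if (den > 0) (Tt * W[i, j] - r * cc) / den else 0
    out[i, j] <- if (v > 0) sqrt(v) else 0
  }
  out
}
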