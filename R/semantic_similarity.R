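# Corpus-based (COALS) and concept-hierarchy (Wu-Palmer) semantic similarity.
#
# COALS (Correlated Occurrence Analogue to Lexical Semantics) builds weighted
# co-occurrence vectors with a ramped window, normalizes each cell by the
# pairwise correlation of its row and column events, zeroes negative
# correlations and square-roots the rest; word similarity is then the Pearson
# correlation of two such vectors.

#' Collapse entity mentions to canonical-id tokens
#'
#' Replaces each mention's token span by a single token equal to its
#' canonical id, so multi-token entity names become one vocabulary item and
#' entity-entity similarity is well-defined.
#'
#' @param docs list of tokenized `ps_document`.
#' @param mentions corpus mention data.frame (from [match_corpus()]).
#' @return list of character vectors, one tokenized sentence each.
#' @export
collapse_mentions <- function(docs, mentions) {
  out <- list()
  for (d in docs) {
    for (s in d$sentences) {
      ms <- mentions[mentions$pmid == d$pmid &
                     mentions$sentence_index == s$index, , drop = FALSE]
      toks <- tolower(s$tokens)
      if (nrow(ms)) {
        ms <- ms[order(-ms$start), , drop = FALSE]  # right-to-left splice
        for (k in seq_len(nrow(ms))) {
          pre <- if (ms$start[[k]] > 1L) toks[1:(ms$start[[k]] - 1L)] else character(0)
          post <- if (ms$end[[k]] < length(toks)) toks[(ms$end[[k]] + 1L):length(toks)] else character(0)
          toks <- c(pre, ms$canonical_id[[k]], post)
        }
      }
      out[[length(out) + 1L]] <- toks
    }
  }
  out
}

#' Train a COALS co-occurrence model
#'
#' Raw counts use a ramped window: a pair at token distance `d <= window`
#' contributes weight `window + 1 - d`. Columns are then restricted to the
#' `dim` most frequent terms (ties alphabetical), each cell is replaced by
#' the correlation of its row/column co-occurrence events
#' `(T*w - r*c) / sqrt(r*(T-r)*c*(T-c))`, negative values are set to 0 and
#' positive values square-rooted. No SVD step is applied; similarities are
#' computed on the truncated normalized vectors directly.
#'
#' @param sentences list of character vectors (tokens, typically from
#'   [collapse_mentions()]).
#' @param window ramp width (default 4).
#' @param dim number of retained column features (default: full vocabulary).
#' @return object of class `ps_coals` with the normalized vector matrix.
#' @export
train_coals <- function(sentences, window = 4L, dim = NULL) {
  stopifnot(length(sentences) > 0L, window >= 1L)
  toks_all <- unlist(sentences, use.names = FALSE)
  freq <- table(toks_all)
  vocab <- sort(names(freq))
  if (is.null(dim)) dim <- length(vocab)
  if (dim < 1L) stop("dim must be >= 1")
  dim <- min(as.integer(dim), length(vocab))
  # columns: top-dim by frequency, ties alphabetical
  ord <- order(-as.integer(freq[vocab]), vocab)
  cols <- sort(vocab[ord][seq_len(dim)])
  W <- matrix(0, nrow = length(vocab), ncol = length(vocab),
              dimnames = list(vocab, vocab))
  for (s in sentences) {
    n <- length(s)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      jmax <- min(n, i + window)
      for (j in (i + 1L):jmax) {
        w <- window + 1L - (j - i)
        W[s[[i]], s[[j]]] <- W[s[[i]], s[[j]]] + w
        W[s[[j]], s[[i]]] <- W[s[[j]], s[[i]]] + w
      }
    }
  }
  W <- W[, cols, drop = FALSE]
  Tt <- sum(W)
  r <- rowSums(W)
  cc <- colSums(W)
  num <- Tt * W - outer(r, cc)
  den <- sqrt(outer(r * (Tt - r), cc * (Tt - cc)))
  corr <- ifelse(den > 0, num / den, 0)
  corr[corr < 0] <- 0
  vec <- sqrt(corr)
  structure(list(vectors = vec, vocabulary = vocab, columns = cols,
                 window = as.integer(window), dim = dim,
                 frequency = freq),
            class = "ps_coals")
}

#' @export
print.ps_coals <- function(x, ...) {
  cat(sprintf("<ps_coals: %d terms x %d features, window %d>\n",
              length(x$vocabulary), x$dim, x$window))
  invisible(x)
}

#' COALS similarity between two terms
#'
#' Pearson correlation of the two normalized vectors, clamped below at 0.
#' Unknown terms (with a warning) and all-zero vectors score 0; a term with a
#' nonzero vector scores 1 against itself.
#'
#' @param model a `ps_coals`.
#' @param a,b term strings (canonical entity ids or words).
#' @return similarity in \[0, 1\].
#' @export
coals_similarity <- function(model, a, b) {
  stopifnot(inherits(model, "ps_coals"))
  for (t in c(a, b)) {
    if (!(t %in% model$vocabulary)) {
      warning("term not in COALS vocabulary: ", t)
      return(0)
    }
  }
  va <- model$vectors[a, ]
  vb <- model$vectors[b, ]
  if (all(va == 0) || all(vb == 0)) return(0)
  if (identical(unname(va), unname(vb))) return(1)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
  max(0, stats::cor(va, vb))
}

#' Persist a COALS model as plain text
#'
#' Writes the vector matrix as TSV (terms x features) next to a small JSON
#' header with window/dim.
#'
#' @param model a `ps_coals`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_coals <- function(model, path) {
  write.table(model$vectors, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              col.names = NA, fileEncoding = "UTF-8")
  jsonlite::write_json(list(window = model$window, dim = model$dim),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a persisted COALS model
#'
#' @param path base path used by [write_coals()].
#' @return a `ps_coals`.
#' @export
read_coals <- function(path) {
  vec <- as.matrix(read.delim(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                              row.names = 1L, check.names = FALSE,
                              fileEncoding = "UTF-8"))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(vectors = vec, vocabulary = rownames(vec),
                 columns = colnames(vec), window = as.integer(meta$window),
                 dim = as.integer(meta$dim), frequency = NULL),
            class = "ps_coals")
}

#' Load a concept hierarchy from TSV
#'
#' Format: `child_id<TAB>parent_id` per line with header, one root row
#' `ROOT<TAB>-`. The structure must be a rooted tree/DAG reaching the single
#' root from every node (a generic stand-in for a licensed medical
#' ontology's IS-A hierarchy). Entity canonical ids are used directly as
#' node ids.
#'
#' @param path TSV path.
#' @return object of class `ps_hierarchy`.
#' @export
load_hierarchy <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("child_id", "parent_id") %in% names(tab))) {
    stop("hierarchy TSV must have columns child_id, parent_id")
  }
  hierarchy_from_table(tab)
}

#' Build a concept hierarchy from an edge table
#'
#' @param tab data.frame with `child_id`, `parent_id`; the root has
#'   parent `"-"`.
#' @return a `ps_hierarchy`.
#' @export
hierarchy_from_table <- function(tab) {
  roots <- tab$child_id[tab$parent_id == "-"]
  if (length(roots) != 1L) stop("hierarchy must have exactly one root row")
  parent <- stats::setNames(tab$parent_id, tab$child_id)
  parent <- parent[names(parent) != roots]
  # depth with cycle detection; root depth = 1
  depth <- stats::setNames(rep(NA_integer_, length(parent) + 1L),
                           c(roots, names(parent)))
  depth[[roots]] <- 1L
  for (nd in names(parent)) {
    chain <- nd
    cur <- nd
    while (is.na(depth[[cur]])) {
      cur <- parent[[cur]]
      if (is.null(cur) || !(cur %in% names(depth))) {
        stop("node '", chain[[1]], "' does not reach the root")
      }
      if (cur %in% chain) stop("parent cycle at node '", cur, "'")
      chain <- c(chain, cur)
    }
    d <- depth[[cur]]
    for (x in rev(setdiff(chain, cur))) {
      d <- d + 1L
      depth[[x]] <- d
    }
  }
  structure(list(root = roots, parent = parent, depth = depth),
            class = "ps_hierarchy")
}

.ps_ancestors <- function(h, node) {
  # node itself first, then parents up to the root
  out <- node
  cur <- node
  while (cur != h$root) {
    cur <- h$parent[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Hierarchy-based semantic similarity
#'
#' Wu-Palmer by default: `2 * depth(lcs) / (depth(a) + depth(b))` with root
#' depth 1, where `lcs` is the deepest common ancestor. Scores are symmetric,
#' in \[0, 1\], and 1 iff the two ids map to the same node. Ids not present
#' in the hierarchy score 0. `method = "leacock"` gives a rescaled
#' Leacock-Chodorow alternative `1 - log(len + 1) / log(2 * maxdepth + 1)`
#' (`len` = shortest path length through the lcs).
#'
#' @param h a `ps_hierarchy`.
#' @param a,b concept/entity ids.
#' @param method `"wupalmer"` (default) or `"leacock"`.
#' @return similarity in \[0, 1\].
#' @export
hierarchy_similarity <- function(h, a, b, method = c("wupalmer", "leacock")) {
  method <- match.arg(method)
  known <- names(h$depth)
  if (!(a %in% known) || !(b %in% known)) return(0)
  if (a == b) return(1)
  anc_a <- .ps_ancestors(h, a)
  anc_b <- .ps_ancestors(h, b)
  common <- intersect(anc_a, anc_b)
  lcs <- common[which.max(h$depth[common])]
  if (method == "wupalmer") {
    2 * h$depth[[lcs]] / (h$depth[[a]] + h$depth[[b]])
  } else {
    len <- (h$depth[[a]] - h$depth[[lcs]]) + (h$depth[[b]] - h$depth[[lcs]])
    maxd <- max(h$depth)
    max(0, 1 - log(len + 1) / log(2 * maxd + 1))
  }
}
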