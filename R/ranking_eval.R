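# Hybrid path ranking (entity-pair weight = weighted sum of COALS similarity,
# side-effect-local pair frequency and hierarchy similarity), baseline
# rankers, and precision-at-k evaluation.

#' Ranking weights
#'
#' The three mixing coefficients of the entity-pair weight: `alpha` for the
#' COALS corpus similarity, `beta` for the side-effect-local frequency term,
#' `gamma` for the hierarchy similarity. Defaults 0.3 / 0.4 / 0.3. Weights
#' must be non-negative; a vector not summing to 1 is renormalized with a
#' warning.
#'
#' @param alpha,beta,gamma non-negative reals.
#' @return object of class `ps_weights`.
#' @export
ranking_weights <- function(alpha = 0.3, beta = 0.4, gamma = 0.3) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s == 0) stop("weights must not all be zero")
  if (abs(s - 1) > 1e-9) {
    warning("weights do not sum to 1; renormalizing")
    w <- w / s
  }
  structure(as.list(w), class = "ps_weights")
}

#' Side-effect-local pair frequency table
#'
#' For the candidate path set under ranking, counts how often each directed
#' entity pair (vi, vj) occurs among the paths terminating in each side
#' effect, and the per-side-effect maximum (the normalizer).
#'
#' @param paths path data.frame (see [enumerate_paths()]).
#' @return object of class `ps_freq`: counts env and max per side effect.
#' @export
local_freq_table <- function(paths) {
  counts <- new.env(parent = emptyenv())
  se_max <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(paths))) {
    nodes <- path_nodes(paths[i, ])
    se <- paths$side_effect[[i]]
    for (j in seq_len(length(nodes) - 1L)) {
      key <- paste(se, nodes[[j]], nodes[[j + 1L]], sep = "\r")
      cnt <- if (is.null(counts[[key]])) 1L else counts[[key]] + 1L
      counts[[key]] <- cnt
      if (is.null(se_max[[se]]) || cnt > se_max[[se]]) se_max[[se]] <- cnt
    }
  }
  structure(list(counts = counts, se_max = se_max), class = "ps_freq")
}

#' Local frequency of a pair for a side effect
#'
#' @param freq a `ps_freq` from [local_freq_table()].
#' @param vi,vj entity ids of the directed pair.
#' @param se_id side-effect id; unknown side effects return 0.
#' @return non-negative integer count.
#' @export
local_frequency <- function(freq, vi, vj, se_id) {
  v <- freq$counts[[paste(se_id, vi, vj, sep = "\r")]]
  if (is.null(v)) 0L else v
}

#' Maximum local frequency for a side effect
#'
#' @param freq a `ps_freq`.
#' @param se_id side-effect id.
#' @return non-negative integer (0 when the side effect has no counted pairs).
#' @export
max_local_frequency <- function(freq, se_id) {
  v <- freq$se_max[[se_id]]
  if (is.null(v)) 0L else v
}

#' Entity-pair weight
#'
#' `alpha * COALS(vi, vj) + beta * LocalFreq(vi, vj, SE) / MaxLocalFreq(SE)
#'  + gamma * HierarchySim(vi, vj)`. When the side effect has no counted
#' pairs (`MaxLocalFreq = 0`) the frequency term is defined as 0.
#'
#' @param vi,vj entity ids of the directed pair.
#' @param se_id side effect the enclosing path terminates in.
#' @param coals a `ps_coals` model.
#' @param hier a `ps_hierarchy`.
#' @param freq a `ps_freq`.
#' @param weights a `ps_weights`.
#' @return weight in \[0, 1\].
#' @export
entity_pair_weight <- function(vi, vj, se_id, coals, hier, freq,
                               weights = ranking_weights()) {
  mx <- max_local_frequency(freq, se_id)
  f <- if (mx > 0) local_frequency(freq, vi, vj, se_id) / mx else 0
  weights$alpha * coals_similarity(coals, vi, vj) +
    weights$beta * f +
    weights$gamma * hierarchy_similarity(hier, vi, vj)
}

#' Score one path
#'
#' Arithmetic mean of the consecutive entity-pair weights along the path
#' (a path with n nodes has n - 1 pairs).
#'
#' @param path_row one row of a path data.frame.
#' @param pair_weight_fn function(vi, vj) -> weight for this path's side
#'   effect.
#' @return the path ranking score.
#' @export
path_score <- function(path_row, pair_weight_fn) {
  nodes <- path_nodes(path_row)
  stopifnot(length(nodes) >= 2L)
  w <- vapply(seq_len(length(nodes) - 1L), function(j) {
    pair_weight_fn(nodes[[j]], nodes[[j + 1L]])
  }, 0)
  mean(w)
}

.ps_path_sortkey <- function(paths) {
  paste(paths$drug, paths$p1,
        ifelse(is.na(paths$p2), "", paths$p2),
        ifelse(is.na(paths$p3), "", paths$p3),
        paths$side_effect)
}

#' Rank paths by a scorer
#'
#' Stable descending sort by score; ties broken lexicographically by
#' (drug, proteins, side effect) for determinism.
#'
#' @param paths path data.frame.
#' @param scores numeric vector of scores, one per path row.
#' @return `paths` with `score` and 1-based `rank` columns, in rank order.
#' @export
rank_paths <- function(paths, scores) {
  stopifnot(length(scores) == nrow(paths))
  out <- paths
  out$score <- scores
  ord <- order(-out$score, .ps_path_sortkey(out))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Score every path with the proposed hybrid weight
#'
#' @param paths path data.frame.
#' @param coals a `ps_coals`.
#' @param hier a `ps_hierarchy`.
#' @param weights a `ps_weights`.
#' @param freq optional `ps_freq`; defaults to [local_freq_table()] over
#'   `paths` (the candidate set under ranking defines the local frequencies).
#' @return numeric vector of path scores.
#' @export
proposed_scores <- function(paths, coals, hier, weights = ranking_weights(),
                            freq = NULL) {
  if (is.null(freq)) freq <- local_freq_table(paths)
  vapply(seq_len(nrow(paths)), function(i) {
    se <- paths$side_effect[[i]]
    path_score(paths[i, ], function(vi, vj) {
      entity_pair_weight(vi, vj, se, coals, hier, freq, weights)
    })
  }, 0)
}

#' Baseline path scores
#'
#' Three comparison rankers: `COOCCURRENCE` averages the normalized pair
#' support (edge support / maximum edge support in the graph) along the
#' path; `COALS_ONLY` and `HIERARCHY_ONLY` average the corresponding
#' similarity alone (equivalently, the proposed score with weight vectors
#' (1,0,0) and (0,0,1)).
#'
#' @param paths path data.frame.
#' @param mode one of `"COOCCURRENCE"`, `"COALS_ONLY"`, `"HIERARCHY_ONLY"`.
#' @param graph a `ps_graph` (COOCCURRENCE mode).
#' @param coals a `ps_coals` (COALS_ONLY mode).
#' @param hier a `ps_hierarchy` (HIERARCHY_ONLY mode).
#' @return numeric vector of path scores.
#' @export
baseline_scores <- function(paths, mode, graph = NULL, coals = NULL,
                            hier = NULL) {
  if (!is.character(mode) ||
      !mode[[1]] %in% c("COOCCURRENCE", "COALS_ONLY", "HIERARCHY_ONLY")) {
    stop("unknown baseline mode: ", mode[[1]])
  }
  mode <- mode[[1]]
  if (mode == "COOCCURRENCE") {
    stopifnot(inherits(graph, "ps_graph"))
    e <- graph$edges
    mx <- if (nrow(e)) max(e$support) else 0L
    sup <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(e))) {
      sup[[paste(e$source_id[[i]], e$target_id[[i]], sep = "\r")]] <-
        e$support[[i]]
    }
    pw <- function(vi, vj) {
      v <- sup[[paste(vi, vj, sep = "\r")]]
      if (is.null(v) || mx == 0L) 0 else v / mx
    }
  } else if (mode == "COALS_ONLY") {
    stopifnot(inherits(coals, "ps_coals"))
    pw <- function(vi, vj) coals_similarity(coals, vi, vj)
  } else {
    stopifnot(inherits(hier, "ps_hierarchy"))
    pw <- function(vi, vj) hierarchy_similarity(hier, vi, vj)
  }
  vapply(seq_len(nrow(paths)), function(i) path_score(paths[i, ], pw), 0)
}

#' Precision at k
#'
#' Fraction of the top `k` ranked items whose label is in `true_labels`.
#'
#' @param labels character vector of labels in rank order (rank 1 first).
#' @param k cutoff, `1 <= k <= length(labels)`.
#' @param true_labels label values counted as correct (e.g. `"TYPE1"` or
#'   `c("TYPE1", "TYPE2")`).
#' @return precision in \[0, 1\].
#' @export
precision_at_k <- function(labels, k, true_labels) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > length(labels)) {
    stop("k must be in 1..length(labels)")
  }
  k <- as.integer(k)
  sum(labels[seq_len(k)] %in% true_labels) / k
}

#' Read a path-label TSV
#'
#' Format: header `path_no<TAB>label`, labels TYPE1/TYPE2/TYPE3.
#'
#' @param path TSV path.
#' @return data.frame with path_no (integer) and label.
#' @export
read_path_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    fileEncoding = "UTF-8")
  stopifnot(all(c("path_no", "label") %in% names(tab)))
  bad <- setdiff(unique(tab$label), c("TYPE1", "TYPE2", "TYPE3"))
  if (length(bad)) stop("unknown path label: ", paste(bad, collapse = ", "))
  tab$path_no <- as.integer(tab$path_no)
  tab
}

#' Curated top-20 ranked paths with plausibility labels
#'
#' A worked example shipped with the package: the top 20
#' drug - protein(^k) - side-effect paths produced by ranking a large
#' cancer-abstract mining run with the hybrid weight (0.3, 0.4, 0.3),
#' together with expert plausibility labels (TYPE1 = entities and verbs both
#' supported by literature, TYPE2 = entities supported but verbs uncertain,
#' TYPE3 = both uncertain).
#'
#' @return list with `paths` (rank order) and `labels` data.frames.
#' @export
cancer_top20 <- function() {
  pfile <- system.file("extdata", "cancer_top20_paths.tsv",
                       package = "pathseeker", mustWork = TRUE)
  lfile <- system.file("extdata", "cancer_top20_labels.tsv",
                       package = "pathseeker", mustWork = TRUE)
  paths <- read.delim(pfile, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", fileEncoding = "UTF-8")
  paths$rank <- as.integer(paths$rank)
  list(paths = paths, labels = read_path_labels(lfile))
}

#' Precision-at-k table for a labeled ranking
#'
#' @param labels labels in rank order.
#' @param ks cutoffs (default 5, 10, 15, 20).
#' @param true_labels labels counted correct.
#' @return data.frame with columns k and precision.
#' @export
precision_table <- function(labels, ks = c(5L, 10L, 15L, 20L), true_labels) {
  data.frame(k = as.integer(ks),
             precision = vapply(ks, function(k)
               precision_at_k(labels, k, true_labels), 0))
}
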