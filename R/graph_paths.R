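# Typed directed multigraph over extracted triples and enumeration of
# drug -> protein^k -> side-effect paths (k = 1..3).

.ps_node_key <- function(id, type) paste(type, id, sep = "\r")

#' Build the knowledge graph from relation triples
#'
#' Parallel triples (same source, target) merge into one edge carrying the
#' set of connecting verb lemmas, the union of their polarities, a support
#' count (number of contributing triples) and the distinct supporting
#' sentence references. Negated triples are excluded by default (the
#' conservative disposal; set `keep_negated = TRUE` to keep them flagged
#' upstream). When `drug_whitelist` is given, drug nodes outside it are
#' dropped with their edges.
#'
#' @param triples triples data.frame (see [extract_relations()]).
#' @param drug_whitelist optional character vector of DRUG canonical ids.
#' @param keep_negated include negated triples (default FALSE).
#' @return object of class `ps_graph` with an `edges` data.frame
#'   (source_id, source_type, target_id, target_type, verbs, polarities,
#'   support, provenance) and a `nodes` data.frame.
#' @export
build_graph <- function(triples, drug_whitelist = NULL, keep_negated = FALSE) {
  tr <- triples
  if (!keep_negated && nrow(tr)) tr <- tr[!tr$negated, , drop = FALSE]
  if (nrow(tr)) {
    ok <- mapply(.ps_pair_allowed, tr$source_type, tr$target_type)
    tr <- tr[ok, , drop = FALSE]
  }
  if (!is.null(drug_whitelist) && nrow(tr)) {
    drop <- (tr$source_type == "DRUG" & !(tr$source_id %in% drug_whitelist))
    tr <- tr[!drop, , drop = FALSE]
  }
  if (!nrow(tr)) {
    edges <- data.frame(source_id = character(0), source_type = character(0),
                        target_id = character(0), target_type = character(0),
                        verbs = character(0), polarities = character(0),
                        support = integer(0), provenance = character(0),
                        stringsAsFactors = FALSE)
  } else {
    key <- paste(tr$source_type, tr$source_id, tr$target_type, tr$target_id,
                 sep = "\r")
    idx <- split(seq_len(nrow(tr)), key)
    edges <- do.call(rbind, lapply(idx, function(ii) {
      g <- tr[ii, , drop = FALSE]
      data.frame(
        source_id = g$source_id[[1]], source_type = g$source_type[[1]],
        target_id = g$target_id[[1]], target_type = g$target_type[[1]],
        verbs = paste(sort(unique(g$verb)), collapse = "|"),
        polarities = paste(sort(unique(g$polarity)), collapse = "|"),
        support = nrow(g),
        provenance = paste(sort(unique(paste(g$pmid, g$sentence_index,
                                             sep = ":"))), collapse = "|"),
        stringsAsFactors = FALSE)
    }))
    edges <- edges[order(edges$source_type, edges$source_id,
                         edges$target_type, edges$target_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- unique(rbind(
    data.frame(id = edges$source_id, type = edges$source_type,
               stringsAsFactors = FALSE),
    data.frame(id = edges$target_id, type = edges$target_type,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "ps_graph")
}

#' @export
print.ps_graph <- function(x, ...) {
  cat(sprintf("<ps_graph: %d nodes, %d edges, total support %d>\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$support)))
  invisible(x)
}

#' Write graph edges to TSV
#'
#' @param graph a `ps_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read graph edges from TSV
#'
#' @param path TSV written by [write_graph()].
#' @return a `ps_graph`.
#' @export
read_graph <- function(path) {
  edges <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                      fileEncoding = "UTF-8",
                      colClasses = c(support = "integer"))
  for (col in setdiff(names(edges), "support")) {
    edges[[col]] <- as.character(edges[[col]])
  }
  nodes <- unique(rbind(
    data.frame(id = edges$source_id, type = edges$source_type,
               stringsAsFactors = FALSE),
    data.frame(id = edges$target_id, type = edges$target_type,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "ps_graph")
}

.ps_adjacency <- function(graph) {
  adj <- new.env(parent = emptyenv())
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    k <- .ps_node_key(e$source_id[[i]], e$source_type[[i]])
    adj[[k]] <- c(adj[[k]], i)
  }
  adj
}

.ps_empty_paths <- function() {
  data.frame(depth = integer(0), drug = character(0),
             p1 = character(0), p2 = character(0), p3 = character(0),
             side_effect = character(0),
             v1 = character(0), v2 = character(0), v3 = character(0),
             v4 = character(0), stringsAsFactors = FALSE)
}

#' Enumerate drug -> protein^k -> side-effect paths
#'
#' Returns exactly the simple directed paths consisting of one drug node,
#' `k` pairwise-distinct protein nodes and one side-effect node, following
#' edges in their stated direction. Output is ordered lexicographically by
#' (drug, proteins, side effect) for determinism. Column `vI` holds the
#' pipe-joined verb set of the I-th edge; `p2`/`p3`/`v3`/`v4` are `NA` below
#' the corresponding depth.
#'
#' @param graph a `ps_graph`.
#' @param k protein depth, 1..3.
#' @return data.frame of paths (depth, drug, p1..p3, side_effect, v1..v4).
#' @export
enumerate_paths <- function(graph, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > 3L) {
    stop("k must be a single integer in 1..3")
  }
  k <- as.integer(k)
  e <- graph$edges
  adj <- .ps_adjacency(graph)
  drugs <- sort(unique(e$source_id[e$source_type == "DRUG"]))
  rows <- list()
  walk <- function(node_id, proteins, verbs) {
    depth_now <- length(proteins)
    out_idx <- adj[[.ps_node_key(node_id, if (depth_now == 0L) "DRUG" else "PROTEIN")]]
    for (i in out_idx) {
      tt <- e$target_type[[i]]
      tid <- e$target_id[[i]]
      if (tt == "PROTEIN" && depth_now < k && !(tid %in% proteins)) {
        walk(tid, c(proteins, tid), c(verbs, e$verbs[[i]]))
      } else if (tt == "SIDE_EFFECT" && depth_now == k) {
        pr <- c(proteins, rep(NA_character_, 3L - k))
        vb <- c(verbs, e$verbs[[i]], rep(NA_character_, 3L - k))
        rows[[length(rows) + 1L]] <<- data.frame(
          depth = k, drug = drug_now, p1 = pr[[1]], p2 = pr[[2]],
          p3 = pr[[3]], side_effect = tid, v1 = vb[[1]], v2 = vb[[2]],
          v3 = vb[[3]], v4 = vb[[4]], stringsAsFactors = FALSE)
      }
    }
  }
  for (drug_now in drugs) {
    walk(drug_now, character(0), character(0))
  }
  if (!length(rows)) return(.ps_empty_paths())
  out <- do.call(rbind, rows)
  ord <- order(out$drug, out$p1,
               ifelse(is.na(out$p2), "", out$p2),
               ifelse(is.na(out$p3), "", out$p3), out$side_effect)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node id sequence of one path row
#'
#' @param path_row one row of a path data.frame.
#' @return character vector drug, proteins..., side effect.
#' @export
path_nodes <- function(path_row) {
  pr <- c(path_row$p1, path_row$p2, path_row$p3)
  c(path_row$drug, pr[!is.na(pr)], path_row$side_effect)
}

#' Verb sets of one path row
#'
#' @param path_row one row of a path data.frame.
#' @return character vector of pipe-joined verb sets, one per edge.
#' @export
path_verbs <- function(path_row) {
  vb <- c(path_row$v1, path_row$v2, path_row$v3, path_row$v4)
  vb[!is.na(vb)]
}

#' Filter paths to significant side-effect paths
#'
#' Two screens mirroring post-hoc path curation: (1) paths whose side-effect
#' name contains an intended-effect term (tumor/cancer/...) describe the
#' drug's therapeutic effect, not a side effect, and are removed;
#' (2) a path is significant only when its verbs represent a change to other
#' bio entities — by default every edge except the terminal
#' protein -> side-effect edge must carry at least one verb of INCREASE or
#' DECREASE polarity (the terminal edge may be purely associative).
#'
#' @param paths path data.frame from [enumerate_paths()].
#' @param effect_terms lowercase substrings flagging intended effects.
#' @param bioverbs a `ps_bioverbs` used by the default significance rule.
#' @param se_names optional named vector canonical_id -> display name used
#'   for the effect-term screen (defaults to the ids themselves).
#' @param significant optional predicate `function(verbs, terminal)` on a
#'   character vector of verb lemmas; overrides the default rule.
#' @return the filtered path data.frame.
#' @export
filter_significant <- function(paths,
                               effect_terms = c("tumor", "tumour", "cancer",
                                                "carcinoma", "neoplasm"),
                               bioverbs = NULL, se_names = NULL,
                               significant = NULL) {
  if (!nrow(paths)) return(paths)
  if (is.null(significant)) {
    if (is.null(bioverbs)) {
      significant <- function(verbs, terminal) TRUE
    } else {
      significant <- function(verbs, terminal) {
        if (terminal) return(TRUE)
        pol <- verb_polarity(bioverbs, verbs)
        any(pol %in% c("INCREASE", "DECREASE"))
      }
    }
  }
  keep <- logical(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    se <- paths$side_effect[[i]]
    nm <- if (!is.null(se_names) && se %in% names(se_names)) se_names[[se]] else se
    if (length(effect_terms) &&
        any(vapply(effect_terms, grepl, TRUE, x = tolower(nm), fixed = TRUE))) {
      keep[[i]] <- FALSE
      next
    }
    vbs <- path_verbs(paths[i, ])
    ok <- TRUE
    for (ei in seq_along(vbs)) {
      verbs <- strsplit(vbs[[ei]], "|", fixed = TRUE)[[1]]
      if (!significant(verbs, terminal = (ei == length(vbs)))) {
        ok <- FALSE
        break
      }
    }
    keep[[i]] <- ok
  }
  out <- paths[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
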