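# Deterministic synthetic corpora with planted drug -> protein^k -> side
# effect chains and rule-violating distractors, so every pipeline stage can
# be tested offline against exact ground truth.
#
# Sentence templates instantiate the extraction rules by construction:
# active and passive phrasings, negated variants, out-of-window pairs,
# non-bio-verb pairs, intended-effect (cancer-named) endpoints and
# neutral-verb chains that the significance screen must drop.

.ps_with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.ps_verb_table <- function() {
  data.frame(
    lemma = c("inhibit", "reduce", "abolish", "silence", "block", "suppress",
              "neutralize", "decrease", "attenuate",
              "activate", "stimulate", "enhance", "accelerate", "induce",
              "increase", "upregulate", "promote",
              "associate", "observe", "suggest", "correlate", "interact"),
    polarity = c(rep("DECREASE", 9L), rep("INCREASE", 8L),
                 rep("NEUTRAL", 5L)),
    stringsAsFactors = FALSE)
}

.ps_conj3 <- function(lemma) {
  if (grepl("(sh|ch|s|x|z)$", lemma)) paste0(lemma, "es")
  else if (grepl("[^aeiou]y$", lemma)) sub("y$", "ies", lemma)
  else paste0(lemma, "s")
}

.ps_ppart <- function(lemma) {
  if (grepl("e$", lemma)) paste0(lemma, "d") else paste0(lemma, "ed")
}

.ps_cap <- function(tokens) {
  substr(tokens[[1]], 1L, 1L) <- toupper(substr(tokens[[1]], 1L, 1L))
  tokens
}

# Build one sentence for edge src --verb--> tgt. Returns the sentence text
# plus the expected mention spans (1-based inclusive token positions).
.ps_edge_sentence <- function(src_surface, tgt_surface, verb, template) {
  sv <- ps_tokenize(src_surface)
  tv <- ps_tokenize(tgt_surface)
  if (template == "active") {
    toks <- c(sv, .ps_conj3(verb), tv)
    s_start <- 1L
    t_start <- length(sv) + 2L
  } else if (template == "active_long") {
    toks <- c(sv, "markedly", .ps_conj3(verb), tv)
    s_start <- 1L
    t_start <- length(sv) + 3L
  } else if (template == "active_np") {
    toks <- c(sv, .ps_conj3(verb), "the", "activity", "of", tv)
    s_start <- 1L
    t_start <- length(sv) + 5L
  } else if (template == "passive") {
    toks <- c(tv, "is", .ps_ppart(verb), "by", sv)
    t_start <- 1L
    s_start <- length(tv) + 4L
  } else if (template == "passive_long") {
    toks <- c(tv, "was", "strongly", .ps_ppart(verb), "by", sv)
    t_start <- 1L
    s_start <- length(tv) + 5L
  } else if (template == "negated") {
    toks <- c(sv, "does", "not", verb, tv)
    s_start <- 1L
    t_start <- length(sv) + 4L
  } else if (template == "window") {
    toks <- c(sv, .ps_conj3(verb), "under", "prolonged", "high", "dose",
              "exposure", "regimens", tv)
    s_start <- 1L
    t_start <- length(sv) + 8L
  } else if (template == "nonverb") {
    toks <- c(sv, "resembles", tv)
    s_start <- 1L
    t_start <- length(sv) + 2L
  } else {
    stop("unknown template: ", template)
  }
  toks <- .ps_cap(toks)
  list(text = paste0(paste(toks, collapse = " "), "."),
       spans = data.frame(
         surface = c(src_surface, tgt_surface),
         start = c(s_start, t_start),
         end = c(s_start + length(sv) - 1L, t_start + length(tv) - 1L),
         stringsAsFactors = FALSE))
}

.ps_filler_sentences <- c(
  "These findings warrant further investigation in larger cohorts.",
  "The experimental design followed standard laboratory procedure.",
  "Additional replication studies are planned for next year.",
  "Samples were processed according to routine practice.")

#' Generate a synthetic corpus with planted paths
#'
#' Builds `n_chains` drug -> protein^k -> side-effect chains (depths drawn
#' from `depth_mix`), realizes every edge as one or more template sentences
#' (active, passive, and padded variants), sprinkles rule-violating
#' distractors (negated pairs, out-of-window pairs, non-bio-verb pairs,
#' cancer-named endpoints, neutral-verb chains) and distributes the
#' sentences over `n_docs` abstracts. Entity names include hyphenated and
#' multi-token forms to stress 1/2/3-gram matching. Regeneration with the
#' same seed is byte-identical; the caller's RNG state is untouched.
#'
#' The ground truth describes the pipeline run with default settings
#' (titles mined, negated triples dropped, window 6).
#'
#' @param n_docs number of abstracts (>= 1).
#' @param n_chains number of planted chains (>= 1).
#' @param depth_mix probability weights for depths 1..3.
#' @param seed integer seed.
#' @param outdir optional directory; when given, writes `corpus.xml`,
#'   `drugs.tsv`, `proteins.tsv`, `sideeffects.tsv`, `verbs.tsv`,
#'   `hierarchy.tsv`.
#' @param distractors include rule-violating distractors (default TRUE).
#' @return list with `docs`, `lexicons` (list DRUG/PROTEIN/SIDE_EFFECT),
#'   `bioverbs`, `hierarchy`, `ground_truth` (mentions, triples, paths,
#'   labels, seed) and `files` (paths or NULL).
#' @export
generate_corpus <- function(n_docs = 20L, n_chains = 10L,
                            depth_mix = c(1, 1, 1), seed = 42L,
                            outdir = NULL, distractors = TRUE) {
  stopifnot(n_docs >= 1L, n_chains >= 1L, length(depth_mix) == 3L)
  .ps_with_seed(seed, {
    verbs <- .ps_verb_table()
    bioverbs <- bioverbs_from_table(verbs)
    dir_verbs <- verbs$lemma[verbs$polarity %in% c("INCREASE", "DECREASE")]

    depths <- sample(1:3, n_chains, replace = TRUE, prob = depth_mix)

    # entity inventories ---------------------------------------------------
    n_decoy <- if (distractors) 5L else 0L
    n_drugs <- n_chains + n_decoy
    n_prot <- sum(depths) + n_decoy * 2L
    n_se <- n_chains + n_decoy
    drug_tab <- data.frame(
      canonical_id = sprintf("DRG%03d", seq_len(n_drugs)),
      canonical_name = sprintf("doxafinib-%d", seq_len(n_drugs)),
      synonyms = vapply(seq_len(n_drugs), function(i) {
        syn <- sprintf("dxf-%d", i)
        if (i %% 2L == 1L) syn <- paste(syn, sprintf("doxafinib %d mesylate", i),
                                        sep = "|")
        syn
      }, ""), stringsAsFactors = FALSE)
    prot_tab <- data.frame(
      canonical_id = sprintf("PRT%03d", seq_len(n_prot)),
      canonical_name = sprintf("kinavin-%d", seq_len(n_prot)),
      synonyms = vapply(seq_len(n_prot), function(i) {
        syn <- sprintf("kv%d", i)
        if (i %% 3L == 0L) syn <- paste(syn, sprintf("little kinavin %d", i),
                                        sep = "|")
        syn
      }, ""), stringsAsFactors = FALSE)
    se_tab <- data.frame(
      canonical_id = sprintf("SE%03d", seq_len(n_se)),
      canonical_name = sprintf("neuralgia-%d", seq_len(n_se)),
      synonyms = sprintf("acute neuralgia-%d", seq_len(n_se)),
      stringsAsFactors = FALSE)
    if (distractors) {
      # intended-effect endpoint: name contains an effect term
      se_tab <- rbind(se_tab, data.frame(
        canonical_id = "SEC01", canonical_name = "colon cancer-1",
        synonyms = "colon cancer-1", stringsAsFactors = FALSE))
    }

    surfaces <- function(tab, i) {
      c(tab$canonical_name[[i]],
        strsplit(tab$synonyms[[i]], "|", fixed = TRUE)[[1]])
    }

    # chain construction ---------------------------------------------------
    sentences <- character(0)
    sent_meta <- list()  # per sentence: spans + expected triple (or NULL)
    add_edge <- function(src_id, src_tab, src_i, tgt_id, tgt_tab, tgt_i,
                         lemmas, src_type, tgt_type, planted = TRUE) {
      for (lem in lemmas) {
        template <- sample(c("active", "active_long", "active_np",
                             "passive", "passive_long"), 1L)
        src_surf <- sample(surfaces(src_tab, src_i), 1L)
        tgt_surf <- sample(surfaces(tgt_tab, tgt_i), 1L)
        es <- .ps_edge_sentence(src_surf, tgt_surf, lem, template)
        sentences[[length(sentences) + 1L]] <<- es$text
        es$spans$canonical_id <- c(src_id, tgt_id)
        es$spans$entity_type <- c(src_type, tgt_type)
        sent_meta[[length(sentences)]] <<- list(
          spans = es$spans,
          triple = data.frame(source_id = src_id, source_type = src_type,
                              verb = lem, target_id = tgt_id,
                              target_type = tgt_type, planted = planted,
                              stringsAsFactors = FALSE))
      }
    }
    add_distractor <- function(src_id, src_tab, src_i, tgt_id, tgt_tab, tgt_i,
                               lem, template, src_type, tgt_type) {
      es <- .ps_edge_sentence(src_tab$canonical_name[[src_i]],
                              tgt_tab$canonical_name[[tgt_i]], lem, template)
      sentences[[length(sentences) + 1L]] <<- es$text
      es$spans$canonical_id <- c(src_id, tgt_id)
      es$spans$entity_type <- c(src_type, tgt_type)
      sent_meta[[length(sentences)]] <<- list(spans = es$spans, triple = NULL)
    }

    paths <- .ps_empty_paths()
    pi <- 0L  # protein cursor
    for (ch in seq_len(n_chains)) {
      k <- depths[[ch]]
      prots <- (pi + 1L):(pi + k)
      pi <- pi + k
      node_ids <- c(drug_tab$canonical_id[[ch]],
                    prot_tab$canonical_id[prots],
                    se_tab$canonical_id[[ch]])
      edge_verbsets <- character(0)
      for (ei in seq_len(k + 1L)) {
        terminal <- ei == k + 1L
        lemmas <- if (terminal && ch %% 2L == 0L) "associate"
                  else sort(sample(dir_verbs, sample(1:2, 1L)))
        edge_verbsets[[ei]] <- paste(sort(unique(lemmas)), collapse = "|")
        src_i <- ei      # position within chain
        if (ei == 1L) {
          add_edge(node_ids[[1]], drug_tab, ch,
                   node_ids[[2]], prot_tab, prots[[1]],
                   lemmas, "DRUG", "PROTEIN")
        } else if (terminal) {
          add_edge(node_ids[[ei]], prot_tab, prots[[k]],
                   node_ids[[ei + 1L]], se_tab, ch,
                   lemmas, "PROTEIN", "SIDE_EFFECT")
        } else {
          add_edge(node_ids[[ei]], prot_tab, prots[[ei - 1L]],
                   node_ids[[ei + 1L]], prot_tab, prots[[ei]],
                   lemmas, "PROTEIN", "PROTEIN")
        }
      }
      pr <- c(prot_tab$canonical_id[prots], rep(NA_character_, 3L - k))
      vb <- c(edge_verbsets, rep(NA_character_, 3L - k))
      paths <- rbind(paths, data.frame(
        depth = k, drug = node_ids[[1]], p1 = pr[[1]], p2 = pr[[2]],
        p3 = pr[[3]], side_effect = se_tab$canonical_id[[ch]],
        v1 = vb[[1]], v2 = vb[[2]], v3 = vb[[3]], v4 = vb[[4]],
        stringsAsFactors = FALSE))
    }

    if (distractors) {
      dd <- n_chains  # decoy index offsets
      pd <- pi
      sd_ <- n_chains
      # 1: negated drug-protein edge; its protein->SE edge is real, but the
      #    negated edge is dropped so no path forms.
      add_distractor(drug_tab$canonical_id[[dd + 1L]], drug_tab, dd + 1L,
                     prot_tab$canonical_id[[pd + 1L]], prot_tab, pd + 1L,
                     "inhibit", "negated", "DRUG", "PROTEIN")
      add_edge(prot_tab$canonical_id[[pd + 1L]], prot_tab, pd + 1L,
               se_tab$canonical_id[[sd_ + 1L]], se_tab, sd_ + 1L,
               "activate", "PROTEIN", "SIDE_EFFECT", planted = TRUE)
      # 2: out-of-window drug-protein pair
      add_distractor(drug_tab$canonical_id[[dd + 2L]], drug_tab, dd + 2L,
                     prot_tab$canonical_id[[pd + 2L]], prot_tab, pd + 2L,
                     "stimulate", "window", "DRUG", "PROTEIN")
      add_edge(prot_tab$canonical_id[[pd + 2L]], prot_tab, pd + 2L,
               se_tab$canonical_id[[sd_ + 2L]], se_tab, sd_ + 2L,
               "induce", "PROTEIN", "SIDE_EFFECT", planted = TRUE)
      # 3: non-bio-verb pair
      add_distractor(drug_tab$canonical_id[[dd + 3L]], drug_tab, dd + 3L,
                     prot_tab$canonical_id[[pd + 3L]], prot_tab, pd + 3L,
                     "resemble", "nonverb", "DRUG", "PROTEIN")
      add_edge(prot_tab$canonical_id[[pd + 3L]], prot_tab, pd + 3L,
               se_tab$canonical_id[[sd_ + 3L]], se_tab, sd_ + 3L,
               "enhance", "PROTEIN", "SIDE_EFFECT", planted = TRUE)
      # 4: complete chain ending in an intended-effect (cancer) node;
      #    removed by the effect-term screen.
      add_edge(drug_tab$canonical_id[[dd + 4L]], drug_tab, dd + 4L,
               prot_tab$canonical_id[[pd + 4L]], prot_tab, pd + 4L,
               "inhibit", "DRUG", "PROTEIN", planted = TRUE)
      add_edge(prot_tab$canonical_id[[pd + 4L]], prot_tab, pd + 4L,
               "SEC01", se_tab, nrow(se_tab),
               "reduce", "PROTEIN", "SIDE_EFFECT", planted = TRUE)
      # 5: complete chain whose drug-protein edge is neutral-verb only;
      #    removed by the significance screen.
      add_edge(drug_tab$canonical_id[[dd + 5L]], drug_tab, dd + 5L,
               prot_tab$canonical_id[[pd + 5L]], prot_tab, pd + 5L,
               "associate", "DRUG", "PROTEIN", planted = TRUE)
      add_edge(prot_tab$canonical_id[[pd + 5L]], prot_tab, pd + 5L,
               se_tab$canonical_id[[sd_ + 5L]], se_tab, sd_ + 5L,
               "increase", "PROTEIN", "SIDE_EFFECT", planted = TRUE)
    }

    # distribute sentences over documents, append fillers -----------------
    doc_of <- sort(rep_len(seq_len(n_docs), length(sentences)))
    docs <- vector("list", n_docs)
    mentions <- list()
    triples <- list()
    for (d in seq_len(n_docs)) {
      idx <- which(doc_of == d)
      texts <- sentences[idx]
      filler <- .ps_filler_sentences[[(d - 1L) %% length(.ps_filler_sentences) + 1L]]
      texts <- c(texts, filler)
      pmid <- sprintf("9%06d", d)
      # with titles mined, abstract sentence j has index j (title is 0)
      for (j in seq_along(idx)) {
        meta <- sent_meta[[idx[[j]]]]
        sp <- meta$spans
        sp$pmid <- pmid
        sp$sentence_index <- j
        mentions[[length(mentions) + 1L]] <- sp
        if (!is.null(meta$triple)) {
          tr <- meta$triple
          tr$pmid <- pmid
          tr$sentence_index <- j
          triples[[length(triples) + 1L]] <- tr
        }
      }
      docs[[d]] <- ps_document(pmid,
                               sprintf("Study %d of signaling mechanisms.", d),
                               paste(texts, collapse = " "))
    }
    mentions <- do.call(rbind, mentions)
    mentions <- mentions[, c("pmid", "sentence_index", "canonical_id",
                             "entity_type", "surface", "start", "end")]
    triples <- do.call(rbind, triples)
    triples <- triples[, c("pmid", "sentence_index", "source_id",
                           "source_type", "verb", "target_id", "target_type",
                           "planted")]

    # plausibility labels for the planted chains (for P@k demos)
    labels <- data.frame(
      path_no = seq_len(nrow(paths)),
      label = sample(c("TYPE1", "TYPE2", "TYPE3"), nrow(paths),
                     replace = TRUE, prob = c(0.4, 0.3, 0.3)),
      stringsAsFactors = FALSE)

    # concept hierarchy: ROOT -> type -> family -> entity -----------------
    hier_rows <- data.frame(child_id = "ROOT", parent_id = "-",
                            stringsAsFactors = FALSE)
    add_h <- function(child, parent) {
      hier_rows <<- rbind(hier_rows, data.frame(child_id = child,
                                                parent_id = parent,
                                                stringsAsFactors = FALSE))
    }
    for (ty in c("DRUGS", "PROTEINS", "EFFECTS")) add_h(ty, "ROOT")
    fam <- function(prefix, n) paste0(prefix, "_FAM", (seq_len(n) - 1L) %% 3L + 1L)
    for (ty in list(list(tab = drug_tab, top = "DRUGS", pf = "DRG"),
                    list(tab = prot_tab, top = "PROTEINS", pf = "PRT"),
                    list(tab = se_tab, top = "EFFECTS", pf = "SE"))) {
      fams <- fam(ty$pf, nrow(ty$tab))
      for (f in unique(fams)) add_h(f, ty$top)
      for (i in seq_len(nrow(ty$tab))) add_h(ty$tab$canonical_id[[i]], fams[[i]])
    }

    lexicons <- list(
      DRUG = lexicon_from_table(drug_tab, "DRUG"),
      PROTEIN = lexicon_from_table(prot_tab, "PROTEIN"),
      SIDE_EFFECT = lexicon_from_table(se_tab, "SIDE_EFFECT"))
    hierarchy <- hierarchy_from_table(hier_rows)

    files <- NULL
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      files <- list(
        corpus = file.path(outdir, "corpus.xml"),
        drugs = file.path(outdir, "drugs.tsv"),
        proteins = file.path(outdir, "proteins.tsv"),
        sideeffects = file.path(outdir, "sideeffects.tsv"),
        verbs = file.path(outdir, "verbs.tsv"),
        hierarchy = file.path(outdir, "hierarchy.tsv"))
      write_medline_xml(docs, files$corpus)
      write.table(drug_tab, files$drugs, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8")
      write.table(prot_tab, files$proteins, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8")
      write.table(se_tab, files$sideeffects, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8")
      write.table(verbs, files$verbs, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8")
      write.table(hier_rows, files$hierarchy, sep = "\t", quote = FALSE,
                  row.names = FALSE, fileEncoding = "UTF-8")
    }

    list(docs = docs, lexicons = lexicons, bioverbs = bioverbs,
         hierarchy = hierarchy,
         ground_truth = list(mentions = mentions, triples = triples,
                             paths = paths, labels = labels, seed = seed),
         files = files)
  })
}
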