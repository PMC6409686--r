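# Abbreviations whose trailing period must not end a sentence.
.ps_abbrev <- c("e.g.", "i.e.", "et al.", "etc.", "vs.", "cf.", "Fig.", "fig.",
                "Dr.", "No.", "ca.", "approx.")

#' Tokenize a span of text
#'
#' Splits on whitespace, then peels leading/trailing punctuation into separate
#' tokens. Internal hyphens, digits and Greek letters are preserved so that
#' biomedical names such as `p38`, `NF-kB` or `gastrin-17` stay single tokens.
#' Concatenating the returned tokens reproduces the input modulo whitespace.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
ps_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chunks <- strsplit(trimws(text), "\\s+")[[1]]
  chunks <- chunks[nzchar(chunks)]
  if (length(chunks) == 0L) return(character(0))
  out <- vector("list", length(chunks))
  lead_re <- "^[([{\"']"       # NB: ']' must lead a POSIX class, '[' may not
  trail_re <- "[].,;:!?)}\"']$"
  for (i in seq_along(chunks)) {
    ch <- chunks[[i]]
    lead <- character(0)
    trail <- character(0)
    while (nchar(ch) > 1L && grepl(lead_re, ch)) {
      lead <- c(lead, substr(ch, 1L, 1L))
      ch <- substring(ch, 2L)
    }
    while (nchar(ch) > 1L && grepl(trail_re, ch)) {
      n <- nchar(ch)
      trail <- c(substr(ch, n, n), trail)
      ch <- substr(ch, 1L, n - 1L)
    }
    out[[i]] <- c(lead, ch, trail)
  }
  unlist(out, use.names = FALSE)
}

#' Split text into sentences
#'
#' Boundary rule: `.`, `?` or `!` followed by whitespace and an uppercase
#' letter or digit. Trailing periods of common abbreviations (`e.g.`,
#' `et al.`, ...) never split. When no boundary is found the whole text is a
#' single sentence.
#'
#' @param text character scalar.
#' @return character vector of sentence strings.
#' @export
ps_split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) return(character(0))
  guard <- ""
  protected <- text
  for (ab in .ps_abbrev) {
    repl <- gsub(".", guard, ab, fixed = TRUE)
    protected <- gsub(ab, repl, protected, fixed = TRUE)
  }
  parts <- strsplit(protected, "(?<=[.!?])\\s+(?=[A-Z0-9])", perl = TRUE)[[1]]
  parts <- gsub(guard, ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

.ps_sentence <- function(pmid, index, text) {
  structure(list(doc_pmid = pmid, index = index, text = text,
                 tokens = ps_tokenize(text),
                 lemmas = NULL, pos = NULL),
            class = "ps_sentence")
}

#' Construct a document
#'
#' @param pmid non-empty string identifier.
#' @param title title text (may be empty).
#' @param abstract abstract text.
#' @return object of class `ps_document`.
#' @export
ps_document <- function(pmid, title = "", abstract = "") {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid))
  structure(list(pmid = pmid, title = title, abstract = abstract,
                 sentences = NULL),
            class = "ps_document")
}

#' @export
print.ps_document <- function(x, ...) {
  cat(sprintf("<ps_document %s: %s (%d sentence(s))>\n", x$pmid,
              substr(x$title, 1L, 50L),
              if (is.null(x$sentences)) 0L else length(x$sentences)))
  invisible(x)
}

#' Segment a document into tokenized sentences
#'
#' Populates `doc$sentences` with 0-indexed sentences. When
#' `include_title = TRUE` (default) the title is prepended as sentence 0 so
#' titles are also mined for relations; disable to mine abstracts only.
#'
#' @param doc a `ps_document`.
#' @param include_title logical; mine the title as an extra sentence.
#' @return the document with `sentences` populated.
#' @export
segment_sentences <- function(doc, include_title = TRUE) {
  stopifnot(inherits(doc, "ps_document"))
  texts <- ps_split_sentences(doc$abstract)
  if (include_title && nzchar(trimws(doc$title))) {
    texts <- c(trimws(doc$title), texts)
  }
  doc$sentences <- lapply(seq_along(texts), function(i) {
    .ps_sentence(doc$pmid, i - 1L, texts[[i]])
  })
  doc
}

#' Parse MEDLINE/PubMed XML into documents
#'
#' One document per `PubmedArticle` record that has a non-empty abstract;
#' records with no abstract are skipped and counted, records with no PMID are
#' skipped with a warning. Multiple `AbstractText` sections (structured
#' abstracts) are concatenated with a space.
#'
#' @param path path to a MEDLINE XML file (or anything [xml2::read_xml()]
#'   accepts).
#' @return list of `ps_document`; attribute `skipped` holds the number of
#'   abstract-less records.
#' @export
parse_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  out <- list()
  skipped <- 0L
  for (art in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      warning("record without PMID skipped")
      next
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//Article/ArticleTitle"))
    if (is.na(title)) title <- ""
    abst_nodes <- xml2::xml_find_all(art, ".//Article/Abstract/AbstractText")
    abstract <- paste(trimws(xml2::xml_text(abst_nodes)), collapse = " ")
    if (!nzchar(trimws(abstract))) {
      skipped <- skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- ps_document(pmid, title, abstract)
  }
  ids <- vapply(out, `[[`, "", "pmid")
  if (anyDuplicated(ids)) {
    stop("duplicate PMID in corpus: ", ids[duplicated(ids)][1L])
  }
  attr(out, "skipped") <- skipped
  out
}

#' Parse the plain-text corpus dialect
#'
#' One record per line: `PMID<TAB>TITLE<TAB>ABSTRACT`.
#'
#' @param path path to a TSV file.
#' @return list of `ps_document`.
#' @export
parse_corpus_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("corpus TSV line needs 3 tab-separated fields")
    ps_document(f[[1]], f[[2]], f[[3]])
  })
  ids <- vapply(out, `[[`, "", "pmid")
  if (anyDuplicated(ids)) stop("duplicate PMID in corpus")
  out
}

#' Write documents as a MEDLINE-style XML file
#'
#' Inverse of [parse_medline_xml()] for the fields this package uses
#' (PMID, title, abstract).
#'
#' @param docs list of `ps_document`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(docs, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (d in docs) {
    art <- xml2::xml_add_child(root, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", d$pmid)
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", d$title)
    ab <- xml2::xml_add_child(a, "Abstract")
    xml2::xml_add_child(ab, "AbstractText", d$abstract)
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' Dump a corpus to JSON-lines
#'
#' One document per line (pmid/title/abstract and, when present, tokenized
#' sentences) for pipeline checkpointing.
#'
#' @param docs list of `ps_document`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in docs) {
    rec <- list(pmid = d$pmid, title = d$title, abstract = d$abstract)
    if (!is.null(d$sentences)) {
      rec$sentences <- lapply(d$sentences, function(s) {
        list(index = s$index, text = s$text, tokens = as.list(s$tokens),
             lemmas = as.list(s$lemmas), pos = as.list(s$pos))
      })
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read a JSON-lines corpus dump
#'
#' @param path path written by [write_corpus_jsonl()].
#' @return list of `ps_document`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    d <- ps_document(rec$pmid, rec$title, rec$abstract)
    if (!is.null(rec$sentences)) {
      d$sentences <- lapply(rec$sentences, function(s) {
        sen <- .ps_sentence(rec$pmid, s$index, s$text)
        sen$tokens <- as.character(unlist(s$tokens))
        if (length(s$lemmas)) sen$lemmas <- as.character(unlist(s$lemmas))
        if (length(s$pos)) sen$pos <- as.character(unlist(s$pos))
        sen
      })
    }
    d
  })
}
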