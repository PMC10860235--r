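#' Term-incidence corpora
#'
#' A `term_incidence` object maps document ids (PMID-like strings) to sets
#' of item strings — MeSH terms (optionally qualified by a subheading, as in
#' `"Insulin/metabolism"` before extraction) and gene symbols. Item matching
#' throughout the package is case-insensitive exact string matching; the
#' first-seen spelling of each item is kept for display.
#'
#' @param docs named list: document id -> character vector of items.
#' @return an object of class `term_incidence`.
#' @export
term_incidence <- function(docs) {
  if (is.null(names(docs)) || anyDuplicated(names(docs)))
    stop("term_incidence: document ids must be unique and named",
         call. = FALSE)
  docs <- lapply(docs, function(x) unique(as.character(x)))
  structure(docs, class = "term_incidence")
}

#' @export
print.term_incidence <- function(x, ...) {
  cat("term_incidence corpus:", length(x), "documents,",
      length(unique(tolower(unlist(x)))), "distinct items\n")
  invisible(x)
}

# inverted index: lowercased item -> integer vector of document indices
ti_index <- function(inc) {
  items <- tolower(unlist(inc, use.names = FALSE))
  doc <- rep.int(seq_along(inc), lengths(inc))
  split(doc, items)
}

# documents (indices) containing an item, case-insensitively
ti_docs_with <- function(inc, item, index = NULL) {
  if (is.null(index)) index <- ti_index(inc)
  idx <- index[[tolower(item)]]
  if (is.null(idx)) integer(0) else idx
}

#' Count documents containing two items simultaneously
#'
#' The co-occurrence count of items `a` and `b` is the number of documents
#' whose item set contains both (case-insensitive exact match) — the local
#' analogue of the number of hits a joint "Term A and Term B" query returns.
#' `a == b` degenerates to the document frequency of the item.
#'
#' @param inc a [term_incidence] corpus.
#' @param a,b item strings.
#' @return integer count.
#' @export
cooccurrence_count <- function(inc, a, b) {
  length(intersect(ti_docs_with(inc, a), ti_docs_with(inc, b)))
}

#' Co-occurrence table of many items against one fixed query
#'
#' @param inc a [term_incidence] corpus.
#' @param items character vector of items to count.
#' @param query the fixed query string (e.g. `"PCOS"`).
#' @return named integer vector: item -> number of documents containing
#'   both the item and the query.
#' @export
cooccurrence_table <- function(inc, items, query) {
  index <- ti_index(inc)
  q_docs <- ti_docs_with(inc, query, index)
  counts <- vapply(items, function(it)
    length(intersect(ti_docs_with(inc, it, index), q_docs)), integer(1))
  names(counts) <- items
  counts
}

#' Read / write corpus TSV
#'
#' The on-disk format is two tab-separated columns: document id, then the
#' document's items joined by `";"`. Documents with no items are written
#' with an empty second field.
#'
#' @param inc a [term_incidence] corpus.
#' @param path file path.
#' @return `write_corpus_tsv` returns `path` invisibly; `read_corpus_tsv`
#'   returns a [term_incidence].
#' @export
write_corpus_tsv <- function(inc, path) {
  lines <- vapply(seq_along(inc), function(i)
    paste(names(inc)[i], paste(inc[[i]], collapse = ";"), sep = "\t"),
    character(1))
  writeLines(c("doc_id\titems", lines), path)
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @export
read_corpus_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  docs <- lapply(tab$items, function(s)
    if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else character(0))
  names(docs) <- tab$doc_id
  term_incidence(docs)
}
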