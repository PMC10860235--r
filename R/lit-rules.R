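#' Extract items from raw abstract records
#'
#' Each record is a list with fields `id`, `mesh` (character vector of
#' `"Term/subheading"` strings; a bare term has no subheading) and `text`.
#' Items kept per document: MeSH terms whose subheading is in the allowlist
#' (the term is stored without its subheading), plus any of the supplied
#' gene symbols occurring in the text as a whole word (case-insensitive).
#' Records without an id are skipped with a warning.
#'
#' @param records list of raw records.
#' @param subheadings subheading allowlist.
#' @param gene_symbols gene symbols to scan the text for.
#' @return a [term_incidence] corpus.
#' @export
extract_items <- function(records,
                          subheadings = c("metabolism", "chemical",
                                          "genetics", "drug effects",
                                          "immunology"),
                          gene_symbols = character(0)) {
  subheadings <- tolower(subheadings)
  docs <- list()
  for (rec in records) {
    if (is.null(rec$id) || !nzchar(rec$id)) {
      warning("extract_items: record without id skipped", call. = FALSE)
      next
    }
    items <- character(0)
    for (m in rec$mesh %||% character(0)) {
      parts <- strsplit(m, "/", fixed = TRUE)[[1]]
      if (length(parts) >= 2L && tolower(parts[2L]) %in% subheadings)
        items <- c(items, parts[1L])
    }
    if (length(gene_symbols) && !is.null(rec$text)) {
      found <- vapply(gene_symbols, function(g)
        grepl(paste0("\\b", g, "\\b"), rec$text, ignore.case = TRUE),
        logical(1))
      items <- c(items, gene_symbols[found])
    }
    docs[[rec$id]] <- unique(items)
  }
  term_incidence(docs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a corpus into subtype sub-corpora
#'
#' A document joins the HA corpus iff it contains at least one HA item
#' (marker or differentiated gene), and the NA corpus analogously; a
#' document can join both; documents containing neither are dropped.
#'
#' @param inc a [term_incidence] corpus.
#' @param ha_genes,na_genes item (gene) lists for the two subtypes.
#' @return list with `ha` and `na` sub-corpora.
#' @export
partition_corpus <- function(inc, ha_genes, na_genes) {
  low <- lapply(inc, tolower)
  ha_low <- tolower(ha_genes); na_low <- tolower(na_genes)
  in_ha <- vapply(low, function(d) any(d %in% ha_low), logical(1))
  in_na <- vapply(low, function(d) any(d %in% na_low), logical(1))
  list(ha = term_incidence(unclass(inc)[in_ha]),
       na = term_incidence(unclass(inc)[in_na]))
}

#' Two-element literature association rules
#'
#' For every ordered pair (A, B) of candidate items:
#' confidence(A -> B) = |docs(A) n docs(B)| / |docs(A)| (0 when A occurs
#' nowhere); support = |docs(A)| + |docs(B)|, by default normalized by the
#' corpus size so the conventional 0.001 cut applies (set
#' `normalize_support = FALSE` for the raw additive count). Both directions
#' are computed; rules strictly above both cuts are reserved.
#'
#' @param inc a [term_incidence] corpus.
#' @param items candidate item strings (default: every item in the corpus).
#' @param conf_cut,supp_cut strict lower thresholds.
#' @param normalize_support divide the additive support by the number of
#'   documents.
#' @return data.frame with columns `lhs`, `rhs`, `confidence`, `support`.
#' @export
lit_rules_2 <- function(inc, items = NULL, conf_cut = 0.1,
                        supp_cut = 0.001, normalize_support = TRUE) {
  if (!length(inc)) stop("lit_rules_2: empty corpus", call. = FALSE)
  index <- ti_index(inc)
  if (is.null(items)) items <- names(index)
  display <- items
  names(display) <- tolower(items)
  display <- display[!duplicated(names(display))]
  keys <- names(display)
  n_docs <- vapply(keys, function(k) length(index[[k]] %||% integer(0)),
                   integer(1))
  pairs <- expand.grid(i = seq_along(keys), j = seq_along(keys))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  conf <- numeric(nrow(pairs)); supp <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    inter <- length(intersect(index[[keys[i]]] %||% integer(0),
                              index[[keys[j]]] %||% integer(0)))
    conf[r] <- if (n_docs[i] == 0L) 0 else inter / n_docs[i]
    supp[r] <- n_docs[i] + n_docs[j]
  }
  if (normalize_support) supp <- supp / length(inc)
  out <- data.frame(lhs = display[keys[pairs$i]],
                    rhs = display[keys[pairs$j]],
                    confidence = conf, support = supp,
                    stringsAsFactors = FALSE)
  out <- out[out$confidence > conf_cut & out$support > supp_cut, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain two-element rules into three-element rules
#'
#' Rules A -> B and B -> C (A, B, C pairwise distinct) chain into
#' A -> B -> C with confidence conf(A -> B) * conf(B -> C); chains with
#' confidence below `conf_cut` are removed (kept at exactly the cut).
#'
#' @param rules2 output of [lit_rules_2()].
#' @param conf_cut minimum chained confidence.
#' @return data.frame with columns `e1`, `e2`, `e3`, `confidence`,
#'   `conf12`, `conf23`.
#' @export
extend_rules_3 <- function(rules2, conf_cut = 0.1) {
  empty <- data.frame(e1 = character(0), e2 = character(0),
                      e3 = character(0), confidence = numeric(0),
                      conf12 = numeric(0), conf23 = numeric(0))
  if (!nrow(rules2)) return(empty)
  left <- data.frame(e1 = rules2$lhs, e2 = rules2$rhs,
                     conf12 = rules2$confidence, stringsAsFactors = FALSE)
  right <- data.frame(e2 = rules2$lhs, e3 = rules2$rhs,
                      conf23 = rules2$confidence, stringsAsFactors = FALSE)
  m <- merge(left, right, by = "e2")
  m <- m[m$e1 != m$e3, , drop = FALSE]
  if (!nrow(m)) return(empty)
  out <- data.frame(e1 = m$e1, e2 = m$e2, e3 = m$e3,
                    confidence = m$conf12 * m$conf23,
                    conf12 = m$conf12, conf23 = m$conf23,
                    stringsAsFactors = FALSE)
  out <- out[out$confidence >= conf_cut, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep chains ending at the terminal phenotype
#'
#' Only chains whose third element equals `terminal` (case-insensitive)
#' survive; the terminal elsewhere in the chain does not qualify.
#'
#' @param rules3 output of [extend_rules_3()].
#' @param terminal terminal item string.
#' @return filtered data.frame.
#' @export
terminal_filter <- function(rules3, terminal = "female infertility") {
  out <- rules3[tolower(rules3$e3) == tolower(terminal), , drop = FALSE]
  rownames(out) <- NULL
  out
}
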