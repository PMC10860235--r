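#' Drugs interacting with a marker set
#'
#' @param markers gene-id set.
#' @param drug_table data.frame with columns `drug`, `gene` (and optionally
#'   `score`); (drug, gene) pairs unique.
#' @return character vector of drugs with at least `min_edges` rows hitting
#'   a marker gene (drug names matched case-insensitively, first spelling
#'   kept).
#' @param min_edges minimum number of marker genes a drug must touch.
#' @export
drugs_for <- function(markers, drug_table, min_edges = 1L) {
  hit <- drug_table[drug_table$gene %in% markers, , drop = FALSE]
  counts <- table(tolower(hit$drug))
  keys <- names(counts)[counts >= min_edges]
  display <- hit$drug[!duplicated(tolower(hit$drug))]
  display[tolower(display) %in% keys]
}

#' Subtype-exclusive drugs
#'
#' Drugs appearing in both subtype lists are removed from each; what
#' remains is exclusive to one subtype.
#'
#' @param ha_drugs,na_drugs drug name vectors.
#' @return list with `ha_only`, `na_only` (case-insensitive set
#'   difference, original spellings kept).
#' @export
exclusive_drugs <- function(ha_drugs, na_drugs) {
  shared <- intersect(tolower(ha_drugs), tolower(na_drugs))
  list(ha_only = ha_drugs[!tolower(ha_drugs) %in% shared],
       na_only = na_drugs[!tolower(na_drugs) %in% shared])
}

#' Bipartite drug-marker interaction network
#'
#' Edges run drug -> gene, restricted to the exclusive drugs and the marker
#' set, weighted by the interaction score (maximum over duplicate evidence
#' rows). The result is a [knowledge_graph] so the usual exporters apply.
#'
#' @param exclusive exclusive drug names.
#' @param markers marker gene ids.
#' @param drug_table drug-gene table with a `score` column.
#' @param terminal terminal label for the graph container (drug networks
#'   have no causal terminal; kept for format compatibility).
#' @return a [knowledge_graph] with drug and gene nodes only.
#' @export
drug_network <- function(exclusive, markers, drug_table,
                         terminal = "female infertility") {
  rows <- drug_table[tolower(drug_table$drug) %in% tolower(exclusive) &
                       drug_table$gene %in% markers, , drop = FALSE]
  score <- if ("score" %in% names(rows)) rows$score else rep(1, nrow(rows))
  edges <- data.frame(source = rows$drug, target = rows$gene,
                      confidence = score, provenance = "drug",
                      stringsAsFactors = FALSE)
  knowledge_graph(edges, terminal, gene_nodes = markers)
}

#' Read/write drug-gene TSV
#' @param path file path.
#' @export
read_drug_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "numeric"))
  names(tab) <- c("drug", "gene", "score")
  tab
}

#' @param drug_table drug-gene table.
#' @rdname read_drug_tsv
#' @export
write_drug_tsv <- function(drug_table, path) {
  utils::write.table(drug_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
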