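#' Causal knowledge graphs
#'
#' A `knowledge_graph` is a directed graph over item strings (genes and
#' MeSH-like terms) with a designated terminal phenotype node. Edges carry a
#' confidence weight and a provenance set (`literature`, `transcriptome`).
#' Node identity is case-insensitive; the first-seen spelling is displayed.
#'
#' @param edges data.frame with columns `source`, `target`, `confidence`,
#'   `provenance` (";"-joined when merged).
#' @param terminal terminal node string.
#' @param gene_nodes item strings to type as genes.
#' @return object of class `knowledge_graph` with `edges`, `nodes`
#'   (data.frame `name`, `type`) and `terminal`.
#' @export
knowledge_graph <- function(edges, terminal, gene_nodes = character(0)) {
  stopifnot(all(c("source", "target", "confidence", "provenance") %in%
                  names(edges)))
  edges <- dedupe_edges(edges)
  nodes <- unique(c(edges$source, edges$target, terminal))
  key <- tolower(nodes)
  nodes <- nodes[!duplicated(key)]
  type <- ifelse(tolower(nodes) == tolower(terminal), "terminal",
                 ifelse(tolower(nodes) %in% tolower(gene_nodes),
                        "gene", "term"))
  structure(list(edges = edges,
                 nodes = data.frame(name = nodes, type = type,
                                    stringsAsFactors = FALSE),
                 terminal = terminal),
            class = "knowledge_graph")
}

# collapse duplicate (source, target) pairs: max confidence, provenance union
dedupe_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  key <- paste(tolower(edges$source), tolower(edges$target), sep = "\r")
  split_idx <- split(seq_len(nrow(edges)), key)
  rows <- lapply(split_idx, function(idx) {
    e <- edges[idx, , drop = FALSE]
    prov <- sort(unique(unlist(strsplit(e$provenance, ";", fixed = TRUE))))
    data.frame(source = e$source[1L], target = e$target[1L],
               confidence = max(e$confidence),
               provenance = paste(prov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge_graph:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges; terminal:", x$terminal, "\n")
  invisible(x)
}

#' Assemble a knowledge graph from literature chains and WLAR rules
#'
#' Every terminal-filtered 3-element chain contributes its two constituent
#' edges (e1 -> e2 with the first confidence, e2 -> e3 with the second).
#' WLAR transcriptome rules are then added only where both endpoints are
#' already gene nodes of the graph. Duplicate edges keep the maximal
#' confidence and the union of provenances; edges leaving the terminal are
#' dropped so the terminal has out-degree 0.
#'
#' @param chains3 data.frame from [terminal_filter()] (`e1`, `e2`, `e3`,
#'   `conf12`, `conf23`).
#' @param wlar_rules data.frame from [compute_wlar()] (may be empty or
#'   `NULL`).
#' @param terminal terminal node string.
#' @param gene_nodes item strings to type as genes.
#' @return a [knowledge_graph].
#' @export
assemble_graph <- function(chains3, wlar_rules = NULL,
                           terminal = "female infertility",
                           gene_nodes = character(0)) {
  lit <- if (nrow(chains3)) {
    data.frame(source = c(chains3$e1, chains3$e2),
               target = c(chains3$e2, chains3$e3),
               confidence = c(chains3$conf12, chains3$conf23),
               provenance = "literature", stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(0), target = character(0),
               confidence = numeric(0), provenance = character(0))
  }
  present <- tolower(unique(c(lit$source, lit$target)))
  gene_present <- intersect(tolower(gene_nodes), present)
  if (!is.null(wlar_rules) && nrow(wlar_rules)) {
    keep <- tolower(wlar_rules$lhs) %in% gene_present &
      tolower(wlar_rules$rhs) %in% gene_present
    if (any(keep)) {
      tr <- data.frame(source = wlar_rules$lhs[keep],
                       target = wlar_rules$rhs[keep],
                       confidence = wlar_rules$conf_sum[keep],
                       provenance = "transcriptome",
                       stringsAsFactors = FALSE)
      lit <- rbind(lit, tr)
    }
  }
  lit <- lit[tolower(lit$source) != tolower(terminal), , drop = FALSE]
  knowledge_graph(lit, terminal, gene_nodes)
}

node_degrees <- function(g) {
  names <- g$nodes$name
  deg <- table(factor(tolower(c(g$edges$source, g$edges$target)),
                      levels = tolower(names)))
  stats::setNames(as.integer(deg), names)
}

#' Iteratively remove weakly connected nodes
#'
#' Non-terminal nodes with total (in + out) degree below `min_degree` are
#' peeled off, repeatedly, until no such node remains (one pass can strand
#' fresh leaves). The terminal node is always retained.
#'
#' @param g a [knowledge_graph].
#' @param min_degree minimum total degree to survive.
#' @return pruned [knowledge_graph].
#' @export
prune_low_degree <- function(g, min_degree = 2L) {
  repeat {
    deg <- node_degrees(g)
    drop <- names(deg)[deg < min_degree &
                         tolower(names(deg)) != tolower(g$terminal)]
    if (!length(drop)) break
    keep_edge <- !(tolower(g$edges$source) %in% tolower(drop) |
                     tolower(g$edges$target) %in% tolower(drop))
    g$edges <- g$edges[keep_edge, , drop = FALSE]
    g$nodes <- g$nodes[!tolower(g$nodes$name) %in% tolower(drop), ,
                       drop = FALSE]
  }
  g
}

#' Remove terms shared by the two subtype graphs
#'
#' Nodes (other than the keep set, by default the terminal) present in both
#' graphs are removed from each and collected, with their incident edges
#' from either graph, into a third "mutual" graph.
#'
#' @param g_ha,g_na subtype [knowledge_graph]s with the same terminal.
#' @param keep node names never removed (default: the terminal).
#' @return list with `ha`, `na`, `mutual` knowledge graphs.
#' @export
remove_mutual_terms <- function(g_ha, g_na, keep = g_ha$terminal) {
  stopifnot(tolower(g_ha$terminal) == tolower(g_na$terminal))
  mutual <- intersect(tolower(g_ha$nodes$name), tolower(g_na$nodes$name))
  mutual <- setdiff(mutual, tolower(keep))
  strip <- function(g) {
    g$edges <- g$edges[!(tolower(g$edges$source) %in% mutual |
                           tolower(g$edges$target) %in% mutual), ,
                       drop = FALSE]
    g$nodes <- g$nodes[!tolower(g$nodes$name) %in% mutual, , drop = FALSE]
    g
  }
  incident <- function(g) {
    g$edges[tolower(g$edges$source) %in% mutual |
              tolower(g$edges$target) %in% mutual, , drop = FALSE]
  }
  mutual_edges <- rbind(incident(g_ha), incident(g_na))
  genes <- c(g_ha$nodes$name[g_ha$nodes$type == "gene"],
             g_na$nodes$name[g_na$nodes$type == "gene"])
  list(ha = strip(g_ha), na = strip(g_na),
       mutual = knowledge_graph(mutual_edges, g_ha$terminal, genes))
}

#' Paths from a node to the terminal
#'
#' @param g a [knowledge_graph].
#' @param from source node name.
#' @return `TRUE` iff a directed path from `from` to the terminal exists.
#' @export
reaches_terminal <- function(g, from) {
  if (!tolower(from) %in% tolower(g$nodes$name)) return(FALSE)
  frontier <- tolower(from)
  seen <- character(0)
  src <- tolower(g$edges$source); tgt <- tolower(g$edges$target)
  while (length(frontier)) {
    if (tolower(g$terminal) %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(tgt[src %in% frontier]), seen)
  }
  FALSE
}

#' Export a knowledge graph
#'
#' Formats: `sif` (lines `source<TAB>causes<TAB>target`), `graphml`
#' (Cytoscape-loadable, with `confidence` and `provenance` edge attributes
#' and a `type` node attribute), or `tsv` (edge list with attributes).
#'
#' @param g a [knowledge_graph].
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(g$edges$source, "causes", g$edges$target, sep = "\t"),
               path)
  } else if (format == "tsv") {
    utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(
      g$edges, directed = TRUE,
      vertices = data.frame(name = g$nodes$name, type = g$nodes$type,
                            stringsAsFactors = FALSE))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @param terminal terminal node for the re-imported graph.
#' @rdname export_graph
#' @export
import_graphml <- function(path, terminal) {
  ig <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(ig, what = "edges")
  vt <- igraph::as_data_frame(ig, what = "vertices")
  names(ed)[1:2] <- c("source", "target")
  genes <- vt$name[vt$type == "gene"]
  knowledge_graph(ed[, c("source", "target", "confidence", "provenance")],
                  terminal, genes)
}
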