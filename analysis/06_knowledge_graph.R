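#!/usr/bin/env Rscript
# Literature rules and causal knowledge graphs. The corpus is partitioned
# into NA-PCOS and HA-PCOS sub-corpora by gene mentions; 2-element rules
# (confidence > 0.1, support > 0.001, both directions) are chained into
# 3-element rules (product confidence >= 0.1) and filtered to those ending
# at "female infertility"; surviving chains are split back into edges,
# WLAR rules between genes already present are merged in, weakly connected
# nodes are pruned, and terms shared by the two subtype graphs are moved
# to a mutual graph. Exports SIF + GraphML for Cytoscape.

suppressMessages(library(pcoskg))

inc <- read_corpus_tsv("results/inputs/corpus.tsv")
spec_na <- readLines("results/specific_na.txt")
spec_ha <- readLines("results/specific_ha.txt")
wlar <- read.delim("results/wlar_rules.tsv")
terminal <- "female infertility"

parts <- partition_corpus(inc, ha_genes = spec_ha, na_genes = spec_na)
cat("Corpus partition: HA", length(parts$ha), "docs | NA",
    length(parts$na), "docs (of", length(inc), ")\n")

graph_for <- function(sub_inc, genes) {
  items <- unique(c(genes, "PCOS", terminal,
                    c("response to cytokine", "ovulation",
                      "insulin resistance", "hyperandrogenism")))
  r2 <- lit_rules_2(sub_inc, items = items)
  r3 <- terminal_filter(extend_rules_3(r2), terminal)
  cat("  rules: ", nrow(r2), "pairs ->", nrow(r3), "terminal chains\n")
  prune_low_degree(assemble_graph(r3, wlar, terminal,
                                  gene_nodes = union(spec_na, spec_ha)), 2)
}
cat("HA graph:\n"); g_ha <- graph_for(parts$ha, spec_ha)
cat("NA graph:\n"); g_na <- graph_for(parts$na, spec_na)
split <- remove_mutual_terms(g_ha, g_na)

for (side in c("ha", "na", "mutual")) {
  g <- split[[side]]
  cat(sprintf("%-6s graph: %d nodes, %d edges\n", side, nrow(g$nodes),
              nrow(g$edges)))
  export_graph(g, sprintf("results/graph_%s.sif", side), "sif")
  export_graph(g, sprintf("results/graph_%s.graphml", side), "graphml")
  export_graph(g, sprintf("results/graph_%s_edges.tsv", side), "tsv")
}
cat("Wrote SIF / GraphML / edge TSVs under results/\n")
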