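#!/usr/bin/env Rscript
# Subtype-exclusive drug screen: drugs interacting with at least one
# functional or classification marker of a subtype are candidate drugs for
# that subtype; drugs hitting both subtypes are removed from both lists.
# The surviving drug-marker interactions are exported as bipartite SIF
# networks weighted by interaction score.

suppressMessages(library(pcoskg))

tab <- read_drug_tsv("results/inputs/drug_table.tsv")
markers_na <- readLines("results/markers_na.txt")
markers_ha <- readLines("results/markers_ha.txt")
cls <- read.delim("results/classification_markers.tsv",
                  colClasses = "character")
cls_na <- strsplit(cls$genes[cls$group == "NA"], ";")[[1]]
cls_ha <- strsplit(cls$genes[cls$group == "HA"], ";")[[1]]

set_na <- union(markers_na, cls_na)
set_ha <- union(markers_ha, cls_ha)
excl <- exclusive_drugs(drugs_for(set_ha, tab), drugs_for(set_na, tab))
cat("HA-exclusive drugs:", length(excl$ha_only), "|",
    paste(excl$ha_only, collapse = ", "), "\n")
cat("NA-exclusive drugs:", length(excl$na_only), "|",
    paste(excl$na_only, collapse = ", "), "\n")

writeLines(excl$ha_only, "results/drugs_ha_exclusive.txt")
writeLines(excl$na_only, "results/drugs_na_exclusive.txt")
export_graph(drug_network(excl$ha_only, set_ha, tab),
             "results/drug_network_ha.sif", "sif")
export_graph(drug_network(excl$na_only, set_na, tab),
             "results/drug_network_na.sif", "sif")
cat("Wrote exclusive drug lists and bipartite SIF networks.\n")
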