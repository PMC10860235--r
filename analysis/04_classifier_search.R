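#!/usr/bin/env Rscript
# Random search for rank-based classification marker sets: genes are pooled
# by the group where they are highest, random 10-50-gene sets per group are
# drawn, and a triple is reserved iff it classifies all 12 training samples
# into their true fine groups by highest mean within-sample rank. Reserved
# triples are then ranked by matching rate on an independently simulated,
# coarsely labelled (NM vs PCOS) validation cohort.

suppressMessages(library(pcoskg))

x <- read_expression_tsv("results/inputs/expression.tsv")
labels <- read_labels_tsv("results/inputs/labels.tsv")

n_iter <- 10000L
search <- search_marker_sets(x, labels, n_iter = n_iter, seed = 1)
cat("Reserved", length(search$reserved), "of", n_iter,
    "triples on training data.\n")

val_cfg <- sim_config(seed = 104730)  # independent validation cohort
val <- generate_expression(val_cfg)
val$labels$group[val$labels$group != "NM"] <- "PCOS"
best <- select_best(search, list(list(matrix = val$matrix,
                                      labels = val$labels)))
cat("Best triple validation matching rate:", max(best$rates),
    "| sizes:", paste(lengths(best$best), collapse = "/"), "\n")

reserved_tab <- do.call(rbind, lapply(seq_along(search$reserved),
                                      function(i) {
  tr <- search$reserved[[i]]
  data.frame(triple = i, rate = best$rates[i],
             nm = paste(tr$NM, collapse = ";"),
             na = paste(tr$`NA`, collapse = ";"),
             ha = paste(tr$HA, collapse = ";"))
}))
write.table(reserved_tab, "results/reserved_triples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
best_tab <- data.frame(group = c("NM", "NA", "HA"),
                       genes = c(paste(best$best$NM, collapse = ";"),
                                 paste(best$best$`NA`, collapse = ";"),
                                 paste(best$best$HA, collapse = ";")))
write.table(best_tab, "results/classification_markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Wrote results/reserved_triples.tsv and classification_markers.tsv\n")
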