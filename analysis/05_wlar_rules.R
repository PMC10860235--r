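#!/usr/bin/env Rscript
# Association rules on the merged, quantile-normalized transcriptome using
# the dual quantile discretization (2-bin and 4-bin): per ordered gene
# pair, confidence and support are computed under each discretization and
# summed; rules with summed confidence > 0.6 and summed support > 30 are
# reserved. Candidates are the specific genes plus functional markers.

suppressMessages(library(pcoskg))

x <- read_expression_tsv("results/inputs/expression.tsv")
labels <- read_labels_tsv("results/inputs/labels.tsv")
spec <- union(readLines("results/specific_na.txt"),
              readLines("results/specific_ha.txt"))
markers <- union(readLines("results/markers_na.txt"),
                 readLines("results/markers_ha.txt"))

val <- generate_expression(sim_config(seed = 104730))
val$labels$group[val$labels$group != "NM"] <- "PCOS"
merged <- merge_and_normalize(list(x, val$matrix),
                              list(labels, val$labels),
                              prefixes = c("train", "valid"))
cat("Merged matrix:", nrow(merged$matrix), "genes x",
    ncol(merged$matrix), "samples (quantile-normalized)\n")

genes <- intersect(union(spec, markers), rownames(merged$matrix))
rules <- compute_wlar(drop_sparse_samples(merged$matrix), genes)
cat("Reserved", nrow(rules), "rules over", length(genes),
    "candidate genes (", length(genes) * (length(genes) - 1),
    "ordered pairs )\n")

write.table(rules, "results/wlar_rules.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/wlar_rules.tsv\n")
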