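#!/usr/bin/env Rscript
# Functional-marker cascades over the specific genes. The NA cascade
# filters by immunity-term membership under four annotation windows,
# term-appearance frequency (> 5 all-terms, > 2 top-20), PPI connectivity,
# PCOS co-occurrence, and finally the most PCOS-co-occurring term; the HA
# cascade uses glucose BP terms (frequency > 1) and PCOS co-occurrence.

suppressMessages(library(pcoskg))

spec_na <- readLines("results/specific_na.txt")
spec_ha <- readLines("results/specific_ha.txt")
ann <- read_annotation_tsv("results/inputs/annotations.tsv")
ppi <- read.delim("results/inputs/ppi.tsv", colClasses = "character")
inc <- read_corpus_tsv("results/inputs/corpus.tsv")

gene_co <- cooccurrence_table(inc, union(spec_na, spec_ha), "PCOS")
term_co <- cooccurrence_table(inc, unique(ann$term_name), "PCOS")

na_out <- suppressWarnings(
  na_cascade(spec_na, ann, ppi, gene_co, term_co))
ha_out <- suppressWarnings(ha_cascade(spec_ha, ann, gene_co))

cat("NA functional markers:", paste(na_out$markers, collapse = ", "),
    "(term", na_out$chosen_term, ")\n")
cat("HA functional markers:", paste(ha_out$markers, collapse = ", "), "\n")

audit <- rbind(
  data.frame(cascade = "NA", stage = names(na_out$stages),
             genes = vapply(na_out$stages, paste, character(1),
                            collapse = ";")),
  data.frame(cascade = "HA", stage = names(ha_out$stages),
             genes = vapply(ha_out$stages, paste, character(1),
                            collapse = ";")))
write.table(audit, "results/cascade_audit.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(na_out$markers, "results/markers_na.txt")
writeLines(ha_out$markers, "results/markers_ha.txt")
cat("Wrote results/cascade_audit.tsv and marker lists.\n")
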