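#!/usr/bin/env Rscript
# Simulate every pipeline input: a 3-group granulosa-cell-like expression
# matrix (NM / NA PCOS / HA PCOS, 4 samples each) with planted
# subtype-specific genes, a literature corpus with planted co-occurrence
# chains ending at "female infertility", an annotation table, a PPI edge
# list and a drug-gene table. Writes TSVs under results/inputs/.

suppressMessages(library(pcoskg))

out_dir <- "results/inputs"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)  # defaults: 2000 genes, 4/group, fold 4
sim <- simulate_all(cfg)

write_expression_tsv(sim$expression, file.path(out_dir, "expression.tsv"))
write_labels_tsv(sim$labels, file.path(out_dir, "labels.tsv"))
write_corpus_tsv(sim$incidence, file.path(out_dir, "corpus.tsv"))
write_annotation_tsv(sim$annotations, file.path(out_dir, "annotations.tsv"))
write.table(sim$ppi, file.path(out_dir, "ppi.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_drug_tsv(sim$drug_table, file.path(out_dir, "drug_table.tsv"))

cat("Simulated", nrow(sim$expression), "genes x",
    ncol(sim$expression), "samples;",
    length(sim$incidence), "documents;",
    nrow(sim$annotations), "annotation terms;",
    nrow(sim$ppi), "PPI edges;",
    length(unique(sim$drug_table$drug)), "drugs.\n")
cat("Planted truth:", length(sim$truth$specific_na), "NA-specific and",
    length(sim$truth$specific_ha), "HA-specific genes;",
    "cascade markers", paste(sim$truth$cascade_na, collapse = ","), "/",
    paste(sim$truth$cascade_ha, collapse = ","), "\n")
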