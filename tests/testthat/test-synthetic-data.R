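test_that("expression generator honours the dimensional contract", {
  cfg <- sim_config(n_genes = 200, n_per_group = 4, n_specific_na = 10,
                    n_specific_ha = 10, fold = 4, seed = 1)
  out <- generate_expression(cfg)
  expect_equal(dim(out$matrix), c(200L, 12L))
  expect_true(all(out$matrix >= 0))
  expect_length(out$truth$specific_na, 10)
  expect_length(out$truth$specific_ha, 10)
  expect_length(intersect(out$truth$specific_na, out$truth$specific_ha), 0)
  counts <- table(out$labels$group)
  expect_setequal(names(counts), c("NM", "NA", "HA"))
  expect_true(all(counts == 4L))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 100, n_docs = 500, seed = 42)
  expect_identical(generate_expression(cfg), generate_expression(cfg))
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  expect_identical(generate_annotations(cfg), generate_annotations(cfg))
  expect_identical(generate_ppi(cfg), generate_ppi(cfg))
  expect_identical(generate_drug_table(cfg), generate_drug_table(cfg))
})

test_that("fold = 1 gives unit group-mean ratio within sampling error", {
  cfg <- sim_config(n_genes = 1000, n_specific_na = 500, n_specific_ha = 0,
                    fold = 1, noise_sd = 0.2, seed = 9)
  out <- generate_expression(cfg)
  na_cols <- out$labels$sample_id[out$labels$group == "NA"]
  nm_cols <- out$labels$sample_id[out$labels$group == "NM"]
  planted <- out$truth$specific_na
  ratio <- rowMeans(out$matrix[planted, na_cols]) /
    rowMeans(out$matrix[planted, nm_cols])
  expect_equal(mean(ratio), 1, tolerance = 0.02)
})

test_that("planted fold change is recovered as noise shrinks", {
  for (sd in c(0.1, 0.01)) {
    cfg <- sim_config(n_genes = 500, n_specific_na = 100, fold = 4,
                      noise_sd = sd, seed = 11)
    out <- generate_expression(cfg)
    na_cols <- out$labels$sample_id[out$labels$group == "NA"]
    nm_cols <- out$labels$sample_id[out$labels$group == "NM"]
    ratio <- rowMeans(out$matrix[out$truth$specific_na, na_cols]) /
      rowMeans(out$matrix[out$truth$specific_na, nm_cols])
    expect_equal(mean(ratio), 4, tolerance = 5 * sd)
  }
})

test_that("corpus conditional co-occurrence matches the planted probability", {
  chains <- data.frame(from = "GENEX", mid = "Ovulation",
                       terminal = "female infertility",
                       p_ab = 0.5, p_bt = 0.4, stringsAsFactors = FALSE)
  cfg <- sim_config(n_docs = 10000, planted_chains = chains, seed = 21)
  inc <- generate_corpus(cfg)$incidence
  n_a <- cooccurrence_count(inc, "GENEX", "GENEX")
  n_ab <- cooccurrence_count(inc, "GENEX", "Ovulation")
  expect_gt(n_a, 1000)
  expect_lt(abs(n_ab / n_a - 0.5), 0.03)
  n_b <- cooccurrence_count(inc, "Ovulation", "Ovulation")
  n_bt <- cooccurrence_count(inc, "Ovulation", "female infertility")
  expect_lt(abs(n_bt / n_b - 0.4), 3 * sqrt(0.4 * 0.6 / n_b))
})

test_that("degenerate chain probabilities are exact", {
  for (p in c(0, 1)) {
    chains <- data.frame(from = "GENEX", mid = "MIDTERM",
                         terminal = "female infertility",
                         p_ab = p, p_bt = 0.5, stringsAsFactors = FALSE)
    cfg <- sim_config(n_docs = 2000, planted_chains = chains, seed = 5)
    inc <- generate_corpus(cfg)$incidence
    n_a <- cooccurrence_count(inc, "GENEX", "GENEX")
    n_ab <- cooccurrence_count(inc, "GENEX", "MIDTERM")
    expect_gt(n_a, 0)
    if (p == 1) expect_equal(n_ab, n_a) else expect_equal(n_ab, 0L)
  }
})

test_that("annotation generator plants marker memberships as designed", {
  cfg <- sim_config(n_genes = 300, seed = 13)
  ann <- generate_annotations(cfg)$annotations
  na_mk <- sprintf("G%04d", 1:2)  # first planted NA-specific genes
  imm_bp <- ann[ann$category == "immunity" & ann$source == "BP", ]
  glu <- ann[ann$category == "glucose", ]
  freq_na <- term_frequency(na_mk, imm_bp)
  expect_true(all(freq_na >= 6))
  ha_mk <- sprintf("G%04d", 11:12)
  freq_ha <- term_frequency(ha_mk, glu)
  expect_true(all(freq_ha >= 2))
  # non-planted genes land on at most one flagged term
  flagged <- ann[ann$category %in% c("immunity", "immunity_related",
                                     "glucose"), ]
  others <- setdiff(unique(unlist(flagged$genes)), c(na_mk, ha_mk))
  expect_true(all(term_frequency(others, flagged) <= 1))
})

test_that("PPI generator connects the planted markers", {
  cfg <- sim_config(n_genes = 200, seed = 17)
  ppi <- generate_ppi(cfg)
  markers <- c(sprintf("G%04d", 1:2), sprintf("G%04d", 11:12))
  expect_setequal(connectivity_filter(markers, ppi), markers)
  expect_true(all(ppi$gene_a != ppi$gene_b))
  key <- ifelse(ppi$gene_a < ppi$gene_b, paste(ppi$gene_a, ppi$gene_b),
                paste(ppi$gene_b, ppi$gene_a))
  expect_false(any(duplicated(key)))
})

test_that("drug table plants exclusive and shared drugs", {
  cfg <- sim_config(n_genes = 200, n_drugs = 10, seed = 19)
  out <- generate_drug_table(cfg)
  tab <- out$drug_table
  expect_length(unique(tab$drug), 10)
  expect_true(all(table(tab$drug) >= 1))
  expect_true(is.numeric(tab$score))
  expect_false(any(duplicated(paste(tab$drug, tab$gene))))
  na_mk <- sprintf("G%04d", 1:2); ha_mk <- sprintf("G%04d", 11:12)
  shared_genes <- tab$gene[tab$drug == out$truth$drugs_shared]
  expect_true(any(shared_genes %in% na_mk) && any(shared_genes %in% ha_mk))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(fold = 0.5), "fold")
  expect_error(sim_config(n_genes = 10, n_specific_na = 8,
                          n_specific_ha = 8), "exceed")
  expect_error(sim_config(planted_chains = data.frame(
    from = "a", mid = "b", terminal = "t", p_ab = 1.5, p_bt = 0.2)),
    "probabilities")
})
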