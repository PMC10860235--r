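ann_row <- function(id, name, category, source, p, genes) {
  out <- data.frame(term_id = id, term_name = name, category = category,
                    source = source, p_value = p, stringsAsFactors = FALSE)
  out$genes <- list(genes)
  out
}

test_that("term frequency counts distinct terms per gene", {
  terms <- do.call(rbind, lapply(1:10, function(i)
    ann_row(paste0("t", i), paste0("term ", i), "immunity", "BP", 0.01,
            if (i <= 6) c("g1", "g9") else "g9")))
  freq <- term_frequency(c("g1", "g2"), terms)
  expect_equal(unname(freq["g1"]), 6L)
  expect_equal(unname(freq["g2"]), 0L)

  # brute-force double loop oracle on random membership tables
  withr::with_seed(61, {
    genes <- sprintf("g%02d", 1:20)
    tab <- do.call(rbind, lapply(1:15, function(i)
      ann_row(paste0("r", i), paste0("rand ", i), "other", "BP", 0.01,
              sample(genes, sample(1:8, 1)))))
  })
  freq <- term_frequency(genes, tab)
  brute <- sapply(genes, function(g) {
    n <- 0L
    for (i in seq_len(nrow(tab))) if (g %in% tab$genes[[i]]) n <- n + 1L
    n
  })
  expect_equal(freq, brute)
})

test_that("top-term selection keeps the k least significant-p survivors", {
  withr::with_seed(62, {
    terms <- do.call(rbind, lapply(1:30, function(i)
      ann_row(sprintf("t%02d", i), paste0("term ", i), "other", "BP",
              if (i <= 25) runif(1, 0, 0.049) else runif(1, 0.05, 1),
              "g1")))
  })
  top <- select_top_terms(terms, 20)
  expect_equal(nrow(top), 20L)
  excluded_surv <- setdiff(terms$term_id[terms$p_value < 0.05], top$term_id)
  expect_lte(max(top$p_value), min(terms$p_value[terms$term_id %in%
                                                   excluded_surv]))
  none <- terms; none$p_value <- 0.5
  expect_warning(out <- select_top_terms(none, 20), "only 0")
  expect_equal(nrow(out), 0L)
  # ties at the k-th p resolved by term id, deterministically
  tied <- do.call(rbind, lapply(1:5, function(i)
    ann_row(sprintf("t%d", 6 - i), paste0("x", i), "other", "BP", 0.01,
            "g")))
  expect_identical(select_top_terms(tied, 3)$term_id, c("t1", "t2", "t3"))
})

test_that("connectivity filter equals nonzero degree in the induced subgraph", {
  edges <- data.frame(gene_a = "a", gene_b = "b")
  expect_setequal(connectivity_filter(c("a", "b", "c"), edges), c("a", "b"))
  expect_length(connectivity_filter(c("a", "b"),
                                    edges[0, , drop = FALSE]), 0)
  withr::with_seed(63, {
    genes <- sprintf("g%02d", 1:15)
    ed <- data.frame(gene_a = sample(genes, 30, replace = TRUE),
                     gene_b = sample(genes, 30, replace = TRUE))
    sub <- sample(genes, 8)
  })
  got <- connectivity_filter(sub, ed)
  ig <- igraph::graph_from_data_frame(
    ed[ed$gene_a != ed$gene_b, ], directed = FALSE,
    vertices = data.frame(name = genes))
  induced <- igraph::induced_subgraph(ig, sub)
  want <- names(which(igraph::degree(induced,
                                     loops = FALSE) > 0))
  expect_setequal(got, want)
})

test_that("co-occurrence filter treats absence as zero", {
  co <- c(g1 = 3L, g2 = 0L)
  expect_equal(cooccurrence_filter(c("g1", "g2"), co), "g1")
  expect_equal(cooccurrence_filter(c("g1", "g3"), co, min_count = 0),
               c("g1", "g3"))
  expect_length(cooccurrence_filter("g9", co), 0)
})

test_that("NA cascade reproduces a hand-enumerated fixture", {
  # plant m1, m2 through all six stages; f1 fails only the frequency stage
  markers <- c("m1", "m2")
  imm_bp <- do.call(rbind, lapply(1:6, function(i)
    ann_row(sprintf("bp%d", i), sprintf("bp term %d", i), "immunity", "BP",
            i * 1e-5, c(markers, "f1")[seq_len(if (i <= 4) 3 else 2)])))
  imm_kegg <- do.call(rbind, lapply(1:6, function(i)
    ann_row(sprintf("kg%d", i), sprintf("kegg term %d", i), "immunity",
            "KEGG", i * 1e-5, markers)))
  other <- ann_row("oth", "unrelated", "other", "BP", 0.001,
                   c("f2", "f3"))
  ann <- rbind(imm_bp, imm_kegg, other)
  edges <- data.frame(gene_a = "m1", gene_b = "m2")
  gene_co <- c(m1 = 5L, m2 = 2L, f1 = 9L)
  term_co <- c("bp term 2" = 7L, "bp term 1" = 3L)

  out <- suppressWarnings(
    na_cascade(c(markers, "f1", "f2"), ann, edges, gene_co, term_co))
  # f1 sits on only 4 BP terms (frequency 4, not > 5) and no KEGG term
  expect_setequal(out$stages$bp_all_frequent, markers)
  expect_setequal(out$stages$intersection, markers)
  expect_setequal(out$markers, markers)
  expect_equal(out$chosen_term, "bp2")  # the most PCOS-co-occurring term
  expect_false("f1" %in% out$markers)
})

test_that("NA cascade drops genes failing connectivity or co-occurrence", {
  markers <- c("m1", "m2", "m3")
  ann <- do.call(rbind, c(
    lapply(1:6, function(i) ann_row(sprintf("bp%d", i), sprintf("b%d", i),
                                    "immunity", "BP", 1e-5, markers)),
    lapply(1:6, function(i) ann_row(sprintf("kg%d", i), sprintf("k%d", i),
                                    "immunity", "KEGG", 1e-5, markers))))
  edges <- data.frame(gene_a = "m1", gene_b = "m2")  # m3 unconnected
  gene_co <- c(m1 = 1L, m2 = 0L, m3 = 4L)            # m2 never cited
  out <- suppressWarnings(
    na_cascade(markers, ann, edges, gene_co, c(b1 = 1L)))
  expect_false("m3" %in% out$stages$bp_all_connected)
  expect_false("m2" %in% out$stages$cooccurrence)
  # only m1 survives; no term holds >= 2 survivors, so no final call
  expect_length(out$markers, 0)
})

test_that("HA cascade applies frequency > 1 then co-occurrence > 0", {
  ann <- rbind(ann_row("g1", "glucose a", "glucose", "BP", 1e-4,
                       c("h1", "h2", "h3")),
               ann_row("g2", "glucose b", "glucose", "BP", 1e-3,
                       c("h1", "h2")),
               ann_row("g3", "glucose c", "glucose", "BP", 0.5, "h3"))
  co <- c(h1 = 5L, h2 = 0L)
  out <- suppressWarnings(ha_cascade(c("h1", "h2", "h3"), ann, co))
  expect_setequal(out$stages$frequent, c("h1", "h2"))  # h3: 1 term only
  expect_equal(out$markers, "h1")                      # h2: count 0
})

test_that("cascade stages are monotone and outputs stay within inputs", {
  cfg <- sim_config(n_genes = 200, n_docs = 1000, seed = 71)
  sim <- simulate_all(cfg)
  gene_co <- cooccurrence_table(sim$incidence,
                                sprintf("G%04d", 1:30), "PCOS")
  term_co <- cooccurrence_table(sim$incidence,
                                unique(sim$annotations$term_name), "PCOS")
  full <- sprintf("G%04d", 1:30)
  out_full <- suppressWarnings(
    na_cascade(full, sim$annotations, sim$ppi, gene_co, term_co))
  expect_true(all(out_full$markers %in% full))
  for (drop in list(full[-1], full[-(1:2)], full[1:5])) {
    out_sub <- suppressWarnings(
      na_cascade(drop, sim$annotations, sim$ppi, gene_co, term_co))
    expect_true(all(out_sub$markers %in% drop))
    # shrinking the input never grows the surviving set
    expect_true(all(out_sub$stages$intersection %in%
                      out_full$stages$intersection))
  }
})
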