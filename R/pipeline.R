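#' Pipeline configuration
#'
#' Collects every threshold of the analysis chain with its conventional
#' default: the 0.1 mean-tpm expression filter; raw p < 0.05 with fold
#' change > 2 or < 0.5 for differentiated genes; term-frequency bounds
#' (> 5 all-terms window, > 2 top-20 window for the NA cascade; > 1 for the
#' HA cascade); classifier set sizes 10-50 with a desk-scale iteration
#' default; WLAR cuts (summed confidence > 0.6, summed support > 30);
#' literature cuts (confidence > 0.1, support > 0.001); the terminal
#' phenotype string; and the graph pruning degree.
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param tpm_min,p_cut,fc_hi,fc_lo expression-stage thresholds.
#' @param freq_all,freq_top,freq_ha cascade frequency bounds (strict).
#' @param n_iter,size_range classifier search controls.
#' @param wlar_conf,wlar_supp WLAR cuts (strict).
#' @param lit_conf,lit_supp literature-rule cuts (strict).
#' @param terminal terminal phenotype.
#' @param min_degree graph pruning bound.
#' @param seed master seed for the stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            tpm_min = 0.1, p_cut = 0.05,
                            fc_hi = 2, fc_lo = 0.5,
                            freq_all = 5L, freq_top = 2L, freq_ha = 1L,
                            n_iter = 2000L, size_range = c(10L, 50L),
                            wlar_conf = 0.6, wlar_supp = 30,
                            lit_conf = 0.1, lit_supp = 0.001,
                            terminal = "female infertility",
                            min_degree = 2L, seed = 1L) {
  structure(list(sim = sim, tpm_min = tpm_min, p_cut = p_cut,
                 fc_hi = fc_hi, fc_lo = fc_lo, freq_all = freq_all,
                 freq_top = freq_top, freq_ha = freq_ha, n_iter = n_iter,
                 size_range = size_range, wlar_conf = wlar_conf,
                 wlar_supp = wlar_supp, lit_conf = lit_conf,
                 lit_supp = lit_supp, terminal = terminal,
                 min_degree = min_degree, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of the [pipeline_config()] fields (missing
#' ones take their defaults) plus an optional `sim:` block with
#' [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_fields <- raw$sim %||% list()
  raw$sim <- NULL
  seed <- raw$seed %||% 1L
  if (is.null(sim_fields$seed)) sim_fields$seed <- seed
  cfg_args <- c(raw, list(sim = do.call(sim_config, sim_fields)))
  do.call(pipeline_config, cfg_args)
}

run_stage <- function(name, expr, counts_env) {
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  counts_env$counts[[name]] <- if (is.data.frame(out)) nrow(out)
    else if (is.matrix(out)) nrow(out)
    else if (is.character(out)) length(out)
    else NA_integer_
  out
}

#' Run the full analysis chain on synthetic inputs
#'
#' Executes, in order: input simulation; low-expression filtering;
#' subtype-specific gene calling; the NA and HA functional-marker cascades;
#' the random classifier-marker search with validation on an independently
#' simulated coarse-labelled dataset; dataset merging with quantile
#' normalization; WLAR rules on the merged matrix; corpus partitioning and
#' literature rules chained to the terminal; knowledge-graph assembly,
#' pruning and mutual-term removal; and the subtype-exclusive drug screen.
#' Writes stage outputs plus a reproducibility manifest (config echo, seed,
#' input checksums, per-stage record counts) under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pcoskg_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- new.env(); env$counts <- list()

  sim <- run_stage("simulate", simulate_all(config$sim), env)
  write_expression_tsv(sim$expression, file.path(out_dir, "expression.tsv"))
  utils::write.table(sim$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_corpus_tsv(sim$incidence, file.path(out_dir, "corpus.tsv"))
  write_annotation_tsv(sim$annotations,
                       file.path(out_dir, "annotations.tsv"))
  utils::write.table(sim$ppi, file.path(out_dir, "ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_drug_tsv(sim$drug_table, file.path(out_dir, "drug_table.tsv"))

  x <- run_stage("filter_low_expression",
                 filter_low_expression(sim$expression, config$tpm_min), env)
  spec_na <- run_stage("specific_na",
                       call_specific(x, sim$labels, "NA", config$p_cut,
                                     config$fc_hi, config$fc_lo), env)
  spec_ha <- run_stage("specific_ha",
                       call_specific(x, sim$labels, "HA", config$p_cut,
                                     config$fc_hi, config$fc_lo), env)

  all_specific <- union(spec_na, spec_ha)
  gene_co <- cooccurrence_table(sim$incidence, all_specific, "PCOS")
  term_co <- cooccurrence_table(sim$incidence,
                                unique(sim$annotations$term_name), "PCOS")
  casc_na <- run_stage("na_cascade",
                       na_cascade(spec_na, sim$annotations, sim$ppi,
                                  gene_co, term_co,
                                  freq_all = config$freq_all,
                                  freq_top = config$freq_top)$markers, env)
  casc_ha <- run_stage("ha_cascade",
                       ha_cascade(spec_ha, sim$annotations, gene_co,
                                  freq_min = config$freq_ha)$markers, env)

  search <- search_marker_sets(x, sim$labels, n_iter = config$n_iter,
                               size_range = config$size_range,
                               seed = config$seed)
  env$counts$classifier_search <- length(search$reserved)
  val_cfg <- config$sim
  val_cfg$seed <- sim_stream(config$sim, 104729L)  # independent cohort
  val <- generate_expression(val_cfg)
  val$labels$group[val$labels$group %in% c("NA", "HA")] <- "PCOS"
  val_x <- filter_low_expression(val$matrix, config$tpm_min)
  common <- intersect(rownames(x), rownames(val_x))
  validation <- list(list(matrix = val_x[common, ], labels = val$labels))
  best <- if (length(search$reserved)) {
    # triples may reference genes filtered out of the validation cohort
    usable <- Filter(function(tr) all(unlist(tr) %in% common),
                     search$reserved)
    if (length(usable))
      select_best(list(reserved = usable), validation)$best
    else NULL
  } else NULL

  merged <- merge_and_normalize(list(x[common, ], val_x[common, ]),
                                list(sim$labels, val$labels),
                                prefixes = c("train", "valid"))
  wlar_genes <- intersect(union(union(casc_na, casc_ha), all_specific),
                          rownames(merged$matrix))
  wlar_rules <- run_stage("wlar",
                          compute_wlar(drop_sparse_samples(merged$matrix),
                                       wlar_genes,
                                       conf_cut = config$wlar_conf,
                                       supp_cut = config$wlar_supp), env)

  parts <- partition_corpus(sim$incidence, ha_genes = spec_ha,
                            na_genes = spec_na)
  lit_items <- function(sub, genes) {
    unique(c(genes, unlist(sim$truth$chain_edges[c("mid", "terminal")]),
             config$terminal))
  }
  graphs <- lapply(list(ha = list(inc = parts$ha, genes = spec_ha),
                        na = list(inc = parts$na, genes = spec_na)),
                   function(side) {
    r2 <- lit_rules_2(side$inc, items = lit_items(side$inc, side$genes),
                      conf_cut = config$lit_conf,
                      supp_cut = config$lit_supp)
    r3 <- terminal_filter(extend_rules_3(r2, config$lit_conf),
                          config$terminal)
    g <- assemble_graph(r3, wlar_rules, config$terminal,
                        gene_nodes = rownames(sim$expression))
    prune_low_degree(g, config$min_degree)
  })
  env$counts$graph_ha_edges <- nrow(graphs$ha$edges)
  env$counts$graph_na_edges <- nrow(graphs$na$edges)
  split_graphs <- remove_mutual_terms(graphs$ha, graphs$na)

  markers_ha <- union(casc_ha, if (!is.null(best)) best$HA else character(0))
  markers_na <- union(casc_na, if (!is.null(best)) best$`NA` else character(0))
  ha_drugs <- drugs_for(markers_ha, sim$drug_table)
  na_drugs <- drugs_for(markers_na, sim$drug_table)
  excl <- exclusive_drugs(ha_drugs, na_drugs)
  env$counts$ha_exclusive_drugs <- length(excl$ha_only)
  env$counts$na_exclusive_drugs <- length(excl$na_only)

  export_graph(split_graphs$ha, file.path(out_dir, "graph_ha.sif"), "sif")
  export_graph(split_graphs$na, file.path(out_dir, "graph_na.sif"), "sif")
  export_graph(split_graphs$ha, file.path(out_dir, "graph_ha.graphml"),
               "graphml")
  export_graph(split_graphs$na, file.path(out_dir, "graph_na.graphml"),
               "graphml")
  writeLines(excl$ha_only, file.path(out_dir, "drugs_ha_exclusive.txt"))
  writeLines(excl$na_only, file.path(out_dir, "drugs_na_exclusive.txt"))

  inputs <- c("expression.tsv", "labels.tsv", "corpus.tsv",
              "annotations.tsv", "ppi.tsv", "drug_table.tsv")
  manifest <- list(config = unclass(config[setdiff(names(config), "sim")]),
                   sim = unclass(config$sim), seed = config$seed,
                   input_md5 = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out_dir, inputs))),
                     inputs)),
                   stage_counts = env$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)

  invisible(list(out_dir = out_dir, sim = sim, filtered = x,
                 specific_na = spec_na, specific_ha = spec_ha,
                 cascade_na = casc_na, cascade_ha = casc_ha,
                 search = search, best = best, merged = merged,
                 wlar = wlar_rules, graphs = split_graphs,
                 drugs = excl, manifest = manifest))
}
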