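#' Generate a three-group expression matrix with planted specific genes
#'
#' Simulates a tpm-scale gene-by-sample matrix for NM (normal), NA
#' (normoandrogenic PCOS) and HA (hyperandrogenic PCOS) groups. Each gene has
#' a log-normal baseline; planted subtype-specific genes are multiplied by
#' `fold` in their subtype only, so their group mean equals `fold` times the
#' baseline mean in expectation. Noise is log-normal with log-scale standard
#' deviation `noise_sd`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (numeric gene x sample), `labels` (data.frame
#'   `sample_id`, `group`), and `truth` (list with `specific_na`,
#'   `specific_ha`).
#' @export
generate_expression <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  spec_na <- sim_specific_na(cfg)
  spec_ha <- sim_specific_ha(cfg)
  genes <- sim_gene_ids(cfg)
  n <- cfg$n_per_group
  samples <- c(sprintf("NM%d", seq_len(n)), sprintf("NA%d", seq_len(n)),
               sprintf("HA%d", seq_len(n)))
  groups <- rep(c("NM", "NA", "HA"), each = n)

  withr::with_seed(sim_stream(cfg, 0L), {
    baseline <- stats::rlnorm(cfg$n_genes, meanlog = log(5), sdlog = 1.5)
    # planted genes must sit comfortably above the low-expression filter
    planted <- genes %in% c(spec_na, spec_ha)
    baseline[planted] <- stats::rlnorm(sum(planted), meanlog = log(10),
                                       sdlog = 0.5)
    effect <- matrix(1, nrow = cfg$n_genes, ncol = length(samples))
    effect[genes %in% spec_na, groups == "NA"] <- cfg$fold
    effect[genes %in% spec_ha, groups == "HA"] <- cfg$fold
    noise <- matrix(stats::rnorm(cfg$n_genes * length(samples),
                                 sd = cfg$noise_sd),
                    nrow = cfg$n_genes)
    x <- baseline * effect * exp(noise)
  })
  dimnames(x) <- list(genes, samples)
  list(matrix = x,
       labels = data.frame(sample_id = samples, group = groups,
                           stringsAsFactors = FALSE),
       truth = list(specific_na = spec_na, specific_ha = spec_ha))
}

#' Generate a literature corpus with planted conditional co-occurrence
#'
#' Builds `n_docs` documents, each a set of item strings (MeSH-like terms
#' and gene symbols). Background terms are drawn independently per document.
#' For every planted chain (A, B, terminal, p_ab, p_bt): A appears with a
#' fixed marginal probability; B appears with probability `p_ab` in documents
#' containing A and with a low base rate otherwise, so that P(B | A) equals
#' `p_ab` exactly (provided B is unique to its chain); the terminal is
#' handled analogously from B with `p_bt`. Chain source items additionally
#' co-occur with the query term "PCOS" so downstream co-occurrence filters
#' are identifiable.
#'
#' @param cfg a [sim_config()].
#' @param p_marginal marginal probability of a chain's source item.
#' @param p_base base rate of a chain's dependent items when the parent is
#'   absent.
#' @return list with `incidence` (a [term_incidence] object) and `truth`
#'   (list with `chain_edges` data.frame).
#' @export
generate_corpus <- function(cfg, p_marginal = 0.3, p_base = 0.05) {
  cfg <- validate_sim_config(cfg)
  chains <- sim_chains(cfg)
  if (!nrow(chains)) stop("generate_corpus: planted_chains is empty",
                          call. = FALSE)
  n <- cfg$n_docs
  background <- c("Ovary", "Granulosa Cells", "Androgens", "Glucose",
                  "Insulin", "Testosterone", "Follicular Phase",
                  "Anovulation", "Luteinizing Hormone", "Obesity",
                  "Metformin", "Inflammation",
                  # NA-cascade annotation term names appear in the corpus so
                  # the final term co-occurrence pick is non-degenerate
                  "response to cytokine", "immune response")

  withr::with_seed(sim_stream(cfg, 1L), {
    pres <- list()
    for (term in background) {
      rate <- stats::runif(1, 0.02, 0.15)
      pres[[tolower(term)]] <- stats::runif(n) < rate
    }
    pcos <- stats::runif(n) < p_base
    for (i in seq_len(nrow(chains))) {
      a <- tolower(chains$from[i]); b <- tolower(chains$mid[i])
      t <- tolower(chains$terminal[i])
      a_pres <- stats::runif(n) < p_marginal
      pres[[a]] <- if (is.null(pres[[a]])) a_pres else (pres[[a]] | a_pres)
      b_pres <- ifelse(pres[[a]], stats::runif(n) < chains$p_ab[i],
                       stats::runif(n) < p_base)
      pres[[b]] <- if (is.null(pres[[b]])) b_pres else (pres[[b]] | b_pres)
      t_pres <- ifelse(pres[[b]], stats::runif(n) < chains$p_bt[i],
                       stats::runif(n) < p_base)
      pres[[t]] <- if (is.null(pres[[t]])) t_pres else (pres[[t]] | t_pres)
      # chain sources co-occur with PCOS (the cascade's fixed query)
      pcos <- pcos | (pres[[a]] & stats::runif(n) < 0.6)
    }
    pres[["pcos"]] <- pcos
  })

  display <- c(background, "PCOS",
               chains$from, chains$mid, chains$terminal)
  names(display) <- tolower(display)
  display <- display[!duplicated(names(display))]

  items <- names(pres)
  mat <- do.call(cbind, pres)  # n_docs x items logical
  docs <- apply(mat, 1L, function(row) unname(display[items[row]]),
                simplify = FALSE)
  names(docs) <- sprintf("PM%06d", seq_len(n))
  list(incidence = term_incidence(docs),
       truth = list(chain_edges = chains))
}

#' Generate an annotation table with planted marker memberships
#'
#' Emulates a GO/KEGG term table: each row has a term id, a human-readable
#' name, a curated category flag (`immunity`, `immunity_related`, `glucose`
#' or `other`), a source (`BP` or `KEGG`) and an enrichment p-value, plus a
#' member gene set. Planted NA-cascade markers sit on 6 immunity terms per
#' source with very small p-values (so they pass both the all-terms
#' frequency > 5 and the top-20 frequency > 2 windows); planted HA-cascade
#' markers sit on 2 glucose BP terms. Non-planted genes appear on at most
#' one flagged term.
#'
#' @param cfg a [sim_config()].
#' @return list with `annotations` (data.frame with list-column `genes`) and
#'   `truth` (`marker_annotations`: named list term_id -> planted genes).
#' @export
generate_annotations <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  na_mk <- sim_cascade_na(cfg)
  ha_mk <- sim_cascade_ha(cfg)
  genes <- sim_gene_ids(cfg)
  other_pool <- setdiff(genes, c(sim_specific_na(cfg), sim_specific_ha(cfg)))

  na_bp_names <- c("response to cytokine", "immune response",
                   "inflammatory response", "cytokine production",
                   "leukocyte activation", "defense response")
  na_kegg_names <- c("Cytokine-cytokine receptor interaction",
                     "JAK-STAT signaling pathway", "Chemokine signaling",
                     "T cell receptor signaling", "NF-kappa B signaling",
                     "PD-L1 checkpoint pathway")
  ha_bp_names <- c("glucose metabolic process", "cellular glucose homeostasis")

  withr::with_seed(sim_stream(cfg, 2L), {
    filler <- sample(other_pool)
    take <- local({
      i <- 0L
      function(k) {
        out <- filler[i + seq_len(k)]
        i <<- i + k
        out
      }
    })
    rows <- list()
    truth <- list()
    add <- function(id, name, category, source, p, members) {
      rows[[length(rows) + 1L]] <<- data.frame(
        term_id = id, term_name = name, category = category, source = source,
        p_value = p, stringsAsFactors = FALSE)
      rows[[length(rows)]]$genes <<- list(members)
    }
    for (i in seq_along(na_bp_names)) {
      id <- sprintf("GO:%07d", i)
      members <- c(na_mk, take(1L))
      add(id, na_bp_names[i], "immunity", "BP",
          stats::runif(1, 1e-7, 1e-4), members)
      truth[[id]] <- na_mk
    }
    for (i in seq_along(na_kegg_names)) {
      id <- sprintf("hsa%05d", i)
      members <- c(na_mk, take(1L))
      add(id, na_kegg_names[i], "immunity", "KEGG",
          stats::runif(1, 1e-7, 1e-4), members)
      truth[[id]] <- na_mk
    }
    for (i in seq_along(ha_bp_names)) {
      id <- sprintf("GO:%07d", 100L + i)
      members <- c(ha_mk, take(1L))
      add(id, ha_bp_names[i], "glucose", "BP",
          stats::runif(1, 1e-6, 1e-3), members)
      truth[[id]] <- ha_mk
    }
    n_planted <- length(rows)
    n_fill <- max(cfg$n_terms - n_planted, 0L)
    for (i in seq_len(n_fill)) {
      id <- sprintf("GO:%07d", 1000L + i)
      # a mix of significant and non-significant background terms
      p <- if (i %% 3L == 0L) stats::runif(1, 0.05, 0.9)
           else stats::runif(1, 1e-4, 0.049)
      src <- if (i %% 2L == 0L) "BP" else "KEGG"
      members <- sample(other_pool, min(8L, length(other_pool)))
      add(id, sprintf("background process %d", i), "other", src, p, members)
    }
    ann <- do.call(rbind, rows)
  })
  list(annotations = ann, truth = list(marker_annotations = truth))
}

#' Generate a PPI edge table connecting planted markers
#'
#' Planted cascade markers (NA and HA) form a connected path; background
#' edges are added among random gene pairs. Edges are undirected, unique,
#' self-loop free, and tagged with an evidence channel.
#'
#' @param cfg a [sim_config()].
#' @param n_background number of random background edges.
#' @return data.frame with columns `gene_a`, `gene_b`, `evidence`.
#' @export
generate_ppi <- function(cfg, n_background = 200L) {
  cfg <- validate_sim_config(cfg)
  markers <- c(sim_cascade_na(cfg), sim_cascade_ha(cfg))
  genes <- sim_gene_ids(cfg)
  edges <- NULL
  if (length(markers) >= 2L) {
    edges <- data.frame(gene_a = markers[-length(markers)],
                        gene_b = markers[-1L],
                        evidence = "Experiment", stringsAsFactors = FALSE)
  }
  withr::with_seed(sim_stream(cfg, 3L), {
    a <- sample(genes, n_background, replace = TRUE)
    b <- sample(genes, n_background, replace = TRUE)
    ev <- sample(c("Experiment", "Databases"), n_background, replace = TRUE)
  })
  bg <- data.frame(gene_a = a, gene_b = b, evidence = ev,
                   stringsAsFactors = FALSE)
  bg <- bg[bg$gene_a != bg$gene_b, ]
  out <- rbind(edges, bg)
  key <- ifelse(out$gene_a < out$gene_b,
                paste(out$gene_a, out$gene_b),
                paste(out$gene_b, out$gene_a))
  out[!duplicated(key), , drop = FALSE]
}

#' Generate a drug-gene interaction table with planted exclusive drugs
#'
#' Plants drugs whose targets lie only among NA-cascade markers, drugs
#' targeting only HA-cascade markers, and at least one shared drug hitting
#' both marker sets; the remaining drugs target background genes.
#'
#' @param cfg a [sim_config()].
#' @return list with `drug_table` (data.frame `drug`, `gene`, `score`) and
#'   `truth` (lists `drugs_na_exclusive`, `drugs_ha_exclusive`,
#'   `drugs_shared`).
#' @export
generate_drug_table <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  na_mk <- sim_cascade_na(cfg)
  ha_mk <- sim_cascade_ha(cfg)
  genes <- sim_gene_ids(cfg)
  bg_pool <- setdiff(genes, c(na_mk, ha_mk))

  n_excl <- 2L
  na_drugs <- sprintf("na-drug-%d", seq_len(n_excl))
  ha_drugs <- sprintf("ha-drug-%d", seq_len(n_excl))
  shared <- "shared-drug-1"
  n_named <- length(na_drugs) + length(ha_drugs) + 1L
  n_bg <- max(cfg$n_drugs - n_named, 0L)
  bg_drugs <- if (n_bg) sprintf("bg-drug-%d", seq_len(n_bg)) else character(0)

  rows <- list()
  for (d in na_drugs)
    rows[[d]] <- data.frame(drug = d, gene = na_mk, stringsAsFactors = FALSE)
  for (d in ha_drugs)
    rows[[d]] <- data.frame(drug = d, gene = ha_mk, stringsAsFactors = FALSE)
  rows[[shared]] <- data.frame(drug = shared,
                               gene = c(na_mk[1L], ha_mk[1L]),
                               stringsAsFactors = FALSE)
  withr::with_seed(sim_stream(cfg, 4L), {
    for (d in bg_drugs) {
      tg <- sample(bg_pool, sample(1:3, 1L))
      rows[[d]] <- data.frame(drug = d, gene = tg, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$score <- round(stats::runif(nrow(tab), 0.1, 1), 3)
  })
  rownames(tab) <- NULL
  list(drug_table = tab,
       truth = list(drugs_na_exclusive = na_drugs,
                    drugs_ha_exclusive = ha_drugs,
                    drugs_shared = shared))
}

#' Generate every pipeline input from one configuration
#'
#' Convenience wrapper running all five generators and merging their planted
#' truth into one record.
#'
#' @param cfg a [sim_config()].
#' @return list with `expression`, `labels`, `incidence`, `annotations`,
#'   `ppi`, `drug_table` and `truth`.
#' @export
simulate_all <- function(cfg) {
  expr <- generate_expression(cfg)
  corp <- generate_corpus(cfg)
  ann <- generate_annotations(cfg)
  ppi <- generate_ppi(cfg)
  drugs <- generate_drug_table(cfg)
  list(expression = expr$matrix, labels = expr$labels,
       incidence = corp$incidence, annotations = ann$annotations,
       ppi = ppi, drug_table = drugs$drug_table,
       truth = c(expr$truth, corp$truth, ann$truth, drugs$truth,
                 list(cascade_na = sim_cascade_na(cfg),
                      cascade_ha = sim_cascade_ha(cfg))))
}
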