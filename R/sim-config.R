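#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators: the expression matrix
#' (three groups of granulosa-cell-like samples with planted subtype-specific
#' genes), the literature corpus (documents carrying MeSH-like terms and gene
#' symbols with planted conditional co-occurrence chains ending at a terminal
#' phenotype), the annotation table, the PPI edge list and the drug-gene
#' table. All generators draw from streams derived from the single `seed`.
#'
#' @param n_genes number of genes in the expression matrix.
#' @param n_per_group samples per group (NM, NA, HA). The emulated study
#'   design has 4 subjects per group.
#' @param n_specific_na,n_specific_ha number of planted subtype-specific
#'   genes (expression raised by `fold` in that group only).
#' @param fold multiplicative effect size for planted genes, > 1 (or exactly
#'   1 for a null generator).
#' @param noise_sd standard deviation of the per-observation noise on the
#'   natural-log scale.
#' @param n_docs corpus size (number of documents).
#' @param planted_chains data.frame with columns `from`, `mid`, `terminal`,
#'   `p_ab`, `p_bt`: conditional co-occurrence chains planted in the corpus.
#'   `NULL` builds a default set anchored on the planted marker genes.
#' @param n_terms total number of annotation terms per source.
#' @param n_drugs number of distinct drugs in the drug-gene table.
#' @param terminal terminal phenotype string used by default chains.
#' @param seed integer RNG seed; every generator derives its stream from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000, n_per_group = 4,
                       n_specific_na = 10, n_specific_ha = 10,
                       fold = 4, noise_sd = 0.2,
                       n_docs = 10000, planted_chains = NULL,
                       n_terms = 40, n_drugs = 20,
                       terminal = "female infertility",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    n_specific_na = as.integer(n_specific_na),
    n_specific_ha = as.integer(n_specific_ha),
    fold = as.numeric(fold), noise_sd = as.numeric(noise_sd),
    n_docs = as.integer(n_docs), planted_chains = planted_chains,
    n_terms = as.integer(n_terms), n_drugs = as.integer(n_drugs),
    terminal = as.character(terminal), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_genes, cfg$n_per_group, cfg$n_docs, cfg$n_terms,
              cfg$n_drugs)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("sim_config: all counts must be >= 1", call. = FALSE)
  if (cfg$n_specific_na < 0L || cfg$n_specific_ha < 0L)
    stop("sim_config: specific-gene counts must be >= 0", call. = FALSE)
  if (cfg$n_specific_na + cfg$n_specific_ha > cfg$n_genes)
    stop("sim_config: planted specific genes exceed n_genes", call. = FALSE)
  if (!is.finite(cfg$fold) || cfg$fold < 1)
    stop("sim_config: fold must be >= 1", call. = FALSE)
  if (cfg$noise_sd < 0)
    stop("sim_config: noise_sd must be >= 0", call. = FALSE)
  if (is.na(cfg$seed))
    stop("sim_config: seed must be an integer", call. = FALSE)
  ch <- sim_chains(cfg)
  if (nrow(ch)) {
    if (!all(c("from", "mid", "terminal", "p_ab", "p_bt") %in% names(ch)))
      stop("sim_config: planted_chains needs columns from, mid, terminal, p_ab, p_bt",
           call. = FALSE)
    if (any(ch$p_ab < 0 | ch$p_ab > 1 | ch$p_bt < 0 | ch$p_bt > 1))
      stop("sim_config: chain probabilities must lie in [0, 1]", call. = FALSE)
  }
  cfg
}

# Deterministic id scheme shared by all generators.
sim_gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

sim_specific_na <- function(cfg) {
  if (cfg$n_specific_na == 0L) return(character(0))
  sim_gene_ids(cfg)[seq_len(cfg$n_specific_na)]
}

sim_specific_ha <- function(cfg) {
  if (cfg$n_specific_ha == 0L) return(character(0))
  sim_gene_ids(cfg)[cfg$n_specific_na + seq_len(cfg$n_specific_ha)]
}

# The subset of planted specific genes that is additionally carried through
# annotations, PPI, corpus and drug table (the "functional marker" truth).
sim_cascade_na <- function(cfg) utils::head(sim_specific_na(cfg), 2L)
sim_cascade_ha <- function(cfg) utils::head(sim_specific_ha(cfg), 2L)

# Default planted chains: each cascade marker drives a distinct intermediate
# term which in turn drives the terminal phenotype. Distinct intermediates
# keep the planted conditional probabilities exact (no cross-chain leakage).
sim_chains <- function(cfg) {
  if (!is.null(cfg$planted_chains)) return(cfg$planted_chains)
  na_mk <- sim_cascade_na(cfg)
  ha_mk <- sim_cascade_ha(cfg)
  mids <- c("response to cytokine", "ovulation",
            "insulin resistance", "hyperandrogenism")
  from <- c(na_mk, ha_mk)
  if (!length(from)) return(data.frame(from = character(0),
                                       mid = character(0),
                                       terminal = character(0),
                                       p_ab = numeric(0), p_bt = numeric(0)))
  data.frame(from = from,
             mid = mids[seq_along(from)],
             terminal = cfg$terminal,
             p_ab = 0.5, p_bt = 0.5,
             stringsAsFactors = FALSE)
}

# Per-generator RNG stream: offset the master seed, wrap within integer range.
sim_stream <- function(cfg, offset) {
  (cfg$seed + offset) %% (.Machine$integer.max - 1L)
}
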