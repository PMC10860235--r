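#' Annotation table helpers
#'
#' Annotation tables are data.frames with columns `term_id`, `term_name`,
#' `category` (one of `immunity`, `immunity_related`, `glucose`, `other` —
#' the manual curation of the original workflow turned into data), `source`
#' (`BP` or `KEGG`), `p_value` and a list-column `genes`. The TSV format
#' joins gene sets with `";"`.
#'
#' @param path file path.
#' @return data.frame annotation table.
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  tab$p_value <- as.numeric(tab$p_value)
  tab$genes <- lapply(tab$genes, function(s)
    if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]] else character(0))
  tab
}

#' @param ann annotation table.
#' @rdname read_annotation_tsv
#' @export
write_annotation_tsv <- function(ann, path) {
  out <- ann
  out$genes <- vapply(ann$genes, paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count, per gene, the terms it appears on
#'
#' @param genes gene-id character vector.
#' @param terms annotation table already restricted to the window of
#'   interest (category and rank window applied by the caller).
#' @return named integer vector gene -> number of distinct terms whose
#'   member set contains it.
#' @export
term_frequency <- function(genes, terms) {
  counts <- vapply(genes, function(g)
    sum(vapply(terms$genes, function(m) g %in% m, logical(1))), integer(1))
  names(counts) <- genes
  counts
}

#' Keep the k most significant terms
#'
#' Removes terms with p >= 0.05, sorts the survivors by ascending p-value
#' (ties broken by lexicographic term id for determinism) and returns the
#' first `k`. Fewer than `k` survivors are returned in full with a warning.
#'
#' @param terms annotation table.
#' @param k number of terms to keep.
#' @param p_cut significance cutoff applied before ranking.
#' @return annotation table subset.
#' @export
select_top_terms <- function(terms, k = 20L, p_cut = 0.05) {
  surv <- terms[terms$p_value < p_cut, , drop = FALSE]
  surv <- surv[order(surv$p_value, surv$term_id), , drop = FALSE]
  if (nrow(surv) < k)
    warning("select_top_terms: only ", nrow(surv), " terms with p < ", p_cut)
  utils::head(surv, k)
}

#' Drop genes with no PPI connection inside the set
#'
#' A gene survives iff it shares at least one edge with another gene of the
#' input set — i.e. it has nonzero degree in the induced subgraph.
#'
#' @param genes gene-id set.
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @return character vector subset of `genes`.
#' @export
connectivity_filter <- function(genes, edges) {
  inside <- edges$gene_a %in% genes & edges$gene_b %in% genes &
    edges$gene_a != edges$gene_b
  connected <- unique(c(edges$gene_a[inside], edges$gene_b[inside]))
  genes[genes %in% connected]
}

#' Keep genes with enough co-occurrence support
#'
#' @param genes gene-id set.
#' @param co named integer vector (see [cooccurrence_table()]); genes absent
#'   from the table count 0.
#' @param min_count minimum count to survive (default 1, i.e. "> 0").
#' @return character vector subset of `genes`.
#' @export
cooccurrence_filter <- function(genes, co, min_count = 1L) {
  counts <- ifelse(genes %in% names(co), co[genes], 0L)
  genes[counts >= min_count]
}

cascade_warn_empty <- function(set, stage) {
  if (!length(set))
    warning("cascade: empty gene set after stage '", stage, "'",
            call. = FALSE)
  set
}

#' Normoandrogenic-PCOS functional-marker cascade
#'
#' Six filtering stages over the NA-specific genes:
#' 1. restrict to genes on immunity(+related) terms under all four windows
#'    (BP all significant terms, BP top-k, KEGG all, KEGG top-k);
#' 2. term-appearance frequency > `freq_all` in the all-terms windows and
#'    > `freq_top` in the top-k windows;
#' 3. PPI connectivity filter within each window's survivors;
#' 4. intersection of the four windows;
#' 5. gene/PCOS co-occurrence > 0;
#' 6. among surviving terms containing >= 2 surviving genes, pick the term
#'    with the largest co-occurrence count (ties: lowest p, then term id)
#'    and return its surviving genes.
#'
#' @param na_specific NA-specific gene ids.
#' @param annotations annotation table with `immunity`/`immunity_related`
#'   categories for both BP and KEGG.
#' @param edges PPI edge table.
#' @param gene_co named counts: gene -> co-occurrence with the PCOS query.
#' @param term_co named counts: term name -> co-occurrence with the query.
#' @param k top-window size; `freq_all`, `freq_top` strict lower bounds on
#'   term frequency in the all-terms and top-k windows.
#' @return list with `markers` (gene ids), `chosen_term` (term_id or NA),
#'   and `stages` (named list of intermediate sets for audit).
#' @export
na_cascade <- function(na_specific, annotations, edges, gene_co, term_co,
                       k = 20L, freq_all = 5L, freq_top = 2L) {
  imm <- annotations[annotations$category %in%
                       c("immunity", "immunity_related"), , drop = FALSE]
  windows <- list(
    bp_all = imm[imm$source == "BP", , drop = FALSE],
    bp_top = select_top_terms(imm[imm$source == "BP", , drop = FALSE], k),
    kegg_all = imm[imm$source == "KEGG", , drop = FALSE],
    kegg_top = select_top_terms(imm[imm$source == "KEGG", , drop = FALSE], k)
  )
  min_freq <- c(bp_all = freq_all, bp_top = freq_top,
                kegg_all = freq_all, kegg_top = freq_top)
  stages <- list()
  per_window <- lapply(names(windows), function(w) {
    terms <- windows[[w]]
    freq <- term_frequency(na_specific, terms)
    frequent <- names(freq)[freq > min_freq[[w]]]
    stages[[paste0(w, "_frequent")]] <<- frequent
    connected <- connectivity_filter(frequent, edges)
    stages[[paste0(w, "_connected")]] <<- connected
    connected
  })
  joint <- cascade_warn_empty(Reduce(intersect, per_window),
                              "window intersection")
  stages$intersection <- joint
  markers <- cascade_warn_empty(cooccurrence_filter(joint, gene_co),
                                "co-occurrence")
  stages$cooccurrence <- markers

  chosen <- NA_character_
  final <- character(0)
  if (length(markers)) {
    imm_all <- rbind(windows$bp_all, windows$kegg_all)
    n_surv <- vapply(imm_all$genes, function(m) sum(markers %in% m),
                     integer(1))
    cand <- imm_all[n_surv >= 2L, , drop = FALSE]
    if (nrow(cand)) {
      co <- ifelse(cand$term_name %in% names(term_co),
                   term_co[cand$term_name], 0L)
      ord <- order(-co, cand$p_value, cand$term_id)
      chosen <- cand$term_id[ord[1L]]
      final <- intersect(markers, cand$genes[[ord[1L]]])
    } else {
      warning("na_cascade: no term contains >= 2 surviving genes",
              call. = FALSE)
    }
  }
  list(markers = final, chosen_term = chosen, stages = stages)
}

#' Hyperandrogenic-PCOS functional-marker cascade
#'
#' Genes on glucose-flagged BP terms with appearance frequency > `freq_min`,
#' then gene/PCOS co-occurrence > 0. (Glucose BP terms only: KEGG results
#' are not used for this subtype.)
#'
#' @param ha_specific HA-specific gene ids.
#' @param annotations annotation table with glucose-flagged BP terms.
#' @param gene_co named counts: gene -> co-occurrence with the PCOS query.
#' @param freq_min strict lower bound on glucose-term frequency.
#' @param p_cut significance cutoff on the glucose terms.
#' @return list with `markers` and `stages`.
#' @export
ha_cascade <- function(ha_specific, annotations, gene_co, freq_min = 1L,
                       p_cut = 0.05) {
  glu <- annotations[annotations$category == "glucose" &
                       annotations$source == "BP" &
                       annotations$p_value < p_cut, , drop = FALSE]
  freq <- term_frequency(ha_specific, glu)
  frequent <- cascade_warn_empty(names(freq)[freq > freq_min], "frequency")
  markers <- cascade_warn_empty(cooccurrence_filter(frequent, gene_co),
                                "co-occurrence")
  list(markers = markers,
       stages = list(frequent = frequent, cooccurrence = markers))
}
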