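#' Rank-based random-set sample classifier
#'
#' A marker-set triple is one gene set per group (NM, NA, HA), each of
#' 10-50 genes drawn from the pool of genes whose highest group mean falls
#' in that group. A sample is classified by ranking all genes within the
#' sample (rank 1 = lowest expression, average ranks on ties) and assigning
#' the group whose marker set has the highest mean rank — i.e. whose markers
#' are, as a set, most highly expressed in that sample.
#'
#' @name classifier
NULL

#' Per-sample ascending expression ranks
#'
#' @param x expression matrix.
#' @return matrix of the same shape; each column holds the within-sample
#'   ranks (1 = lowest, average on ties).
#' @export
rank_matrix <- function(x) {
  apply(x, 2L, rank, ties.method = "average")
}

#' Assign each gene to the group where it is highest
#'
#' @param x expression matrix.
#' @param labels fine sample labels.
#' @return named character vector gene -> group; genes whose maximal group
#'   mean is tied are dropped (excluded from all sampling pools).
#' @export
assign_gene_groups <- function(x, labels) {
  validate_labels(x, labels)
  groups <- c("NM", "NA", "HA")
  gm <- sapply(groups, function(g)
    rowMeans(x[, intersect(colnames(x), group_samples(labels, g)),
               drop = FALSE]))
  gm <- matrix(gm, nrow = nrow(x), dimnames = list(rownames(x), groups))
  top <- apply(gm, 1L, function(m) {
    w <- which(m == max(m))
    if (length(w) == 1L) groups[w] else NA_character_
  })
  top[!is.na(top)]
}

#' Predict one sample's group from its gene ranks
#'
#' @param sample_ranks named numeric vector: gene -> within-sample rank.
#' @param triple list with gene-id vectors `NM`, `NA`, `HA`.
#' @return the group with the highest mean marker rank, or `NA_character_`
#'   when the maximum is tied (no call; counted as a misclassification).
#' @export
predict_sample <- function(sample_ranks, triple) {
  groups <- c("NM", "NA", "HA")
  missing <- setdiff(unlist(triple[groups]), names(sample_ranks))
  if (length(missing))
    stop("predict_sample: marker genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  means <- vapply(groups, function(g) mean(sample_ranks[triple[[g]]]),
                  numeric(1))
  w <- which(means == max(means))
  if (length(w) == 1L) groups[w] else NA_character_
}

predict_all <- function(rank_mat, triple) {
  groups <- c("NM", "NA", "HA")
  means <- vapply(groups, function(g)
    colMeans(rank_mat[triple[[g]], , drop = FALSE]), numeric(ncol(rank_mat)))
  means <- matrix(means, ncol = 3L, dimnames = list(colnames(rank_mat),
                                                    groups))
  apply(means, 1L, function(m) {
    w <- which(m == max(m))
    if (length(w) == 1L) groups[w] else NA_character_
  })
}

#' Random search for marker-set triples that classify training perfectly
#'
#' Each iteration draws an independent uniform size in `size_range` per
#' group (clamped to the pool size), samples that many genes without
#' replacement from the group's pool, and keeps the triple iff every
#' training sample is predicted into its true fine group. Deterministic
#' given `seed`.
#'
#' @param x expression matrix (training data, fine labels).
#' @param labels fine sample labels.
#' @param n_iter number of random draws.
#' @param size_range inclusive bounds on the per-group set size.
#' @param seed integer seed.
#' @return list of class `marker_search` with `reserved` (list of triples),
#'   `n_iter` and `seed`.
#' @export
search_marker_sets <- function(x, labels, n_iter = 10000L,
                               size_range = c(10L, 50L), seed = 1L) {
  validate_labels(x, labels)
  assignment <- assign_gene_groups(x, labels)
  pools <- split(names(assignment), assignment)
  groups <- c("NM", "NA", "HA")
  if (!all(groups %in% names(pools)))
    stop("search_marker_sets: some group has an empty gene pool",
         call. = FALSE)
  rk <- rank_matrix(x)
  actual <- labels$group[match(colnames(x), labels$sample_id)]
  reserved <- list()
  withr::with_seed(seed, {
    for (i in seq_len(n_iter)) {
      triple <- lapply(groups, function(g) {
        hi <- min(size_range[2L], length(pools[[g]]))
        lo <- min(size_range[1L], hi)
        size <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        sample(pools[[g]], size)
      })
      names(triple) <- groups
      pred <- predict_all(rk, triple)
      if (!anyNA(pred) && all(pred == actual))
        reserved[[length(reserved) + 1L]] <- triple
    }
  })
  structure(list(reserved = reserved, n_iter = n_iter, seed = seed),
            class = "marker_search")
}

#' Matching rate of predictions against (possibly coarse) labels
#'
#' A prediction of NA or HA counts as correct against a coarse `PCOS`
#' label; NM must match NM; against fine labels the groups must match
#' exactly. A no-call (`NA`) prediction is always wrong.
#'
#' @param predictions named character vector sample -> predicted group.
#' @param actual label data.frame (`sample_id`, `group`), coarse or fine.
#' @return fraction of correctly matched samples in `[0, 1]`.
#' @export
matching_rate <- function(predictions, actual) {
  idx <- match(names(predictions), actual$sample_id)
  if (anyNA(idx))
    stop("matching_rate: samples missing from labels", call. = FALSE)
  truth <- actual$group[idx]
  ok <- ifelse(truth == "PCOS",
               predictions %in% c("NA", "HA"),
               !is.na(predictions) & predictions == truth)
  mean(ok)
}

#' Pick the reserved triple with the best validation matching rate
#'
#' @param search a `marker_search` result with >= 1 reserved triple.
#' @param validation list of `list(matrix =, labels =)` pairs with coarse
#'   (or fine) labels.
#' @return list with `best` (the winning triple), `rates` (per-triple mean
#'   matching rate) — ties broken by smallest total gene count, then by the
#'   lexicographic order of the concatenated gene ids.
#' @export
select_best <- function(search, validation) {
  if (!length(search$reserved))
    stop("select_best: no reserved triples; increase n_iter", call. = FALSE)
  rank_mats <- lapply(validation, function(v) rank_matrix(v$matrix))
  rates <- vapply(search$reserved, function(triple) {
    mean(vapply(seq_along(validation), function(i) {
      preds <- predict_all(rank_mats[[i]], triple)
      matching_rate(preds, validation[[i]]$labels)
    }, numeric(1)))
  }, numeric(1))
  size <- vapply(search$reserved, function(tr) length(unlist(tr)), integer(1))
  key <- vapply(search$reserved, function(tr)
    paste(sort(unlist(tr)), collapse = ","), character(1))
  ord <- order(-rates, size, key)
  list(best = search$reserved[[ord[1L]]], rates = rates)
}
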