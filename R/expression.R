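#' Expression matrix input/output and validation
#'
#' Matrices are plain numeric matrices with gene ids as row names and sample
#' ids as column names, on a nonnegative tpm scale. Labels are data.frames
#' with columns `sample_id` and `group`; fine labels use groups
#' `{NM, NA, HA}`, coarse validation labels `{NM, PCOS}`.
#'
#' @param x numeric matrix, genes x samples.
#' @return the validated matrix (invisibly for the check).
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene and sample ids", call. = FALSE)
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate gene or sample ids", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("expression values must be finite and >= 0", call. = FALSE)
  invisible(x)
}

#' @param labels data.frame with `sample_id`, `group`.
#' @rdname validate_expression
#' @export
validate_labels <- function(x, labels) {
  if (!all(c("sample_id", "group") %in% names(labels)))
    stop("labels need columns sample_id and group", call. = FALSE)
  missing <- setdiff(colnames(x), labels$sample_id)
  if (length(missing))
    stop("unlabelled samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(labels$sample_id))
    stop("duplicated sample ids in labels", call. = FALSE)
  invisible(labels)
}

#' Read and write gene-by-sample TSV
#'
#' Genes as rows with a `gene` id column; header row of sample ids.
#' @param path file path.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab[[1]]
  validate_expression(x)
  x
}

#' @param x expression matrix.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  out <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample-label TSV
#'
#' Two columns, `sample_id` and `group`. The normoandrogenic group is
#' literally named "NA", so reading must not treat it as a missing value —
#' use these helpers rather than a bare `read.delim()`.
#'
#' @param path file path.
#' @export
read_labels_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character",
                    na.strings = character(0))
}

#' @param labels label data.frame.
#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

group_samples <- function(labels, group) {
  labels$sample_id[labels$group == group]
}

#' Remove genes with low mean expression
#'
#' Genes whose row mean falls strictly below `threshold` (default 0.1 tpm)
#' are removed; a gene with mean exactly at the threshold is retained. The
#' sample set is unchanged.
#'
#' @param x expression matrix.
#' @param threshold mean-tpm cutoff.
#' @return filtered matrix (possibly with zero rows, with a warning).
#' @export
filter_low_expression <- function(x, threshold = 0.1) {
  validate_expression(x)
  keep <- rowMeans(x) >= threshold
  if (!any(keep)) warning("filter_low_expression: no genes retained")
  x[keep, , drop = FALSE]
}

#' Two-group differential test (classic equal-variance t, fold change)
#'
#' Per gene, the two-sided two-sample Student t-test with pooled variance
#' (the classic equal-variance form, not Welch) and the raw-mean fold change
#' mean(A)/mean(B). Zero-variance conventions: equal means give p = 1,
#' unequal means with zero pooled variance give p = 0. A zero denominator
#' mean yields an infinite fold change (treated as exceeding any upper
#' threshold downstream). p-values are deliberately NOT adjusted for
#' multiplicity: downstream calls use the raw p < 0.05 rule.
#'
#' @param x expression matrix.
#' @param labels fine sample labels.
#' @param group_a,group_b group names; fold change is mean(A)/mean(B).
#' @return data.frame with columns `gene`, `p_value`, `fold_change`.
#' @export
differential_test <- function(x, labels, group_a, group_b) {
  validate_expression(x)
  validate_labels(x, labels)
  sa <- intersect(colnames(x), group_samples(labels, group_a))
  sb <- intersect(colnames(x), group_samples(labels, group_b))
  if (length(sa) < 2L || length(sb) < 2L)
    stop("differential_test: each group needs >= 2 samples", call. = FALSE)
  a <- x[, sa, drop = FALSE]
  b <- x[, sb, drop = FALSE]
  na <- length(sa); nb <- length(sb)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tt), df = na + nb - 2, lower.tail = FALSE)
  degen <- se == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  fc <- ma / mb
  data.frame(gene = rownames(x), p_value = unname(p),
             fold_change = unname(fc), stringsAsFactors = FALSE)
}

#' Call differentiated genes from two comparisons
#'
#' A gene is differentiated if in either comparison it has p < `p_cut` and a
#' fold change > `fc_hi` or < `fc_lo` (defaults 0.05, 2, 0.5; all strict).
#'
#' @param d1,d2 [differential_test()] results over the same gene set.
#' @param p_cut,fc_hi,fc_lo thresholds.
#' @return character vector of gene ids.
#' @export
call_differentiated <- function(d1, d2, p_cut = 0.05, fc_hi = 2,
                                fc_lo = 0.5) {
  if (!setequal(d1$gene, d2$gene))
    stop("call_differentiated: gene sets differ", call. = FALSE)
  d2 <- d2[match(d1$gene, d2$gene), ]
  hit <- function(d) d$p_value < p_cut &
    (d$fold_change > fc_hi | d$fold_change < fc_lo)
  d1$gene[hit(d1) | hit(d2)]
}

#' Call subtype-specific genes
#'
#' A gene is specific to `target` (NA or HA) if (a) its mean in the target
#' group strictly exceeds its mean in each of the other two groups (a tie
#' disqualifies), and (b) it passes the differentiated-gene thresholds in
#' BOTH the target-vs-NM and target-vs-other-PCOS comparisons.
#'
#' @param x expression matrix.
#' @param labels fine sample labels covering NM, NA and HA.
#' @param target `"NA"` or `"HA"`.
#' @inheritParams call_differentiated
#' @return character vector of gene ids.
#' @export
call_specific <- function(x, labels, target = c("NA", "HA"), p_cut = 0.05,
                          fc_hi = 2, fc_lo = 0.5) {
  target <- match.arg(target)
  other <- if (target == "NA") "HA" else "NA"
  d_nm <- differential_test(x, labels, target, "NM")
  d_ot <- differential_test(x, labels, target, other)
  hit <- function(d) d$p_value < p_cut &
    (d$fold_change > fc_hi | d$fold_change < fc_lo)
  both <- d_nm$gene[hit(d_nm) & hit(d_ot)[match(d_nm$gene, d_ot$gene)]]

  gm <- sapply(c("NM", "NA", "HA"), function(g)
    rowMeans(x[, intersect(colnames(x), group_samples(labels, g)),
               drop = FALSE]))
  gm <- matrix(gm, nrow = nrow(x),
               dimnames = list(rownames(x), c("NM", "NA", "HA")))
  highest <- rownames(x)[gm[, target] > gm[, other] & gm[, target] > gm[, "NM"]]
  intersect(both, highest)
}

#' Merge expression datasets and quantile-normalize
#'
#' Restricts every matrix to the common gene set, prefixes sample ids with a
#' dataset tag to keep them unique, concatenates, and quantile-normalizes
#' all samples to the pooled reference distribution (every sample ends with
#' the same sorted value vector; within-sample rank order is preserved).
#'
#' @param x_list list of expression matrices.
#' @param labels_list list of matching label data.frames.
#' @param prefixes optional character vector of dataset tags.
#' @return list with `matrix` and `labels`.
#' @export
merge_and_normalize <- function(x_list, labels_list,
                                prefixes = paste0("ds", seq_along(x_list))) {
  stopifnot(length(x_list) >= 1L, length(x_list) == length(labels_list))
  common <- Reduce(intersect, lapply(x_list, rownames))
  if (!length(common))
    stop("merge_and_normalize: no genes shared by all datasets",
         call. = FALSE)
  mats <- vector("list", length(x_list))
  labs <- vector("list", length(x_list))
  for (i in seq_along(x_list)) {
    m <- x_list[[i]][common, , drop = FALSE]
    colnames(m) <- paste(prefixes[i], colnames(m), sep = ".")
    mats[[i]] <- m
    li <- labels_list[[i]]
    li$sample_id <- paste(prefixes[i], li$sample_id, sep = ".")
    labs[[i]] <- li
  }
  merged <- do.call(cbind, mats)
  normalized <- limma::normalizeBetweenArrays(merged, method = "quantile")
  list(matrix = normalized, labels = do.call(rbind, labs))
}
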