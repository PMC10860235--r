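#' Dual-quantile-discretization association rules on expression data (WLAR)
#'
#' Expression values are discretized per gene by within-gene rank, twice:
#' into 4 bins (cuts at the 25/50/75% rank fractions) and into 2 bins (cut
#' at 50%). For an ordered gene pair A -> B and one discretization,
#'
#'   confidence = n(A = B  &  A > min(A)  &  B > min(B)) / n(A > min(A))
#'   support    = n(A > min(A)) + n(B > min(B))
#'
#' where comparisons are on bins and min() is bin 1. Confidence and support
#' are summed over the two discretizations; rules with summed confidence
#' strictly above `conf_cut` (default 0.6) and summed support strictly above
#' `supp_cut` (default 30) are reserved. The direction reads "driver ->
#' driven".
#'
#' @name wlar
NULL

#' Drop samples with fewer than two positive genes
#'
#' @param x expression matrix.
#' @return matrix restricted to samples with >= 2 strictly positive values.
#' @export
drop_sparse_samples <- function(x) {
  validate_expression(x)
  keep <- colSums(x > 0) >= 2L
  if (!any(keep))
    stop("drop_sparse_samples: every sample has < 2 positive genes",
         call. = FALSE)
  x[, keep, drop = FALSE]
}

#' Quantile-discretize each gene across samples
#'
#' Per gene, samples are ranked ascending (average ranks on ties) and the
#' rank fraction rank/n is binned: bin = 1 + number of quantile cuts
#' strictly below the fraction (cuts 0.25/0.5/0.75 for 4 bins, 0.5 for 2).
#' A fraction exactly at a cut falls in the lower bin. Samples at the gene's
#' minimum value are always bin 1 (so a constant gene is all bin 1).
#'
#' @param x expression matrix.
#' @param n_bins 2 or 4.
#' @return integer matrix of bins, same shape as `x`.
#' @export
discretize <- function(x, n_bins = c(4L, 2L)) {
  n_bins <- as.integer(n_bins[1L])
  if (!n_bins %in% c(2L, 4L))
    stop("discretize: n_bins must be 2 or 4", call. = FALSE)
  if (ncol(x) < n_bins)
    stop("discretize: need at least n_bins samples", call. = FALSE)
  cuts <- if (n_bins == 4L) c(0.25, 0.5, 0.75) else 0.5
  n <- ncol(x)
  bins <- t(apply(x, 1L, function(v) {
    frac <- rank(v, ties.method = "average") / n
    b <- 1L + vapply(frac, function(f) sum(cuts < f), integer(1))
    b[v == min(v)] <- 1L
    b
  }))
  dimnames(bins) <- dimnames(x)
  bins
}

#' Confidence of one discretized rule A -> B
#'
#' @param a,b integer bin vectors of equal length (bin 1 = minimum).
#' @return numerator / denominator as defined for [wlar]; 0 when no sample
#'   has A above bin 1.
#' @export
rule_confidence <- function(a, b) {
  if (length(a) != length(b))
    stop("rule_confidence: unequal lengths", call. = FALSE)
  denom <- sum(a > 1L)
  if (denom == 0L) return(0)
  sum(a == b & a > 1L & b > 1L) / denom
}

#' Support of one discretized rule A -> B
#'
#' @inheritParams rule_confidence
#' @return n(A > min) + n(B > min); symmetric in its arguments.
#' @export
rule_support <- function(a, b) {
  if (length(a) != length(b))
    stop("rule_support: unequal lengths", call. = FALSE)
  sum(a > 1L) + sum(b > 1L)
}

#' Compute reserved WLAR rules over candidate gene pairs
#'
#' Both directions of every candidate pair are evaluated independently. By
#' default the candidates are all ordered pairs among the supplied genes;
#' an optional absolute-Spearman prefilter restricts pairs to co-expressed
#' ones for scale.
#'
#' @param x expression matrix (already through [drop_sparse_samples()] if
#'   desired).
#' @param genes genes to pair (default: all rows of `x`).
#' @param conf_cut,supp_cut strict lower thresholds on the summed
#'   confidence and summed support.
#' @param spearman_min if non-`NULL`, only pairs with absolute Spearman
#'   correlation >= this value are evaluated.
#' @return data.frame with columns `lhs`, `rhs`, `conf2`, `conf4`,
#'   `conf_sum`, `supp2`, `supp4`, `supp_sum`.
#' @export
compute_wlar <- function(x, genes = rownames(x), conf_cut = 0.6,
                         supp_cut = 30, spearman_min = NULL) {
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("compute_wlar: genes absent from matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  xs <- x[genes, , drop = FALSE]
  b2 <- discretize(xs, 2L)
  b4 <- discretize(xs, 4L)
  pairs <- expand.grid(lhs = genes, rhs = genes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$lhs != pairs$rhs, , drop = FALSE]
  if (!is.null(spearman_min) && nrow(pairs)) {
    rho <- stats::cor(t(xs), method = "spearman")
    keep <- abs(rho[cbind(pairs$lhs, pairs$rhs)]) >= spearman_min
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs))
    return(data.frame(lhs = character(0), rhs = character(0),
                      conf2 = numeric(0), conf4 = numeric(0),
                      conf_sum = numeric(0), supp2 = numeric(0),
                      supp4 = numeric(0), supp_sum = numeric(0)))
  stats_for <- function(bins) {
    conf <- numeric(nrow(pairs)); supp <- numeric(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- bins[pairs$lhs[i], ]; b <- bins[pairs$rhs[i], ]
      conf[i] <- rule_confidence(a, b)
      supp[i] <- rule_support(a, b)
    }
    list(conf = conf, supp = supp)
  }
  s2 <- stats_for(b2); s4 <- stats_for(b4)
  out <- data.frame(lhs = pairs$lhs, rhs = pairs$rhs,
                    conf2 = s2$conf, conf4 = s4$conf,
                    conf_sum = s2$conf + s4$conf,
                    supp2 = s2$supp, supp4 = s4$supp,
                    supp_sum = s2$supp + s4$supp,
                    stringsAsFactors = FALSE)
  out <- out[out$conf_sum > conf_cut & out$supp_sum > supp_cut, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
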