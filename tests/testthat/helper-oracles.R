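# Independent brute-force oracles. These recompute every quantity from its
# definition with naive loops, sharing no code with the implementation.

# average rank of v[i] computed from scratch (no rank())
oracle_ranks <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}

# quantile discretization from the stated cut semantics
oracle_discretize_row <- function(v, n_bins) {
  cuts <- if (n_bins == 4) c(0.25, 0.5, 0.75) else 0.5
  frac <- oracle_ranks(v) / length(v)
  b <- vapply(frac, function(f) 1 + sum(cuts < f), numeric(1))
  b[v == min(v)] <- 1
  as.integer(b)
}

oracle_confidence <- function(a, b) {
  num <- 0L; den <- 0L
  for (i in seq_along(a)) {
    if (a[i] > 1) {
      den <- den + 1L
      if (b[i] > 1 && a[i] == b[i]) num <- num + 1L
    }
  }
  if (den == 0L) 0 else num / den
}

oracle_support <- function(a, b) sum(a > 1) + sum(b > 1)

# full re-derivation of the reserved dual-discretization rules
oracle_wlar <- function(x, genes, conf_cut = 0.6, supp_cut = 30) {
  rows <- list()
  for (lhs in genes) for (rhs in genes) {
    if (lhs == rhs) next
    cs <- 0; ss <- 0
    for (nb in c(2L, 4L)) {
      a <- oracle_discretize_row(x[lhs, ], nb)
      b <- oracle_discretize_row(x[rhs, ], nb)
      cs <- cs + oracle_confidence(a, b)
      ss <- ss + oracle_support(a, b)
    }
    if (cs > conf_cut && ss > supp_cut)
      rows[[length(rows) + 1L]] <- data.frame(
        lhs = lhs, rhs = rhs, conf_sum = cs, supp_sum = ss,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(lhs = character(0), rhs = character(0),
                      conf_sum = numeric(0), supp_sum = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$lhs, out$rhs), ]
}

# sort/index/average reimplementation of the rank classifier
oracle_predict <- function(sample_values, triple) {
  rk <- oracle_ranks(sample_values)
  names(rk) <- names(sample_values)
  groups <- c("NM", "NA", "HA")
  means <- vapply(groups, function(g) {
    s <- 0
    for (gene in triple[[g]]) s <- s + rk[[gene]]
    s / length(triple[[g]])
  }, numeric(1))
  top <- which(means == max(means))
  if (length(top) == 1L) groups[top] else NA_character_
}

# document-level double loop co-occurrence
oracle_cooccur <- function(docs, a, b) {
  n <- 0L
  for (d in docs)
    if (tolower(a) %in% tolower(d) && tolower(b) %in% tolower(d))
      n <- n + 1L
  n
}

# one-node-at-a-time iterative peeling
oracle_peel <- function(edges, nodes, terminal, min_degree) {
  repeat {
    deg <- vapply(nodes, function(v)
      sum(edges$source == v) + sum(edges$target == v), integer(1))
    victim <- nodes[deg < min_degree & nodes != terminal]
    if (!length(victim)) return(sort(nodes))
    v <- victim[1L]
    nodes <- setdiff(nodes, v)
    edges <- edges[edges$source != v & edges$target != v, , drop = FALSE]
  }
}

# small random expression matrix with gene/sample names
random_matrix <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    x <- matrix(stats::rlnorm(n_genes * n_samples), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    # inject ties and zeros so degenerate paths are exercised
    x[sample(length(x), ceiling(length(x) / 10))] <- 0
    x
  })
  x
}

# labels helper for 3 x n designs
three_group_labels <- function(n_per_group,
                               samples = c(sprintf("NM%d", 1:n_per_group),
                                           sprintf("NA%d", 1:n_per_group),
                                           sprintf("HA%d", 1:n_per_group))) {
  data.frame(sample_id = samples,
             group = rep(c("NM", "NA", "HA"), each = n_per_group),
             stringsAsFactors = FALSE)
}
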