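# Independent brute-force implementations of the DIRAC statistics, written as
# explicit loops over gene pairs, used to pin the vectorized implementations.

oracle_pair_bits <- function(values) {
  m <- length(values)
  bits <- integer(0)
  for (i in seq_len(m - 1)) {
    for (j in seq.int(i + 1, m)) {
      bits <- c(bits, if (values[i] < values[j]) 1L else 0L)
    }
  }
  bits
}

oracle_template <- function(mat) {
  # mat: genes x samples; returns majority template over pair bits
  bits <- apply(mat, 2, oracle_pair_bits)
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  tmpl <- integer(nrow(bits))
  ties <- logical(nrow(bits))
  for (p in seq_len(nrow(bits))) {
    ones <- sum(bits[p, ] == 1)
    zeros <- sum(bits[p, ] == 0)
    if (ones > zeros) tmpl[p] <- 1L
    if (ones == zeros) ties[p] <- TRUE
  }
  list(template = tmpl, tie_mask = ties)
}

oracle_matching_score <- function(values, template) {
  bits <- oracle_pair_bits(values)
  n_match <- 0
  for (p in seq_along(bits)) if (bits[p] == template[p]) n_match <- n_match + 1
  n_match / length(bits)
}

oracle_conservation <- function(mat) {
  tmpl <- oracle_template(mat)$template
  mean(apply(mat, 2, oracle_matching_score, template = tmpl))
}

# Naive per-fold LOOCV with the same tie rule (larger remaining class, A on
# equal sizes), built from the oracle primitives only.
oracle_loocv_accuracy <- function(mat, grp, a, b) {
  n <- ncol(mat)
  correct <- 0
  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    ia <- tr[grp[tr] == a]
    ib <- tr[grp[tr] == b]
    ta <- oracle_template(mat[, ia, drop = FALSE])$template
    tb <- oracle_template(mat[, ib, drop = FALSE])$template
    sa <- oracle_matching_score(mat[, j], ta)
    sb <- oracle_matching_score(mat[, j], tb)
    pred <- if (sa > sb) a else if (sb > sa) b else {
      # tie rule: larger remaining class; equal sizes -> name order
      if (length(ia) != length(ib)) {
        if (length(ia) > length(ib)) a else b
      } else if (a <= b) a else b
    }
    if (pred == grp[j]) correct <- correct + 1
  }
  correct / n
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free values only).
oracle_wilcoxon_enum <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  nA <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nA)])
  mu <- nA * (n + 1) / 2
  splits <- utils::combn(n, nA)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  mean(abs(stats - mu) >= abs(obs - mu))
}

# A random genes-by-samples matrix with dimnames.
random_expr <- function(n_genes, n_samples, prefix = "g") {
  m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# Strictly increasing random transforms for rank-invariance checks.
random_monotone <- function() {
  a <- stats::runif(1, 0.5, 3)
  b <- stats::runif(1, -2, 2)
  pick <- sample(3, 1)
  switch(pick,
         function(x) a * x + b,
         function(x) exp(a * x / (1 + max(abs(x)))) + b,
         function(x) a * x^3 + x + b)
}

# Small labelled two-phenotype matrix for classifier tests.
two_class_labels <- function(m, n_a, a = "A", b = "B") {
  phenotype_labels(rep(c(a, b), c(n_a, ncol(m) - n_a)),
                   phenotype_levels = c(a, b), sample_ids = colnames(m))
}
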