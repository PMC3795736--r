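#' Pairwise ordering bits of one sample over a network
#'
#' For genes `g_1, ..., g_m` (in collection order), the pair-order vector has
#' one bit per pair `(i, j)` with `i < j`, in lexicographic order:
#' bit = 1 iff `expression(g_i) < expression(g_j)`. Equal values give bit 0
#' (strict inequality; ties are measure-zero for continuous data).
#'
#' @param values Numeric vector of one sample's expression over the network
#'   genes, length >= 2.
#' @return Integer 0/1 vector of length `m (m - 1) / 2`.
#' @export
pair_order <- function(values) {
  m <- length(values)
  if (m < 2) stop("pair order needs at least two genes")
  idx <- pair_indices(m)
  as.integer(values[idx$i] < values[idx$j])
}

# Lexicographic pair indices (1,2),(1,3),...,(m-1,m).
pair_indices <- function(m) {
  i <- rep.int(seq_len(m - 1), rev(seq_len(m - 1)))
  j <- unlist(lapply(seq_len(m - 1), function(k) seq.int(k + 1, m)), use.names = FALSE)
  list(i = i, j = j)
}

# Pair-order bit matrix (pairs x samples) for a network's genes; genes are
# intersected with the matrix in collection order. Returns NULL (with a
# warning) when fewer than 2 genes are present.
pair_order_matrix <- function(m, genes, network = "<network>") {
  present <- genes[genes %in% rownames(m)]
  if (length(present) < 2) {
    warning("network ", network, " has fewer than 2 genes in the data; skipped")
    return(NULL)
  }
  sub <- m[present, , drop = FALSE]
  idx <- pair_indices(length(present))
  bits <- (sub[idx$i, , drop = FALSE] < sub[idx$j, , drop = FALSE]) * 1
  rownames(bits) <- paste(present[idx$i], present[idx$j], sep = "<")
  attr(bits, "genes") <- present
  bits
}

#' Majority rank template of a phenotype over a network
#'
#' Per pair, the template bit is the strict-majority pair-order bit across the
#' phenotype's samples; pairs split exactly 50/50 are ties and carry template
#' bit 0 with `tie_mask = TRUE`.
#'
#' @param m Expression matrix restricted to (or covering) the phenotype's
#'   samples; all columns are used.
#' @param genes Network gene identifiers (collection order).
#' @param network Network name, for messages.
#' @return List with `genes` (those present), `template` (0/1 integer
#'   vector), `tie_mask` (logical), `n_samples`.
#' @export
build_rank_template <- function(m, genes, network = "<network>") {
  if (ncol(m) < 1) stop("cannot build a template from an empty phenotype")
  bits <- pair_order_matrix(m, genes, network)
  if (is.null(bits)) return(NULL)
  cnt <- rowSums(bits)
  n <- ncol(bits)
  list(genes = attr(bits, "genes"),
       template = as.integer(2 * cnt > n),
       tie_mask = unname(2 * cnt == n),
       n_samples = n)
}

#' Rank matching score of sample(s) against a template
#'
#' Fraction of pairs whose sample bit equals the template bit, over all pairs
#' (tied template pairs count in the denominator).
#'
#' @param bits 0/1 vector (one sample) or pairs-by-samples matrix from
#'   [pair_order_matrix()].
#' @param template A [build_rank_template()] result, or a bare 0/1 vector.
#' @return Scalar (vector input) or per-sample named vector, in `[0, 1]`.
#' @export
rank_matching_score <- function(bits, template) {
  tmpl <- if (is.list(template)) template$template else template
  if (is.matrix(bits)) {
    if (nrow(bits) != length(tmpl)) stop("pair length mismatch between sample and template")
    colMeans(bits == tmpl)
  } else {
    if (length(bits) != length(tmpl)) stop("pair length mismatch between sample and template")
    mean(bits == tmpl)
  }
}

#' Rank conservation index of a phenotype for one network
#'
#' Mean rank matching score of the phenotype's samples against their own
#' majority template. Always >= 0.5 against the own template (majority
#' property), up to 1 for perfectly consistent ordering.
#'
#' @inheritParams build_rank_template
#' @return Scalar index, or `NA` when the network has < 2 genes present.
#' @export
conservation_index <- function(m, genes, network = "<network>") {
  tmpl <- build_rank_template(m, genes, network)
  if (is.null(tmpl)) return(NA_real_)
  bits <- pair_order_matrix(m, genes, network)
  mean(rank_matching_score(bits, tmpl))
}

#' Conservation indices for every (network, phenotype)
#'
#' @param m Expression matrix (rank layer by convention; any layer works —
#'   all DIRAC statistics depend only on within-sample orderings).
#' @param labels [phenotype_labels()] for the samples of `m`.
#' @param networks Named list of gene-id vectors (e.g. [generate_networks()]
#'   or [read_gmt()]).
#' @param min_samples Minimum samples required per phenotype (default 2).
#' @return Matrix of indices, retained networks x phenotypes, with attribute
#'   `scores`: per-network list of per-sample matching-score vectors (for
#'   auditing). Networks with < 2 genes present are dropped with a warning.
#' @export
conservation_table <- function(m, labels, networks, min_samples = 2L) {
  lab <- align_labels(m, labels)
  phen <- levels(droplevels(lab))
  sizes <- table(lab)[phen]
  if (any(sizes < min_samples)) {
    stop("phenotype(s) with fewer than ", min_samples, " samples: ",
         paste(phen[sizes < min_samples], collapse = ", "))
  }
  rows <- list()
  scores <- list()
  for (nm in names(networks)) {
    bits <- withCallingHandlers(
      pair_order_matrix(m, networks[[nm]], nm),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(bits)) next
    idx <- numeric(length(phen))
    names(idx) <- phen
    sc <- list()
    for (p in phen) {
      pb <- bits[, lab == p, drop = FALSE]
      cnt <- rowSums(pb)
      tmpl <- as.integer(2 * cnt > ncol(pb))
      sc[[p]] <- colMeans(pb == tmpl)
      idx[p] <- mean(sc[[p]])
    }
    rows[[nm]] <- idx
    scores[[nm]] <- sc
  }
  if (!length(rows)) stop("no network has >= 2 genes present in the data")
  if (length(rows) < length(networks)) {
    message(sprintf("dropped %d network(s) with < 2 genes present",
                    length(networks) - length(rows)))
  }
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  out
}

#' Global dysregulation summary for a phenotype
#'
#' Unweighted mean of the rank conservation indices over all retained
#' networks; a single number estimating how consistently the phenotype's
#' networks are ordered (lower = more dysregulated).
#'
#' @param conservation Matrix from [conservation_table()].
#' @param phenotype Column to summarize; omit for all phenotypes.
#' @return Named numeric vector (or scalar for one phenotype).
#' @export
global_dysregulation <- function(conservation, phenotype = NULL) {
  if (is.null(phenotype)) return(colMeans(conservation))
  colMeans(conservation[, phenotype, drop = FALSE])[phenotype]
}

#' Differentially regulated networks between two phenotypes
#'
#' For each network, the observed difference in rank conservation indices
#' `delta = index(a) - index(b)`. Significance comes from a permutation null:
#' the a/b labels are permuted among the pooled samples of the two phenotypes
#' (the same permutation applied to every network), templates and indices are
#' recomputed, and the per-network p-value is the add-one-smoothed fraction of
#' null absolute differences at least as large as the observed one. By
#' default the null pools all networks and permutations (`null = "pooled"`,
#' the fraction-at-random formulation); `null = "per_network"` restricts each
#' network to its own null row.
#'
#' @inheritParams conservation_table
#' @param a,b Phenotype labels to compare.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param null `"pooled"` or `"per_network"`.
#' @return Data frame (one row per retained network, sorted by decreasing
#'   `|delta|`): `network`, `index_a`, `index_b`, `delta`, `direction`, `p`.
#'   Attributes: `n_perm`, `null`, `phenotypes`.
#' @export
differential_regulation <- function(m, labels, networks, a, b,
                                    n_perm = 1000L, seed = 1L,
                                    null = c("pooled", "per_network")) {
  null <- match.arg(null)
  if (n_perm < 1) stop("n_perm must be >= 1")
  lab <- align_labels(m, labels)
  keep <- lab %in% c(a, b)
  if (!any(lab == a) || !any(lab == b)) stop("both phenotypes must be present")
  sub <- m[, keep, drop = FALSE]
  grp <- droplevels(lab[keep])
  nA <- sum(grp == a)
  nB <- sum(grp == b)
  n <- nA + nB
  if (nA < 2 || nB < 2) stop("each phenotype needs >= 2 samples")

  in_a <- as.numeric(grp == a)
  ZA <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      z <- numeric(n)
      z[sample.int(n, nA)] <- 1
      z
    }, numeric(n))
  })

  res <- list()
  null_abs <- list()
  for (nm in names(networks)) {
    bits <- withCallingHandlers(
      pair_order_matrix(sub, networks[[nm]], nm),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(bits)) next
    obs <- split_deltas(bits, matrix(in_a, ncol = 1), nA, nB)
    nulls <- split_deltas(bits, ZA, nA, nB)
    res[[nm]] <- c(obs_delta = obs$delta,
                   index_a = obs$index_a, index_b = obs$index_b)
    null_abs[[nm]] <- abs(nulls$delta)
  }
  if (!length(res)) stop("no network has >= 2 genes present in the data")
  tab <- do.call(rbind, res)
  obs_abs <- abs(tab[, "obs_delta"])
  p <- if (null == "pooled") {
    pool <- unlist(null_abs, use.names = FALSE)
    vapply(obs_abs, function(d) (1 + sum(pool >= d)) / (1 + length(pool)),
           numeric(1))
  } else {
    mapply(function(d, nl) (1 + sum(nl >= d)) / (1 + length(nl)),
           obs_abs, null_abs)
  }
  out <- data.frame(
    network = rownames(tab),
    index_a = tab[, "index_a"],
    index_b = tab[, "index_b"],
    delta = tab[, "obs_delta"],
    direction = ifelse(tab[, "obs_delta"] > 0, paste("more conserved in", a),
                ifelse(tab[, "obs_delta"] < 0, paste("more conserved in", b),
                       "none")),
    p = p,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$delta), out$network), ]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "null") <- null
  attr(out, "phenotypes") <- c(a = a, b = b)
  out
}

# Conservation-index differences for many A/B splits at once.
# bits: pairs x samples 0/1 matrix; ZA: samples x K assignment matrix
# (1 = group A); nA, nB group sizes. Returns per-split indices and deltas.
# Template bits and matching agreements are computed with BLAS products:
# agree[k, j] = P - sum(T_k) - sum(bits_j) + 2 * T_k . bits_j.
split_deltas <- function(bits, ZA, nA, nB) {
  P <- nrow(bits)
  cB <- colSums(bits)
  idx_for <- function(Z, ngrp) {
    cnt <- bits %*% Z                       # pairs x K
    TT <- (2 * cnt > ngrp) * 1
    agree <- sweep(2 * crossprod(TT, bits), 1, P - colSums(TT), "+")
    agree <- sweep(agree, 2, cB, "-")       # K x samples
    rowSums(agree * t(Z)) / (P * ngrp)
  }
  index_a <- idx_for(ZA, nA)
  index_b <- idx_for(1 - ZA, nB)
  list(index_a = index_a, index_b = index_b, delta = index_a - index_b)
}

#' One-way ANOVA on conservation indices across phenotypes
#'
#' Unit of analysis: the per-network conservation index, grouped by
#' phenotype. Tests whether mean rank conservation differs across phenotypes.
#'
#' @param conservation Matrix from [conservation_table()] (>= 2 networks,
#'   >= 2 phenotypes).
#' @return List with `F` and `p`.
#' @export
anova_conservation <- function(conservation) {
  if (nrow(conservation) < 2 || ncol(conservation) < 2) {
    stop("need >= 2 networks and >= 2 phenotypes")
  }
  d <- data.frame(index = as.vector(conservation),
                  phenotype = factor(rep(colnames(conservation),
                                         each = nrow(conservation))))
  if (stats::var(d$index) == 0) stop("zero total variance: ANOVA is degenerate")
  an <- stats::anova(stats::lm(index ~ phenotype, data = d))
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1])
}

#' Pairwise paired t-tests on conservation indices
#'
#' For each phenotype pair, a paired t-test across networks (the same
#' networks measured in both phenotypes). Identical columns give t = 0 and
#' p = 1; a constant nonzero shift has zero variance of differences (t
#' unbounded) and is flagged degenerate with p = `NA`.
#'
#' @param conservation Matrix from [conservation_table()] (>= 2 networks).
#' @return List of symmetric matrices: `p`, `statistic`, `degenerate`.
#' @export
pairwise_t_tests <- function(conservation) {
  if (nrow(conservation) < 2) stop("need >= 2 shared networks")
  phen <- colnames(conservation)
  k <- length(phen)
  p <- s <- matrix(NA_real_, k, k, dimnames = list(phen, phen))
  dg <- matrix(FALSE, k, k, dimnames = list(phen, phen))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    d <- conservation[, i] - conservation[, j]
    if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
      if (all(d == 0)) {
        p[i, j] <- p[j, i] <- 1
        s[i, j] <- s[j, i] <- 0
      } else {
        # constant nonzero shift: zero variance of differences, t unbounded
        dg[i, j] <- dg[j, i] <- TRUE
      }
    } else {
      tt <- tryCatch(
        stats::t.test(conservation[, i], conservation[, j], paired = TRUE),
        error = function(e) NULL)
      if (is.null(tt)) {
        dg[i, j] <- dg[j, i] <- TRUE
      } else {
        p[i, j] <- p[j, i] <- tt$p.value
        s[i, j] <- s[j, i] <- unname(tt$statistic)
      }
    }
  }
  list(p = p, statistic = s, degenerate = dg)
}

#' Exact binomial test for the direction of dysregulation
#'
#' Given `n` significantly differentially regulated networks of which `k`
#' are more dysregulated in the higher grade, the one-sided exact binomial
#' tail probability `P(X >= k | n, 1/2)`.
#'
#' @param k Number of networks more dysregulated in the higher grade.
#' @param n Total significant networks.
#' @return One-sided p-value.
#' @export
binomial_direction_test <- function(k, n) {
  if (n == 0) stop("binomial direction test undefined for n = 0")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
}
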