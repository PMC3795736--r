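#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Exact enumeration when the smaller group has at most 8 values and the
#' pooled values are tie-free; otherwise the normal approximation with tie
#' and continuity corrections.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

# Row-wise two-sided Wilcoxon rank-sum p-values: X is genes x samples, idx_a /
# idx_b index the two groups. Normal approximation with tie + continuity
# corrections, vectorized across rows (per-row exact fallback for small
# groups). Rows whose pooled values are all tied get p = 1.
row_wilcoxon <- function(X, idx_a, idx_b) {
  nA <- length(idx_a)
  nB <- length(idx_b)
  if (nA < 1 || nB < 1) stop("both groups must be non-empty")
  if (min(nA, nB) <= 8) {
    return(vapply(seq_len(nrow(X)),
                  function(g) wilcoxon_rank_sum(X[g, idx_a], X[g, idx_b]),
                  numeric(1)))
  }
  Y <- X[, c(idx_a, idx_b), drop = FALSE]
  G <- nrow(Y)
  n <- nA + nB
  # rank all rows in one call: a per-row offset larger than the value range
  # makes rows non-overlapping, so within-row midranks are preserved
  off <- (seq_len(G) - 1) * (diff(range(Y)) + 1)
  R <- matrix(rank(as.vector(Y + off)), G, n) - (seq_len(G) - 1) * n
  W <- rowSums(R[, seq_len(nA), drop = FALSE]) - nA * (nA + 1) / 2
  # per-row tie term sum(t^3 - t) via one global sort (rows made disjoint)
  v <- as.vector(Y + off)
  o <- order(v)
  rv <- v[o]
  new_run <- c(TRUE, rv[-1] != rv[-length(rv)])
  run_id <- cumsum(new_run)
  len <- tabulate(run_id)
  run_row <- ((o[new_run] - 1) %% G) + 1
  tie_term <- numeric(G)
  agg <- rowsum(len^3 - len, run_row)
  tie_term[as.integer(rownames(agg))] <- agg[, 1]
  sigma2 <- (nA * nB / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - nA * nB / 2
  sigma <- sqrt(sigma2)
  zc <- (z - sign(z) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(zc))
  p[sigma == 0] <- 1
  pmin(p, 1)
}

#' Differentially expressed genes for each adjacent pair of grades
#'
#' Wilcoxon rank-sum tests on the within-array rank layer for the four
#' adjacent-grade comparisons (Normal vs G2, G2 vs G3, G3 vs pGBM,
#' G3 vs sGBM), each Bonferroni-corrected over all tested genes: a gene is
#' significant when `p < alpha / n_genes`.
#'
#' @param m Rank-layer expression matrix.
#' @param labels [phenotype_labels()] containing all five grades.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Named list of four DEG sets, each a list with `pair`, `p` (named
#'   per-gene vector), `significant` (logical), `alpha`, `n_genes`.
#' @export
adjacent_degs <- function(m, labels, alpha = 0.05) {
  lab <- align_labels(m, labels)
  need <- c("Normal", "G2", "G3", "pGBM", "sGBM")
  missing <- setdiff(need, as.character(unique(lab)))
  if (length(missing)) {
    stop("phenotype(s) missing from the cohort: ", paste(missing, collapse = ", "))
  }
  pairs <- list(c("Normal", "G2"), c("G2", "G3"), c("G3", "pGBM"), c("G3", "sGBM"))
  ng <- nrow(m)
  out <- lapply(pairs, function(pr) {
    ia <- which(lab == pr[1])
    ib <- which(lab == pr[2])
    p <- row_wilcoxon(m, ia, ib)
    names(p) <- rownames(m)
    list(pair = pr, p = p, significant = p < alpha / ng,
         alpha = alpha, n_genes = ng)
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  out
}

#' Monotonically changing genes across the grade ordering
#'
#' Candidates are the genes significant in all four adjacent-grade DEG sets.
#' A candidate is *increasing* when its per-phenotype mean within-array rank
#' strictly increases Normal < G2 < G3 < pGBM and G3 < sGBM (both
#' glioblastoma subtypes must continue the trend past G3; their relative
#' order is unconstrained since they share a grade); *decreasing* is the
#' mirror. Candidates violating both patterns are reported with direction
#' `"none"`.
#'
#' @param deg_sets Output of [adjacent_degs()].
#' @param m Rank-layer expression matrix.
#' @param labels [phenotype_labels()].
#' @return Data frame: `gene`, `direction`, and `mean_rank_<phenotype>`
#'   columns, sorted by gene id.
#' @export
find_monotonic <- function(deg_sets, m, labels) {
  lab <- align_labels(m, labels)
  candidates <- Reduce(intersect,
                       lapply(deg_sets, function(d) names(d$p)[d$significant]))
  phen <- c("Normal", "G2", "G3", "pGBM", "sGBM")
  mr <- vapply(phen, function(p) {
    if (length(candidates)) {
      rowMeans(m[candidates, lab == p, drop = FALSE])
    } else numeric(0)
  }, numeric(length(candidates)))
  if (length(candidates) == 1) mr <- matrix(mr, 1, dimnames = list(candidates, phen))
  direction <- if (length(candidates)) {
    inc <- mr[, "Normal"] < mr[, "G2"] & mr[, "G2"] < mr[, "G3"] &
      mr[, "G3"] < mr[, "pGBM"] & mr[, "G3"] < mr[, "sGBM"]
    dec <- mr[, "Normal"] > mr[, "G2"] & mr[, "G2"] > mr[, "G3"] &
      mr[, "G3"] > mr[, "pGBM"] & mr[, "G3"] > mr[, "sGBM"]
    ifelse(inc, "increasing", ifelse(dec, "decreasing", "none"))
  } else character(0)
  out <- data.frame(gene = candidates, direction = direction,
                    stringsAsFactors = FALSE)
  for (p in phen) out[[paste0("mean_rank_", p)]] <- if (length(candidates)) mr[, p] else numeric(0)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsampling robustness of the monotonic gene calls
#'
#' Repeatedly redraws a fraction of each phenotype's samples (without
#' replacement), reruns the DEG + monotonicity pipeline, and counts how often
#' each full-data monotonic gene recurs with the same direction. Genes whose
#' support reaches `min_support` are flagged high-confidence.
#'
#' @inheritParams find_monotonic
#' @param n_rep Number of subsampling replicates (default 1000).
#' @param frac Fraction of each phenotype drawn per replicate (default 0.8;
#'   sizes are rounded up).
#' @param min_support Minimum recurrence count for the high-confidence flag
#'   (default 500; scale together with `n_rep`).
#' @param seed Integer seed.
#' @param alpha Significance level passed to [adjacent_degs()].
#' @param report Optional precomputed full-data [find_monotonic()] report.
#' @return The full-data report restricted to monotonic genes, with `support`
#'   and `high_confidence` columns; attributes `n_rep`, `frac`, `min_support`.
#' @export
subsample_robustness <- function(m, labels, n_rep = 1000L, frac = 0.8,
                                 min_support = 500L, seed = 1L, alpha = 0.05,
                                 report = NULL) {
  lab <- align_labels(m, labels)
  sizes <- table(droplevels(lab))
  take <- ceiling(frac * sizes)
  if (any(take < 2)) {
    stop("subsampling fraction leaves fewer than 2 samples for: ",
         paste(names(sizes)[take < 2], collapse = ", "))
  }
  if (is.null(report)) {
    report <- find_monotonic(adjacent_degs(m, labels, alpha), m, labels)
  }
  mono <- report[report$direction != "none", , drop = FALSE]
  support <- stats::setNames(integer(nrow(mono)), mono$gene)
  if (n_rep > 0 && nrow(mono) > 0) {
    with_seed(seed, {
      for (r in seq_len(n_rep)) {
        keep <- unlist(lapply(names(sizes), function(p) {
          ids <- names(lab)[lab == p]
          sample(ids, take[[p]])
        }), use.names = FALSE)
        sm <- m[, keep, drop = FALSE]
        sl <- lab[keep]
        rep_report <- find_monotonic(adjacent_degs(sm, sl, alpha), sm, sl)
        hit <- match(mono$gene, rep_report$gene)
        same <- !is.na(hit) & rep_report$direction[hit] == mono$direction
        support[same] <- support[same] + 1L
      }
    })
  }
  mono$support <- as.integer(support)
  mono$high_confidence <- n_rep > 0 & mono$support >= min_support
  rownames(mono) <- NULL
  attr(mono, "n_rep") <- n_rep
  attr(mono, "frac") <- frac
  attr(mono, "min_support") <- min_support
  mono
}

#' Permutation test for the directionality of monotonic genes
#'
#' Permutes all phenotype labels jointly, reruns the DEG + monotonicity
#' pipeline, and compares the observed counts of increasing and decreasing
#' genes with the null counts:
#' `p = (1 + #(null count >= observed)) / (n_perm + 1)` per direction.
#'
#' @inheritParams subsample_robustness
#' @param n_perm Number of label permutations (default 1000).
#' @return List: `n_increasing`, `n_decreasing` (observed),
#'   `p_increasing`, `p_decreasing`, and `null_counts` (n_perm x 2 matrix).
#' @export
directionality_test <- function(m, labels, n_perm = 1000L, seed = 1L,
                                alpha = 0.05) {
  lab <- align_labels(m, labels)
  obs <- find_monotonic(adjacent_degs(m, lab, alpha), m, lab)
  n_inc <- sum(obs$direction == "increasing")
  n_dec <- sum(obs$direction == "decreasing")
  null_counts <- matrix(NA_integer_, n_perm, 2,
                        dimnames = list(NULL, c("increasing", "decreasing")))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      pl <- lab
      names(pl) <- names(lab)[sample.int(length(lab))]
      pl <- pl[names(lab)]
      rep_report <- find_monotonic(adjacent_degs(m, pl, alpha), m, pl)
      null_counts[k, ] <- c(sum(rep_report$direction == "increasing"),
                            sum(rep_report$direction == "decreasing"))
    }
  })
  list(n_increasing = n_inc, n_decreasing = n_dec,
       p_increasing = (1 + sum(null_counts[, 1] >= n_inc)) / (n_perm + 1),
       p_decreasing = (1 + sum(null_counts[, 2] >= n_dec)) / (n_perm + 1),
       null_counts = null_counts)
}
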