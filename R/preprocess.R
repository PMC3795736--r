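#' Remove probes with zero present calls in any phenotype
#'
#' A probe is retained only if it has at least one present call in every
#' phenotype of the cohort; probes silent across a whole phenotype are
#' removed. The number removed is reported via `message()` and recorded in the
#' `n_removed` attribute.
#'
#' @param probes A [probe_layer()].
#' @param labels [phenotype_labels()] covering every sample of the layer.
#' @return Filtered `probe_layer`.
#' @export
filter_probes_by_present_call <- function(probes, labels) {
  stopifnot(inherits(probes, "probe_layer"))
  lab <- align_labels(probes$intensity, labels)
  phen <- levels(droplevels(lab))
  present_per_phen <- vapply(phen, function(p) {
    rowSums(probes$calls[, lab == p, drop = FALSE]) > 0
  }, logical(nrow(probes$calls)))
  keep <- rowSums(present_per_phen) == length(phen)
  n_removed <- sum(!keep)
  message(sprintf("present-call filter: removed %d of %d probes", n_removed,
                  length(keep)))
  kept_ids <- rownames(probes$intensity)[keep]
  out <- probe_layer(probes$map[probes$map$probe %in% kept_ids, , drop = FALSE],
                     probes$intensity[keep, , drop = FALSE],
                     probes$calls[keep, , drop = FALSE])
  attr(out, "n_removed") <- n_removed
  out
}

#' Collapse probe intensities to a gene-level expression matrix
#'
#' Probes mapping to more than one gene are dropped (ambiguous); for genes
#' measured by several probes, each cell takes the per-sample maximum
#' intensity over that gene's probes.
#'
#' @param probes A [probe_layer()].
#' @return Intensity-layer [expression_matrix()], one row per gene with at
#'   least one surviving single-gene probe.
#' @export
collapse_probes_to_genes <- function(probes) {
  stopifnot(inherits(probes, "probe_layer"))
  map <- probes$map
  multi <- unique(map$probe[duplicated(map$probe)])
  map <- map[!map$probe %in% multi, , drop = FALSE]
  if (nrow(map) == 0) stop("no single-gene probes survive the collapse")
  genes <- sort(unique(map$gene))
  vals <- matrix(NA_real_, length(genes), ncol(probes$intensity),
                 dimnames = list(genes, colnames(probes$intensity)))
  for (gn in genes) {
    rows <- map$probe[map$gene == gn]
    sub <- probes$intensity[rows, , drop = FALSE]
    vals[gn, ] <- if (nrow(sub) == 1) sub[1, ] else apply(sub, 2, max)
  }
  expression_matrix(vals, layer = "intensity")
}

#' Replace intensities by within-array ranks
#'
#' Each sample (column) is ranked independently, ascending (1 = lowest
#' intensity); ties receive average (mid) ranks, so each column sums to
#' `n (n + 1) / 2`.
#'
#' @param m Intensity-layer [expression_matrix()].
#' @return Rank-layer [expression_matrix()] of the same shape.
#' @export
rank_transform <- function(m) {
  if (!is.numeric(m) || anyNA(m)) stop("intensity matrix must be numeric with no NA")
  r <- apply(m, 2, rank)
  dimnames(r) <- dimnames(m)
  expression_matrix(r, layer = "rank")
}

#' Mean sample-to-sample Pearson correlation
#'
#' The correlation QC statistic: the mean of off-diagonal Pearson correlations
#' over all unordered sample pairs. Zero-variance samples cannot be
#' correlated; pairs involving them are excluded with a warning.
#'
#' @param m Expression matrix (either layer), at least two samples.
#' @return Scalar in `[-1, 1]`.
#' @export
mean_sample_correlation <- function(m) {
  if (ncol(m) < 2) stop("need at least two samples")
  sds <- apply(m, 2, stats::sd)
  ok <- sds > 0
  if (any(!ok)) {
    warning("excluding zero-variance sample(s): ",
            paste(colnames(m)[!ok], collapse = ", "))
  }
  if (sum(ok) < 2) stop("fewer than two samples with nonzero variance")
  cm <- stats::cor(m[, ok, drop = FALSE])
  mean(cm[upper.tri(cm)])
}
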