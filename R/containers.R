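#' Construct a genes-by-samples expression matrix
#'
#' Light wrapper around a numeric matrix that records which layer the values
#' live on: raw (post-normalization) intensities, or within-array ranks.
#' Row names are gene identifiers, column names are sample identifiers; both
#' must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param layer Either `"intensity"` or `"rank"`.
#' @return The matrix with a `layer` attribute.
#' @export
expression_matrix <- function(values, layer = c("intensity", "rank")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (layer == "rank") {
    n <- nrow(values)
    target <- n * (n + 1) / 2
    sums <- colSums(values)
    if (any(abs(sums - target) > 1e-6 * max(1, target))) {
      stop("rank layer columns must be midranks of 1..n_genes")
    }
  }
  attr(values, "layer") <- layer
  values
}

#' Layer of an expression matrix
#' @param m Matrix created by [expression_matrix()] (or any matrix carrying a
#'   `layer` attribute).
#' @return `"intensity"`, `"rank"`, or `NA` if untagged.
#' @export
expr_layer <- function(m) {
  l <- attr(m, "layer")
  if (is.null(l)) NA_character_ else l
}

#' Construct phenotype labels for a cohort
#'
#' @param labels Character vector or factor of phenotype labels, named by
#'   sample identifier (or `sample_ids` supplied separately).
#' @param phenotype_levels Ordered universe of phenotypes, lowest grade first.
#'   Defaults to the five-grade astrocytoma ordering.
#' @param sample_ids Optional sample identifiers when `labels` is unnamed.
#' @return Named factor with the ordered phenotype levels.
#' @export
phenotype_labels <- function(labels,
                             phenotype_levels = c("Normal", "G2", "G3", "pGBM", "sGBM"),
                             sample_ids = NULL) {
  if (!is.null(sample_ids)) names(labels) <- sample_ids
  if (is.null(names(labels))) stop("labels must carry sample identifiers")
  if (anyDuplicated(names(labels))) stop("duplicate sample identifiers in labels")
  bad <- setdiff(unique(as.character(labels)), phenotype_levels)
  if (length(bad)) {
    stop("unknown phenotype label(s): ", paste(bad, collapse = ", "))
  }
  out <- factor(as.character(labels), levels = phenotype_levels)
  names(out) <- names(labels)
  out
}

# Check that every sample of `m` has a label; returns labels aligned to columns.
align_labels <- function(m, labels) {
  missing <- setdiff(colnames(m), names(labels))
  if (length(missing)) {
    stop("sample(s) without phenotype label: ", paste(missing, collapse = ", "))
  }
  labels[colnames(m)]
}

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' Every stochastic stage draws from a seed deterministically derived from the
#' single top-level run seed and the stage name, so changing one stage's
#' parameters never perturbs another stage's draws.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1) + 1)
}
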