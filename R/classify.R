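#' Two-template DIRAC classification of one network (apparent)
#'
#' Builds a rank template per phenotype from all of its samples, then assigns
#' every pooled sample to the phenotype whose template it matches more
#' closely. Equal matching scores go to the larger class (ties recorded);
#' with equal class sizes they go to the phenotype whose name sorts first, a
#' deterministic rule that is symmetric under swapping `a` and `b`.
#'
#' @param m Expression matrix.
#' @param labels [phenotype_labels()].
#' @param genes Network gene identifiers.
#' @param a,b The two phenotypes; `a` is treated as the positive class for
#'   sensitivity.
#' @param network Network name, for messages.
#' @param balanced If `TRUE`, report balanced accuracy
#'   `(sensitivity + specificity) / 2` as `accuracy`; default is raw accuracy
#'   over all pooled samples.
#' @return List of class `dirac_classification`: `accuracy`, `sensitivity`,
#'   `specificity`, `confusion`, `predicted` (named vector), `n_ties`,
#'   `group_sizes`; or `NULL` when the network has < 2 usable genes.
#' @export
classify_samples <- function(m, labels, genes, a, b, network = "<network>",
                             balanced = FALSE) {
  lab <- align_labels(m, labels)
  keep <- lab %in% c(a, b)
  sub <- m[, keep, drop = FALSE]
  grp <- factor(as.character(lab[keep]), levels = c(a, b))
  if (sum(grp == a) < 2 || sum(grp == b) < 2) {
    stop("each phenotype needs >= 2 samples")
  }
  bits <- pair_order_matrix(sub, genes, network)
  if (is.null(bits)) return(NULL)
  in_a <- grp == a
  ta <- template_from_counts(rowSums(bits[, in_a, drop = FALSE]), sum(in_a))
  tb <- template_from_counts(rowSums(bits[, !in_a, drop = FALSE]), sum(!in_a))
  sa <- rank_matching_score(bits, ta)
  sb <- rank_matching_score(bits, tb)
  tie_to_a <- tie_goes_to_a(sum(in_a), sum(!in_a), a, b)
  pred_a <- ifelse(sa == sb, tie_to_a, sa > sb)
  predicted <- stats::setNames(ifelse(pred_a, a, b), colnames(sub))
  finish_classification(predicted, grp, a, b, n_ties = sum(sa == sb),
                        balanced = balanced)
}

template_from_counts <- function(cnt, n) as.integer(2 * cnt > n)

# Prediction tie rule: larger class wins; equal sizes fall back to phenotype
# name order so the rule is symmetric under label swap.
tie_goes_to_a <- function(nA, nB, a, b) {
  if (nA != nB) nA > nB else a <= b
}

finish_classification <- function(predicted, grp, a, b, n_ties, balanced) {
  truth <- as.character(grp)
  tp <- sum(predicted == a & truth == a)
  fn <- sum(predicted == b & truth == a)
  tn <- sum(predicted == b & truth == b)
  fp <- sum(predicted == a & truth == b)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- if (balanced) (sens + spec) / 2 else (tp + tn) / length(truth)
  structure(list(
    accuracy = acc, sensitivity = sens, specificity = spec,
    confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                       dimnames = list(predicted = c(a, b), truth = c(a, b))),
    predicted = predicted, n_ties = n_ties,
    group_sizes = stats::setNames(c(tp + fn, tn + fp), c(a, b)),
    balanced = balanced), class = "dirac_classification")
}

#' Permutation significance and FDR of network classification accuracies
#'
#' The null distribution pools the apparent accuracies of every network under
#' each of `n_perm` label permutations (each permutation reassigns the a/b
#' labels among the pooled samples, identically for all networks). Per
#' network, `p = (1 + #null >= observed) / (1 + pooled size)`. The FDR at a
#' network's accuracy cutoff is the expected number of null positives at that
#' cutoff (pooled null count / `n_perm`) divided by the observed number of
#' networks at or above it, clipped to `[0, 1]`; Benjamini-Hochberg on the
#' permutation p-values is available as an option.
#'
#' @inheritParams classify_samples
#' @param networks Named list of gene-id vectors.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param fdr_method `"pooled"` (expected-false-positive ratio) or `"BH"`.
#' @return Data frame per retained network: `network`, `accuracy`, `p`,
#'   `fdr`, sorted by decreasing accuracy.
#' @export
classification_significance <- function(m, labels, networks, a, b,
                                        n_perm = 1000L, seed = 1L,
                                        fdr_method = c("pooled", "BH")) {
  fdr_method <- match.arg(fdr_method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  lab <- align_labels(m, labels)
  keep <- lab %in% c(a, b)
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
  obs <- numeric(0)
  null_acc <- list()
  for (nm in names(networks)) {
    bits <- withCallingHandlers(
      pair_order_matrix(sub, networks[[nm]], nm),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(bits)) next
    tie_a <- tie_goes_to_a(nA, nB, a, b)
    obs[nm] <- split_accuracies(bits, matrix(in_a, ncol = 1), nA, nB, tie_a)
    null_acc[[nm]] <- split_accuracies(bits, ZA, nA, nB, tie_a)
  }
  if (!length(obs)) stop("no network has >= 2 genes present in the data")
  pool <- unlist(null_acc, use.names = FALSE)
  p <- vapply(obs, function(x) (1 + sum(pool >= x)) / (1 + length(pool)),
              numeric(1))
  fdr <- if (fdr_method == "BH") {
    stats::p.adjust(p, "BH")
  } else {
    vapply(obs, function(t) {
      efp <- sum(pool >= t) / n_perm
      min(1, efp / sum(obs >= t))
    }, numeric(1))
  }
  out <- data.frame(network = names(obs), accuracy = unname(obs),
                    p = unname(p), fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$accuracy, out$network), ]
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "phenotypes") <- c(a = a, b = b)
  out
}

# Apparent two-template accuracies for many A/B splits at once.
# bits: pairs x samples; ZA: samples x K (1 = class A); sizes fixed across
# splits; tie_a says whether prediction ties go to class A.
split_accuracies <- function(bits, ZA, nA, nB, tie_a = nA >= nB) {
  P <- nrow(bits)
  cB <- colSums(bits)
  agree_for <- function(Z, ngrp) {
    TT <- (2 * (bits %*% Z) > ngrp) * 1
    agree <- sweep(2 * crossprod(TT, bits), 1, P - colSums(TT), "+")
    sweep(agree, 2, cB, "-")                # K x samples
  }
  agA <- agree_for(ZA, nA)
  agB <- agree_for(1 - ZA, nB)
  pred_a <- if (tie_a) agA >= agB else agA > agB
  correct <- pred_a * t(ZA) + (1 - pred_a) * t(1 - ZA)
  rowMeans(correct)
}

#' Leave-one-out cross-validated DIRAC classification of one network
#'
#' For each pooled sample, both templates are rebuilt with that sample held
#' out, the sample is predicted, and accuracy/sensitivity/specificity are
#' tallied over all held-out predictions. Fully deterministic.
#'
#' @inheritParams classify_samples
#' @param min_samples Minimum per-phenotype size (default 3, so a template
#'   survives the removal).
#' @return `dirac_classification` list (cross-validated), or `NULL` when the
#'   network has < 2 usable genes.
#' @export
loocv <- function(m, labels, genes, a, b, network = "<network>",
                  min_samples = 3L, balanced = FALSE) {
  lab <- align_labels(m, labels)
  keep <- lab %in% c(a, b)
  sub <- m[, keep, drop = FALSE]
  grp <- factor(as.character(lab[keep]), levels = c(a, b))
  nA <- sum(grp == a)
  nB <- sum(grp == b)
  if (nA < min_samples || nB < min_samples) {
    stop("each phenotype needs >= ", min_samples, " samples for LOOCV")
  }
  bits <- pair_order_matrix(sub, genes, network)
  if (is.null(bits)) return(NULL)
  P <- nrow(bits)
  n <- ncol(bits)
  in_a <- as.numeric(grp == a)
  cntA <- as.vector(bits %*% in_a)
  cntB <- as.vector(bits %*% (1 - in_a))
  # per held-out sample: counts and sizes with that sample removed
  inA_row <- matrix(in_a, P, n, byrow = TRUE)
  cntA_mat <- cntA - bits * inA_row
  cntB_mat <- cntB - bits * (1 - inA_row)
  nA_vec <- nA - in_a
  nB_vec <- nB - (1 - in_a)
  TA <- sweep(2 * cntA_mat, 2, nA_vec, ">") * 1
  TB <- sweep(2 * cntB_mat, 2, nB_vec, ">") * 1
  agA <- colSums(TA == bits)
  agB <- colSums(TB == bits)
  tie_to_a <- ifelse(nA_vec != nB_vec, nA_vec > nB_vec, a <= b)
  pred_a <- ifelse(agA == agB, tie_to_a, agA > agB)
  predicted <- stats::setNames(ifelse(pred_a, a, b), colnames(sub))
  finish_classification(predicted, grp, a, b, n_ties = sum(agA == agB),
                        balanced = balanced)
}

#' One phenotype against all others, over a network collection
#'
#' Pools every non-target phenotype into a single `rest` class and runs the
#' two-template classifier (apparent + LOOCV) per network plus the pooled
#' permutation significance, emitting a best-network table (top `top_k` by
#' apparent accuracy, ties broken by network name).
#'
#' @inheritParams classification_significance
#' @param phenotype Target phenotype.
#' @param top_k Rows in the best-network table.
#' @param do_loocv Set `FALSE` to skip the (slower) cross-validation.
#' @return List: `summary` (per-network data frame with apparent accuracy,
#'   sensitivity, specificity, p, FDR, LOOCV metrics), `top` (head of the
#'   summary), `phenotype`, and `mean_loocv_accuracy`.
#' @export
one_vs_rest <- function(m, labels, networks, phenotype, n_perm = 1000L,
                        seed = 1L, top_k = 10L, do_loocv = TRUE) {
  lab <- align_labels(m, labels)
  if (!phenotype %in% lab) stop("phenotype not present: ", phenotype)
  bin <- phenotype_labels(
    ifelse(as.character(lab) == phenotype, phenotype, "rest"),
    phenotype_levels = c(phenotype, "rest"),
    sample_ids = names(lab))
  sig <- classification_significance(m, bin, networks, phenotype, "rest",
                                     n_perm = n_perm, seed = seed)
  rows <- lapply(sig$network, function(nm) {
    app <- classify_samples(m, bin, networks[[nm]], phenotype, "rest", nm)
    cv <- if (do_loocv) loocv(m, bin, networks[[nm]], phenotype, "rest", nm)
    data.frame(network = nm,
               accuracy = app$accuracy, sensitivity = app$sensitivity,
               specificity = app$specificity,
               loocv_accuracy = if (do_loocv) cv$accuracy else NA_real_,
               loocv_sensitivity = if (do_loocv) cv$sensitivity else NA_real_,
               loocv_specificity = if (do_loocv) cv$specificity else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$p <- sig$p[match(summary$network, sig$network)]
  summary$fdr <- sig$fdr[match(summary$network, sig$network)]
  summary <- summary[order(-summary$accuracy, summary$network), ]
  rownames(summary) <- NULL
  list(summary = summary,
       top = utils::head(summary, top_k),
       phenotype = phenotype,
       mean_loocv_accuracy = mean(summary$loocv_accuracy))
}

#' Merge the two glioblastoma subtypes into one GBM class
#'
#' For global (grade-ladder) analyses that treat primary and secondary GBM as
#' a single Grade 4 endpoint.
#'
#' @param labels [phenotype_labels()] with `pGBM`/`sGBM` levels.
#' @return Relabelled factor with a single `GBM` level.
#' @export
merge_gbm <- function(labels) {
  lv <- levels(labels)
  out <- as.character(labels)
  out[out %in% c("pGBM", "sGBM")] <- "GBM"
  new_lv <- unique(replace(lv, lv %in% c("pGBM", "sGBM"), "GBM"))
  phenotype_labels(out, phenotype_levels = new_lv, sample_ids = names(labels))
}
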