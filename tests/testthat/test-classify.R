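make_separable <- function(n_a = 5, n_b = 5, n_genes = 6) {
  # phenotype A carries the ascending ordering, B the exact reverse
  a <- matrix(rep(seq_len(n_genes), n_a), n_genes, n_a)
  b <- matrix(rep(rev(seq_len(n_genes)), n_b), n_genes, n_b)
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_a + n_b)))
  list(m = m, labels = two_class_labels(m, n_a))
}

test_that("opposite orderings are classified perfectly, apparent and LOOCV", {
  sep <- make_separable()
  res <- classify_samples(sep$m, sep$labels, rownames(sep$m), "A", "B")
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$sensitivity, 1.0)
  expect_equal(res$specificity, 1.0)
  expect_identical(unname(res$predicted), as.character(sep$labels))

  cv <- loocv(sep$m, sep$labels, rownames(sep$m), "A", "B")
  expect_equal(cv$accuracy, 1.0)
})

test_that("samples go to the template with the higher matching score", {
  sep <- make_separable(4, 4, 5)
  res <- classify_samples(sep$m, sep$labels, rownames(sep$m), "A", "B")
  # a sample identical to the A ordering scores 1 vs A and 0 vs B
  expect_identical(unname(res$predicted[1]), "A")
  expect_identical(unname(res$predicted[8]), "B")
})

test_that("swapping class labels preserves accuracy and swaps sens/spec", {
  cfg <- sim_config(n_genes = 80, n_networks = 4L, network_sizes = c(5L, 10L),
                    phenotypes = c(Normal = 8L, G2 = 8L, G3 = 8L, pGBM = 8L, sGBM = 8L),
                    seed = 41L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  genes <- co$networks[[1]]
  ab <- classify_samples(rk, co$labels, genes, "Normal", "G2")
  ba <- classify_samples(rk, co$labels, genes, "G2", "Normal")
  expect_equal(ab$accuracy, ba$accuracy)
  expect_equal(ab$sensitivity, ba$specificity)
  expect_equal(ab$specificity, ba$sensitivity)
  cv_ab <- loocv(rk, co$labels, genes, "Normal", "G2")
  cv_ba <- loocv(rk, co$labels, genes, "G2", "Normal")
  expect_equal(cv_ab$accuracy, cv_ba$accuracy)
  expect_equal(cv_ab$sensitivity, cv_ba$specificity)
})

test_that("prediction ties go to the larger class and are recorded", {
  # identical templates for both classes: every score pair ties
  base <- matrix(rep(c(1, 2, 3), 7), 3, 7,
                 dimnames = list(c("a", "b", "c"), sprintf("s%02d", 1:7)))
  lab <- two_class_labels(base, 3)  # A has 3 samples, B has 4
  res <- classify_samples(base, lab, c("a", "b", "c"), "A", "B")
  expect_identical(res$n_ties, 7L)
  expect_true(all(res$predicted == "B"))
  expect_equal(res$accuracy, 4 / 7)
})

test_that("LOOCV is deterministic and equals a naive per-fold trace", {
  set.seed(601)
  for (k in 1:8) {
    ng <- sample(3:6, 1)
    na <- sample(3:5, 1)
    nb <- sample(3:5, 1)
    m <- random_expr(ng, na + nb)
    lab <- two_class_labels(m, na)
    cv1 <- loocv(m, lab, rownames(m), "A", "B")
    cv2 <- loocv(m, lab, rownames(m), "A", "B")
    expect_identical(cv1, cv2)
    expect_equal(cv1$accuracy,
                 oracle_loocv_accuracy(m, as.character(lab), "A", "B"))
  }
})

test_that("LOOCV accuracy does not beat apparent accuracy on average", {
  set.seed(602)
  gap <- vapply(1:20, function(k) {
    m <- random_expr(5, 14)
    lab <- two_class_labels(m, 7)
    classify_samples(m, lab, rownames(m), "A", "B")$accuracy -
      loocv(m, lab, rownames(m), "A", "B")$accuracy
  }, numeric(1))
  expect_gte(mean(gap), 0)
})

test_that("pooled permutation p and FDR behave at the extremes", {
  set.seed(604)
  sep <- make_separable(8, 8, 6)
  m <- rbind(sep$m, random_expr(24, 16, prefix = "r"))
  colnames(m) <- colnames(sep$m)
  nets <- c(list(SEP = rownames(sep$m)),
            lapply(setNames(1:4, paste0("R", 1:4)),
                   function(i) sprintf("r%03d", (i - 1) * 6 + 1:6)))
  sig <- classification_significance(m, sep$labels, nets, "A", "B",
                                     n_perm = 100, seed = 5)
  pooled_n <- 100 * nrow(sig)
  expect_identical(sig$network[1], "SEP")
  # a perfectly separable network can only be matched, never beaten, by nulls
  expect_lte(sig$p[1], (1 + 100) / (1 + pooled_n))
  expect_lt(sig$fdr[1], 0.05)
  # worst case: observed accuracy at or below every pooled null
  expect_equal(max(sig$p), sig$p[which.min(sig$accuracy)])
  bh <- classification_significance(m, sep$labels, nets, "A", "B",
                                    n_perm = 50, seed = 5, fdr_method = "BH")
  expect_true(all(bh$fdr >= bh$p - 1e-12))
})

test_that("one-vs-rest pools the remaining phenotypes and surfaces planted signal", {
  set.seed(605)
  m <- random_expr(60, 40)
  lab <- phenotype_labels(rep(c("Normal", "G2", "G3", "pGBM", "sGBM"), each = 8),
                          sample_ids = colnames(m))
  # plant a network whose ordering is specific to G3: ascending there,
  # descending in every other phenotype
  sep_genes <- rownames(m)[1:6]
  m[sep_genes, lab == "G3"] <- rep(1:6, sum(lab == "G3"))
  m[sep_genes, lab != "G3"] <- rep(6:1, sum(lab != "G3"))
  nets <- c(list(SEP = sep_genes),
            lapply(setNames(1:6, sprintf("R%02d", 1:6)),
                   function(i) rownames(m)[6 + (i - 1) * 9 + 1:9]))
  ovr <- one_vs_rest(m, lab, nets, "G3", n_perm = 50, seed = 6, top_k = 3)
  expect_identical(nrow(ovr$top), 3L)
  expect_true(all(c("accuracy", "sensitivity", "specificity", "p", "fdr",
                    "loocv_accuracy") %in% names(ovr$summary)))
  expect_identical(ovr$top$network[1], "SEP")
  expect_equal(ovr$top$accuracy[1], 1.0)
  expect_equal(ovr$top$loocv_accuracy[1], 1.0)
  expect_true(all(diff(ovr$summary$accuracy) <= 0))
  expect_error(one_vs_rest(m, lab, nets, "G5"), "not present")
})

test_that("balanced accuracy option averages sensitivity and specificity", {
  sep <- make_separable(4, 8, 5)
  raw <- classify_samples(sep$m, sep$labels, rownames(sep$m), "A", "B")
  bal <- classify_samples(sep$m, sep$labels, rownames(sep$m), "A", "B",
                          balanced = TRUE)
  expect_equal(bal$accuracy, (raw$sensitivity + raw$specificity) / 2)
})
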