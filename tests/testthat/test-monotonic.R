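test_that("wilcoxon p-values match exact enumeration and the textbook example", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0.5)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")

  # full enumeration oracle: every split with pooled n <= 6, tie-free values
  set.seed(701)
  for (na in 2:4) for (nb in 2:(6 - na)) {
    for (rep in 1:5) {
      v <- sample(seq(1, 100), na + nb)
      a <- v[seq_len(na)]
      b <- v[-seq_len(na)]
      expect_equal(wilcoxon_rank_sum(a, b), oracle_wilcoxon_enum(a, b))
    }
  }
})

test_that("normal approximation stays close to the exact test at n = 8 vs 8", {
  set.seed(702)
  errs <- vapply(1:10, function(rep) {
    a <- rnorm(8)
    b <- rnorm(8, 0.5)
    p_exact <- wilcoxon_rank_sum(a, b)  # min(n) = 8: exact path
    p_approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    abs(p_exact - p_approx)
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
})

test_that("the row-wise engine equals wilcox.test with tie and continuity corrections", {
  set.seed(703)
  X <- matrix(sample(1:15, 40 * 25, replace = TRUE), 40, 25)  # plenty of ties
  ia <- 1:12
  ib <- 13:25
  p_rows <- diracnet:::row_wilcoxon(X, ia, ib)
  p_ref <- vapply(1:40, function(g) {
    suppressWarnings(stats::wilcox.test(X[g, ia], X[g, ib],
                                        exact = FALSE, correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(p_rows, p_ref, tolerance = 1e-12)
  # fully tied row is degenerate: p = 1
  X[1, ] <- 7
  expect_equal(diracnet:::row_wilcoxon(X, ia, ib)[1], 1)
})

test_that("adjacent-grade DEG sets apply Bonferroni over all tested genes", {
  cfg <- sim_config(n_genes = 300, n_networks = 3L, network_sizes = c(4L, 8L),
                    phenotypes = c(Normal = 20L, G2 = 20L, G3 = 20L,
                                   pGBM = 20L, sGBM = 20L),
                    sigma_by_phenotype = c(Normal = 1, G2 = 1, G3 = 1,
                                           pGBM = 1, sGBM = 1),
                    planted_increasing = "g0001", delta = 4, seed = 51L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  degs <- adjacent_degs(rk, co$labels)
  expect_named(degs, c("Normal_vs_G2", "G2_vs_G3", "G3_vs_pGBM", "G3_vs_sGBM"))
  expect_true(all(vapply(degs, function(d) d$significant["g0001"], logical(1))))
  expect_true(all(vapply(degs, function(d)
    identical(d$significant, d$p < 0.05 / 300), logical(1))))

  none <- adjacent_degs(rk, co$labels, alpha = 0)
  expect_true(all(vapply(none, function(d) !any(d$significant), logical(1))))

  dropped <- co$labels[co$labels != "sGBM"]
  expect_error(adjacent_degs(rk[, names(dropped)], dropped), "sGBM")
})

test_that("monotonicity uses strict per-phenotype mean-rank orderings", {
  genes <- c("inc", "bump", "dec")
  phen <- c("Normal", "G2", "G3", "pGBM", "sGBM")
  counts <- c(2, 2, 2, 2, 2)
  lab <- phenotype_labels(rep(phen, counts),
                          sample_ids = sprintf("s%02d", 1:10))
  mk <- function(means) rep(means, counts)
  m <- rbind(inc = mk(c(100, 200, 300, 400, 410)),
             bump = mk(c(100, 300, 200, 400, 410)),
             dec = mk(c(410, 400, 300, 200, 100)))
  colnames(m) <- names(lab)
  deg <- lapply(1:4, function(i) {
    list(pair = c("x", "y"),
         p = setNames(rep(1e-9, 3), genes),
         significant = setNames(rep(TRUE, 3), genes),
         alpha = 0.05, n_genes = 3)
  })
  names(deg) <- c("Normal_vs_G2", "G2_vs_G3", "G3_vs_pGBM", "G3_vs_sGBM")
  rep_out <- find_monotonic(deg, m, lab)
  expect_identical(rep_out$direction[rep_out$gene == "inc"], "increasing")
  expect_identical(rep_out$direction[rep_out$gene == "bump"], "none")
  expect_identical(rep_out$direction[rep_out$gene == "dec"], "decreasing")
  expect_equal(rep_out$mean_rank_G3[rep_out$gene == "inc"], 300)

  # genes outside the DEG intersection never enter the report
  deg$G2_vs_G3$significant["dec"] <- FALSE
  rep2 <- find_monotonic(deg, m, lab)
  expect_false("dec" %in% rep2$gene)
})

test_that("negating all expression swaps increasing and decreasing exactly", {
  cfg <- sim_config(n_genes = 250, n_networks = 3L, network_sizes = c(4L, 8L),
                    phenotypes = c(Normal = 15L, G2 = 15L, G3 = 15L,
                                   pGBM = 15L, sGBM = 15L),
                    sigma_by_phenotype = c(Normal = 1, G2 = 1, G3 = 1,
                                           pGBM = 1, sGBM = 1),
                    planted_increasing = sprintf("g%04d", 1:5),
                    planted_decreasing = sprintf("g%04d", 6:10),
                    delta = 4, seed = 52L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  rk_neg <- rank_transform(-co$expr)
  r1 <- find_monotonic(adjacent_degs(rk, co$labels), rk, co$labels)
  r2 <- find_monotonic(adjacent_degs(rk_neg, co$labels), rk_neg, co$labels)
  expect_identical(sort(r1$gene[r1$direction == "increasing"]),
                   sort(r2$gene[r2$direction == "decreasing"]))
  expect_identical(sort(r1$gene[r1$direction == "decreasing"]),
                   sort(r2$gene[r2$direction == "increasing"]))
})

test_that("subsampling robustness counts same-direction recurrences", {
  cfg <- sim_config(n_genes = 200, n_networks = 3L, network_sizes = c(4L, 8L),
                    phenotypes = c(Normal = 15L, G2 = 15L, G3 = 15L,
                                   pGBM = 15L, sGBM = 15L),
                    sigma_by_phenotype = c(Normal = 1, G2 = 1, G3 = 1,
                                           pGBM = 1, sGBM = 1),
                    planted_increasing = "g0001", delta = 6, seed = 53L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  rob <- subsample_robustness(rk, co$labels, n_rep = 15, frac = 0.8,
                              min_support = 8, seed = 4)
  strong <- rob[rob$gene == "g0001", ]
  expect_equal(strong$support, 15L)
  expect_true(strong$high_confidence)
  expect_identical(rob, subsample_robustness(rk, co$labels, n_rep = 15,
                                             frac = 0.8, min_support = 8,
                                             seed = 4))
  vac <- subsample_robustness(rk, co$labels, n_rep = 0, min_support = 1, seed = 4)
  expect_true(all(vac$support == 0L))
  expect_false(any(vac$high_confidence))

  small <- co$labels[c(1:2, 16:17, 31:32, 46:47, 61:62)]
  expect_error(subsample_robustness(rk[, names(small)], small, n_rep = 2,
                                    frac = 0.5, min_support = 1, seed = 1),
               "fewer than 2")
})

test_that("directionality permutation p-values use the add-one estimator", {
  # null cohort: observed count 0, p near 1
  cfg <- sim_config(n_genes = 150, n_networks = 3L, network_sizes = c(4L, 8L),
                    phenotypes = c(Normal = 10L, G2 = 10L, G3 = 10L,
                                   pGBM = 10L, sGBM = 10L),
                    seed = 54L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  dt <- directionality_test(rk, co$labels, n_perm = 20, seed = 8)
  expect_equal(dt$n_increasing + dt$n_decreasing, 0)
  expect_equal(dt$p_increasing, 1)
  expect_equal(dt$p_decreasing, 1)
  expect_identical(dim(dt$null_counts), c(20L, 2L))
  # determinism and the (1 + count) / (n_perm + 1) floor
  dt2 <- directionality_test(rk, co$labels, n_perm = 20, seed = 8)
  expect_identical(dt, dt2)
  expect_gte(min(dt$p_increasing, dt$p_decreasing), 1 / 21)
})
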