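test_that("pair order encodes relative expression with ties as 0", {
  expect_identical(pair_order(c(1, 2, 3)), c(1L, 1L, 1L))
  expect_identical(pair_order(c(3, 2, 1)), c(0L, 0L, 0L))
  expect_identical(pair_order(c(2, 2, 5)), c(0L, 1L, 1L))
  expect_error(pair_order(1), "at least two")
})

test_that("rank templates take the strict majority with 50/50 ties masked", {
  # 3 samples whose pair-bit columns are (1,1,1), (1,1,1), (1,1,0)
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(1, 3, 2))
  rownames(m) <- c("a", "b", "c")
  tm <- build_rank_template(m, c("a", "b", "c"))
  expect_identical(tm$template, c(1L, 1L, 1L))
  expect_false(any(tm$tie_mask))

  same <- cbind(s1 = c(2, 4, 9), s2 = c(1, 5, 8))
  rownames(same) <- c("a", "b", "c")
  tm2 <- build_rank_template(same, c("a", "b", "c"))
  expect_identical(tm2$template, c(1L, 1L, 1L))
  expect_false(any(tm2$tie_mask))

  opp <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  rownames(opp) <- c("a", "b", "c")
  tm3 <- build_rank_template(opp, c("a", "b", "c"))
  expect_identical(tm3$template, c(0L, 0L, 0L))
  expect_true(all(tm3$tie_mask))
})

test_that("matching scores count agreeing pairs over all pairs", {
  tmpl <- pair_order(c(1, 2, 3, 4))           # template: A<B<C<D
  expect_equal(rank_matching_score(pair_order(c(1, 2, 3, 4)), tmpl), 1.0)
  expect_equal(rank_matching_score(pair_order(c(3, 2, 1)), pair_order(c(1, 2, 3))), 0.0)
  # A=2, B=1, C=3, D=4 disagrees only on the (A,B) pair: 5/6
  expect_equal(rank_matching_score(pair_order(c(2, 1, 3, 4)), tmpl), 5 / 6)
  expect_error(rank_matching_score(c(1L, 0L), tmpl), "mismatch")
})

test_that("conservation index averages own-template scores", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(1, 3, 2), s3 = c(1, 2, 3))
  rownames(m) <- c("a", "b", "c")
  # pair bits (1,1,1), (1,1,0), (1,1,1): template (1,1,1); scores 1, 2/3, 1
  expect_equal(conservation_index(m, c("a", "b", "c")), 8 / 9)

  ident <- cbind(s1 = c(5, 7, 9), s2 = c(1, 2, 3), s3 = c(2, 4, 8))
  rownames(ident) <- c("a", "b", "c")
  expect_equal(conservation_index(ident, c("a", "b", "c")), 1.0)
})

test_that("matching scores and indices equal the brute-force oracle", {
  set.seed(501)
  for (k in 1:30) {
    ng <- sample(2:6, 1)
    ns <- sample(2:8, 1)
    m <- random_expr(ng, ns)
    genes <- rownames(m)
    tmpl <- build_rank_template(m, genes)
    orc <- oracle_template(m)
    expect_identical(tmpl$template, orc$template)
    expect_identical(tmpl$tie_mask, orc$tie_mask)
    for (j in seq_len(ns)) {
      expect_identical(rank_matching_score(pair_order(m[, j]), tmpl),
                       oracle_matching_score(m[, j], orc$template))
    }
    ci <- conservation_index(m, genes)
    expect_identical(ci, oracle_conservation(m))
    expect_gte(ci, 0.5)  # majority bound
  }
})

test_that("global dysregulation is the unweighted network mean", {
  ct <- rbind(NET_A = c(Normal = 0.9, G2 = 0.8),
              NET_B = c(Normal = 1.0, G2 = 0.9))
  expect_equal(unname(global_dysregulation(ct, "Normal")), 0.95)
  expect_equal(unname(global_dysregulation(ct)), c(0.95, 0.85))
})

test_that("one-way ANOVA on conservation indices matches the textbook formula", {
  ct_same <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  rownames(ct_same) <- paste0("n", 1:3)
  res <- anova_conservation(ct_same)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(502)
  ct_sep <- cbind(A = rnorm(10, 0, 1e-4), B = rnorm(10, 1, 1e-4))
  rownames(ct_sep) <- paste0("n", 1:10)
  expect_lt(anova_conservation(ct_sep)$p, 1e-10)

  # hand ANOVA: groups {1,2,3} and {3,4,5}: SSB = 6, SSW = 4, F = 6/(4/4) = 6
  ct_hand <- cbind(A = c(1, 2, 3), B = c(3, 4, 5))
  rownames(ct_hand) <- paste0("n", 1:3)
  res_hand <- anova_conservation(ct_hand)
  expect_equal(res_hand$F, 6)
  expect_equal(res_hand$p, pf(6, 1, 4, lower.tail = FALSE))

  expect_error(anova_conservation(cbind(A = c(1, 1), B = c(1, 1))), "degenerate")
})

test_that("pairwise paired t-tests across networks handle degenerate columns", {
  ct <- cbind(A = c(0.9, 0.8, 0.7, 0.95), B = c(0.9, 0.8, 0.7, 0.95))
  rownames(ct) <- paste0("n", 1:4)
  res <- pairwise_t_tests(ct)
  expect_equal(res$p["A", "B"], 1)
  expect_equal(res$statistic["A", "B"], 0)
  expect_false(res$degenerate["A", "B"])

  ct2 <- cbind(A = c(0.9, 0.8, 0.7, 0.95), B = c(0.9, 0.8, 0.7, 0.95) + 0.1)
  rownames(ct2) <- paste0("n", 1:4)
  res2 <- pairwise_t_tests(ct2)
  expect_true(res2$degenerate["A", "B"])
  expect_true(is.na(res2$p["A", "B"]))

  set.seed(503)
  ct3 <- cbind(A = runif(6, 0.7, 1), B = runif(6, 0.7, 1))
  rownames(ct3) <- paste0("n", 1:6)
  d <- ct3[, "A"] - ct3[, "B"]
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  p_hand <- 2 * pt(-abs(t_hand), 5)
  res3 <- pairwise_t_tests(ct3)
  expect_equal(res3$statistic["A", "B"], t_hand)
  expect_equal(res3$p["A", "B"], p_hand)
  expect_equal(res3$p["A", "B"], res3$p["B", "A"])
})

test_that("binomial direction test is the one-sided exact tail", {
  expect_equal(binomial_direction_test(5, 5), 1 / 32)
  expect_equal(binomial_direction_test(10, 12), 79 / 4096)
  expect_gt(binomial_direction_test(6, 12), 0.5)
  expect_error(binomial_direction_test(0, 0), "n = 0")
})

test_that("differential regulation: null split of one population gives delta 0, p 1", {
  # noiseless population: both phenotypes carry the identical ordering
  base <- matrix(rep(seq_len(12), 10), 12, 10,
                 dimnames = list(sprintf("g%03d", 1:12), sprintf("s%02d", 1:10)))
  lab <- two_class_labels(base, 5)
  nets <- list(N1 = sprintf("g%03d", 1:6), N2 = sprintf("g%03d", 7:12))
  dr <- differential_regulation(base, lab, nets, "A", "B", n_perm = 20, seed = 1)
  expect_true(all(dr$delta == 0))
  expect_true(all(dr$p == 1))
  expect_true(all(dr$direction == "none"))
})

test_that("differential regulation recovers a planted noisy network", {
  cfg <- sim_config(n_genes = 200, n_networks = 10L, network_sizes = c(6L, 12L),
                    phenotypes = c(Normal = 15L, G2 = 15L, G3 = 15L,
                                   pGBM = 15L, sGBM = 15L),
                    sigma_by_phenotype = c(Normal = 0.5, G2 = 0.5, G3 = 0.5,
                                           pGBM = 0.5, sGBM = 0.5),
                    planted_dysreg = list(list(network = "NET_003",
                                               phenotype = "G2", extra_sigma = 5)),
                    seed = 21L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  dr <- differential_regulation(rk, co$labels, co$networks, "Normal", "G2",
                                n_perm = 200, seed = 9)
  expect_identical(dr$network[1], "NET_003")
  expect_lt(dr$p[1], 0.01)
  expect_true(all(abs(dr$delta) <= 0.5))
  # planted noise is in G2 (phenotype B): delta > 0, more conserved in Normal
  expect_gt(dr$delta[1], 0)
  expect_identical(dr$direction[1], "more conserved in Normal")
  # determinism
  dr2 <- differential_regulation(rk, co$labels, co$networks, "Normal", "G2",
                                 n_perm = 200, seed = 9)
  expect_identical(dr, dr2)
})

test_that("delta keeps the index(A) - index(B) sign convention", {
  # conserved phenotype B, heterogeneous phenotype A
  set.seed(504)
  a <- random_expr(6, 6)
  b <- matrix(rep(seq_len(6), 6), 6, 6,
              dimnames = list(rownames(a), sprintf("t%02d", 1:6)))
  m <- cbind(a, b)
  lab <- two_class_labels(m, 6)
  dr <- differential_regulation(m, lab, list(N = rownames(a)), "A", "B",
                                n_perm = 10, seed = 2)
  expect_equal(dr$delta, dr$index_a - dr$index_b)
  expect_lt(dr$delta[1], 0)
  expect_identical(dr$direction[1], "more conserved in B")
})

test_that("per-network null option and pooled null agree on extreme networks", {
  cfg <- sim_config(n_genes = 100, n_networks = 6L, network_sizes = c(5L, 10L),
                    phenotypes = c(Normal = 10L, G2 = 10L, G3 = 10L,
                                   pGBM = 10L, sGBM = 10L),
                    planted_dysreg = list(list(network = "NET_001",
                                               phenotype = "G2", extra_sigma = 6)),
                    seed = 31L)
  co <- generate_cohort(cfg)
  rk <- rank_transform(co$expr)
  pooled <- differential_regulation(rk, co$labels, co$networks, "Normal", "G2",
                                    n_perm = 100, seed = 3)
  pernet <- differential_regulation(rk, co$labels, co$networks, "Normal", "G2",
                                    n_perm = 100, seed = 3, null = "per_network")
  expect_identical(pooled$network[1], "NET_001")
  expect_identical(pernet$network[1], "NET_001")
  expect_lt(pernet$p[1], 0.05)
})
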