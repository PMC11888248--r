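test_that("auroc matches the pairwise-comparison definition", {
  expect_equal(auroc(c(0.1, 0.2, 0.9), c(FALSE, FALSE, TRUE)), 1)
  expect_equal(auroc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  # enumerate the 4 positive-negative pairs: 2 of 4 concordant
  expect_equal(auroc(c(3, 1, 2, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "positive")

  set.seed(1)
  for (i in 1:20) {
    s <- sample(rnorm(8), 12, replace = TRUE)  # duplicates force ties
    pos <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(pos) || all(pos)) next
    # brute force: P(pos > neg) + P(tie)/2 over all pairs
    brute <- mean(outer(s[pos], s[!pos], function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, pos), brute, tolerance = 1e-12)
    # complement and monotone-transform invariances
    expect_equal(auroc(s, pos) + auroc(s, !pos), 1, tolerance = 1e-12)
    expect_equal(auroc(exp(3 * s), pos), auroc(s, pos), tolerance = 1e-12)
  }
})

test_that("grouped one-vs-rest auroc equals per-cluster calls", {
  set.seed(2)
  s <- rnorm(60)
  labels <- sample(letters[1:4], 60, replace = TRUE)
  grp <- atlasrep:::auroc_grouped(s, labels)
  for (k in unique(labels)) {
    expect_equal(grp[[k]], auroc(s, labels == k), tolerance = 1e-12)
  }
})

test_that("spearman correlation handles monotone, antitone and tied input", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  # mid-ranks x = (1.5, 1.5, 3), y = (1, 2, 3): Pearson = sqrt(3)/2
  expect_equal(spearman_rho(c(1, 1, 2), 1:3), sqrt(3) / 2, tolerance = 1e-4)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("rank-sum test: exact enumeration agrees with closed cases and wilcox.test", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "two-sided")$p_value, 1 / 3)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2), "two-sided")$p_value, 1)
  r1 <- rank_sum_test(c(1, 5, 3), c(2, 8, 9, 4), "two-sided")$p_value
  r2 <- rank_sum_test(c(2, 8, 9, 4), c(1, 5, 3), "two-sided")$p_value
  expect_equal(r1, r2)
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    ours <- rank_sum_test(x, y, "two-sided")$p_value
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation tracks the exact tail at n = 25 per group", {
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(25, mean = runif(1, -0.5, 0.5)); y <- rnorm(25)
    approx_p <- rank_sum_test(x, y, "two-sided")$p_value
    exact_p <- wilcox.test(x, y, exact = TRUE, correct = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.02)
  }
})

test_that("hypergeometric overlap test matches closed form and enumeration", {
  expect_equal(hypergeom_overlap_test(4, 4, 5, 10)$p_value, 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_test(0, 4, 5, 10)$p_value, 1)
  expect_equal(hypergeom_overlap_test(3, 4, 6, 11)$p_value,
               hypergeom_overlap_test(3, 6, 4, 11)$p_value, tolerance = 1e-12)
  expect_error(hypergeom_overlap_test(5, 4, 5, 10), "infeasible")

  # exhaustive enumeration of draws for universes up to 12
  for (case in list(c(12, 5, 7, 3), c(10, 4, 4, 2), c(8, 3, 6, 1), c(12, 6, 6, 6))) {
    n_tot <- case[1]; n_a <- case[2]; n_b <- case[3]; k <- case[4]
    draws <- utils::combn(n_tot, n_b)
    overlaps <- colSums(draws <= n_a)  # set A = first n_a elements
    expect_equal(hypergeom_overlap_test(k, n_a, n_b, n_tot)$p_value,
                 mean(overlaps >= k), tolerance = 1e-12)
  }
})

test_that("Fisher exact 2x2 matches enumeration with fixed margins", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  flat <- fisher_exact_2x2(matrix(1, 2, 2))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$odds_ratio, 1)
  tab <- matrix(c(5, 1, 2, 7), 2)
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_exact_2x2(t(tab))$p_value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab)$odds_ratio, (5 * 7) / (1 * 2))

  set.seed(5)
  for (i in 1:8) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 12) next
    ours <- fisher_exact_2x2(tab, "two-sided")$p_value
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
    # enumeration oracle: all splits of the row-1 margin over column-1 items
    n_tot <- sum(tab); m <- sum(tab[, 1]); kk <- sum(tab[1, ])
    draws <- utils::combn(n_tot, kk)
    a_all <- colSums(draws <= m)
    p_enum <- vapply(0:min(m, kk), function(a) mean(a_all == a), numeric(1))
    obs_p <- p_enum[tab[1, 1] + 1]
    expect_equal(ours, sum(p_enum[p_enum <= obs_p * (1 + 1e-7)]), tolerance = 1e-12)
  }
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_p(rep(0.01, 5), "bonferroni")[1], 0.05)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  set.seed(6)
  p <- runif(30)
  expect_true(all(adjust_p(p, "bh") >= p))
  expect_true(all(adjust_p(p, "bonferroni") >= p))
})

test_that("permutation overlap test is calibrated against the hypergeometric mean", {
  sets <- list(c("a", "b"), c("c", "d"))
  res <- permutation_overlap_test(sets, letters[1:4], n_perm = 2000, seed = 9)
  # analytic expected overlap of two random size-2 subsets of 4: 2*2/4 = 1
  expect_lt(abs(res$expected - 1), 0.05)
  expect_equal(res$statistic, 0)

  one <- permutation_overlap_test(list(c("a", "b")), letters[1:4], n_perm = 200, seed = 1)
  expect_equal(one$expected, 2)
  expect_equal(one$p_value, 1)

  r1 <- permutation_overlap_test(sets, letters[1:4], n_perm = 500, seed = 4)
  r2 <- permutation_overlap_test(sets, letters[1:4], n_perm = 500, seed = 4)
  expect_identical(r1, r2)
  expect_error(permutation_overlap_test(list(c("z")), letters[1:4], n_perm = 100),
               "subsets")
})
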