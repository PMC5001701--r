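test_that("contingency construction restricts the pathway to ever-targeted genes", {
  u <- paste0("G", 1:10)
  tab <- build_contingency(c("G1", "G2"), c("G1", "G3", "G99"), u)
  # G99 is excluded: never annotated as any miRNA's target
  expect_equal(unlist(tab[1, 1:4]),
               c(np_plus = 1L, np_minus = 1L, nm_plus = 2L, nm_minus = 8L))
  expect_false(tab$degenerate)

  # disjoint targets and pathway
  expect_equal(build_contingency("G1", c("G2", "G3"), u)$np_plus, 0L)
  # pathway fully covered by targets
  full <- build_contingency(c("G1", "G2", "G3"), c("G1", "G2"), u)
  expect_equal(full$np_minus, 0L)
  # no testable pathway gene -> degenerate flag, not an error
  expect_true(build_contingency("G1", "G99", u)$degenerate)
  # targets outside the universe violate the background contract
  expect_error(build_contingency("G99", "G1", u), "subset of the universe")
})

test_that("contingency invariants hold over random set draws", {
  withr::local_seed(31)
  genes <- sprintf("G%03d", 1:200)
  for (i in 1:25) {
    u <- sample(genes, sample(50:200, 1))
    targ <- sample(u, sample(1:40, 1))
    pg <- sample(genes, sample(1:60, 1))
    tab <- build_contingency(targ, pg, u)
    expect_gte(tab$np_plus, 0)
    expect_lte(tab$np_plus, tab$nm_plus)
    expect_lte(tab$np_minus, tab$nm_minus)
    expect_equal(tab$nm_plus + tab$nm_minus, length(u))
    expect_equal(tab$np_plus + tab$np_minus, length(intersect(unique(pg), u)))
  }
})

test_that("the one-tailed Fisher test equals explicit hypergeometric summation", {
  # P(X >= 0) is exactly 1
  expect_identical(fisher_one_tailed(0, 5, 10, 40), 1)
  # worked combinatorial example: N = 20, K = 4, n = 5
  manual <- sum(sapply(2:4, function(k) {
    choose(4, k) * choose(16, 5 - k) / choose(20, 5)
  }))
  expect_equal(fisher_one_tailed(2, 2, 5, 15), manual, tolerance = 1e-12)
  # random tables against the lchoose oracle and fisher.test
  withr::local_seed(32)
  for (i in 1:40) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    x <- sample(max(0, n + K - N):min(K, n), 1)
    p <- fisher_one_tailed(x, K - x, n, N - n)
    expect_equal(p, hyper_upper_oracle(x, N, K, n), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(x, K - x, n - x, (N - K) - (n - x)), 2),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  # invariant-violating tables are rejected
  expect_error(fisher_one_tailed(3, 0, 2, 10), "np_plus <= nm_plus")
  expect_error(fisher_one_tailed(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment matches the hand-rolled step-up and preserves order", {
  expect_equal(fdr_adjust(0.01), 0.01)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  withr::local_seed(33)
  for (i in 1:25) {
    p <- stats::runif(sample(1:100, 1))
    adj <- fdr_adjust(p)
    expect_identical(adj, bh_oracle(p))
    expect_gte(min(adj - p), 0)
    expect_identical(order(adj, p), order(p, p))
  }
})

test_that("the Lancaster transform is the chi-square quantile with fractional df", {
  p <- c(0.05, 0.5, 0.999, 1e-8)
  expect_equal(lancaster_transform(p, 2), -2 * log(p), tolerance = 1e-10)
  # p = 1 maps to 0 for every weight
  expect_equal(lancaster_transform(rep(1, 4), c(0.5, 1, 2, 7)), rep(0, 4))
  # fractional df against a bisection quantile oracle on the regularized
  # incomplete gamma CDF
  quantile_by_root <- function(p, w) {
    stats::uniroot(function(x) stats::pgamma(x, shape = w / 2, scale = 2) - (1 - p),
                   c(0, 1e4), tol = 1e-12)$root
  }
  expect_equal(lancaster_transform(0.5, 0.5), quantile_by_root(0.5, 0.5),
               tolerance = 1e-8)
  for (w in c(0.5, 1, 1.3, 2.7)) {
    for (pp in c(0.01, 0.2, 0.5, 0.9)) {
      expect_equal(lancaster_transform(pp, w), quantile_by_root(pp, w),
                   tolerance = 1e-8)
    }
  }
  # underflow clamp is applied and reported
  expect_message(v <- lancaster_transform(0, 2), "clamped")
  expect_true(is.finite(v))
  expect_error(lancaster_transform(1.5, 2), "\\[0, 1\\]")
  expect_error(lancaster_transform(0.5, -1), "positive")
})

test_that("Lancaster combination reduces to Fisher's test at weight 2 and round-trips singletons", {
  withr::local_seed(34)
  # all weights 2, independent null == classical Fisher combined test
  p <- stats::runif(10)
  res <- combine_lancaster(p, rep(2, 10))
  expect_equal(res$lancaster_T, -2 * sum(log(p)), tolerance = 1e-10)
  expect_equal(res$p_combined,
               stats::pchisq(-2 * sum(log(p)), df = 20, lower.tail = FALSE),
               tolerance = 1e-10)
  # single pathway: quantile then tail of the same distribution is identity
  for (w in c(0.5, 1, 2, 3.4)) {
    expect_equal(combine_lancaster(0.037, w)$p_combined, 0.037,
                 tolerance = 1e-10)
  }
  expect_error(combine_lancaster(c(0.1, 0.2), 2), "mismatch")
})

test_that("the independent-null tail matches a Monte-Carlo oracle for mixed weights", {
  withr::local_seed(35)
  p <- c(0.01, 0.5, 0.9)
  w <- c(2, 1, 0.5)
  res <- combine_lancaster(p, w)
  n_mc <- 2e6
  t_null <- stats::rgamma(n_mc, w[1] / 2, scale = 2) +
    stats::rgamma(n_mc, w[2] / 2, scale = 2) +
    stats::rgamma(n_mc, w[3] / 2, scale = 2)
  p_mc <- mean(t_null >= res$lancaster_T)
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(res$p_combined - p_mc), 3 * se)
})

test_that("the moment-matched null detects correlation and is seed-deterministic", {
  withr::local_seed(36)
  genes <- sprintf("G%04d", 1:8000)
  # disjoint equal-size pathways covering a small slice of a large universe,
  # with target sets big enough for the discrete p-values to be near-uniform:
  # the permuted statistic should look like the independent chi-square
  sets <- split(genes[1:600], rep(1:6, each = 100))
  names(sets) <- paste0("P", 1:6)
  pw <- make_pathways(sets, stats::setNames(rep("A", 6), names(sets)))
  tm <- make_target_map(lapply(stats::setNames(1:40, paste0("m", 1:40)),
                               function(i) sample(genes, 2000)))
  u <- genes
  null_ind <- estimate_null(pw, tm, u, n_permutations = 600, seed = 5,
                            combine_on = "raw")
  expect_equal(null_ind$df_effective, sum(pw$weight), tolerance = 0.2)
  expect_equal(null_ind$scale, 1, tolerance = 0.2)

  # duplicated pathway (perfect correlation) shrinks the effective df
  pw_dup <- make_pathways(list(P1 = genes[1:100], P2 = genes[1:100]),
                          c(P1 = "A", P2 = "A"))
  null_dup <- estimate_null(pw_dup, tm, u, n_permutations = 600, seed = 5,
                            combine_on = "raw")
  expect_lt(null_dup$df_effective, sum(pw_dup$weight))

  # fixed seed reproduces the null exactly
  again <- estimate_null(pw, tm, u, n_permutations = 600, seed = 5,
                         combine_on = "raw")
  expect_identical(again$t_perm, null_ind$t_perm)
  expect_identical(again$scale, null_ind$scale)
  b <- estimate_null(pw, tm, u, n_permutations = 600, seed = 6,
                     combine_on = "raw")
  expect_false(identical(b$t_perm, null_ind$t_perm))
})

test_that("ranking applies the strict threshold and the documented tie-break", {
  scores <- tibble::tibble(
    mirna = c("m1", "m2", "m3"),
    lancaster_T = c(30, 20, 5),
    p_combined = c(0.005, 0.01, 0.5)
  )
  sel <- rank_and_select(scores, alpha = 0.01)
  expect_equal(sel$mirna, "m1")  # 0.01 excluded: strict inequality
  expect_identical(rank_and_select(scores[0, ]), scores[0, ])
  tie <- tibble::tibble(
    mirna = c("mB", "mA", "mC"),
    lancaster_T = c(10, 10, 25),
    p_combined = c(0.004, 0.004, 0.004)
  )
  expect_equal(rank_and_select(tie)$mirna, c("mC", "mA", "mB"))
})

test_that("adding an in-pathway target (size held fixed) never raises the pair p-value", {
  withr::local_seed(37)
  for (i in 1:50) {
    N <- sample(20:300, 1); K <- sample(2:min(N, 60), 1); n <- sample(2:min(N, 80), 1)
    lo <- max(0, n + K - N)
    x <- sample(lo:(min(K, n) - 1), 1)
    p0 <- fisher_one_tailed(x, K - x, n, N - n)
    p1 <- fisher_one_tailed(x + 1, K - x - 1, n, N - n)
    expect_lte(p1, p0 + 1e-15)
  }
})
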