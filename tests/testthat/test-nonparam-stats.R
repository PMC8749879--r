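# Statistical battery, each routine checked against an independent oracle:
# explicit sign-matrix enumeration, stats::wilcox.test / friedman.test,
# brute-force pair counting, direct quantile arithmetic.

test_that("exact signed-rank p-values match hand-enumerable cases", {
  # differences (+1, +2, +3): only the all-positive and all-negative of the
  # 8 sign patterns are as extreme -> p = 2/8
  r <- wilcoxon_signed_rank(c(4, 5, 6), c(3, 3, 3))
  expect_equal(r$statistic, 6)
  expect_true(r$exact)
  expect_equal(r$p_value, 0.25)
  # n = 8, all positive, distinct magnitudes -> 2/256
  r8 <- wilcoxon_signed_rank(11:18, rep(10, 8) - (1:8) * 0.01)
  expect_equal(r8$p_value, 2 / 256)
  expect_equal(r8$statistic, 36)
})

test_that("exact p equals full enumeration on random tie-free samples", {
  set.seed(101)
  for (i in 1:150) {
    n <- sample(4:10, 1)
    d <- stats::rnorm(n)
    while (anyDuplicated(abs(d)) || any(d == 0)) d <- stats::rnorm(n)
    mine <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(mine$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
    # independent library oracle
    wt <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(mine$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("swapping pre and post leaves the p-value unchanged", {
  set.seed(5)
  pre <- stats::rnorm(8, 10)
  post <- stats::rnorm(8, 9)
  a <- wilcoxon_signed_rank(pre, post)
  b <- wilcoxon_signed_rank(post, pre)
  expect_equal(a$p_value, b$p_value)
  n <- a$n
  expect_equal(a$statistic - n * (n + 1) / 4,
               -(b$statistic - n * (n + 1) / 4))
})

test_that("zero differences are dropped and all-zero input errors", {
  r <- wilcoxon_signed_rank(c(5, 5, 1, 2, 3, 4), c(5, 5, 0, 0, 0, 0))
  expect_equal(r$n, 4)
  expect_match(r$notes, "2 zero difference")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "non-zero")
})

test_that("tied samples: exact enumeration at small n, tie-corrected normal above", {
  # identical differences: enumeration conditional on mid-ranks
  r <- wilcoxon_signed_rank(rep(5, 8), rep(4, 8))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 256)
  # large-n tied path against the library's tie-corrected approximation
  set.seed(8)
  x <- round(stats::rnorm(25, 0.3), 1)
  x <- x[x != 0]
  mine <- wilcoxon_signed_rank(x, rep(0, length(x)),
                               analysis_config(exact_max_n = 5))
  wt <- stats::wilcox.test(x, exact = FALSE, correct = FALSE)
  expect_false(mine$exact)
  expect_equal(mine$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("Friedman statistic matches hand computation and the library", {
  # two blocks ranking the three treatments identically:
  # Q = 12/(2*3*4) * (4 + 16 + 36) - 3*2*4 = 4
  m <- rbind(c(1, 2, 3), c(10, 20, 30))
  r <- friedman_rank_test(m)
  expect_equal(r$statistic, 4)
  # no treatment effect at all
  same <- matrix(rep(c(7, 7, 7), 4), nrow = 4, byrow = TRUE)
  r0 <- friedman_rank_test(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  set.seed(33)
  for (i in 1:30) {
    mm <- matrix(stats::rnorm(20), nrow = 5)
    if (i %% 3 == 0) mm <- round(mm, 0)      # induce ties sometimes
    mine <- friedman_rank_test(mm)
    ref <- stats::friedman.test(mm)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Friedman is invariant to within-block monotone transforms", {
  set.seed(4)
  m <- matrix(stats::rnorm(24), nrow = 6)
  q1 <- friedman_rank_test(m)$statistic
  m2 <- t(apply(m, 1, function(row) exp(3 * row) - 5))
  expect_equal(friedman_rank_test(m2)$statistic, q1)
  expect_error(friedman_rank_test(matrix(1:4, 2)), ">= 2 blocks")
  mna <- m; mna[2, 3] <- NA
  expect_error(friedman_rank_test(mna), "aggregate sessions")
})

test_that("Bonferroni post hoc: combinatorics, monotonicity, null behavior", {
  set.seed(21)
  m <- matrix(stats::rnorm(32), nrow = 8, ncol = 4)
  ph <- bonferroni_posthoc(m)
  expect_equal(nrow(ph), 6L)                     # 4 choose 2
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-15))
  expect_true(all(ph$p_adj <= 1))
  # identical columns: nothing can be flagged
  same <- matrix(rep(stats::rnorm(8), 4), nrow = 8)
  ph0 <- bonferroni_posthoc(same)
  expect_false(any(ph0$significant))
  # rank critical-difference variant agrees on the obvious extreme case
  strong <- cbind(matrix(stats::rnorm(16), 8, 2), stats::rnorm(8) + 50,
                  stats::rnorm(8) + 100)
  ph_cd <- bonferroni_posthoc(strong, analysis_config(posthoc = "rank_cd"))
  expect_true(ph_cd$significant[ph_cd$col_a == "1" & ph_cd$col_b == "4"])
})

test_that("Cliff's delta equals brute-force pair counting", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(cliffs_delta(c(10, 11), c(1, 2))$delta, 1)
  expect_equal(cliffs_delta(c(3, 4, 5), c(1, 2, 3))$delta, 8 / 9)
  set.seed(55)
  for (i in 1:100) {
    x <- sample(0:10, sample(2:8, 1), replace = TRUE)
    y <- sample(0:10, sample(2:8, 1), replace = TRUE)
    d <- cliffs_delta(x, y)$delta
    expect_equal(d, oracle_cliffs_delta(x, y))
    expect_equal(cliffs_delta(y, x)$delta, -d)
    expect_lte(abs(d), 1)
  }
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})

test_that("CQV and median/IQR follow the fixed quartile rule", {
  # type-7 interpolation at (n-1)p + 1: [1..5] -> Q1 = 2, Q3 = 4
  expect_equal(cqv(1:5), 100 * 2 / 6, tolerance = 1e-12)
  mi <- median_iqr(1:5)
  expect_equal(mi$median, 3)
  expect_equal(mi$iqr, 2)
  expect_equal(median_iqr(5)$median, 5)
  expect_equal(median_iqr(5)$iqr, 0)
  expect_equal(cqv(rep(3, 6)), 0)
  set.seed(6)
  x <- stats::rlnorm(20)
  expect_equal(cqv(3.7 * x), cqv(x), tolerance = 1e-12)
  perm <- sample(x)
  expect_equal(median_iqr(perm), median_iqr(x))
  expect_error(cqv(c(-5, -4, 4, 4.5)), "Q1 \\+ Q3")
  expect_error(cqv(1:3), "at least 4")
})

test_that("normalized variation is percent change from baseline", {
  expect_equal(normalized_variation(10, 10), 0)
  expect_equal(normalized_variation(400, 340), -15)
  expect_equal(normalized_variation(200, 250), 25)
  expect_error(normalized_variation(0, 5), "zero")
})

test_that("KS normality: statistic equals the Lilliefors construction", {
  x <- c(1, 1, 1, 2, 3)
  r <- ks_normality(x, analysis_config(ks_mc = 500))
  # brute-force grid oracle for sup |F_n - Phi_fitted|
  grid <- seq(min(x) - 2, max(x) + 2, by = 1e-4)
  fn <- stats::ecdf(x)
  dev <- abs(fn(grid) - stats::pnorm(grid, mean(x), stats::sd(x)))
  expect_equal(r$statistic, max(dev), tolerance = 1e-3)
  skip_if_not_installed("nortest")
  expect_equal(r$statistic,
               unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
})

test_that("KS Monte-Carlo p is seeded and consistent", {
  set.seed(77)
  x <- stats::rnorm(30)
  cfg <- analysis_config(ks_mc = 2000)
  a <- ks_normality(x, cfg, seed = 9)
  b <- ks_normality(x, cfg, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0.05)          # truly normal sample, small D
  y <- stats::rexp(200)               # clearly non-normal
  expect_lt(ks_normality(y, cfg)$p_value, 0.01)
  expect_error(ks_normality(rep(2, 10)), "zero variance")
})
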