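## Small-sample nonparametric statistics: exact Wilcoxon signed-rank,
## Friedman test with ties, Bonferroni post hoc, Cliff's delta, coefficient
## of quartile variation, Lilliefors-style KS normality check.
##
## With eight athletes per cell, asymptotic p-values are unreliable; the
## signed-rank test therefore enumerates the full sign-permutation null
## distribution whenever the sample is small and tie-free.

#' Analysis configuration
#'
#' @param alpha significance threshold.
#' @param exact_max_n largest n for which the Wilcoxon signed-rank null is
#'   enumerated exactly (2^n sign patterns via a rank-sum convolution).
#' @param quantile_type order-statistic interpolation rule passed to
#'   [stats::quantile()]. Type 7 interpolates linearly at position
#'   `(n - 1) * p + 1`, the convention used for all quartile-based summaries
#'   (median/IQR/CQV) in this package.
#' @param posthoc `"pairwise_wilcoxon"` (pairwise signed-rank tests with
#'   multiplicative Bonferroni correction, the default) or `"rank_cd"`
#'   (Friedman mean-rank critical differences).
#' @param ks_mc number of Monte-Carlo replicates for the normality test.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, exact_max_n = 12L,
                            quantile_type = 7L,
                            posthoc = c("pairwise_wilcoxon", "rank_cd"),
                            ks_mc = 10000L) {
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop_domain("`alpha` must be in (0, 1)")
  structure(list(alpha = alpha, exact_max_n = as.integer(exact_max_n),
                 quantile_type = as.integer(quantile_type),
                 posthoc = match.arg(posthoc), ks_mc = as.integer(ks_mc)),
            class = "analysis_config")
}

new_test_result <- function(method, statistic, p_value, n, exact, notes = "") {
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, exact = exact,
                 notes = notes), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %g, p = %.5g (n = %s%s)%s\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "x"),
              if (x$exact) ", exact" else "",
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

## exact null distribution of the signed-rank sum over all 2^n sign
## assignments, by polynomial convolution. Works on doubled ranks so that
## mid-ranks (ties) stay integer; with ties the enumeration is conditional
## on the observed tie pattern.
signed_rank_null_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- c(1, numeric(total))       # counts[w + 1] = #patterns with W2 = w
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Ranks the absolute pre/post differences (mid-ranks for ties, zero
#' differences dropped) and sums the ranks of positive differences. For
#' `n <= exact_max_n`, the two-sided p-value is computed by full enumeration
#' of all `2^n` sign assignments:
#' `p = P(|W - mu| >= |w_obs - mu|)` with `mu = n(n+1)/4`; with tied
#' `|differences|` the enumeration is conditional on the observed mid-rank
#' pattern. Above `exact_max_n` a normal approximation with tie-corrected
#' variance (no continuity correction) is used.
#'
#' @param pre,post equal-length paired measurement vectors. Differences are
#'   taken as `pre - post`.
#' @param cfg an [analysis_config()].
#' @return A `test_result` with the W+ statistic; `notes` records dropped
#'   zeros and tie handling.
#' @examples
#' wilcoxon_signed_rank(c(4, 5, 6), c(3, 3, 3))  # p = 0.25
#' @export
wilcoxon_signed_rank <- function(pre, post, cfg = analysis_config()) {
  if (length(pre) != length(post))
    stop_domain("`pre` and `post` must have equal length")
  d <- pre - post
  if (anyNA(d)) stop_domain("missing values in paired differences")
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n < 3L)
    stop_domain("fewer than 3 non-zero differences (all pairs equal?)")
  ranks <- rank(abs(d))
  w_plus <- sum(ranks[d > 0])
  mu <- n * (n + 1) / 4
  has_ties <- anyDuplicated(abs(d)) > 0
  notes <- character(0)
  if (n_zero > 0) notes <- c(notes, sprintf("%d zero difference(s) dropped",
                                            n_zero))
  if (n <= cfg$exact_max_n) {
    ranks2 <- as.integer(round(2 * ranks))   # doubled mid-ranks are integer
    counts <- signed_rank_null_counts(ranks2)
    w_vals <- seq_along(counts) - 1
    w2 <- 2 * w_plus
    mu2 <- 2 * mu
    p <- sum(counts[abs(w_vals - mu2) >= abs(w2 - mu2) - 1e-9]) / 2^n
    exact <- TRUE
    if (has_ties)
      notes <- c(notes, "tied |differences|: enumeration conditional on ties")
  } else {
    if (has_ties) notes <- c(notes, "tied |differences|: normal approximation")
    tie_tab <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  new_test_result("Wilcoxon signed-rank", statistic = w_plus,
                  p_value = min(p, 1), n = n, exact = exact,
                  notes = paste(notes, collapse = "; "))
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric one-way repeated-measures ANOVA. Values are mid-ranked
#' within each block (athlete); the tie-corrected statistic
#' \deqn{Q = \frac{12 \sum_j (R_j - n(k+1)/2)^2}
#'   {n k (k+1) - \frac{1}{k-1}\sum_{i,\mathrm{ties}} (t^3 - t)}}
#' is referred to a chi-square distribution with `k - 1` degrees of freedom.
#' Without ties this reduces to the classical
#' `12/(nk(k+1)) * sum(R_j^2) - 3n(k+1)`.
#'
#' @param block_matrix numeric matrix, blocks (athletes) in rows, treatments
#'   (weeks) in columns; no missing cells.
#' @return A `test_result` with statistic `Q`.
#' @export
friedman_rank_test <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (anyNA(m))
    stop_domain(paste("missing cells in the block matrix;",
                      "aggregate sessions per (athlete, week) first"))
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 3L)
    stop_domain("need >= 2 blocks and >= 3 treatments (got %d x %d)", n, k)
  r <- t(apply(m, 1L, rank))
  R_j <- colSums(r)
  num <- 12 * sum((R_j - n * (k + 1) / 2)^2)
  tie_term <- sum(apply(r, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  den <- n * k * (k + 1) - tie_term / (k - 1)
  if (num == 0 || den <= 0) {
    q <- 0
    p <- 1
  } else {
    q <- num / den
    p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  new_test_result("Friedman", statistic = q, p_value = p, n = c(n, k),
                  exact = FALSE,
                  notes = if (tie_term > 0) "tie-corrected" else "")
}

#' Bonferroni post hoc comparisons after a Friedman test
#'
#' Default method: all `k(k-1)/2` pairwise Wilcoxon signed-rank tests between
#' treatment columns, with each p-value multiplied by the number of
#' comparisons and clipped at 1. The alternative `"rank_cd"` method compares
#' Friedman mean-rank differences against a normal critical difference.
#'
#' @inheritParams friedman_rank_test
#' @param cfg an [analysis_config()]; `cfg$posthoc` selects the method and
#'   `cfg$alpha` the flagging threshold.
#' @return A data frame with one row per pair: `col_a`, `col_b`,
#'   `statistic`, `p_raw`, `p_adj`, `significant`.
#' @export
bonferroni_posthoc <- function(block_matrix, cfg = analysis_config()) {
  m <- as.matrix(block_matrix)
  k <- ncol(m)
  if (k < 2L) stop_domain("need >= 2 treatments for post hoc comparisons")
  pairs <- utils::combn(k, 2L)
  n_cmp <- ncol(pairs)
  labs <- colnames(m)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  if (cfg$posthoc == "pairwise_wilcoxon") {
    rows <- lapply(seq_len(n_cmp), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      # identical columns carry no evidence of a difference: p = 1
      tr <- if (all(m[, a] == m[, b]))
        list(statistic = NA_real_, p_value = 1)
      else wilcoxon_signed_rank(m[, a], m[, b], cfg)
      data.frame(col_a = labs[a], col_b = labs[b], statistic = tr$statistic,
                 p_raw = tr$p_value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    n <- nrow(m)
    r <- t(apply(m, 1L, rank))
    mean_rank <- colMeans(r)
    se <- sqrt(k * (k + 1) / (6 * n))
    out <- do.call(rbind, lapply(seq_len(n_cmp), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      z <- abs(mean_rank[a] - mean_rank[b]) / se
      data.frame(col_a = labs[a], col_b = labs[b], statistic = z,
                 p_raw = 2 * stats::pnorm(-z), stringsAsFactors = FALSE)
    }))
  }
  out$p_adj <- pmin(1, out$p_raw * n_cmp)
  out$significant <- out$p_adj < cfg$alpha
  out
}

#' Cliff's delta effect size
#'
#' Normalized excess of pairs where one group exceeds the other:
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, in `[-1, 1]`.
#'
#' @param x,y numeric samples.
#' @return A list of class `effect_size` with `delta`, `n_x`, `n_y`.
#' @examples
#' cliffs_delta(c(3, 4, 5), c(1, 2, 3))$delta # 8/9
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop_domain("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values in samples")
  delta <- mean(sign(outer(x, y, "-")))
  structure(list(delta = delta, n_x = length(x), n_y = length(y)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> Cliff's delta = %.3f (n = %d vs %d)\n",
              x$delta, x$n_x, x$n_y))
  invisible(x)
}

#' Coefficient of quartile variation
#'
#' Robust relative-dispersion measure `100 * (Q3 - Q1) / (Q3 + Q1)`,
#' in percent; scale-invariant for positive samples.
#'
#' @param sample numeric vector, `n >= 4`.
#' @param cfg an [analysis_config()] supplying the quartile rule.
#' @return CQV in percent.
#' @export
cqv <- function(sample, cfg = analysis_config()) {
  if (length(sample) < 4L)
    stop_domain("CQV needs at least 4 observations")
  q <- stats::quantile(sample, c(0.25, 0.75), names = FALSE,
                       type = cfg$quantile_type)
  if (sum(q) <= 0)
    stop_domain("CQV undefined: Q1 + Q3 <= 0")
  100 * (q[2] - q[1]) / (q[2] + q[1])
}

#' Median and interquartile range
#'
#' @inheritParams cqv
#' @return A named list with `median` and `iqr`.
#' @export
median_iqr <- function(sample, cfg = analysis_config()) {
  if (length(sample) < 1L) stop_domain("empty sample")
  q <- stats::quantile(sample, c(0.25, 0.5, 0.75), names = FALSE,
                       type = cfg$quantile_type)
  list(median = q[2], iqr = q[3] - q[1])
}

#' Normalized variation (percent change from baseline)
#'
#' `100 * (post - pre) / pre`. For "larger is better" parameters a negative
#' value is a performance loss. Used to remove inter-subject scale before
#' pooling athletes.
#'
#' @param pre,post numeric vectors (recycled as usual); `pre` must be
#'   non-zero.
#' @return Percent change.
#' @export
normalized_variation <- function(pre, post) {
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop_domain("inputs must be finite")
  if (any(pre == 0)) stop_domain("baseline (pre) value is zero")
  100 * (post - pre) / pre
}

#' Kolmogorov-Smirnov normality check with estimated parameters
#'
#' One-sample KS statistic against the normal distribution with mean and
#' standard deviation estimated from the sample,
#' `D = sup |F_n(x) - Phi((x - mean) / sd)|`. Because the reference
#' parameters are fitted, the p-value is calibrated by seeded Monte Carlo
#' (the Lilliefors construction): `ks_mc` normal samples of the same size are
#' drawn, each refitted, and the p-value is the (add-one corrected) fraction
#' of simulated statistics at least as large as the observed one.
#'
#' @param sample numeric vector, `n >= 4`, non-degenerate.
#' @param cfg an [analysis_config()]; `cfg$ks_mc` sets the replicate count.
#' @param seed integer seed for the Monte-Carlo calibration.
#' @return A `test_result` with statistic `D`; `exact` is `FALSE`.
#' @export
ks_normality <- function(sample, cfg = analysis_config(), seed = 171L) {
  n <- length(sample)
  if (n < 4L) stop_domain("normality check needs n >= 4")
  if (anyNA(sample)) stop_domain("missing values in sample")
  s <- stats::sd(sample)
  if (s == 0) stop_domain("degenerate sample: zero variance")
  ks_stat <- function(x) {
    nn <- length(x)
    xs <- sort(x)
    f <- stats::pnorm(xs, mean(x), stats::sd(x))
    max(max(seq_len(nn) / nn - f), max(f - (seq_len(nn) - 1) / nn))
  }
  d_obs <- ks_stat(sample)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d_sim <- vapply(seq_len(cfg$ks_mc), function(i) ks_stat(stats::rnorm(n)),
                  numeric(1))
  p <- (1 + sum(d_sim >= d_obs)) / (cfg$ks_mc + 1)
  new_test_result("KS normality (Lilliefors MC)", statistic = d_obs,
                  p_value = p, n = n, exact = FALSE,
                  notes = sprintf("%d Monte-Carlo replicates, seed %d",
                                  cfg$ks_mc, seed))
}

## save/restore the global RNG state so seeded internals do not disturb the
## caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
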