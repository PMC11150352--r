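long_paired <- function(m) {
  tibble::tibble(
    s = rep(seq_len(nrow(m)), times = ncol(m)),
    c = rep(colnames(m) %||% paste0("C", seq_len(ncol(m))), each = nrow(m)),
    v = as.vector(m)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("repeated-measures ANOVA handles identical columns and matches aov", {
  m <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  res <- rm_anova(long_paired(m), s, c, v)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # independent oracle: base aov with subject error stratum
  set.seed(5)
  m <- matrix(rnorm(18, mean = rep(c(10, 12, 11), each = 6)), 6, 3)
  df <- long_paired(m)
  df$s <- factor(df$s); df$c <- factor(df$c)
  fit <- summary(stats::aov(v ~ c + Error(s), data = df))
  f_oracle <- fit[["Error: Within"]][[1]]["c", "F value"]
  p_oracle <- fit[["Error: Within"]][[1]]["c", "Pr(>F)"]
  res <- rm_anova(long_paired(m), s, c, v)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-10)
})

test_that("two-condition RM-ANOVA equals the squared paired t statistic", {
  m <- matrix(c(1, 2, 3, 2, 4, 5), 3, 2)
  a <- rm_anova(long_paired(m), s, c, v)
  t <- paired_t(m[, 2], m[, 1])
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-12)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-12)
  # and on seeded data
  set.seed(8)
  m <- matrix(rnorm(20, mean = rep(c(0, 0.8), each = 10)), 10, 2)
  a <- rm_anova(long_paired(m), s, c, v)
  t <- paired_t(m[, 2], m[, 1])
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-10)
})

test_that("subject relabeling leaves the F statistic unchanged", {
  set.seed(13)
  m <- matrix(rnorm(15), 5, 3)
  f1 <- rm_anova(long_paired(m), s, c, v)$statistic
  f2 <- rm_anova(long_paired(m[sample(5), ]), s, c, v)$statistic
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("Tukey-Kramer reduces to the paired t-test for two conditions", {
  set.seed(17)
  m <- matrix(rnorm(16, mean = rep(c(0, 1), each = 8)), 8, 2,
              dimnames = list(NULL, c("A", "B")))
  tk <- tukey_kramer(long_paired(m), s, c, v)
  t <- paired_t(m[, "B"], m[, "A"])
  expect_equal(tk$pairs$p_adj, t$p_value, tolerance = 1e-9)
  # identical columns: every adjusted p is 1
  m0 <- matrix(rep(c(5, 6, 7), 3), 3, 3)
  tk0 <- tukey_kramer(long_paired(m0), s, c, v)
  expect_true(all(tk0$pairs$p_adj == 1))
})

test_that("Tukey-adjusted p-values never undercut the pairwise p at pooled error", {
  set.seed(19)
  m <- matrix(rnorm(24, mean = rep(c(0, 0.3, 0.9), each = 8)), 8, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  tk <- tukey_kramer(long_paired(m), s, c, v)
  df_err <- (3 - 1) * (8 - 1)
  p_unadj <- 2 * pt(-tk$pairs$q / sqrt(2), df_err)
  expect_true(all(tk$pairs$p_adj >= p_unadj - 1e-12))
})

test_that("exact Wilcoxon p equals the full sign-pattern enumeration", {
  # 5 uniformly positive differences: p = 2 / 2^5
  res <- wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(res$p_value, 0.0625)
  # degenerate: identical vectors
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p_value, 1)
  # enumeration oracle, several n and tie structures
  set.seed(23)
  for (n in c(6, 9, 10, 12)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(x, y, mode = "exact")$p_value,
                 oracle_wilcoxon_p(x, y), tolerance = 1e-12)
    # with ties in |d|
    xt <- round(x * 2) / 2; yt <- round(y * 2) / 2
    if (any(xt != yt)) {
      expect_equal(wilcoxon_signed_rank(xt, yt, mode = "exact")$p_value,
                   oracle_wilcoxon_p(xt, yt), tolerance = 1e-12)
    }
  }
  # tie-free cross-check against the standard implementation
  set.seed(29)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y, mode = "exact")$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("normal-approximation Wilcoxon agrees with the exact tail for larger n", {
  set.seed(31)
  x <- rnorm(20, 0.6); y <- rnorm(20)
  p_norm <- wilcoxon_signed_rank(x, y, mode = "normal")$p_value
  p_exact <- wilcoxon_signed_rank(x, y, mode = "exact")$p_value
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("paired t-test matches the closed form and is sign-symmetric", {
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$statistic, sqrt(12), tolerance = 1e-4)   # 3.4641
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)
  # oracle: stats::t.test
  set.seed(37)
  x <- rnorm(12, 1); y <- rnorm(12)
  tt <- stats::t.test(x, y, paired = TRUE)
  res <- paired_t(x, y)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  # sign flip negates t, keeps p
  flip <- paired_t(y, x)
  expect_equal(flip$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(flip$p_value, res$p_value, tolerance = 1e-12)
  # symmetric zero-mean differences
  z <- paired_t(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
})

test_that("Cohen's d follows the paired-differences convention", {
  expect_equal(cohens_d_paired(c(2, 4, 6), c(1, 2, 3)), 2)
  expect_equal(cohens_d_paired(1:5, 1:5), 0)
  set.seed(41)
  x <- rnorm(10, 1); y <- rnorm(10)
  expect_equal(cohens_d_paired(3 * x, 3 * y), cohens_d_paired(x, y),
               tolerance = 1e-12)
})

test_that("minimum sample size reproduces the z-formula and its monotonicity", {
  expect_identical(min_sample_size(0.80, 0.01, 1.24), 8L)
  expect_identical(min_sample_size(0.80, 0.05, 1.0), 8L)
  # z-formula oracle recomputed literally
  z <- qnorm(1 - 0.01 / 2) + qnorm(0.80)
  expect_identical(min_sample_size(0.80, 0.01, 1.24),
                   as.integer(ceiling((z / 1.24)^2)))
  # monotone nonincreasing in d and alpha
  d_grid <- c(0.4, 0.8, 1.24, 2, 5)
  ns <- vapply(d_grid, function(d) min_sample_size(0.8, 0.01, d), 1L)
  expect_true(all(diff(ns) <= 0))
  a_grid <- c(0.001, 0.01, 0.05, 0.2)
  ns <- vapply(a_grid, function(a) min_sample_size(0.8, a, 1.24), 1L)
  expect_true(all(diff(ns) <= 0))
  # large effects need almost no one: n -> 1
  expect_identical(min_sample_size(0.8, 0.01, 50), 1L)
  # the noncentral-t alternative is at least as demanding
  expect_gte(min_sample_size(0.8, 0.01, 1.24, method = "nct"),
             min_sample_size(0.8, 0.01, 1.24, method = "z"))
  expect_error(min_sample_size(0.8, 0, 1), class = "cm_input_error")
})

test_that("incomplete paired designs are rejected", {
  df <- tibble::tibble(s = c(1, 1, 2), c = c("A", "B", "A"), v = 1:3)
  expect_error(rm_anova(df, s, c, v), class = "cm_input_error")
})

test_that("tidy and glance return tibbles for test results", {
  res <- paired_t(c(2, 4, 6), c(1, 2, 3))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  tk <- tukey_kramer(long_paired(matrix(rnorm(12), 4, 3)), s, c, v)
  expect_identical(nrow(tidy(tk)), 3L)
  expect_true("p_value" %in% names(glance(res)))
})
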