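new_htest <- function(method, statistic = NA_real_, df = NULL, p_value = NA_real_,
                      estimate = NA_real_, effect_size = NA_real_,
                      pairs = NULL, alpha = NA_real_, note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, estimate = estimate,
                 effect_size = effect_size, pairs = pairs, alpha = alpha,
                 note = note),
            class = "cm_htest")
}

#' @export
print.cm_htest <- function(x, ...) {
  cat(sprintf("<%s>\n", x$method))
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4f%s, p = %.4g\n", x$statistic,
                if (!is.null(x$df)) sprintf(" (df %s)", paste(round(x$df, 2), collapse = ", ")) else "",
                x$p_value))
  }
  if (!is.null(x$pairs)) print(x$pairs)
  invisible(x)
}

#' Tidy a test result
#'
#' @param x A `cm_htest` object.
#' @param ... Unused.
#' @return For post hoc tests, the tibble of pairwise comparisons; otherwise
#'   a one-row tibble with the statistic, degrees of freedom and p-value.
#' @export
tidy.cm_htest <- function(x, ...) {
  if (!is.null(x$pairs)) return(x$pairs)
  tibble(method = x$method, statistic = x$statistic,
         df1 = if (length(x$df)) x$df[1] else NA_real_,
         df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
         p_value = x$p_value, estimate = x$estimate,
         effect_size = x$effect_size)
}

#' @rdname tidy.cm_htest
#' @export
glance.cm_htest <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value)
}

# long data frame -> subjects x conditions matrix, validating completeness
paired_matrix <- function(data, subject, condition, value) {
  subject <- rlang::enquo(subject); condition <- rlang::enquo(condition)
  value <- rlang::enquo(value)
  wide <- data |>
    dplyr::select(s = !!subject, c = !!condition, v = !!value) |>
    tidyr::pivot_wider(names_from = "c", values_from = "v")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$s)
  if (anyNA(m)) abort("Design is incomplete: every subject needs every condition exactly once.",
                      class = "cm_input_error")
  m
}

rm_anova_matrix <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 2L) abort("Need >= 2 conditions and >= 2 subjects.",
                              class = "cm_input_error")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1; ms_err <- ss_err / df2
  f <- if (ms_err <= .Machine$double.eps * abs(ms_cond + 1)) {
    if (ss_cond <= 1e-12 * max(ss_tot, 1)) 0 else Inf
  } else ms_cond / ms_err
  list(f = f, df1 = df1, df2 = df2, ms_err = ms_err, n = n, k = k,
       p = if (f == 0) 1 else pf(f, df1, df2, lower.tail = FALSE))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA on a long paired-samples table:
#' `F = MS_condition / MS_error` with degrees of freedom `(k - 1)` and
#' `(k - 1)(n - 1)`, subject variability removed as a blocking factor. No
#' sphericity correction is applied.
#'
#' @param data Long data frame of paired samples.
#' @param subject,condition,value Unquoted column names identifying the
#'   subject, the within-subject condition and the measured value.
#' @return A `cm_htest` with the F statistic, degrees of freedom and
#'   p-value; [tidy()] turns it into a tibble.
#' @export
#' @examples
#' df <- tidyr::expand_grid(s = 1:5, c = c("A", "B", "C"))
#' df$v <- rnorm(nrow(df)) + as.integer(factor(df$c))
#' rm_anova(df, s, c, v)
rm_anova <- function(data, subject, condition, value) {
  m <- paired_matrix(data, {{ subject }}, {{ condition }}, {{ value }})
  a <- rm_anova_matrix(m)
  new_htest("repeated-measures ANOVA", statistic = a$f, df = c(a$df1, a$df2),
            p_value = a$p)
}

#' Tukey-Kramer post hoc comparisons after repeated-measures ANOVA
#'
#' All pairwise condition comparisons using the studentized range
#' distribution with the ANOVA's error mean square and error degrees of
#' freedom: `q = |diff| / sqrt(MS_error / n)` and the adjusted p-value is
#' the studentized-range tail over `k` groups. With two conditions this
#' reduces exactly to the paired t-test (`q = t * sqrt(2)`).
#'
#' @inheritParams rm_anova
#' @return A `cm_htest` whose `pairs` tibble holds one row per condition
#'   pair with the mean difference, `q` statistic and adjusted p-value.
#' @export
tukey_kramer <- function(data, subject, condition, value) {
  m <- paired_matrix(data, {{ subject }}, {{ condition }}, {{ value }})
  a <- rm_anova_matrix(m)
  cm <- colMeans(m)
  combs <- utils::combn(colnames(m), 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combs)), function(j) {
    g1 <- combs[1, j]; g2 <- combs[2, j]
    diff <- cm[g2] - cm[g1]
    se <- sqrt(a$ms_err / a$n)
    q <- abs(diff) / se
    p_adj <- if (a$ms_err == 0) as.numeric(abs(diff) > 0) * 0 + as.numeric(abs(diff) == 0)
             else ptukey(q, nmeans = a$k, df = a$df2, lower.tail = FALSE)
    tibble(contrast = paste(g2, "-", g1), estimate = unname(diff),
           q = unname(q), p_adj = unname(p_adj))
  })
  new_htest("Tukey-Kramer post hoc", statistic = a$f, df = c(a$df1, a$df2),
            p_value = a$p, pairs = pairs)
}

# exact null distribution of W+ via subset-sum over doubled (integer) ranks
wilcoxon_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)          # index i holds count of doubled-sum i - 1
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  w2 <- round(2 * w)
  p_le <- sum(counts[seq_len(w2 + 1)]) / 2^length(ranks)
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^length(ranks)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided test on paired samples. Zero differences are discarded
#' (the classical convention) and tied absolute differences receive
#' mid-ranks. The exact p-value enumerates all `2^n` sign assignments of
#' the ranks (feasible for `n <= 25`); above that, or on request, a normal
#' approximation with tie correction is used.
#'
#' @param x,y Paired numeric vectors.
#' @param mode `"auto"` (exact up to n = 25), `"exact"`, or `"normal"`.
#' @return A `cm_htest` with the signed-rank sum `W+` and p-value. If all
#'   differences are zero the test is degenerate and `p = 1`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))  # p = 0.0625
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_htest("Wilcoxon matched-pairs signed-rank", statistic = 0,
                     p_value = 1, note = "degenerate: all differences zero"))
  }
  if (n < 3) {
    warn("Fewer than 3 nonzero differences; the test has almost no power.")
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= 25)
  if (use_exact) {
    p <- wilcoxon_exact_p(r, w)
    method <- "Wilcoxon matched-pairs signed-rank (exact)"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon matched-pairs signed-rank (normal approximation)"
  }
  new_htest(method, statistic = w, p_value = p, estimate = stats::median(d))
}

#' Two-tailed paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences, with
#' `n - 1` degrees of freedom and a two-sided p-value.
#'
#' @param x,y Paired numeric vectors (`n >= 2`).
#' @return A `cm_htest`; a zero difference standard deviation is degenerate
#'   (`p = 1` when the mean difference is also zero, error otherwise).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  if (n < 2) abort("Need n >= 2 pairs.", class = "cm_input_error")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      return(new_htest("paired t-test", statistic = 0, df = n - 1, p_value = 1,
                       estimate = 0, note = "degenerate: zero-variance differences"))
    }
    abort("Differences have zero variance but nonzero mean.", class = "cm_degenerate")
  }
  t <- mean(d) / (s / sqrt(n))
  new_htest("paired t-test", statistic = t, df = n - 1,
            p_value = 2 * pt(-abs(t), n - 1), estimate = mean(d),
            effect_size = cohens_d_paired(x, y))
}

#' Cohen's d for paired samples
#'
#' Paired-differences convention: `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y Paired numeric vectors.
#' @return Effect size `d`; 0 when all differences are zero.
#' @export
cohens_d_paired <- function(x, y) {
  d <- x - y
  if (length(d) < 2) abort("Need n >= 2 pairs.", class = "cm_input_error")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(0)
    abort("Zero-variance differences with nonzero mean.", class = "cm_degenerate")
  }
  mean(d) / s
}

#' Minimum sample size for a paired-difference test
#'
#' Normal-approximation sample size for detecting a standardized
#' paired-difference effect `d` at the given significance level and power:
#' `n = ceiling(((z_{1 - alpha/sided} + z_{power}) / d)^2)`. An alternative
#' noncentral-t mode (`method = "nct"`, via the exact one-sample t power
#' calculation) is provided; it yields somewhat larger n and is clearly
#' labeled, since sample-size software differs in which it uses.
#'
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param d Standardized effect size (Cohen's d of the paired differences).
#' @param sided 1 or 2 (default 2, two-sided).
#' @param method `"z"` (normal approximation, default) or `"nct"`
#'   (noncentral t).
#' @return Integer minimum sample size.
#' @export
#' @examples
#' min_sample_size(power = 0.80, alpha = 0.01, d = 1.24)  # 8
min_sample_size <- function(power, alpha, d, sided = 2, method = c("z", "nct")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1 || d <= 0) {
    abort("Require 0 < alpha < 1, 0 < power < 1, d > 0.", class = "cm_input_error")
  }
  if (!sided %in% c(1, 2)) abort("`sided` must be 1 or 2.", class = "cm_input_error")
  if (method == "z") {
    z <- qnorm(1 - alpha / sided) + qnorm(power)
    as.integer(ceiling((z / d)^2))
  } else {
    res <- power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                        type = "one.sample",
                        alternative = if (sided == 2) "two.sided" else "one.sided")
    as.integer(ceiling(res$n))
  }
}
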