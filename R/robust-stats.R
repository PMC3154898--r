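#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) from the one-way ANOVA decomposition of a subjects-by-repeats
#' matrix: `(MSB - MSW) / (MSB + (k - 1) * MSW)`, with a confidence
#' interval from the F distribution (Searle's interval). Used here to
#' quantify the stability of repeated 15-second epochs within a child's
#' activity bout — epochs are exchangeable, so no rater structure is
#' assumed.
#'
#' @param m Numeric matrix (or data frame) with one row per subject and
#'   one column per repeated measurement; no missing cells.
#' @param confidence Confidence level for the interval.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_measurements`.
#' @examples
#' icc_oneway(rbind(c(1, 2), c(3, 4), c(5, 6))) # 15/17
#' @export
icc_oneway <- function(m, confidence = 0.95) {
  m <- as.matrix(m)
  if (anyNA(m)) abort("ICC input must have no missing cells.")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) abort("Need >= 2 subjects and >= 2 measurements.")
  grand <- mean(m)
  row_means <- rowMeans(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  if (ssb + ssw == 0) {
    abort("Zero total variance: the ICC is undefined for constant data.")
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  est <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - confidence
  if (msw == 0) {
    ci <- c(est, est)
  } else {
    f_obs <- msb / msw
    fl <- f_obs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f_obs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  tibble(
    estimate = est, ci_low = ci[1], ci_high = ci[2],
    n_subjects = n, k_measurements = k
  )
}

#' Shapiro-Wilk normality test
#'
#' Thin tidy wrapper around [stats::shapiro.test()], the normality gate
#' used before choosing Pearson over Spearman correlation and before
#' treating a class distribution as Gaussian.
#'
#' @param x Numeric vector, `3 <= length(x) <= 5000`, non-constant.
#' @return A one-row tibble: `statistic` (W), `p_value`, `method`, `n`.
#' @export
normality_test <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.")
  }
  if (var(x) == 0) abort("Normality test undefined for constant data.")
  res <- shapiro.test(x)
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = "shapiro_wilk", n = length(x))
}

#' Normality-gated correlation
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk test at
#' `normality_alpha`, Spearman rank correlation otherwise; the returned
#' row records which was used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param normality_alpha Significance level of the normality gate.
#' @return A one-row tibble: `estimate`, `statistic`, `p_value`, `method`
#'   (`"pearson"` or `"spearman"`), `n`.
#' @export
gated_correlation <- function(x, y, normality_alpha = 0.05) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("Need at least 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0) {
    abort("Correlation undefined for constant input.")
  }
  normal <- normality_test(x)$p_value > normality_alpha &&
    normality_test(y)$p_value > normality_alpha
  method <- if (normal) "pearson" else "spearman"
  res <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(estimate = unname(res$estimate), statistic = unname(res$statistic),
         p_value = res$p.value, method = method, n = length(x))
}

grubbs_critical <- function(n, alpha) {
  tcrit <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

grubbs_p_value <- function(g, n) {
  denom <- (n - 1)^2 - n * g^2
  if (denom <= 0) return(0)
  t_stat <- sqrt((n - 2) * n * g^2 / denom)
  min(1, 2 * n * pt(t_stat, n - 2, lower.tail = FALSE))
}

#' Iterative Grubbs outlier detection
#'
#' Repeatedly applies the two-sided Grubbs test: the most extreme
#' studentised value `G = max|x - mean| / sd` is compared with the
#' critical value at level `alpha`; if it exceeds it, the value is
#' removed, its per-step p-value recorded, and the test re-run on the
#' remainder ("one at a time"). No family-wise correction is applied
#' across steps. Stops cleanly when the remaining values are constant.
#'
#' @param x Numeric vector, n >= 3.
#' @param alpha Two-sided significance level per step.
#' @return An object of class `outlier_report`: a tibble of flagged rows
#'   (`index`, `value`, `statistic`, `p_value`) with attributes `method`,
#'   `alpha` and `n`.
#' @examples
#' grubbs_iterative(c(1, 2, 3, 4, 100))
#' @export
grubbs_iterative <- function(x, alpha = 0.05) {
  if (length(x) < 3) abort("Grubbs test requires n >= 3.")
  keep <- !is.na(x)
  idx <- which(keep)
  vals <- x[keep]
  flagged <- list()
  while (length(vals) >= 3) {
    s <- sd(vals)
    if (s == 0) break
    dev <- abs(vals - mean(vals))
    i_max <- which.max(dev)
    g <- dev[i_max] / s
    n <- length(vals)
    if (g <= grubbs_critical(n, alpha)) break
    flagged[[length(flagged) + 1L]] <- tibble(
      index = idx[i_max], value = vals[i_max], statistic = g,
      p_value = grubbs_p_value(g, n)
    )
    vals <- vals[-i_max]
    idx <- idx[-i_max]
  }
  out <- if (length(flagged)) bind_rows(flagged) else
    tibble(index = integer(), value = numeric(), statistic = numeric(),
           p_value = numeric())
  structure(out, method = "grubbs", alpha = alpha, n = sum(keep),
            class = c("outlier_report", class(out)))
}

#' Medcouple robust skewness
#'
#' The medcouple MC of a sample: the median of the kernel
#' `h(xi, xj) = ((xj - m) - (m - xi)) / (xj - xi)` over all pairs with
#' `xi <= m <= xj` and `xi != xj`, where `m` is the sample median. Pairs
#' tied at the median use the signum kernel of the original definition
#' (`sign(i + j - 1 - q)` over the `q` tied observations) — essential for
#' the heavily zero-inflated sedentary count data this package handles,
#' where most of the sample can sit exactly at the median. The
#' implementation is the O(n^2) kernel enumeration.
#'
#' @param x Numeric vector, n >= 3, not all values identical.
#' @return MC in `[-1, 1]`; 0 for symmetric samples, positive for
#'   right skew.
#' @examples
#' medcouple(c(1, 2, 3, 4, 10)) # 5/18
#' @export
medcouple <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 3) abort("Medcouple requires n >= 3.")
  if (x[1] == x[n]) abort("Medcouple undefined: all values identical.")
  m <- median(x)
  left <- which(x <= m)
  right <- which(x >= m)
  n_below <- sum(x < m)
  q <- sum(x == m)
  h <- numeric(0)
  for (i in left) {
    js <- right[right > i]
    if (!length(js)) next
    xi <- x[i]
    xj <- x[js]
    hij <- ((xj - m) - (m - xi)) / (xj - xi)
    ties <- xi == m & xj == m
    if (any(ties)) {
      ti <- i - n_below
      tj <- js[ties] - n_below
      hij[ties] <- sign(ti + tj - 1 - q)
    }
    h <- c(h, hij)
  }
  median(h)
}

#' Adjusted boxplot outlier detection for skewed data
#'
#' The medcouple-adjusted boxplot: with `MC = medcouple(x)` and type-7
#' sample quartiles, the fences are
#' `[Q1 - 1.5 * exp(-4 * MC) * IQR, Q3 + 1.5 * exp(3 * MC) * IQR]` for
#' `MC >= 0` (exponents -3 and 4 when `MC < 0`); values outside the
#' fences are flagged. For symmetric data (`MC = 0`) this is exactly the
#' classical 1.5 IQR rule. A zero IQR with non-constant data collapses the
#' fences to the quartiles; only values beyond them are flagged.
#'
#' @param x Numeric vector, n >= 4.
#' @return An object of class `outlier_report`: a tibble of flagged rows
#'   (`index`, `value`) with attributes `method`, `medcouple`, `fences`
#'   and `n`.
#' @examples
#' adjusted_boxplot_outliers(reference_sitting_counts())
#' @export
adjusted_boxplot_outliers <- function(x) {
  keep <- !is.na(x)
  vals <- x[keep]
  if (length(vals) < 4) abort("Adjusted boxplot requires n >= 4.")
  mc <- medcouple(vals)
  qs <- quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- qs[2] - qs[1]
  if (mc >= 0) {
    fences <- c(qs[1] - 1.5 * exp(-4 * mc) * iqr,
                qs[2] + 1.5 * exp(3 * mc) * iqr)
  } else {
    fences <- c(qs[1] - 1.5 * exp(-3 * mc) * iqr,
                qs[2] + 1.5 * exp(4 * mc) * iqr)
  }
  out_idx <- which(keep)[vals < fences[1] | vals > fences[2]]
  out <- tibble(index = out_idx, value = x[out_idx])
  structure(out, method = "adjusted_boxplot", medcouple = mc,
            fences = fences, n = length(vals),
            class = c("outlier_report", class(out)))
}

#' Welch two-sample t test
#'
#' Tidy wrapper around [stats::t.test()] with Welch's unequal-variance
#' correction (Satterthwaite degrees of freedom); used for sex-subgroup
#' comparisons.
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `n_x`, `n_y`.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("Each group needs n >= 2.")
  if (var(x) == 0 && var(y) == 0) {
    abort("Welch test undefined: zero variance in both groups.")
  }
  res <- t.test(x, y, var.equal = FALSE)
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, method = "welch_t",
         n_x = length(x), n_y = length(y))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Tidy wrapper around [stats::wilcox.test()] reporting the Mann-Whitney U
#' statistic; exact enumeration for small tie-free samples
#' (`min(n) <= 8`), otherwise the normal approximation with tie and
#' continuity correction. Used for morning/afternoon energy-expenditure
#' comparisons.
#'
#' @param x,y Numeric vectors, each n >= 1.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A one-row tibble: `statistic` (U for `x` vs `y`), `p_value`,
#'   `method`, `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1) abort("Each group needs n >= 1.")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && min(length(x), length(y)) <= 8
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
         n_x = length(x), n_y = length(y))
}

#' Variance in counts attributable to height
#'
#' R-squared of the ordinary least-squares regression of per-child mean
#' counts per minute on height, quantifying how much of the between-child
#' count variation a simple stature effect explains.
#'
#' @param cpm Per-child mean counts per minute.
#' @param height_cm Per-child height.
#' @return R-squared in `[0, 1]`.
#' @export
height_variance_r2 <- function(cpm, height_cm) {
  if (length(cpm) != length(height_cm)) {
    abort("`cpm` and `height_cm` must have equal length.")
  }
  if (length(cpm) < 3) abort("Need n >= 3.")
  if (var(height_cm) == 0) abort("Height is constant; R^2 undefined.")
  summary(lm(cpm ~ height_cm))$r.squared
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report: %s, %d of %d value(s) flagged>\n",
              attr(x, "method"), nrow(x), attr(x, "n")))
  if (identical(attr(x, "method"), "adjusted_boxplot")) {
    f <- attr(x, "fences")
    cat(sprintf("medcouple %.3f, fences [%.3f, %.3f]\n",
                attr(x, "medcouple"), f[1], f[2]))
  }
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.outlier_report <- function(x, ...) {
  as_tibble(x)
}
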