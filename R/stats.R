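#' @section Test results:
#' Every hypothesis-test helper returns a one-row tibble with columns
#' `test_name`, `statistic`, `p_value`, `n1`, `n2`, `notes`, so results
#' from different tests bind into one report table.
#' @name stats-toolkit
NULL

test_result <- function(test_name, statistic, p_value, n1, n2 = NA_integer_,
                        notes = NA_character_) {
  tibble(
    test_name = test_name,
    statistic = as.numeric(statistic),
    p_value = as.numeric(p_value),
    n1 = as.integer(n1), n2 = as.integer(n2),
    notes = notes
  )
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities
#' of all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a`/`b` first row, `c`/`d` second row).
#' @return One-row test-result tibble; the odds-ratio estimate is the
#'   statistic. A table with an all-zero margin yields `p = 1` with a note.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(test_result(
      "fisher_exact", NA_real_, 1, a + b, c + d,
      notes = "degenerate margin"
    ))
  }
  ft <- fisher.test(m, alternative = "two.sided")
  test_result("fisher_exact", unname(ft$estimate), ft$p.value, a + b, c + d)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return One-row test-result tibble.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("welch_t requires at least 2 finite values per sample")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(test_result(
        "welch_t", 0, 1, length(x), length(y),
        notes = "zero variance in both samples"
      ))
    }
    abort("welch_t undefined: zero variance in both samples")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  test_result("welch_t", unname(tt$statistic), tt$p.value, length(x), length(y))
}

#' Brunner-Munzel test (generalised Wilcoxon)
#'
#' Rank-based two-sample test of the relative effect
#' `p = P(X < Y) + 0.5 P(X = Y)`, valid under unequal variances and shapes.
#' Uses the studentized statistic with the Brunner-Munzel t approximation.
#' The relative-effect estimate is attached in a `estimate` column.
#'
#' @param x,y Numeric samples; a warning is issued below 10 observations
#'   per group where the t approximation is rough.
#' @return One-row test-result tibble with an extra `estimate` column.
#' @export
brunner_munzel <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("brunner_munzel requires >= 2 values per sample")
  if (n1 < 10 || n2 < 10) {
    warn("brunner_munzel: sample size below 10; t approximation is rough")
  }
  N <- n1 + n2
  r_all <- rank(c(x, y))
  r1 <- r_all[seq_len(n1)]
  r2 <- r_all[n1 + seq_len(n2)]
  m1 <- mean(r1)
  m2 <- mean(r2)
  p_hat <- (m2 - (n2 + 1) / 2) / n1

  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  if (v1 == 0 && v2 == 0) {
    if (isTRUE(all.equal(m1, m2))) {
      out <- test_result(
        "brunner_munzel", 0, 1, n1, n2,
        notes = "all ties across both samples"
      )
      out$estimate <- 0.5
    } else {
      # complete separation: the studentized statistic degenerates
      out <- test_result(
        "brunner_munzel", sign(m2 - m1) * Inf, 0, n1, n2,
        notes = "complete separation"
      )
      out$estimate <- p_hat
    }
    return(out)
  }
  stat <- n1 * n2 * (m2 - m1) / (N * sqrt(n1 * v1 + n2 * v2))
  df <- (n1 * v1 + n2 * v2)^2 /
    ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(stat), df)
  out <- test_result("brunner_munzel", stat, p, n1, n2)
  out$estimate <- p_hat
  out
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample (3 <= n <= 5000).
#' @return One-row test-result tibble.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("shapiro_wilk requires between 3 and 5000 finite values")
  }
  if (sd(x) == 0) {
    return(test_result(
      "shapiro_wilk", NA_real_, 0, length(x),
      notes = "degenerate constant sample"
    ))
  }
  st <- shapiro.test(x)
  test_result("shapiro_wilk", unname(st$statistic), st$p.value, length(x))
}

#' F-test for equality of two variances
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return One-row test-result tibble.
#' @export
f_test <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("f_test requires at least 2 finite values per sample")
  }
  if (sd(y) == 0) {
    return(test_result(
      "f_test", NA_real_, 0, length(x), length(y),
      notes = "degenerate zero variance"
    ))
  }
  vt <- var.test(x, y)
  test_result("f_test", unname(vt$statistic), vt$p.value, length(x), length(y))
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' Two-sided, normal approximation with continuity correction for samples
#' with ties or n > 50 (the [stats::wilcox.test()] default).
#'
#' @param x,y Numeric samples.
#' @return One-row test-result tibble.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 1 || length(y) < 1) {
    abort("mann_whitney requires non-empty samples")
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
  test_result(
    "mann_whitney", unname(wt$statistic), wt$p.value,
    length(x), length(y)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values.
#' @return Vector of q-values (monotone, bounded by 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(length(p) >= 1)
  p.adjust(p, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Assumption-driven two-sample test selection
#'
#' Implements the test-selection flow used for group comparisons: if the
#' Shapiro-Wilk test accepts normality for both samples (p >= `alpha`),
#' Welch's t-test is used; otherwise the F-test decides between the
#' Mann-Whitney-Wilcoxon test (variances compatible) and the
#' Brunner-Munzel test (variances not compatible). The chosen path is
#' recorded in `notes`.
#'
#' @param x,y Numeric samples of size >= 3.
#' @param alpha Significance level for the assumption tests (default 0.05).
#' @return One-row test-result tibble; `notes` records the decision path.
#' @export
select_two_sample_test <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("select_two_sample_test requires at least 3 values per sample")
  }
  normal_ok <- tryCatch(
    shapiro_wilk(x)$p_value >= alpha && shapiro_wilk(y)$p_value >= alpha,
    error = function(e) NA
  )
  if (is.na(normal_ok)) {
    out <- suppressWarnings(brunner_munzel(x, y))
    out$notes <- "normality test unavailable -> brunner_munzel"
    return(out)
  }
  if (normal_ok) {
    out <- welch_t(x, y)
    out$notes <- "normality accepted -> welch_t"
    return(out)
  }
  equal_var <- f_test(x, y)$p_value >= alpha
  if (isTRUE(equal_var)) {
    out <- mann_whitney(x, y)
    out$notes <- "non-normal, variances compatible -> mann_whitney"
  } else {
    out <- suppressWarnings(brunner_munzel(x, y))
    out$notes <- "non-normal, variances differ -> brunner_munzel"
  }
  out
}
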