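#' @section Inflection-point estimation:
#' The PS values of the retained genes are ordered against standard-normal
#' theoretical quantiles (plotting positions `(i - 0.5) / n`, ties in PS
#' broken by gene symbol) and a continuous one-breakpoint piecewise-linear
#' model `y = b0 + b1 x + b2 (x - psi)+` is fitted by profiling the
#' residual sum of squares over a grid of candidate breaks (the observed
#' quantiles between the 5th and 95th percentiles). The inflection point
#' (IP) is the fitted PS value at the selected break. Significance of the
#' slope change is assessed with a Davies-type bound on the maximal
#' |t|-statistic over the grid, and a percentile bootstrap over genes
#' yields the IP confidence interval that drives the three-period
#' classification.
#' @name qq-inflection
NULL

# Q-Q coordinates for PS values: ascending PS (ties broken by gene symbol)
# against standard-normal quantiles at plotting positions (i - 0.5)/n.
qq_coords <- function(ps, genes = NULL) {
  n <- length(ps)
  if (is.null(genes)) genes <- sprintf("g%06d", seq_len(n))
  ord <- order(ps, genes)
  tibble(
    gene = genes[ord],
    y = ps[ord],
    x = qnorm((seq_len(n) - 0.5) / n)
  )
}

# Profiled least-squares over candidate breaks, vectorised via suffix sums.
# x must be sorted ascending and strictly increasing.
profile_break_fit <- function(x, y, j_candidates) {
  n <- length(x)
  Sx <- sum(x); Sxx <- sum(x^2); Sy <- sum(y)
  Sxy <- sum(x * y); Syy <- sum(y^2)
  sufx <- rev(cumsum(rev(x)))
  sufxx <- rev(cumsum(rev(x^2)))
  sufy <- rev(cumsum(rev(y)))
  sufxy <- rev(cumsum(rev(x * y)))
  suf <- function(v, j) ifelse(j >= n, 0, v[j + 1])

  j <- j_candidates
  psi <- x[j]
  m <- n - j
  sx_r <- suf(sufx, j)
  sxx_r <- suf(sufxx, j)
  sy_r <- suf(sufy, j)
  sxy_r <- suf(sufxy, j)

  Sh <- sx_r - m * psi
  Shh <- sxx_r - 2 * psi * sx_r + m * psi^2
  Shx <- sxx_r - psi * sx_r
  Shy <- sxy_r - psi * sy_r

  a11 <- n; a12 <- Sx; a13 <- Sh
  a22 <- Sxx; a23 <- Shx; a33 <- Shh
  c1 <- Sy; c2 <- Sxy; c3 <- Shy

  det <- a11 * (a22 * a33 - a23^2) -
    a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)

  b0 <- ((a22 * a33 - a23^2) * c1 -
    (a12 * a33 - a13 * a23) * c2 +
    (a12 * a23 - a13 * a22) * c3) / det
  b1 <- (-(a12 * a33 - a23 * a13) * c1 +
    (a11 * a33 - a13^2) * c2 -
    (a11 * a23 - a12 * a13) * c3) / det
  b2 <- ((a12 * a23 - a22 * a13) * c1 -
    (a11 * a23 - a12 * a13) * c2 +
    (a11 * a22 - a12^2) * c3) / det

  rss <- Syy - (b0 * c1 + b1 * c2 + b2 * c3)
  rss <- pmax(rss, 0)
  inv33 <- (a11 * a22 - a12^2) / det
  sigma2 <- rss / (n - 3)
  t_break <- b2 / sqrt(pmax(sigma2 * inv33, .Machine$double.eps))

  bad <- !is.finite(det) | abs(det) < .Machine$double.eps * n^3
  rss[bad] <- Inf
  t_break[bad] <- 0

  tibble(
    j = j, psi = psi, b0 = b0, b1 = b1, b2 = b2,
    rss = rss, t_break = t_break
  )
}

# Davies-type upper bound for the significance of a slope change:
# M = max |t| over the candidate grid, V = total variation of the
# t-process; two-sided p <= 2*pnorm(-M) + V*exp(-M^2/2)/sqrt(8*pi).
davies_p_value <- function(t_break) {
  t_break <- t_break[is.finite(t_break)]
  if (length(t_break) == 0) {
    return(NA_real_)
  }
  M <- max(abs(t_break))
  V <- sum(abs(diff(t_break)))
  min(1, 2 * pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi))
}

#' Fit a one-breakpoint segmented regression
#'
#' Fits the continuous piecewise-linear model
#' `y = b0 + b1 x + b2 (x - psi)+` to paired data by profiled least
#' squares over a grid of candidate breaks (the observed `x` values
#' between the 5th and 95th percentiles) and bounds the significance of
#' the slope change with a Davies-type maximal-|t| test. The test's iid
#' error assumption holds for ordinary regression pairs; for Q-Q data
#' (order statistics) the p-value is descriptive, not calibrated.
#'
#' @param x,y Paired numeric vectors (at least 20 finite pairs; `y` not
#'   constant).
#' @return An `ip_fit` object: `psi_x` (break on the x axis), `ip_ps`
#'   (fitted value at the break), `slopes` (left/right), `davies_p`, `n`,
#'   the sorted `data` and the per-candidate profile.
#' @export
fit_segmented <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 20) abort("insufficient genes: need at least 20 finite values")
  if (diff(range(y)) == 0) abort("degenerate values: all equal")
  ord <- order(x)
  fit_segmented_sorted(tibble(x = x[ord], y = y[ord], gene = NA_character_))
}

fit_segmented_sorted <- function(d) {
  n <- nrow(d)
  j_lo <- max(2L, ceiling(0.05 * n))
  j_hi <- min(n - 2L, floor(0.95 * n))
  if (j_hi <= j_lo) abort("insufficient genes for a breakpoint grid")
  prof <- profile_break_fit(d$x, d$y, j_lo:j_hi)

  best <- prof[which.min(prof$rss), ]
  if (!is.finite(best$rss)) abort("breakpoint fit failed: singular profile")

  structure(
    list(
      psi_x = best$psi,
      ip_ps = best$b0 + best$b1 * best$psi,
      slopes = c(left = best$b1, right = best$b1 + best$b2),
      davies_p = davies_p_value(prof$t_break),
      n = n,
      data = d,
      profile = prof,
      ci = NULL, n_boot = NULL, level = NULL, seed = NULL,
      n_failed_refits = NULL
    ),
    class = "ip_fit"
  )
}

#' Fit the Q-Q inflection point by segmented regression
#'
#' Orders PS values against standard-normal theoretical quantiles and fits
#' a continuous one-breakpoint piecewise-linear model by profiled least
#' squares over the observed quantiles between the 5th and 95th
#' percentiles (see [fit_segmented()]). The inflection point (IP) is the
#' fitted PS at the breakpoint.
#'
#' @param ps Numeric PS values (at least 20 finite, not all equal).
#' @param genes Optional gene symbols used for deterministic tie-breaking.
#' @return An `ip_fit` object (see [fit_segmented()]); `ip_ps` is on the
#'   PS scale and `psi_x` on the theoretical-quantile axis.
#' @export
fit_qq_breakpoint <- function(ps, genes = NULL) {
  keep <- is.finite(ps)
  ps <- ps[keep]
  if (!is.null(genes)) genes <- genes[keep]
  n <- length(ps)
  if (n < 20) abort("insufficient genes: need at least 20 finite PS values")
  if (diff(range(ps)) == 0) abort("degenerate PS values: all equal")
  fit_segmented_sorted(qq_coords(ps, genes))
}

#' Bootstrap confidence interval for the inflection point
#'
#' Resamples genes (PS values) with replacement, refits the segmented Q-Q
#' model on each resample, and forms the percentile interval of the
#' refitted IP values at the requested level. Refits that fail (no
#' identifiable break) are dropped and counted; more than 50% failures is
#' an error. Results are reproducible under a fixed seed.
#'
#' @param ps Numeric PS values.
#' @param genes Optional gene symbols for tie-breaking.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.99999; note that percentile
#'   intervals at such extreme levels under-cover, which the buffering
#'   role of the indefinite period tolerates).
#' @param seed Integer seed for the resampling.
#' @return The `ip_fit` from the full data, augmented with `ci`
#'   (`c(lower, upper)` on the PS scale), `n_boot`, `level`, `seed`,
#'   `n_failed_refits` and the vector of bootstrap IPs (`boot_ips`).
#' @export
bootstrap_ip_ci <- function(ps, genes = NULL, n_boot = 2000,
                            level = 0.99999, seed = NULL) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  fit <- fit_qq_breakpoint(ps, genes)
  keep <- is.finite(ps)
  ps <- ps[keep]
  if (!is.null(genes)) genes <- genes[keep]
  n <- length(ps)

  if (!is.null(seed)) set.seed(seed)
  boot_ips <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_ips[b] <- tryCatch(
      {
        f <- fit_qq_breakpoint(ps[idx], genes = NULL)
        f$ip_ps
      },
      error = function(e) NA_real_
    )
  }
  n_failed <- sum(is.na(boot_ips))
  if (n_failed > n_boot / 2) {
    abort(sprintf(
      "unstable breakpoint: %d of %d bootstrap refits failed",
      n_failed, n_boot
    ))
  }
  ok <- boot_ips[!is.na(boot_ips)]
  alpha <- (1 - level) / 2
  ci <- unname(quantile(ok, c(alpha, 1 - alpha), type = 7))

  fit$ci <- ci
  fit$n_boot <- n_boot
  fit$level <- level
  fit$seed <- seed
  fit$n_failed_refits <- n_failed
  fit$boot_ips <- boot_ips
  fit
}

#' @export
print.ip_fit <- function(x, ...) {
  cat("Segmented Q-Q inflection-point fit\n")
  cat(sprintf("  n genes: %d\n", x$n))
  cat(sprintf(
    "  break psi_x = %.4f (theoretical quantile), IP = %.3f (PS)\n",
    x$psi_x, x$ip_ps
  ))
  cat(sprintf(
    "  slopes: left %.3f, right %.3f; Davies p = %.3g\n",
    x$slopes[1], x$slopes[2], x$davies_p
  ))
  if (!is.null(x$ci)) {
    cat(sprintf(
      "  %.5g%% bootstrap CI of IP: [%.3f, %.3f] (%d resamples, %d failed)\n",
      100 * x$level, x$ci[1], x$ci[2], x$n_boot, x$n_failed_refits
    ))
  }
  invisible(x)
}

#' Tidy an inflection-point fit
#'
#' @param x An `ip_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per model quantity (`psi_x`, `ip_ps`,
#'   `slope_left`, `slope_right`, and CI bounds when available).
#' @method tidy ip_fit
#' @export
tidy.ip_fit <- function(x, ...) {
  out <- tibble(
    term = c("psi_x", "ip_ps", "slope_left", "slope_right"),
    estimate = c(x$psi_x, x$ip_ps, unname(x$slopes[1]), unname(x$slopes[2]))
  )
  if (!is.null(x$ci)) {
    out <- bind_rows(out, tibble(
      term = c("ci_lower", "ci_upper"),
      estimate = c(x$ci[1], x$ci[2])
    ))
  }
  out
}

#' Glance at an inflection-point fit
#'
#' @param x An `ip_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `psi_x`, `ip_ps`, `davies_p`, CI bounds,
#'   `n_boot`, `level`.
#' @method glance ip_fit
#' @export
glance.ip_fit <- function(x, ...) {
  tibble(
    n = x$n, psi_x = x$psi_x, ip_ps = x$ip_ps, davies_p = x$davies_p,
    ci_lower = if (is.null(x$ci)) NA_real_ else x$ci[1],
    ci_upper = if (is.null(x$ci)) NA_real_ else x$ci[2],
    n_boot = x$n_boot %||% NA_integer_,
    level = x$level %||% NA_real_
  )
}

#' Plot the PS Q-Q plot with the fitted segments
#'
#' @param object An `ip_fit` object.
#' @param ... Unused.
#' @return A ggplot: Q-Q points, fitted piecewise-linear model, the
#'   breakpoint, and (when available) the IP confidence band on the PS
#'   scale.
#' @method autoplot ip_fit
#' @export
autoplot.ip_fit <- function(object, ...) {
  d <- object$data
  b <- object$profile[which.min(object$profile$rss), ]
  fitted <- tibble(
    x = d$x,
    y = b$b0 + b$b1 * d$x + b$b2 * pmax(d$x - b$psi, 0)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6)
  if (!is.null(object$ci)) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = -Inf, xmax = Inf, ymin = object$ci[1], ymax = object$ci[2],
      fill = "grey70", alpha = 0.4
    )
  }
  p +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::geom_vline(
      xintercept = object$psi_x, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Theoretical quantile",
      y = "Propensity score (PS)",
      title = sprintf(
        "Q-Q inflection point: IP = %.2f (Davies p = %.2g)",
        object$ip_ps, object$davies_p
      )
    ) +
    ggplot2::theme_minimal()
}
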