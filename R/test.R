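# Fast test evaluation on bare vectors; no tibbles, no tie warnings. Used by
# srd_test() and, heavily, by the Monte-Carlo study engine.
test_core <- function(x, y, measure = "spearman", method = "modified",
                      alternative = "two.sided", kernel_fn = quartic_kernel,
                      bandwidth = NULL, exact_iid_kendall = FALSE,
                      sigma2 = NULL) {
  m <- length(x)
  rcx <- rank(x, ties.method = "average"); rcx <- rcx - mean(rcx)
  rcy <- rank(y, ties.method = "average"); rcy <- rcy - mean(rcy)
  if (all(rcx == 0) || all(rcy == 0)) {
    abort("Degenerate input: constant series (zero rank variance).")
  }
  est <- switch(measure,
                spearman = sum(rcx * rcy) / sqrt(sum(rcx^2) * sum(rcy^2)),
                kendall  = kendall_core(x, y, warn_ties = FALSE))
  floored <- FALSE
  if (method == "classical") {
    sigma2 <- m / (m - 1)
  } else if (is.null(sigma2)) {
    bw <- if (is.null(bandwidth)) default_bandwidth(m) else bandwidth
    sigma2 <- lrv_core(rcx, rcy, kernel_fn, bw)$sigma2
    if (sigma2 <= 0) {
      sigma2 <- 1 / m
      floored <- TRUE
    }
  }
  if (measure == "kendall" && method == "classical" && exact_iid_kendall) {
    statistic <- est / sqrt(2 * (2 * m + 5) / (9 * m * (m - 1)))
    var_scale <- NA_real_
  } else {
    var_scale <- if (measure == "kendall") (4 / 9) * sigma2 else sigma2
    statistic <- sqrt(m) * est / sqrt(var_scale)
  }
  p <- switch(alternative,
              two.sided = 2 * pnorm(-abs(statistic)),
              greater   = pnorm(statistic, lower.tail = FALSE),
              less      = pnorm(statistic))
  list(estimate = est, statistic = statistic, sigma2 = sigma2,
       variance = var_scale, p_value = p, floored = floored)
}

#' Significance test for rank cross-correlations under autocorrelation
#'
#' Tests the null hypothesis of pairwise independence between two time series
#' using Spearman's Rho or Kendall's Tau. Two variance conventions are
#' offered:
#' \describe{
#'   \item{`"modified"`}{standardises by the kernel long-run variance
#'     [long_run_variance()], which accounts for autocorrelation in both
#'     components (valid for strictly stationary, beta-mixing, i.e.
#'     short-range dependent, series);}
#'   \item{`"classical"`}{the textbook iid-based test, with
#'     \eqn{\hat\sigma^2 = n/(n-1)}; anti-conservative when both series are
#'     positively autocorrelated.}
#' }
#' The statistic is \eqn{T = \sqrt{n}\,\hat\rho_S / \sqrt{\hat\sigma^2}} for
#' Spearman and \eqn{T = \sqrt{n}\,\hat\tau / \sqrt{(4/9)\hat\sigma^2}} for
#' Kendall (the Kendall limit variance is exactly 4/9 of the Spearman one);
#' p-values come from the standard normal.
#'
#' @param data A data frame holding the paired series.
#' @param x,y Columns with the two series (tidy evaluation; defaults `x`, `y`).
#' @param measure `"spearman"` (default) or `"kendall"`.
#' @param method `"modified"` (default) or `"classical"`.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @param lag Integer lag; positive pairs \eqn{x_i} with \eqn{y_{i+lag}}. The
#'   test runs on the overlap of length \eqn{n - |lag|}, which replaces
#'   \eqn{n} everywhere.
#' @param kernel,bandwidth Passed to [long_run_variance()] for the modified
#'   test.
#' @param alpha Significance level in (0, 1), used for the `reject` flag and
#'   the reported critical region.
#' @param exact_iid_kendall For the classical Kendall test only: use the exact
#'   iid null variance \eqn{2(2n+5)/(9n(n-1))} of \eqn{\hat\tau} instead of
#'   substituting \eqn{n/(n-1)} into the asymptotic form. Default `FALSE`.
#' @param warn_ties Warn on midranks.
#' @return An object of class `srd_test` with the estimate, statistic,
#'   variance used, p-value, rejection flag and critical region on the
#'   estimate scale. Use [tidy()] for a one-row tibble.
#' @examples
#' set.seed(1)
#' d <- simulate_var1(80, phi_x = 0.8, phi_y = 0.8, rho = 0)
#' srd_test(d, method = "modified")
#' srd_test(d, method = "classical")
#' @export
srd_test <- function(data, x = x, y = y,
                     measure = c("spearman", "kendall"),
                     method = c("modified", "classical"),
                     alternative = c("two.sided", "greater", "less"),
                     lag = 0L, kernel = "quartic", bandwidth = NULL,
                     alpha = 0.05, exact_iid_kendall = FALSE,
                     warn_ties = TRUE) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  pr <- extract_pair(data, enquo(x), enquo(y))
  p <- apply_lag(pr$x, pr$y, lag)
  if (p$m < 10L) {
    warn(sprintf("Effective sample size %d is below 10; the normal approximation may be poor.", p$m))
  }
  if (warn_ties && (anyDuplicated(p$x) > 0L || anyDuplicated(p$y) > 0L)) {
    warn("Ties present; midranks used, but the asymptotic theory assumes tie-free data.")
  }
  ks <- resolve_kernel(kernel)
  bw <- resolve_bandwidth(bandwidth, p$m)
  res <- test_core(p$x, p$y, measure = measure, method = method,
                   alternative = alternative, kernel_fn = ks$fn, bandwidth = bw,
                   exact_iid_kendall = exact_iid_kendall)
  if (res$floored) {
    warn(sprintf("Non-positive long-run variance floored at 1/n = %.4f.", 1 / p$m))
  }
  cr <- critical_region(p$m, alpha = alpha, sigma2 = res$sigma2,
                        measure = measure, alternative = alternative)
  structure(list(
    estimate = res$estimate, statistic = res$statistic,
    sigma2 = res$sigma2, variance = res$variance, p_value = res$p_value,
    reject = res$p_value < alpha, alpha = alpha,
    measure = measure, method = method, alternative = alternative,
    lag = as.integer(lag), n_effective = p$m,
    kernel = if (method == "modified") ks$name else NA_character_,
    bandwidth = if (method == "modified") bw else NA_real_,
    floored = res$floored, critical_region = cr
  ), class = "srd_test")
}

#' Rejection boundaries on the estimate scale
#'
#' The values of \eqn{\hat\rho_S} (or \eqn{\hat\tau}) at which the test at
#' level `alpha` starts rejecting: \eqn{\pm z_{1-\alpha/2}\sqrt{v/n}} for the
#' two-sided test, where \eqn{v} is the variance of the limiting law
#' (\eqn{\sigma^2} for Spearman, \eqn{(4/9)\sigma^2} for Kendall).
#'
#' @param n Effective sample size.
#' @param alpha Significance level in (0, 1).
#' @param sigma2 Long-run variance (1 corresponds to iid observations).
#' @param measure `"spearman"` or `"kendall"`.
#' @param alternative Sidedness of the test.
#' @return A tibble with columns `lower` and `upper` (one of them infinite for
#'   one-sided alternatives).
#' @examples
#' critical_region(100, alpha = 0.05, sigma2 = 1)
#' @export
critical_region <- function(n, alpha = 0.05, sigma2 = 1,
                            measure = c("spearman", "kendall"),
                            alternative = c("two.sided", "greater", "less")) {
  measure <- match.arg(measure)
  alternative <- match.arg(alternative)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  v <- if (measure == "kendall") (4 / 9) * sigma2 else sigma2
  half <- qnorm(1 - alpha / 2) * sqrt(v / n)
  one <- qnorm(1 - alpha) * sqrt(v / n)
  switch(alternative,
         two.sided = tibble::tibble(lower = -half, upper = half),
         greater   = tibble::tibble(lower = -Inf, upper = one),
         less      = tibble::tibble(lower = -one, upper = Inf))
}

#' @export
print.srd_test <- function(x, ...) {
  cat(sprintf("\n\t%s rank cross-correlation test (%s)\n\n",
              tools::toTitleCase(x$method),
              if (x$measure == "spearman") "Spearman's Rho" else "Kendall's Tau"))
  cat(sprintf("estimate = %.4f, T = %.4f, p-value = %.4g (%s)\n",
              x$estimate, x$statistic, x$p_value, x$alternative))
  cat(sprintf("sigma^2 = %.4f (%s), n = %d, lag = %d\n", x$sigma2,
              if (x$method == "modified")
                sprintf("%s kernel, bandwidth %.2f", x$kernel, x$bandwidth)
              else "iid-based n/(n-1)",
              x$n_effective, x$lag))
  cat(sprintf("%s H0 of pairwise independence at alpha = %g\n",
              if (x$reject) "Reject" else "Do not reject", x$alpha))
  invisible(x)
}

#' @describeIn srd_test One-row tibble of the test result.
#' @export
tidy.srd_test <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, method = x$method, lag = x$lag,
    n_effective = x$n_effective, estimate = x$estimate,
    statistic = x$statistic, sigma2 = x$sigma2, p_value = x$p_value,
    reject = x$reject, alpha = x$alpha, alternative = x$alternative
  )
}

#' @describeIn srd_test Same one-row tibble (a test has a single summary row).
#' @export
glance.srd_test <- function(x, ...) tidy(x)

#' @describeIn srd_test Null density with shaded critical region and the
#'   observed estimate.
#' @param object An `srd_test` object.
#' @export
autoplot.srd_test <- function(object, ...) {
  v <- if (is.na(object$variance)) object$sigma2 else object$variance
  sd0 <- sqrt(v / object$n_effective)
  lim <- max(4 * sd0, abs(object$estimate) * 1.2)
  grid <- tibble::tibble(
    r = seq(-lim, lim, length.out = 400),
    density = stats::dnorm(.data$r, sd = sd0)
  )
  cr <- object$critical_region
  shaded <- dplyr::filter(grid, .data$r <= cr$lower | .data$r >= cr$upper)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$r, y = .data$density)) +
    ggplot2::geom_area(data = shaded, fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2) +
    ggplot2::annotate("point", x = object$estimate, y = 0, size = 3, shape = 21,
                      fill = "white") +
    ggplot2::labs(
      x = if (object$measure == "spearman") expression(hat(rho)[S]) else expression(hat(tau)),
      y = "null density",
      title = sprintf("%s test: estimate %.3f, p = %.3g",
                      tools::toTitleCase(object$method), object$estimate,
                      object$p_value),
      subtitle = sprintf("sigma^2 = %.3f, n = %d, critical region beyond (%.3f, %.3f)",
                         object$sigma2, object$n_effective, cr$lower, cr$upper)
    )
}
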