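#' Ranks of a series, with midranks for ties
#'
#' Ascending ranks: rank 1 for the smallest observation. Tied observations
#' receive midranks (the average of the ranks they span), in which case a
#' warning is emitted because the asymptotic theory behind the significance
#' tests assumes absolutely continuous marginals, i.e. tie-free data.
#'
#' @param v A finite numeric vector.
#' @param warn_ties Emit a warning when ties are present (default `TRUE`).
#' @return A numeric vector of ranks with attributes `tie_flag` (logical) and
#'   `mean_rank` (`(n + 1) / 2`).
#' @examples
#' compute_ranks(c(3.1, 1.2, 2.7))
#' @export
compute_ranks <- function(v, warn_ties = TRUE) {
  check_series(v, deparse(substitute(v)), min_n = 1L)
  r <- rank(v, ties.method = "average")
  ties <- anyDuplicated(v) > 0L
  if (ties && warn_ties) {
    warn(paste(
      "Ties detected; midranks are used, but the asymptotic null distributions",
      "are derived for tie-free (absolutely continuous) data."
    ))
  }
  structure(r, tie_flag = ties, mean_rank = (length(v) + 1) / 2)
}

# Centered ranks; errors on constant input (zero rank variance).
centered_ranks <- function(v, label = "series", warn_ties = TRUE, call = rlang::caller_env()) {
  r <- rank(v, ties.method = "average")
  rc <- r - mean(r)
  if (all(rc == 0)) {
    abort(sprintf("Degenerate input: `%s` is constant (zero rank variance).", label),
          call = call)
  }
  if (warn_ties && anyDuplicated(v) > 0L) {
    warn(paste0("Ties in `", label, "`; midranks used, asymptotics assume tie-free data."))
  }
  rc
}

# Shift a pair by `lag`: positive lag pairs x_i with y_{i+lag}. Returns the
# overlapping subseries of length n - |lag|.
apply_lag <- function(x, y, lag, min_n = 3L, call = rlang::caller_env()) {
  n <- length(x)
  lag <- as.integer(lag)
  m <- n - abs(lag)
  if (m < min_n) {
    abort(sprintf("Lag %d leaves an overlap of %d observations; need at least %d.",
                  lag, m, min_n), call = call)
  }
  if (lag > 0L) {
    list(x = x[seq_len(m)], y = y[seq_len(m) + lag], m = m)
  } else if (lag < 0L) {
    list(x = x[seq_len(m) - lag], y = y[seq_len(m)], m = m)
  } else {
    list(x = x, y = y, m = n)
  }
}

spearman_core <- function(x, y, warn_ties = TRUE, call = rlang::caller_env()) {
  rcx <- centered_ranks(x, "x", warn_ties = warn_ties, call = call)
  rcy <- centered_ranks(y, "y", warn_ties = warn_ties, call = call)
  sum(rcx * rcy) / sqrt(sum(rcx^2) * sum(rcy^2))
}

# Inversions of a tie-free numeric vector by divide and conquer; findInterval
# counts, per right-half element, how many left-half elements precede it.
count_inversions <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(inv = 0, sorted = v))
  m <- n %/% 2L
  a <- count_inversions(v[seq_len(m)])
  b <- count_inversions(v[(m + 1L):n])
  cross <- sum(m - findInterval(b$sorted, a$sorted))
  list(inv = a$inv + b$inv + cross, sorted = sort(c(a$sorted, b$sorted)))
}

kendall_core <- function(x, y, warn_ties = TRUE, call = rlang::caller_env()) {
  n <- length(x)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("Degenerate input: constant series (zero rank variance).", call = call)
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (ties) {
    if (warn_ties) {
      warn("Ties present; sign products for tied pairs are zero, asymptotics assume tie-free data.")
    }
    s <- 0
    for (i in seq_len(n - 1L)) {
      idx <- (i + 1L):n
      s <- s + sum(sign(x[idx] - x[i]) * sign(y[idx] - y[i]))
    }
    return(2 * s / (n * (n - 1)))
  }
  ys <- y[order(x)]
  inv <- count_inversions(ys)$inv
  npairs <- n * (n - 1) / 2
  2 * (npairs - 2 * inv) / (n * (n - 1))
}

#' Spearman's Rho of a paired series
#'
#' The product-moment correlation of the two rank vectors; for tie-free data
#' this equals \eqn{1 - 6 \sum d_i^2 / (n(n^2 - 1))}. A non-zero `lag` pairs
#' \eqn{x_i} with \eqn{y_{i+lag}} and uses the overlap of length
#' \eqn{n - |lag|}.
#'
#' @param x,y Finite numeric vectors of common length.
#' @param lag Integer lag (positive shifts `y` forward relative to `x`).
#' @param warn_ties Warn on midranks.
#' @return The estimate, a number in \eqn{[-1, 1]}.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
spearman_rho <- function(x, y, lag = 0L, warn_ties = TRUE) {
  check_series(x, "x"); check_series(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  p <- apply_lag(x, y, lag)
  spearman_core(p$x, p$y, warn_ties = warn_ties)
}

#' Kendall's Tau of a paired series
#'
#' The average sign product over all pairs,
#' \eqn{\hat\tau = \frac{2}{n(n-1)} \sum_{i<j} \mathrm{sgn}(R_j^X - R_i^X)\,
#' \mathrm{sgn}(R_j^Y - R_i^Y)}. Tie-free inputs are computed in
#' \eqn{O(n \log n)} by inversion counting; inputs with ties fall back to pair
#' enumeration with zero sign products for tied pairs.
#'
#' @inheritParams spearman_rho
#' @return The estimate, a number in \eqn{[-1, 1]}.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))
#' @export
kendall_tau <- function(x, y, lag = 0L, warn_ties = TRUE) {
  check_series(x, "x"); check_series(y, "y")
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  p <- apply_lag(x, y, lag)
  kendall_core(p$x, p$y, warn_ties = warn_ties)
}

rank_autocorr_core <- function(rc, h) {
  n <- length(rc)
  sum(rc[seq_len(n - h)] * rc[(1L + h):n]) / sum(rc^2)
}

#' Lagged rank (Spearman) autocorrelation of a single series
#'
#' For lag \eqn{h}, the numerator is \eqn{\sum_{i=1}^{n-h} (R_i - \bar R)
#' (R_{i+h} - \bar R)} and the denominator the full-sample rank sum of squares
#' \eqn{\sum_{i=1}^{n} (R_i - \bar R)^2}. This normalisation makes the matrix
#' of autocorrelations positive semidefinite, the standard lag-window property
#' the long-run variance estimator relies on.
#'
#' @param v A finite numeric vector, length at least 3.
#' @param lags Integer lags in `1:(n - 2)`; defaults to all of them.
#' @param warn_ties Warn on midranks.
#' @return A tibble with columns `lag` and `acf`.
#' @examples
#' rank_autocorr(1:5, lags = 1)
#' @export
rank_autocorr <- function(v, lags = NULL, warn_ties = TRUE) {
  check_series(v, "v")
  n <- length(v)
  if (is.null(lags)) lags <- seq_len(n - 2L)
  lags <- as.integer(lags)
  if (any(lags < 1L | lags > n - 2L)) {
    abort(sprintf("Lags must lie in 1..%d for a series of length %d.", n - 2L, n))
  }
  rc <- centered_ranks(v, "v", warn_ties = warn_ties)
  tibble::tibble(lag = lags,
                 acf = vapply(lags, function(h) rank_autocorr_core(rc, h), numeric(1)))
}

#' Rank cross-correlation of two columns of a data frame
#'
#' Data-frame-first wrapper around [spearman_rho()] and [kendall_tau()].
#'
#' @param data A data frame holding the paired series.
#' @param x,y Columns with the two series (tidy evaluation; defaults `x`, `y`).
#' @param measure `"spearman"` or `"kendall"`.
#' @param lag Integer lag (positive shifts `y` forward relative to `x`).
#' @return A one-row tibble with `measure`, `lag`, `n_effective`, `estimate`,
#'   `ties`.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
#' rank_correlation(d)
#' @export
rank_correlation <- function(data, x = x, y = y,
                             measure = c("spearman", "kendall"), lag = 0L) {
  measure <- match.arg(measure)
  pr <- extract_pair(data, enquo(x), enquo(y))
  p <- apply_lag(pr$x, pr$y, lag)
  ties <- anyDuplicated(p$x) > 0L || anyDuplicated(p$y) > 0L
  est <- switch(measure,
                spearman = spearman_core(p$x, p$y),
                kendall  = kendall_core(p$x, p$y))
  tibble::tibble(measure = measure, lag = as.integer(lag),
                 n_effective = p$m, estimate = est, ties = ties)
}
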