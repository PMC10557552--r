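#' Lag-window kernels and the default bandwidth
#'
#' Kernels downweight rank autocorrelations at large lags inside the long-run
#' variance estimator: high-lag autocorrelations are estimated from fewer
#' overlapping pairs and are noisier. Both built-ins are symmetric, equal 1 at
#' 0, and vanish outside \eqn{[-1, 1]}, so lags beyond the bandwidth contribute
#' nothing.
#'
#' @param t Numeric vector of scaled lags \eqn{h / b_n}.
#' @return Kernel weights, same length as `t`.
#' @examples
#' quartic_kernel(c(0, 0.5, 1.5))
#' bartlett_kernel(c(0, -0.25, 2))
#' @name kernels
NULL

#' @rdname kernels
#' @export
quartic_kernel <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  ifelse(abs(t) <= 1, (1 - t^2)^2, 0)
}

#' @rdname kernels
#' @export
bartlett_kernel <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  ifelse(abs(t) <= 1, 1 - abs(t), 0)
}

#' Default bandwidth rule
#'
#' \eqn{b_n = 3 n^{1/4}}, used as a real number (not truncated to an integer).
#' It is non-decreasing in \eqn{n} and grows slower than \eqn{\sqrt n}, as the
#' consistency of the long-run variance estimator requires.
#'
#' @param n Sample size, at least 3.
#' @return The bandwidth, a positive real.
#' @examples
#' default_bandwidth(16) # 6
#' @export
default_bandwidth <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3) {
    abort("`n` must be a single sample size >= 3.")
  }
  3 * n^(1 / 4)
}

# Resolve a kernel argument ("quartic", "bartlett", or a function) to a
# weight function, validating the finite kernel contract for custom functions:
# k(0) = 1, symmetry, |k| <= 1, support within [-1, 1].
resolve_kernel <- function(kernel, call = rlang::caller_env()) {
  if (is.character(kernel)) {
    kernel <- match.arg(kernel, c("quartic", "bartlett"))
    return(list(name = kernel,
                fn = switch(kernel, quartic = quartic_kernel, bartlett = bartlett_kernel)))
  }
  if (is.function(kernel)) {
    tt <- seq(-2, 2, by = 0.125)
    w <- vapply(tt, kernel, numeric(1))
    ok <- isTRUE(all.equal(kernel(0), 1)) &&
      max(abs(w - rev(w))) < 1e-10 &&
      all(abs(w) <= 1 + 1e-10) &&
      all(abs(w[abs(tt) > 1]) < 1e-10)
    if (!ok) {
      abort(paste("Custom kernel must satisfy k(0) = 1, k(t) = k(-t), |k| <= 1",
                  "and k(t) = 0 for |t| > 1."), call = call)
    }
    return(list(name = "custom", fn = function(t) vapply(t, kernel, numeric(1))))
  }
  abort('`kernel` must be "quartic", "bartlett", or a kernel function.', call = call)
}

# Resolve a bandwidth argument (NULL -> default rule) for overlap length m.
resolve_bandwidth <- function(bandwidth, m, call = rlang::caller_env()) {
  if (is.null(bandwidth)) return(default_bandwidth(m))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    abort("`bandwidth` must be NULL (default rule) or a single positive number.",
          call = call)
  }
  as.numeric(bandwidth)
}
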