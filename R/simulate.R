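# Draw m correlated standard-normal pairs (unit variances, correlation rho).
rbinorm <- function(m, rho) {
  z1 <- rnorm(m)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  cbind(z1, z2)
}

resolve_transform <- function(marginal, call = rlang::caller_env()) {
  if (is.null(marginal)) return(NULL)
  if (is.function(marginal)) return(marginal)
  switch(as.character(marginal),
         identity = identity,
         exp = exp,
         cube = function(v) v^3,
         lognormal = exp,
         abort(sprintf('Unknown marginal transform "%s"; supply a strictly increasing function.',
                       marginal), call = call))
}

apply_transform <- function(x, y, fn, call = rlang::caller_env()) {
  if (is.null(fn)) return(list(x = x, y = y))
  tx <- fn(x); ty <- fn(y)
  if (!identical(order(tx), order(x)) || !identical(order(ty), order(y))) {
    abort("Marginal transform is not strictly increasing on the sampled values.",
          call = call)
  }
  list(x = tx, y = ty)
}

#' Simulate a bivariate Gaussian VAR(1) process
#'
#' Each component follows an AR(1) recursion with its own coefficient
#' (`phi_x`, `phi_y`); the innovations are bivariate normal with unit
#' variances and cross-correlation `rho`, which is the only source of
#' dependence between the components. With `phi_x = phi_y = 0` the process is
#' iid. The path is strictly stationary from the first observation: the
#' initial state is drawn from the exact stationary distribution (component
#' variances \eqn{1/(1-\varphi^2)}, cross-covariance
#' \eqn{\rho/(1-\varphi_X \varphi_Y)}). The population Spearman
#' cross-correlation is [true_spearman_var1()].
#'
#' @param n Path length.
#' @param phi_x,phi_y AR(1) coefficients, absolute value below 1.
#' @param rho Innovation cross-correlation in \eqn{[-1, 1]}.
#' @param marginal Optional strictly increasing marginal transform applied
#'   componentwise (name `"identity"`, `"exp"`, `"cube"`, or a function);
#'   leaves all rank statistics unchanged.
#' @param burn_in Extra leading steps discarded before the output (default 0;
#'   unnecessary given the exact stationary start, exposed for cross-checks).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `t`, `x`, `y`.
#' @examples
#' simulate_var1(5, phi_x = 0.8, phi_y = 0.8, rho = 0, seed = 1)
#' @export
simulate_var1 <- function(n, phi_x = 0, phi_y = 0, rho = 0, marginal = NULL,
                          burn_in = 0L, seed = NULL) {
  if (abs(phi_x) >= 1 || abs(phi_y) >= 1) {
    abort("Stationarity requires |phi_x| < 1 and |phi_y| < 1.")
  }
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  if (n < 1) abort("`n` must be positive.")
  fn <- resolve_transform(marginal)
  with_seed(seed, {
    p <- var1_path(n, phi_x, phi_y, rho, burn_in)
    tr <- apply_transform(p$x, p$y, fn)
    tibble::tibble(t = seq_len(n), x = tr$x, y = tr$y)
  })
}

# Bare-vector VAR(1) path (no seed handling, no tibble); hot path for studies.
var1_path <- function(n, phi_x, phi_y, rho, burn_in = 0L) {
  total <- n + burn_in
  # exact stationary initial state
  vx <- 1 / (1 - phi_x^2)
  vy <- 1 / (1 - phi_y^2)
  r0 <- (rho / (1 - phi_x * phi_y)) / sqrt(vx * vy)
  z <- rbinorm(1L, r0)
  e <- rbinorm(total, rho)
  x <- as.numeric(filter(e[, 1], phi_x, method = "recursive", init = z[1] * sqrt(vx)))
  y <- as.numeric(filter(e[, 2], phi_y, method = "recursive", init = z[2] * sqrt(vy)))
  if (burn_in > 0L) {
    x <- x[-seq_len(burn_in)]
    y <- y[-seq_len(burn_in)]
  }
  list(x = x, y = y)
}

#' Population Spearman cross-correlation of the Gaussian VAR(1) model
#'
#' For bivariate normal pairs with Pearson cross-correlation \eqn{\rho}, the
#' Spearman cross-correlation is \eqn{\rho_S = \frac{6}{\pi}
#' \arcsin(\rho / 2)}. In the VAR(1) model with equal innovation scaling in
#' both components, the stationary Pearson cross-correlation equals the
#' innovation correlation parameter, so this maps the simulator parameter to
#' the estimand of the rank test.
#'
#' @param rho Pearson cross-correlation in \eqn{[-1, 1]}.
#' @return The Spearman cross-correlation.
#' @examples
#' true_spearman_var1(0.5)
#' @export
true_spearman_var1 <- function(rho) {
  if (any(abs(rho) > 1)) abort("`rho` must lie in [-1, 1].")
  (6 / pi) * asin(rho / 2)
}

#' Draw pairs from a bivariate t distribution
#'
#' Elliptical bivariate t via the Gaussian scale mixture
#' \eqn{Z \sqrt{\nu / W}} with \eqn{Z \sim N(0, \Sigma)} (unit diagonal,
#' off-diagonal `rho`) and \eqn{W \sim \chi^2_\nu}. With
#' `independent = TRUE`, two independent univariate t draws are returned
#' instead (pairwise independent components, unlike the elliptical
#' `rho = 0` case, which is uncorrelated but not independent).
#'
#' @param m Number of pairs.
#' @param nu Degrees of freedom, positive. Small values give heavy tails; for
#'   \eqn{\nu \le 2} the Pearson correlation does not exist while rank
#'   correlations remain well defined.
#' @param rho Shape-matrix off-diagonal in \eqn{[-1, 1]}.
#' @param independent Draw two independent univariate t series instead.
#' @param seed Optional integer seed.
#' @return A tibble with columns `x`, `y`.
#' @examples
#' sample_bivariate_t(4, nu = 4, rho = 0.5, seed = 1)
#' @export
sample_bivariate_t <- function(m, nu, rho = 0, independent = FALSE, seed = NULL) {
  if (!is.numeric(nu) || nu <= 0) abort("`nu` must be positive.")
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  with_seed(seed, {
    if (independent) {
      tibble::tibble(x = stats::rt(m, df = nu), y = stats::rt(m, df = nu))
    } else {
      z <- rbinorm(m, rho)
      s <- sqrt(nu / rchisq(m, df = nu))
      tibble::tibble(x = z[, 1] * s, y = z[, 2] * s)
    }
  })
}

#' Simulate an equal-weight vector moving average of bivariate-t innovations
#'
#' Each output pair is the mean of \eqn{2q + 1} consecutive innovation pairs
#' (weights equal, summing to 1), emulating time series smoothed by a
#' centred moving-average filter. Innovations are bivariate t (see
#' [sample_bivariate_t()]). `q = 0` returns the innovations themselves (iid
#' process). `n + 2q` innovations are generated so the output has exactly
#' length `n` with no edge truncation. The process is \eqn{2q}-dependent,
#' hence short-range dependent by construction.
#'
#' @param n Output length.
#' @param q Window half-width, non-negative integer; window length
#'   \eqn{2q + 1}.
#' @param nu Degrees of freedom of the t innovations.
#' @param rho Innovation cross-correlation parameter.
#' @param independent_t Use two independent univariate t innovation series
#'   (the natural null version of the model, used in place of the elliptical
#'   `rho = 0` case, whose components are uncorrelated but not independent).
#' @param marginal Optional strictly increasing marginal transform.
#' @param seed Optional integer seed.
#' @return A tibble with columns `t`, `x`, `y`.
#' @examples
#' simulate_vma(5, q = 2, nu = 4, independent_t = TRUE, seed = 1)
#' @export
simulate_vma <- function(n, q = 0L, nu = 4, rho = 0, independent_t = FALSE,
                         marginal = NULL, seed = NULL) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q != round(q)) {
    abort("`q` must be a non-negative integer.")
  }
  if (n < 1) abort("`n` must be positive.")
  q <- as.integer(q)
  fn <- resolve_transform(marginal)
  with_seed(seed, {
    p <- vma_path(n, q, nu, rho, independent_t)
    tr <- apply_transform(p$x, p$y, fn)
    tibble::tibble(t = seq_len(n), x = tr$x, y = tr$y)
  })
}

# Bare-vector VMA path; hot path for studies.
vma_path <- function(n, q, nu, rho, independent_t = FALSE) {
  m <- n + 2L * q
  if (independent_t) {
    ex <- stats::rt(m, df = nu)
    ey <- stats::rt(m, df = nu)
  } else {
    z <- rbinorm(m, rho)
    s <- sqrt(nu / rchisq(m, df = nu))
    ex <- z[, 1] * s
    ey <- z[, 2] * s
  }
  if (q == 0L) return(list(x = ex, y = ey))
  w <- 2L * q + 1L
  csx <- c(0, cumsum(ex))
  csy <- c(0, cumsum(ey))
  idx <- seq_len(n)
  list(x = (csx[idx + w] - csx[idx]) / w, y = (csy[idx + w] - csy[idx]) / w)
}

#' Apply a strictly increasing marginal transform to a paired series
#'
#' Componentwise quantile-style transformation. Because both test statistics
#' depend on the data only through ranks, any strictly increasing transform
#' leaves estimates, long-run variances, statistics and p-values unchanged;
#' the function asserts monotonicity on the observed values and errors
#' otherwise.
#'
#' @param data A data frame holding the paired series.
#' @param transform Name (`"identity"`, `"exp"`, `"cube"`) or a strictly
#'   increasing function.
#' @param x,y Columns with the two series.
#' @return A tibble with the same columns, `x`/`y` transformed.
#' @examples
#' transform_marginals(data.frame(x = 1:5, y = 5:1), "exp")
#' @export
transform_marginals <- function(data, transform, x = x, y = y) {
  fn <- resolve_transform(transform)
  if (is.null(fn)) abort("`transform` must be supplied.")
  pr <- extract_pair(data, enquo(x), enquo(y), min_n = 1L)
  tr <- apply_transform(pr$x, pr$y, fn)
  out <- tibble::as_tibble(data)
  out[[rlang::as_name(enquo(x))]] <- tr$x
  out[[rlang::as_name(enquo(y))]] <- tr$y
  out
}
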