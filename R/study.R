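#' Build a factorial Monte-Carlo study grid
#'
#' One row per simulation cell: the cross of the autocorrelation parameter
#' (`phi` for the VAR(1) model, `q` for the moving-average model), the
#' cross-dependence `rho`, and the sample size `n`. For the VAR(1) model the
#' two components share the AR coefficient (`phi_x = phi_y = phi`), the
#' configuration used throughout the type-I-error and power experiments. For
#' the moving-average model, `rho = 0` cells use two independent univariate t
#' innovation series (the null version of the model).
#'
#' @param model `"var1"` or `"vma"`.
#' @param n Vector of sample sizes.
#' @param rho Vector of cross-dependence parameters.
#' @param phi Vector of AR(1) coefficients (`var1` only).
#' @param q Vector of window half-widths (`vma` only).
#' @param nu Degrees of freedom of the t innovations (`vma` only).
#' @return A tibble with columns `model`, `phi`, `q`, `nu`, `rho`, `n`.
#' @examples
#' study_grid("var1", n = c(40, 200), phi = c(0, 0.4, 0.8), rho = 0)
#' @export
study_grid <- function(model = c("var1", "vma"), n, rho = 0, phi = 0, q = 0L,
                       nu = 4) {
  model <- match.arg(model)
  if (model == "var1") {
    g <- tidyr::expand_grid(phi = phi, rho = rho, n = as.integer(n))
    g$q <- NA_integer_
    g$nu <- NA_real_
  } else {
    g <- tidyr::expand_grid(q = as.integer(q), rho = rho, n = as.integer(n))
    g$phi <- NA_real_
    g$nu <- nu
  }
  g$model <- model
  dplyr::select(g, "model", "phi", "q", "nu", "rho", "n")
}

# Rejection counting for one grid cell: simulate reps paths, evaluate every
# requested method x measure on each path (shared ranks and shared long-run
# variance estimate), count rejections at level alpha.
run_cell <- function(simfun, n, reps, alpha, combos, kernel_fn, bandwidth,
                     alternative = "two.sided") {
  need_mod <- any(combos$method == "modified")
  need_tau <- any(combos$measure == "kendall")
  bw <- if (is.null(bandwidth)) default_bandwidth(n) else bandwidth
  ncomb <- nrow(combos)
  rej <- numeric(ncomb)
  s2_cl <- n / (n - 1)
  for (r in seq_len(reps)) {
    p <- simfun()
    rcx <- rank(p$x, ties.method = "average"); rcx <- rcx - mean(rcx)
    rcy <- rank(p$y, ties.method = "average"); rcy <- rcy - mean(rcy)
    rho_hat <- sum(rcx * rcy) / sqrt(sum(rcx^2) * sum(rcy^2))
    tau_hat <- if (need_tau) kendall_core(p$x, p$y, warn_ties = FALSE) else NA_real_
    s2_mod <- NA_real_
    if (need_mod) {
      s2_mod <- lrv_core(rcx, rcy, kernel_fn, bw)$sigma2
      if (s2_mod <= 0) s2_mod <- 1 / n
    }
    for (k in seq_len(ncomb)) {
      est <- if (combos$measure[k] == "spearman") rho_hat else tau_hat
      s2 <- if (combos$method[k] == "modified") s2_mod else s2_cl
      v <- if (combos$measure[k] == "kendall") (4 / 9) * s2 else s2
      stat <- sqrt(n) * est / sqrt(v)
      pval <- switch(alternative,
                     two.sided = 2 * pnorm(-abs(stat)),
                     greater   = pnorm(stat, lower.tail = FALSE),
                     less      = pnorm(stat))
      if (pval < alpha) rej[k] <- rej[k] + 1
    }
  }
  rej / reps
}

#' Monte-Carlo rejection-rate study
#'
#' For every cell of a [study_grid()], simulates `reps` independent paths and
#' records the frequency with which each requested test rejects the null of
#' pairwise independence at level `alpha`. With `rho = 0` cells this measures
#' the observed type-I error; with `rho != 0` it measures power (see
#' [power_curve()]). All method/measure combinations are evaluated on the same
#' simulated paths, which removes simulation noise from their comparison.
#' Results are reproducible: each cell gets a seed derived deterministically
#' from `seed` and the cell index, independent of evaluation order.
#'
#' @param grid A tibble from [study_grid()] (columns `model`, `phi`, `q`,
#'   `nu`, `rho`, `n`).
#' @param methods Subset of `c("classical", "modified")`.
#' @param measures Subset of `c("spearman", "kendall")`.
#' @param reps Replicates per cell.
#' @param alpha Significance level.
#' @param kernel,bandwidth Long-run variance settings for the modified test.
#' @param alternative Sidedness (the studies use two-sided tests).
#' @param seed Root integer seed.
#' @return A tibble of class `srd_study`: one row per cell x method x
#'   measure with `rejection_rate` and its binomial Monte-Carlo standard
#'   error `mc_se`.
#' @examples
#' g <- study_grid("var1", n = 50, phi = 0.8, rho = 0)
#' run_rejection_study(g, reps = 200, seed = 1)
#' @export
run_rejection_study <- function(grid, methods = c("classical", "modified"),
                                measures = "spearman", reps = 10000L,
                                alpha = 0.05, kernel = "quartic",
                                bandwidth = NULL,
                                alternative = c("two.sided", "greater", "less"),
                                seed = 1L) {
  alternative <- match.arg(alternative)
  if (!is.data.frame(grid) || nrow(grid) == 0) abort("`grid` must be a non-empty data frame.")
  req <- c("model", "phi", "q", "nu", "rho", "n")
  if (!all(req %in% names(grid))) {
    abort(sprintf("`grid` must have columns %s (see study_grid()).",
                  paste(req, collapse = ", ")))
  }
  if (length(methods) == 0 || length(measures) == 0) {
    abort("At least one method and one measure are required.")
  }
  methods <- match.arg(methods, c("classical", "modified"), several.ok = TRUE)
  measures <- match.arg(measures, c("spearman", "kendall"), several.ok = TRUE)
  if (reps < 1) abort("`reps` must be at least 1.")
  ks <- resolve_kernel(kernel)
  combos <- tidyr::expand_grid(method = methods, measure = measures)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    simfun <- if (cell$model == "var1") {
      function() var1_path(cell$n, cell$phi, cell$phi, cell$rho)
    } else {
      function() vma_path(cell$n, cell$q, cell$nu, cell$rho,
                          independent_t = cell$rho == 0)
    }
    set.seed(derive_seed(seed, i))
    rate <- run_cell(simfun, cell$n, reps, alpha, combos, ks$fn, bandwidth,
                     alternative)
    dplyr::bind_cols(
      cell[rep(1L, nrow(combos)), ],
      combos,
      tibble::tibble(reps = as.integer(reps), alpha = alpha,
                     rejection_rate = rate,
                     mc_se = sqrt(rate * (1 - rate) / reps))
    )
  })
  class(out) <- c("srd_study", class(out))
  out
}

#' Power curves over sample size
#'
#' [run_rejection_study()] restricted to alternatives (`rho != 0` in every
#' cell), with rows ordered by sample size for curve plotting.
#'
#' @inheritParams run_rejection_study
#' @return A tibble of class `srd_study`, ordered by `n`.
#' @examples
#' g <- study_grid("var1", n = c(40, 100), phi = 0.4, rho = 0.7)
#' power_curve(g, reps = 100, seed = 1)
#' @export
power_curve <- function(grid, methods = c("classical", "modified"),
                        measures = "spearman", reps = 10000L, alpha = 0.05,
                        kernel = "quartic", bandwidth = NULL, seed = 1L) {
  if (any(grid$rho == 0)) {
    abort("Power curves need `rho != 0` in every cell; use run_rejection_study() for null cells.")
  }
  out <- run_rejection_study(grid, methods = methods, measures = measures,
                             reps = reps, alpha = alpha, kernel = kernel,
                             bandwidth = bandwidth, seed = seed)
  out <- dplyr::arrange(out, .data$rho, .data$n)
  class(out) <- c("srd_study", class(out))
  out
}

#' Write a study result to disk
#'
#' One row per cell, stable column order; CSV or JSON. The file round-trips:
#' reading it back reproduces the result table.
#'
#' @param result An `srd_study` tibble.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
summarize_study <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(result) || nrow(result) == 0) {
    abort("`result` must be a non-empty study result.")
  }
  cols <- c("model", "phi", "q", "nu", "rho", "n", "method", "measure",
            "reps", "alpha", "rejection_rate", "mc_se")
  out <- dplyr::select(as.data.frame(result), dplyr::all_of(cols))
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a study result written by [summarize_study()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A tibble of class `srd_study`.
#' @export
read_study <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- if (format == "csv") {
    tibble::as_tibble(read.csv(path))
  } else {
    tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  }
  out$n <- as.integer(out$n)
  out$reps <- as.integer(out$reps)
  out$q <- as.integer(out$q)
  class(out) <- c("srd_study", class(out))
  out
}

#' Plot a rejection-rate study
#'
#' Rejection rate against sample size, coloured by the autocorrelation
#' parameter, line type by method, faceted by `rho`. For type-I-error grids
#' (`rho = 0`) a horizontal line marks the nominal level.
#'
#' @param object An `srd_study` tibble.
#' @param ... Unused.
#' @export
autoplot.srd_study <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$autocorr <- factor(ifelse(d$model == "var1", d$phi, d$q))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$rejection_rate,
                                       colour = .data$autocorr,
                                       linetype = .data$method,
                                       shape = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size n", y = "rejection rate",
                  colour = "autocorrelation\nparameter")
  if (all(d$rho == 0)) {
    p <- p + ggplot2::geom_hline(yintercept = unique(d$alpha), linetype = 3)
  }
  p
}
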