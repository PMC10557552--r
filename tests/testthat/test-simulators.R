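test_that("simulators are reproducible given a seed and leave the RNG state alone", {
  a <- simulate_var1(50, 0.5, 0.3, 0.2, seed = 99)
  b <- simulate_var1(50, 0.5, 0.3, 0.2, seed = 99)
  expect_identical(a, b)
  v1 <- simulate_vma(50, q = 2, nu = 4, rho = 0.3, seed = 7)
  v2 <- simulate_vma(50, q = 2, nu = 4, rho = 0.3, seed = 7)
  expect_identical(v1, v2)
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_var1(10, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("phi = 0 VAR(1) is iid standard normal pairs with correlation rho", {
  d <- simulate_var1(20000, 0, 0, 0.6, seed = 2)
  expect_equal(stats::sd(d$x), 1, tolerance = 0.03)
  expect_equal(stats::sd(d$y), 1, tolerance = 0.03)
  expect_equal(cor(d$x, d$y), 0.6, tolerance = 0.03)
  # no serial dependence
  expect_lt(abs(cor(d$x[-1], d$x[-20000])), 0.03)
})

test_that("VAR(1) paths have the stationary AR(1) variance and cross-correlation", {
  d <- simulate_var1(50000, 0.8, 0.8, 0, seed = 3)
  expect_equal(stats::var(d$x), 1 / (1 - 0.64), tolerance = 0.08)
  # phi_x = phi_y = 0.5, rho = 0.6: cross-cov c = rho / (1 - phi^2),
  # marginal var = 1 / (1 - phi^2), so the Pearson cross-correlation is rho
  d2 <- simulate_var1(50000, 0.5, 0.5, 0.6, seed = 4)
  expect_equal(cor(d2$x, d2$y), 0.6, tolerance = 0.02)
  # lag-1 autocorrelation equals phi
  expect_equal(cor(d2$x[-1], d2$x[-50000]), 0.5, tolerance = 0.02)
})

test_that("the stationary start makes the first observation distributionally like the rest", {
  set.seed(5)
  first <- replicate(4000, srdcor:::var1_path(2, 0.9, 0.9, 0)$x[1])
  expect_equal(stats::var(first), 1 / (1 - 0.81), tolerance = 0.35)
  # and a long burn-in does not change the marginal variance
  d <- simulate_var1(20000, 0.9, 0.9, 0, burn_in = 500, seed = 6)
  expect_equal(stats::var(d$x), 1 / (1 - 0.81), tolerance = 0.35)
})

test_that("true_spearman_var1 evaluates (6/pi) asin(rho/2)", {
  expect_equal(true_spearman_var1(0), 0)
  expect_equal(true_spearman_var1(1), 1)
  expect_equal(true_spearman_var1(0.5), (6 / pi) * asin(0.25))
  expect_equal(true_spearman_var1(-1), -1)
  expect_error(true_spearman_var1(1.2), "rho")
})

test_that("mean Spearman estimate under the VAR(1) model matches the arcsine map", {
  set.seed(10)
  reps <- 300
  n <- 1000
  for (rho in c(0.25, 0.5, 0.7)) {
    est <- replicate(reps, {
      p <- srdcor:::var1_path(n, 0.3, 0.3, rho)
      cor(rank(p$x), rank(p$y))
    })
    target <- true_spearman_var1(rho)
    expect_lt(abs(mean(est) - target), 3 * stats::sd(est) / sqrt(reps) + 0.005)
  }
})

test_that("bivariate t pairs realize the elliptical Kendall identity", {
  d <- sample_bivariate_t(30000, nu = 4, rho = 0.5, seed = 11)
  # tau = (2/pi) asin(rho) for elliptical distributions
  expect_equal(kendall_tau(d$x, d$y), (2 / pi) * asin(0.5), tolerance = 0.02)
  # independent option: tau near 0
  di <- sample_bivariate_t(30000, nu = 4, independent = TRUE, seed = 12)
  expect_lt(abs(kendall_tau(di$x, di$y)), 0.02)
  # very large nu approaches the Gaussian case
  dg <- sample_bivariate_t(30000, nu = 1e6, rho = 0.5, seed = 13)
  expect_equal(stats::sd(dg$x), 1, tolerance = 0.02)
  expect_equal(cor(dg$x, dg$y), 0.5, tolerance = 0.02)
  expect_error(sample_bivariate_t(10, nu = -1), "nu")
})

test_that("q = 0 vector moving average is the innovation process itself", {
  a <- simulate_vma(100, q = 0, nu = 5, rho = 0.4, seed = 14)
  b <- sample_bivariate_t(100, nu = 5, rho = 0.4, seed = 14)
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
})

test_that("VMA autocorrelation follows the overlap-count formula (2q+1-h)/(2q+1)", {
  q <- 2
  d <- simulate_vma(60000, q = q, nu = 10, rho = 0, independent_t = TRUE, seed = 15)
  n <- nrow(d)
  for (h in 1:(2 * q + 1)) {
    emp <- cor(d$x[1:(n - h)], d$x[(1 + h):n])
    theo <- max(0, (2 * q + 1 - h) / (2 * q + 1))
    expect_equal(emp, theo, tolerance = 0.02)
  }
})

test_that("dispersion of sqrt(n) * rho_hat under the null matches the limiting variance", {
  # phi = 0.5 both components, rho = 0: limit variance is
  # 1 + 2 sum_h [(6/pi) asin(0.5^h / 2)]^2
  sigma2_limit <- 1 + 2 * sum(((6 / pi) * asin(0.5^(1:50) / 2))^2)
  set.seed(18)
  reps <- 400
  n <- 1000
  z <- replicate(reps, {
    p <- srdcor:::var1_path(n, 0.5, 0.5, 0)
    sqrt(n) * cor(rank(p$x), rank(p$y))
  })
  expect_gt(stats::var(z), 1.2) # clearly inflated relative to iid
  expect_equal(stats::var(z), sigma2_limit,
               tolerance = 3 * sqrt(2 / reps) + 0.02)
})

test_that("heavy-tailed VMA keeps rank correlations stable while Pearson is unstable", {
  set.seed(16)
  reps <- 60
  pearson <- numeric(reps); spear <- numeric(reps)
  for (r in seq_len(reps)) {
    p <- srdcor:::vma_path(400, 0L, 1.5, 0.5, independent_t = FALSE)
    pearson[r] <- cor(p$x, p$y)
    spear[r] <- cor(rank(p$x), rank(p$y))
  }
  expect_gt(stats::sd(pearson), 3 * stats::sd(spear))
})

test_that("marginal transforms leave every test ingredient unchanged", {
  set.seed(17)
  d <- simulate_var1(80, 0.6, 0.6, 0.4)
  for (tr in list("exp", "cube", function(v) qt(pnorm(v), df = 3))) {
    td <- transform_marginals(d, tr)
    expect_equal(spearman_rho(td$x, td$y), spearman_rho(d$x, d$y))
    expect_equal(kendall_tau(td$x, td$y), kendall_tau(d$x, d$y))
    a <- srd_test(d, method = "modified")
    b <- srd_test(td, method = "modified")
    expect_equal(a$sigma2, b$sigma2)
    expect_equal(a$statistic, b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
  expect_error(transform_marginals(d, function(v) -v), "increasing")
  expect_error(transform_marginals(d, "sawtooth"), "Unknown")
})

test_that("invalid simulator configurations error", {
  expect_error(simulate_var1(10, phi_x = 1), "Stationarity")
  expect_error(simulate_var1(10, rho = 2), "rho")
  expect_error(simulate_vma(10, q = -1), "non-negative")
  expect_error(simulate_vma(10, q = 1.5), "non-negative")
})
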