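test_that("the classical Spearman statistic is rho * sqrt(n - 1)", {
  # with sigma2 = n/(n-1), T = sqrt(n) rho / sqrt(n/(n-1)) = rho sqrt(n-1)
  set.seed(1)
  n <- 50
  repeat { # draw until the sample estimate is near 0.46 for a readable check
    d <- simulate_var1(n, 0.8, 0.8, 0)
    r <- spearman_rho(d$x, d$y)
    if (abs(r - 0.46) < 0.05) break
  }
  out <- srd_test(d, method = "classical")
  expect_equal(out$statistic, r * sqrt(n - 1))
  expect_equal(out$sigma2, n / (n - 1))
  expect_equal(out$p_value, 2 * pnorm(-abs(r * sqrt(49))))
  # at rho_hat ~ 0.46 and n = 50 the classical test rejects firmly
  expect_true(out$reject)
  expect_lt(out$p_value, 0.01)
})

test_that("a large long-run variance can turn the same estimate into a non-rejection", {
  set.seed(2)
  n <- 50
  repeat {
    d <- simulate_var1(n, 0.8, 0.8, 0)
    if (abs(spearman_rho(d$x, d$y) - 0.46) < 0.04) break
  }
  cl <- srd_test(d, method = "classical")
  mod <- srd_test(d, method = "modified")
  expect_equal(cl$estimate, mod$estimate)
  expect_gt(mod$sigma2, cl$sigma2)
  expect_lt(abs(mod$statistic), abs(cl$statistic))
  expect_gt(mod$p_value, cl$p_value)
})

test_that("a zero estimate gives T = 0 and two-sided p = 1", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(3, 1, 4, 2)) # sum d^2 = 10 -> rho = 0
  expect_equal(spearman_rho(d$x, d$y), 0)
  out <- suppressWarnings(srd_test(d, method = "classical", warn_ties = FALSE))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_false(out$reject)
})

test_that("Kendall shares sigma2 with Spearman and uses exactly (4/9) of it", {
  set.seed(3)
  d <- simulate_var1(60, 0.5, 0.5, 0.3)
  sp <- srd_test(d, measure = "spearman", method = "modified")
  kd <- srd_test(d, measure = "kendall", method = "modified")
  expect_equal(kd$sigma2, sp$sigma2)
  expect_equal(kd$variance, (4 / 9) * sp$sigma2)
  expect_equal(kd$statistic,
               sqrt(kd$n_effective) * kd$estimate / sqrt((4 / 9) * kd$sigma2))
})

test_that("the exact iid Kendall variance option matches the textbook formula", {
  set.seed(4)
  n <- 40
  d <- data.frame(x = rnorm(n), y = rnorm(n))
  out <- srd_test(d, measure = "kendall", method = "classical",
                  exact_iid_kendall = TRUE)
  tau <- kendall_tau(d$x, d$y)
  expect_equal(out$statistic, tau / sqrt(2 * (2 * n + 5) / (9 * n * (n - 1))))
  # close to base R's normal-approximation z for the same data
  default <- srd_test(d, measure = "kendall", method = "classical")
  expect_lt(abs(out$statistic - default$statistic), 0.2)
})

test_that("two-sided p-values strictly decrease in |T|", {
  set.seed(5)
  stats <- sort(abs(rnorm(25, sd = 2)))
  p <- 2 * pnorm(-stats)
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  ps <- vapply(c(0, 1, 2), function(lag) {
    srd_test(d, method = "classical", lag = lag)$p_value
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("one-sided alternatives partition the two-sided p-value", {
  set.seed(6)
  d <- simulate_var1(80, 0.3, 0.3, 0.5)
  g <- srd_test(d, method = "classical", alternative = "greater")
  l <- srd_test(d, method = "classical", alternative = "less")
  t2 <- srd_test(d, method = "classical", alternative = "two.sided")
  expect_equal(g$p_value + l$p_value, 1)
  expect_equal(t2$p_value, 2 * min(g$p_value, l$p_value))
})

test_that("critical_region scales as qnorm * sqrt(sigma2 / n)", {
  cr <- critical_region(100, alpha = 0.05, sigma2 = 1)
  expect_equal(cr$upper, qnorm(0.975) / 10, tolerance = 1e-8)
  expect_equal(cr$lower, -cr$upper)
  # quadrupling sigma2 doubles the boundaries
  cr4 <- critical_region(100, alpha = 0.05, sigma2 = 4)
  expect_equal(cr4$upper, 2 * cr$upper)
  # boundaries shrink to 0 as alpha -> 1
  expect_lt(critical_region(100, alpha = 0.999, sigma2 = 1)$upper, 1e-3)
  # Kendall region uses the (4/9) variance
  crk <- critical_region(100, alpha = 0.05, sigma2 = 1, measure = "kendall")
  expect_equal(crk$upper, (2 / 3) * cr$upper)
})

test_that("reject flag matches p < alpha and the critical region", {
  set.seed(7)
  d <- simulate_var1(100, 0, 0, 0.6)
  out <- srd_test(d, method = "classical", alpha = 0.01)
  expect_equal(out$reject, out$p_value < 0.01)
  cr <- out$critical_region
  expect_equal(out$reject,
               out$estimate < cr$lower || out$estimate > cr$upper)
})

test_that("lagged tests report the overlap as n_effective and use it in the statistic", {
  set.seed(8)
  d <- simulate_var1(60, 0.2, 0.2, 0.4)
  out <- srd_test(d, method = "classical", lag = 5)
  expect_equal(out$n_effective, 55L)
  expect_equal(out$statistic, out$estimate * sqrt(54))
  expect_warning(srd_test(d[1:12, ], method = "classical", lag = 4), "below 10")
})

test_that("classical type-I error on iid Gaussian pairs is near alpha", {
  g <- study_grid("var1", n = 200, phi = 0, rho = 0)
  out <- run_rejection_study(g, methods = "classical", reps = 4000, seed = 11)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(out$rejection_rate - 0.05), 3 * se)
})

test_that("modified and classical rates agree when at most one component is autocorrelated", {
  g <- study_grid("var1", n = 200, phi = 0, rho = 0)
  # one-sided autocorrelation: simulate manually since the grid ties phi_x = phi_y
  set.seed(12)
  reps <- 1500
  rej <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    p <- srdcor:::var1_path(200, 0.8, 0, 0)
    d <- data.frame(x = p$x, y = p$y)
    rej[r, 1] <- srd_test(d, method = "classical")$reject
    rej[r, 2] <- srd_test(d, method = "modified")$reject
  }
  rates <- colMeans(rej)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rates[1] - rates[2]), 4 * se)
  expect_lt(abs(rates[1] - 0.05), 4 * se)
})

test_that("the modified test is consistent under dependence: rejection rises to 1 with n", {
  g <- study_grid("var1", n = c(40, 100, 200, 500), phi = 0.4, rho = 0.5)
  out <- power_curve(g, methods = "modified", reps = 400, seed = 13)
  rates <- out$rejection_rate[order(out$n)]
  expect_true(all(diff(rates) > -0.1)) # monotone up to MC noise
  expect_gt(rates[length(rates)], 0.95)
})

test_that("configuration errors are caught", {
  d <- data.frame(x = rnorm(20), y = rnorm(20))
  expect_error(srd_test(d, alpha = 0), "alpha")
  expect_error(srd_test(d, alpha = 1.2), "alpha")
  expect_error(srd_test(d, bandwidth = -1), "bandwidth")
  expect_error(srd_test(d, lag = 18), "overlap")
  expect_error(suppressWarnings(srd_test(data.frame(x = rep(1, 20), y = rnorm(20)))),
               "constant|Degenerate")
})

test_that("tidy and glance return one well-formed row", {
  set.seed(9)
  d <- simulate_var1(50, 0.4, 0.4, 0.2)
  out <- srd_test(d)
  td <- tidy(out)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("measure", "method", "lag", "n_effective", "estimate",
                     "statistic", "sigma2", "p_value", "reject", "alpha",
                     "alternative"))
  expect_identical(td, glance(out))
})
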