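test_that("loglik equals the sum of log densities (guards the x-exponent correction)", {
  set.seed(31)
  for (rep in 1:8) {
    # zeta bounded away from the heavy-tail regime so draws stay in range
    pars <- c(exp(runif(1, log(0.3), log(3))), exp(runif(1, log(0.8), log(3))),
              exp(runif(2, log(0.3), log(3))))
    x <- rnowiw(15, pars[1], pars[2], pars[3], pars[4])
    ll <- nowiw_loglik(x, pars[1], pars[2], pars[3], pars[4])
    expect_equal(ll, sum(dnowiw(x, pars[1], pars[2], pars[3], pars[4], log = TRUE)),
                 tolerance = 1e-10)
    expect_equal(ll, nowiw_loglik(sample(x), pars[1], pars[2], pars[3], pars[4]),
                 tolerance = 1e-12) # exchangeability
  }
  # m = 1 identity and a two-point hand assembly
  expect_equal(nowiw_loglik(2, 1, 1, 1, 1), dnowiw(2, 1, 1, 1, 1, log = TRUE),
               tolerance = 1e-12)
  expect_equal(nowiw_loglik(c(1, 2), 1, 1, 1, 1),
               log(0.32339) + dnowiw(2, 1, 1, 1, 1, log = TRUE),
               tolerance = 1e-4)
  expect_error(nowiw_loglik(c(1, -1), 1, 1, 1, 1), "positive")
})

test_that("LSE/WLSE objectives vanish at quantile-spaced data and match hand sums", {
  m <- 30; i <- 1:m
  x <- qnowiw(i / (m + 1), 1, 2, 1, 1)
  expect_lt(lse_objective(x, 1, 2, 1, 1), 1e-16)
  expect_lt(wlse_objective(x, 1, 2, 1, 1), 1e-16)
  # three-term brute force at (1,2,1,1), data {1,2,3}
  u <- naive_cdf(c(1, 2, 3), 1, 2, 1, 1)
  pos <- (1:3) / 4
  expect_equal(lse_objective(c(1, 2, 3), 1, 2, 1, 1),
               sum((u - pos)^2), tolerance = 1e-12)
  w <- 16 * 5 / ((1:3) * (3 - 1:3 + 1))
  expect_equal(wlse_objective(c(1, 2, 3), 1, 2, 1, 1),
               sum(w * (u - pos)^2), tolerance = 1e-12)
  # weight symmetry at the extremes: i(m - i + 1) is symmetric
  expect_equal(w[1], w[3])
})

test_that("LSE and WLSE fits recover generating parameters from quantile-spaced data", {
  m <- 40
  x <- qnowiw((1:m) / (m + 1), 1, 2, 1, 1)
  cfg <- fit_config(starts = 10, seed = 3)
  for (method in c("lse", "wlse")) {
    fit <- fit_nowiw(x, method, cfg)
    expect_true(fit$converged)
    expect_equal(unname(fit$estimate), c(1, 2, 1, 1), tolerance = 1e-3)
    expect_lt(fit$objective, 1e-10)
    # determinism: same config reproduces bitwise
    fit2 <- fit_nowiw(x, method, cfg)
    expect_identical(fit$estimate, fit2$estimate)
  }
})

test_that("estimators recover the data-generating distribution on simulated samples", {
  grid <- seq(0.1, 12, length.out = 300)
  truthF <- pnowiw(grid, 1, 2, 1, 1)
  x <- rnowiw(500, 1, 2, 1, 1, seed = 4)
  fit <- fit_nowiw(x, "mle", fit_config(starts = 10, seed = 1))
  expect_true(fit$converged)
  e <- fit$estimate
  expect_lt(max(abs(pnowiw(grid, e[["eta"]], e[["zeta"]], e[["k"]], e[["n"]]) - truthF)),
            0.05)
  y <- rnowiw(200, 2.3, 1.1, 1.5, 1.8, seed = 42)
  for (method in c("lse", "wlse")) {
    f <- fit_nowiw(y, method, fit_config(starts = 8, seed = 1))
    expect_true(f$converged)
    expect_true(all(is.finite(f$estimate)) && all(f$estimate > 0))
  }
})

test_that("neutrosophic fits pair endpoints into ordered intervals", {
  d <- rnnowiw(60, table3_truth(), seed = 8)
  fit <- fit_nnowiw(d, "wlse", fit_config(starts = 6, seed = 2))
  expect_true(fit$converged)
  td <- tidy(fit)
  expect_true(all(td$lower <= td$upper))
  expect_identical(td$term, c("eta", "zeta", "k", "n"))
  # degenerate sample gives zero-width intervals
  dd <- tibble::tibble(lower = d$lower, upper = d$lower)
  fd <- fit_nnowiw(dd, "wlse", fit_config(starts = 6, seed = 2))
  tdd <- tidy(fd)
  expect_identical(tdd$lower, tdd$upper)
  gl <- glance(fd)
  expect_identical(gl$neg_loglik_lower, gl$neg_loglik_upper)
})

test_that("battery MLE fit reproduces the package's reference optimum", {
  # frozen regression anchor for the dominant interior optimum
  fit <- fit_nnowiw(battery(), "mle", fit_config(starts = 20, seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$neg_loglik[["lower"]], 88.58480, tolerance = 1e-5)
  expect_equal(fit$neg_loglik[["upper"]], 95.77761, tolerance = 1e-5)
})
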