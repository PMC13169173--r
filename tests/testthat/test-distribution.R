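test_that("log-space cdf/pdf/sf/hazard match naive direct evaluation and hand values", {
  # hand evaluation at (1,1,1,1), x = 1: H = e^-1, g = -H log(1-H)
  expect_equal(pnowiw(1, 1, 1, 1, 1), 0.15527, tolerance = 1e-4)
  expect_equal(dnowiw(1, 1, 1, 1, 1), 0.32339, tolerance = 1e-4)
  expect_equal(snowiw(1, 1, 1, 1, 1), 0.84473, tolerance = 1e-4)
  expect_equal(hnowiw(1, 1, 1, 1, 1), 0.38284, tolerance = 1e-4)

  x <- c(0.3, 0.7, 1, 2, 5, 20)
  grid <- param_grid()
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    expect_equal(pnowiw(x, p$eta, p$zeta, p$k, p$n),
                 naive_cdf(x, p$eta, p$zeta, p$k, p$n), tolerance = 1e-12)
    expect_equal(dnowiw(x, p$eta, p$zeta, p$k, p$n),
                 naive_pdf(x, p$eta, p$zeta, p$k, p$n), tolerance = 1e-10)
  }
})

test_that("generated family with inverse-Weibull baseline equals the specialized cdf", {
  x <- c(0.4, 1, 3, 10)
  for (pars in list(c(1, 1, 1, 1), c(0.5, 2, 2.5, 0.8), c(2, 0.5, 0.8, 1.5))) {
    bl <- baseline_inverse_weibull(pars[3], pars[4])
    expect_equal(now_family_cdf(x, pars[1], pars[2], bl),
                 pnowiw(x, pars[1], pars[2], pars[3], pars[4]),
                 tolerance = 1e-14)
  }
  # baseline cdf exactly 1 at a finite point -> 1 with support-boundary warning
  bl1 <- list(cdf = function(x, params) rep(1, length(x)), params = NULL)
  expect_warning(out <- now_family_cdf(2, 1, 1, bl1), "support boundary")
  expect_identical(out, 1)
})

test_that("cdf is a proper distribution function with matching sf and hazard", {
  x <- exp(seq(log(0.05), log(50), length.out = 60))
  grid <- param_grid()
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    Fx <- pnowiw(x, p$eta, p$zeta, p$k, p$n)
    expect_true(all(diff(Fx) >= 0))
    expect_true(all(Fx >= 0 & Fx <= 1)) # F reaches 1 to double precision
    expect_lt(pnowiw(min(x), p$eta, p$zeta, p$k, p$n), 1)
    # support limits (the upper tail can be sub-polynomially slow, so probe
    # it through the quantile function rather than a fixed far point)
    expect_equal(pnowiw(1e-8, p$eta, p$zeta, p$k, p$n), 0)
    x999 <- qnowiw(0.999, p$eta, p$zeta, p$k, p$n)
    expect_gt(pnowiw(10 * x999, p$eta, p$zeta, p$k, p$n), 0.999)
    # mutual identities
    Sx <- snowiw(x, p$eta, p$zeta, p$k, p$n)
    expect_equal(Sx + Fx, rep(1, length(x)), tolerance = 1e-12)
    expect_equal(hnowiw(x, p$eta, p$zeta, p$k, p$n) * Sx,
                 dnowiw(x, p$eta, p$zeta, p$k, p$n), tolerance = 1e-10)
  }
})

test_that("pdf integrates to one and differentiates the cdf", {
  grid <- param_grid()
  for (r in seq_len(nrow(grid))) {
    p <- grid[r, ]
    X <- min(qnowiw(1 - 1e-9, p$eta, p$zeta, p$k, p$n), 1e10)
    total <- total_mass(function(x) dnowiw(x, p$eta, p$zeta, p$k, p$n),
                        function(x) snowiw(x, p$eta, p$zeta, p$k, p$n), X)
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # centered finite difference on an interior grid
  x <- c(0.5, 1, 2, 4)
  h <- 1e-6
  for (pars in list(c(1, 2, 1, 1), c(0.5, 1.5, 2, 0.8))) {
    fd <- (pnowiw(x + h, pars[1], pars[2], pars[3], pars[4]) -
             pnowiw(x - h, pars[1], pars[2], pars[3], pars[4])) / (2 * h)
    expect_equal(dnowiw(x, pars[1], pars[2], pars[3], pars[4]), fd,
                 tolerance = 1e-6)
  }
})

test_that("quantile function inverts the cdf to tight tolerance", {
  expect_equal(qnowiw(0.15527, 1, 1, 1, 1), 1, tolerance = 1e-4)
  for (pars in list(c(1, 1, 1, 1), c(2, 0.5, 0.8, 1.5), c(0.5, 2, 2.5, 0.8))) {
    x <- c(0.5, 1, 2, 5)
    expect_equal(qnowiw(pnowiw(x, pars[1], pars[2], pars[3], pars[4]),
                        pars[1], pars[2], pars[3], pars[4]),
                 x, tolerance = 1e-6)
    p <- c(1e-6, 0.01, 0.25, 0.5, 0.75, 0.99, 1 - 1e-6)
    q <- qnowiw(p, pars[1], pars[2], pars[3], pars[4])
    expect_true(all(diff(q) > 0))
    expect_true(all(abs(pnowiw(q, pars[1], pars[2], pars[3], pars[4]) - p) < 1e-10))
  }
  # support limits: the lower tail closes extremely slowly (essential
  # singularity of the baseline), so probe it at an astronomically small p
  expect_lt(qnowiw(1e-300, 1, 1, 1, 1), 0.01)
  expect_lt(qnowiw(1e-10, 1, 1, 1, 1), qnowiw(1e-4, 1, 1, 1, 1))
  expect_gt(qnowiw(1 - 1e-12, 1, 1, 1, 1), 1e4)
})

test_that("domain violations raise errors", {
  expect_error(pnowiw(-1, 1, 1, 1, 1), "positive")
  expect_error(dnowiw(0, 1, 1, 1, 1), "positive")
  expect_error(qnowiw(0, 1, 1, 1, 1), "inside")
  expect_error(qnowiw(1, 1, 1, 1, 1), "inside")
  expect_error(pnowiw(1, -1, 1, 1, 1), "parameters")
  expect_error(pnowiw(1, 1, 1, Inf, 1), "parameters")
})

test_that("Lambert-W closed form is quarantined: flags instead of crashes, residual contract", {
  res <- qnowiw_lambert(seq(0.1, 0.9, by = 0.2), 0.3, 1.7, 0.5, 0.8)
  expect_true(all(res$status %in%
                    c("ok", "branch-domain-violation", "invalid-intermediate")))
  expect_true(all(is.na(res$value[res$status != "ok"])))
  # inversion consistency: any tiny-residual value must agree with qnowiw
  ok <- res[res$status == "ok" & !is.na(res$residual) & res$residual < 1e-8, ]
  if (nrow(ok)) {
    expect_equal(ok$value, qnowiw(ok$p, 0.3, 1.7, 0.5, 0.8), tolerance = 1e-6)
  }
})

test_that("random generation is seeded, reproducible and distributed as the cdf", {
  expect_length(rnowiw(0, 1, 2, 1, 1), 0)
  a <- rnowiw(50, 1, 2, 1, 1, seed = 7)
  b <- rnowiw(50, 1, 2, 1, 1, seed = 7)
  expect_identical(a, b)
  x <- rnowiw(5000, 1, 2, 1, 1, seed = 123)
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) pnowiw(q, 1, 2, 1, 1)))
  expect_gt(ks$p.value, 0.01)
})
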