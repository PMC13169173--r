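test_that("moment divergence follows the survival-tail analysis", {
  # zeta = 1: polynomial tail of order eta*n; r >= eta*n diverges
  expect_false(nowiw_moment(1, 1, 1, 1, 1)$finite)
  expect_true(nowiw_moment(1, 2.5, 1, 1, 1)$finite)
  expect_false(nowiw_moment(3, 2.5, 1, 1, 1)$finite)
  # zeta < 1: every moment diverges; zeta > 1: all finite
  expect_false(nowiw_moment(1, 2, 0.5, 1, 2)$finite)
  expect_true(all(nowiw_moment(1:4, 1, 2, 1, 1)$finite))
})

test_that("moments match a dense-trapezoid brute-force oracle", {
  for (pars in list(c(1, 2, 1, 1), c(0.5, 1.5, 2, 0.8))) {
    m1 <- nowiw_moment(1, pars[1], pars[2], pars[3], pars[4])$value
    m2 <- nowiw_moment(2, pars[1], pars[2], pars[3], pars[4])$value
    oracle1 <- trapezoid_0inf(function(x) x * naive_pdf(x, pars[1], pars[2], pars[3], pars[4]))
    expect_equal(m1, oracle1, tolerance = 1e-6)
    expect_gte(m2, m1^2) # Jensen
  }
})

test_that("summary assembles central moments and propagates divergence", {
  s <- nowiw_summary(1, 2, 1, 1)
  mom <- s$moments[[1]]
  expect_equal(s$variance, mom$value[2] - mom$value[1]^2, tolerance = 1e-8)
  expect_gt(s$skewness, 0) # right-skewed lifetime model
  # finite mean/variance but divergent 3rd/4th moments (zeta = 1, eta*n = 2.5)
  s2 <- nowiw_summary(2.5, 1, 1, 1)
  expect_true(s2$variance_finite)
  expect_false(s2$skewness_finite)
  expect_false(s2$kurtosis_finite)
  expect_true(is.na(s2$kurtosis))
})

test_that("incomplete moments are monotone and converge to the full moment", {
  pars <- c(1, 2, 1, 1)
  y <- c(0.2, 0.5, 1, 2, 5, 10)
  inc <- nowiw_incomplete_moment(1, y, pars[1], pars[2], pars[3], pars[4])
  expect_true(all(diff(inc) >= 0))
  expect_lt(nowiw_incomplete_moment(1, 1e-4, pars[1], pars[2], pars[3], pars[4]), 1e-8)
  # the top 1% of probability carries ~4% of this slowly-tailed mean, so the
  # 99% quantile recovers the moment to ~5% and the 99.99% quantile almost all
  mu <- nowiw_moment(1, pars[1], pars[2], pars[3], pars[4])$value
  y99 <- qnowiw(0.99, pars[1], pars[2], pars[3], pars[4])
  expect_equal(nowiw_incomplete_moment(1, y99, pars[1], pars[2], pars[3], pars[4]),
               mu, tolerance = 0.05)
  y4 <- qnowiw(1 - 1e-4, pars[1], pars[2], pars[3], pars[4])
  expect_equal(nowiw_incomplete_moment(1, y4, pars[1], pars[2], pars[3], pars[4]),
               mu, tolerance = 0.005)
})

test_that("Lorenz and Bonferroni curves satisfy their identities", {
  pars <- c(1, 2, 1, 1)
  med <- qnowiw(0.5, pars[1], pars[2], pars[3], pars[4])
  y <- c(0.5, med, 3, 20)
  iq <- nowiw_inequality(y, pars[1], pars[2], pars[3], pars[4])
  expect_true(all(iq$lorenz >= 0 & iq$lorenz <= 1))
  expect_equal(iq$bonferroni * pnowiw(y, pars[1], pars[2], pars[3], pars[4]),
               iq$lorenz, tolerance = 1e-10)
  expect_lt(iq$lorenz[iq$y == med], 0.5) # right skew: Lorenz below diagonal
  expect_gt(tail(iq$lorenz, 1), 0.9)
  # divergent mean is flagged
  bad <- nowiw_inequality(1, 1, 1, 1, 1)
  expect_false(bad$mean_finite)
  expect_true(is.na(bad$lorenz))
})

test_that("probability-weighted moments reduce and bound correctly", {
  pars <- c(1, 2, 1, 1)
  p10 <- nowiw_pwm(1, 0, pars[1], pars[2], pars[3], pars[4])
  p11 <- nowiw_pwm(1, 1, pars[1], pars[2], pars[3], pars[4])
  expect_equal(p10$value, nowiw_moment(1, pars[1], pars[2], pars[3], pars[4])$value,
               tolerance = 1e-8)
  expect_lte(p11$value, p10$value)
  oracle <- trapezoid_0inf(function(x) {
    x * naive_pdf(x, pars[1], pars[2], pars[3], pars[4]) *
      naive_cdf(x, pars[1], pars[2], pars[3], pars[4])
  })
  expect_equal(p11$value, oracle, tolerance = 1e-6)
  expect_false(nowiw_pwm(1, 1, 1, 1, 1, 1)$finite)
})

test_that("the four entropies share one J(c) and match brute force", {
  e1 <- nowiw_entropy(2, 1, 2, 1, 1)
  e2 <- nowiw_entropy(2, 1, 2, 1, 1)
  expect_identical(e1, e2) # determinism
  expect_equal(length(unique(e1$J)), 1L)
  oracleJ <- trapezoid_0inf(function(x) naive_pdf(x, 1, 2, 1, 1)^2)
  expect_equal(e1$J[1], oracleJ, tolerance = 1e-6)
  expect_lt(e1$value[e1$kind == "tsallis"], 1) # T_2 with integral of f^2 > 0
  # Renyi -> differential entropy continuity near c = 1
  r_lo <- nowiw_entropy(0.999, 1, 2, 1, 1, kind = "renyi")$value
  r_hi <- nowiw_entropy(1.001, 1, 2, 1, 1, kind = "renyi")$value
  expect_equal(r_lo, r_hi, tolerance = 1e-2)
  # divergent J flagged (zeta < 1, c < 1)
  bad <- nowiw_entropy(0.5, 1, 0.5, 1, 1)
  expect_false(any(bad$finite))
})

test_that("characteristic function has the defining symmetries and matches Monte Carlo", {
  expect_identical(nowiw_cf(0, 1, 2, 1, 1), 1 + 0i)
  phi <- nowiw_cf(c(-0.5, 0.5), 1, 2, 1, 1)
  expect_equal(phi[1], Conj(phi[2]), tolerance = 1e-8)
  expect_true(all(Mod(phi) <= 1 + 1e-10))
  x <- rnowiw(1e6, 1, 2, 1, 1, seed = 2024)
  mc <- mean(exp(1i * x))
  se_re <- stats::sd(cos(x)) / sqrt(length(x))
  se_im <- stats::sd(sin(x)) / sqrt(length(x))
  phi1 <- nowiw_cf(1, 1, 2, 1, 1)
  expect_lt(abs(Re(phi1) - Re(mc)), 3 * se_re)
  expect_lt(abs(Im(phi1) - Im(mc)), 3 * se_im)
})
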