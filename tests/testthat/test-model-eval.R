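test_that("information criteria follow their defining identities", {
  expect_equal(information_criteria(100, k = 0, m = 23)$aic, 200)
  ic <- information_criteria(100, k = 4, m = 23)
  expect_equal(ic$bic, 200 + 4 * log(23), tolerance = 1e-10)
  expect_equal(ic$caic, ic$aic + 2 * 4 * 5 / (23 - 5), tolerance = 1e-10)
  expect_equal(ic$hqic, 200 + 8 * log(log(23)), tolerance = 1e-10)
  # endpoint-wise on intervals
  ici <- information_criteria(interval(88.62533, 95.80281), k = 4, m = 23)
  expect_identical(ici$endpoint, c("lower", "upper"))
  expect_equal(ici$aic, 2 * c(88.62533, 95.80281) + 8, tolerance = 1e-10)
  expect_error(information_criteria(100, k = 4, m = 5), "CAIC")
})

test_that("gof statistics match hand sums and a naive double-loop oracle", {
  # single observation at its median: D = 1/2
  g1 <- gof_statistics(1, function(q) rep(0.5, length(q)))
  expect_equal(g1$ks, 0.5)
  # three-term hand computation
  u3 <- c(0.2, 0.5, 0.9)
  g3 <- gof_statistics(c(1, 2, 3), function(q) u3[match(q, c(1, 2, 3))])
  expect_equal(g3$cvm, 1 / 36 + sum((u3 - c(1, 3, 5) / 6)^2), tolerance = 1e-12)
  expect_equal(g3$cvm, 0.03333, tolerance = 3e-4)
  # random inputs vs the naive reference, m <= 50
  set.seed(99)
  for (rep in 1:10) {
    m <- sample(3:50, 1)
    x <- sort(runif(m, 0.5, 10))
    u <- sort(runif(m, 0.001, 0.999))
    cdf <- function(q) u[match(q, x)]
    got <- gof_statistics(x, cdf)
    ref <- naive_gof(x, u)
    expect_equal(got$ks, ref$ks, tolerance = 1e-12)
    expect_equal(got$cvm, ref$cvm, tolerance = 1e-12)
    expect_equal(got$ad, ref$ad, tolerance = 1e-10)
    expect_equal(got$ad_modified, ref$ad * (1 + 0.75 / m + 2.25 / m^2),
                 tolerance = 1e-12)
    expect_equal(got$cvm_modified, ref$cvm * (1 + 0.5 / m), tolerance = 1e-12)
  }
  expect_warning(gof_statistics(1, function(q) rep(1, length(q))), "clamping")
})

test_that("exact Kolmogorov p-values match the ks.test oracle", {
  expect_equal(ks_pvalue(0, 23), 1)
  expect_equal(ks_pvalue(1, 23), 0, tolerance = 1e-12)
  set.seed(7)
  for (m in c(5, 23, 60)) {
    u <- runif(m)
    ref <- suppressWarnings(stats::ks.test(u, "punif", exact = TRUE))
    expect_equal(ks_pvalue(unname(ref$statistic), m), ref$p.value,
                 tolerance = 1e-6)
  }
  # the asymptotic branch (m > 100) stays close to the exact distribution
  d <- 0.08
  expect_lt(abs(ks_pvalue(d, 101) - (1 - nnowiw:::kolmogorov_cdf_exact(d, 101))),
            0.05)
})

test_that("descriptive statistics reproduce the battery table endpoint-wise", {
  d <- describe_sample(battery())
  lo <- d[d$endpoint == "lower", ]
  up <- d[d$endpoint == "upper", ]
  expect_equal(round(c(lo$mean, up$mean), 2), c(20.59, 28.19))
  expect_equal(round(c(lo$sd, up$sd), 2), c(15.93, 21.46))
  expect_equal(c(lo$median, up$median), c(17.05, 23.45))
  expect_equal(round(c(lo$trimmed, up$trimmed), 2), c(18.10, 24.89))
  expect_equal(round(c(lo$mad, up$mad), 2), c(8.08, 11.10))
  expect_equal(c(lo$min, up$min), c(2.9, 3.99))
  expect_equal(c(lo$max, up$max), c(73.48, 98.04))
  expect_equal(round(c(lo$range, up$range), 2), c(70.58, 94.05))
  expect_equal(round(c(lo$se, up$se), 2), c(3.32, 4.48))
  # degenerate constant sample
  dc <- describe_sample(tibble::tibble(lower = rep(5, 6), upper = rep(5, 6)))
  expect_true(all(dc$sd == 0) && all(dc$range == 0) && all(dc$mean == 5))
})

test_that("model comparison ranks the NOWIW model ahead of the inverse Weibull", {
  cfg <- fit_config(starts = 10, seed = 1)
  cmp <- compare_models(battery(), c("nnowiw", "niw"), cfg)
  tab <- cmp$table
  aic_lo <- function(m) tab$aic[tab$model == m & tab$endpoint == "lower"]
  expect_lt(aic_lo("nnowiw"), aic_lo("niw"))
  expect_identical(cmp$ranking[1], "nnowiw")
  expect_error(compare_models(battery(), "nnowiw"), "at least 2")
  cmp2 <- compare_models(battery(), c("nnowiw", "niw"), cfg)
  expect_identical(cmp$table, cmp2$table) # same-seed reproducibility
})
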