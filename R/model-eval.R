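# Model assessment: information criteria, goodness-of-fit statistics with an
# exact small-sample Kolmogorov-Smirnov p-value, endpoint-wise descriptive
# statistics, and the multi-model comparison driver.

#' Information criteria from a fitted negative log-likelihood
#'
#' \deqn{AIC = 2\hat\ell^- + 2k, \quad CAIC = AIC + 2k(k+1)/(m-k-1),}
#' \deqn{BIC = 2\hat\ell^- + k \ln m, \quad HQIC = 2\hat\ell^- + 2k\ln(\ln m),}
#' where \eqn{\hat\ell^-} is the negative maximized log-likelihood, `k` the
#' number of free parameters and `m` the sample size; natural logarithms
#' throughout. Interval-valued inputs are handled endpoint-wise.
#'
#' @param neg_loglik a single number or an [interval()].
#' @param k number of free parameters.
#' @param m sample size; must exceed `k + 1` (CAIC denominator).
#' @return A tibble with one row per endpoint and columns `endpoint`,
#'   `neg_loglik`, `aic`, `caic`, `bic`, `hqic`, `k`, `m`.
#' @examples
#' information_criteria(88.62533, k = 4, m = 23)
#' @export
information_criteria <- function(neg_loglik, k, m) {
  stopifnot(k >= 0, m >= 1)
  if (m <= k + 1) abort("CAIC undefined: need m > k + 1.")
  if (inherits(neg_loglik, "interval")) {
    vals <- c(neg_loglik[["lower"]], neg_loglik[["upper"]])
    eps <- c("lower", "upper")
  } else {
    stopifnot(is.numeric(neg_loglik), length(neg_loglik) == 1L)
    vals <- neg_loglik
    eps <- "point"
  }
  aic <- 2 * vals + 2 * k
  tibble(
    endpoint = eps, neg_loglik = vals, aic = aic,
    caic = aic + 2 * k * (k + 1) / (m - k - 1),
    bic = 2 * vals + k * log(m),
    hqic = 2 * vals + 2 * k * log(log(m)),
    k = k, m = m
  )
}

#' Goodness-of-fit statistics against a fitted CDF
#'
#' Kolmogorov-Smirnov, Cramer-von Mises and Anderson-Darling statistics of a
#' positive sample against a fitted continuous CDF, with
#' \eqn{u_i = F(x_{(i)})}:
#' \deqn{D = \max_i \max(i/m - u_i,\; u_i - (i-1)/m),}
#' \deqn{W = 1/(12m) + \sum_i (u_i - (2i-1)/(2m))^2,}
#' \deqn{A = -m - \frac1m \sum_i (2i-1)[\ln u_i + \ln(1 - u_{m+1-i})].}
#' Small-sample modified variants \eqn{A^* = A(1 + 0.75/m + 2.25/m^2)} and
#' \eqn{W^* = W(1 + 0.5/m)} are also returned. Any \eqn{u_i} exactly 0 or 1
#' is clamped into the open unit interval with a warning (the log terms).
#'
#' @param x positive observations (sorted internally, stable).
#' @param cdf a vectorized fitted CDF, function of `x` only.
#' @return A one-row tibble with columns `ks`, `cvm`, `cvm_modified`, `ad`,
#'   `ad_modified`, `m`.
#' @export
gof_statistics <- function(x, cdf) {
  check_positive_x(x)
  stopifnot(is.function(cdf))
  xs <- sort(x, method = "radix")
  m <- length(xs); i <- seq_len(m)
  u <- cdf(xs)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    abort("Fitted CDF returned values outside [0, 1] on the data range.")
  }
  if (any(u == 0 | u == 1)) {
    warn("Fitted CDF hit 0 or 1 exactly at a data point; clamping for the log terms.")
    u <- pmin(pmax(u, .Machine$double.eps), 1 - .Machine$double.eps)
  }
  ks <- max(pmax(i / m - u, u - (i - 1) / m))
  cvm <- 1 / (12 * m) + sum((u - (2 * i - 1) / (2 * m))^2)
  ad <- -m - sum((2 * i - 1) * (log(u) + log1p(-rev(u)))) / m
  tibble(
    ks = ks, cvm = cvm, cvm_modified = cvm * (1 + 0.5 / m),
    ad = ad, ad_modified = ad * (1 + 0.75 / m + 2.25 / m^2),
    m = m
  )
}

# Exact P(D_m < d) for the one-sample Kolmogorov statistic
# (Marsaglia-Tsang-Wang matrix method).
kolmogorov_cdf_exact <- function(d, m) {
  if (d <= 0) return(0)
  if (d >= 1) return(1)
  k <- ceiling(m * d)
  h <- k - m * d
  sz <- 2 * k - 1
  H <- matrix(0, sz, sz)
  for (i in seq_len(sz)) {
    for (j in seq_len(sz)) if (i - j + 1 >= 0) H[i, j] <- 1
  }
  for (i in seq_len(sz)) {
    H[i, 1] <- H[i, 1] - h^i
    H[sz, sz - i + 1] <- H[sz, sz - i + 1] - h^i
  }
  H[sz, 1] <- H[sz, 1] + if (2 * h - 1 > 0) (2 * h - 1)^sz else 0
  for (i in seq_len(sz)) {
    for (j in seq_len(sz)) {
      if (i - j + 1 > 0) H[i, j] <- H[i, j] / factorial(i - j + 1)
    }
  }
  # H^m by binary powering with overflow rescaling
  pow <- function(A, p) {
    e <- 0
    R <- diag(nrow(A)); eR <- 0
    while (p > 0) {
      if (p %% 2 == 1) {
        R <- R %*% A; eR <- eR + e
        if (R[k, k] > 1e140) { R <- R * 1e-140; eR <- eR + 140 }
      }
      A <- A %*% A; e <- 2 * e
      if (A[k, k] > 1e140) { A <- A * 1e-140; e <- e + 140 }
      p <- p %/% 2
    }
    list(R = R, e = eR)
  }
  pw <- pow(H, m)
  s <- pw$R[k, k]; e <- pw$e
  for (i in seq_len(m)) {
    s <- s * i / m
    if (s < 1e-140) { s <- s * 1e140; e <- e - 140 }
  }
  s * 10^e
}

#' Kolmogorov-Smirnov p-value
#'
#' \eqn{P(D_m \ge d)} under the null that the data follow the evaluated
#' continuous CDF. Uses the exact finite-sample Kolmogorov distribution
#' (Marsaglia-Tsang-Wang matrix method) for \eqn{m \le 100} and the
#' asymptotic Kolmogorov series for larger samples.
#'
#' @param ks observed statistic in \eqn{[0, 1]}.
#' @param m sample size.
#' @return A probability.
#' @export
ks_pvalue <- function(ks, m) {
  stopifnot(length(ks) == 1L, ks >= 0, ks <= 1, m >= 1)
  if (m <= 100) return(1 - kolmogorov_cdf_exact(ks, m))
  if (ks == 0) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * m * ks^2))))
}

#' Endpoint-wise descriptive statistics of an interval sample
#'
#' Classical descriptive statistics computed separately on the lower- and
#' upper-endpoint series: sample mean; SD (divisor m-1); median; 10% per-side
#' trimmed mean; MAD scaled by 1.4826; min, max, range; moment-based
#' skewness \eqn{g_1} and excess kurtosis \eqn{g_2} (population-moment
#' convention, divisor m); and the standard error of the mean sd/sqrt(m).
#'
#' @inheritParams as_interval_sample
#' @return A tibble with one row per endpoint and columns `endpoint`, `m`,
#'   `mean`, `sd`, `median`, `trimmed`, `mad`, `min`, `max`, `range`,
#'   `skewness`, `kurtosis`, `se`.
#' @examples
#' describe_sample(battery_lifetimes())
#' @export
describe_sample <- function(data) {
  series <- split_sample(data)
  purrr::imap_dfr(series, function(x, ep) {
    m <- length(x)
    cm <- function(r) mean((x - mean(x))^r)
    tibble(
      endpoint = ep, m = m, mean = mean(x), sd = sd(x),
      median = median(x), trimmed = mean(x, trim = 0.1),
      mad = mad(x), min = min(x), max = max(x), range = max(x) - min(x),
      skewness = cm(3) / cm(2)^1.5, kurtosis = cm(4) / cm(2)^2 - 3,
      se = sd(x) / sqrt(m)
    )
  })
}

#' Compare candidate models on an interval-valued sample
#'
#' Fits each registry model by maximum likelihood to both endpoint series,
#' assembles information criteria and goodness-of-fit statistics per model
#' and endpoint, and ranks models by lower-endpoint AIC (smaller is better).
#' Models whose fits fail to converge are recorded and the comparison
#' proceeds with the survivors.
#'
#' @inheritParams as_interval_sample
#' @param models at least two registry names (see [iw_family_names()]).
#' @param config a [fit_config()].
#' @return An object of class `nnowiw_comparison`: a list with `table` (a
#'   tidy tibble: one row per model and endpoint with estimates list-column,
#'   criteria and GoF columns), `ranking` (models ordered by lower AIC),
#'   `failed` (non-converged models), `fits`, and the `config`.
#' @export
compare_models <- function(data, models = iw_family_names(),
                           config = fit_config()) {
  if (length(models) < 2) abort("Model comparison needs at least 2 models.")
  data <- as_interval_sample(data)
  series <- split_sample(data)
  m <- nrow(data)
  rows <- list(); fits <- list(); failed <- character(0)
  for (name in models) {
    spec <- iw_family(name)
    fit_lo <- fit_iw_family(name, series$lower, config)
    fit_up <- fit_iw_family(name, series$upper, config)
    fits[[name]] <- list(lower = fit_lo, upper = fit_up)
    if (!fit_lo$converged || !fit_up$converged) {
      failed <- c(failed, name)
      next
    }
    for (ep in c("lower", "upper")) {
      fit <- if (ep == "lower") fit_lo else fit_up
      x <- series[[ep]]
      crit <- information_criteria(fit$neg_loglik, spec$n_params, m)
      gof <- gof_statistics(x, function(q) spec$cdf(q, unname(fit$estimate)))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(model = name, endpoint = ep, k = spec$n_params, m = m,
               estimate = list(fit$estimate), neg_loglik = fit$neg_loglik),
        crit[c("aic", "caic", "bic", "hqic")],
        gof[c("ks", "cvm", "cvm_modified", "ad", "ad_modified")],
        tibble(ks_pvalue = ks_pvalue(gof$ks, m))
      )
    }
  }
  if (!length(rows)) abort("No model converged; nothing to compare.")
  table <- dplyr::bind_rows(rows)
  ranking <- table |>
    dplyr::filter(.data$endpoint == "lower") |>
    dplyr::arrange(.data$aic) |>
    dplyr::pull(.data$model)
  structure(list(table = table, ranking = ranking, failed = failed,
                 fits = fits, config = config),
            class = "nnowiw_comparison")
}

#' @export
print.nnowiw_comparison <- function(x, ...) {
  cat("Model comparison (ranked by lower-endpoint AIC):\n")
  cat(" ", paste(x$ranking, collapse = " > "), "\n")
  if (length(x$failed)) cat("  failed fits:", paste(x$failed, collapse = ", "), "\n")
  print(x$table[c("model", "endpoint", "neg_loglik", "aic", "ks", "ks_pvalue")])
  invisible(x)
}
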