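# Core mathematics of the new odd Weibull-inverse Weibull (NOWIW) model.
#
# The model arises from the odd-Weibull transform of a baseline CDF H:
#   F(x) = 1 - exp(-eta * [-H(x) * log(1 - H(x))]^zeta)
# with the inverse Weibull baseline H(x) = exp(-k x^-n) on x > 0.
#
# All evaluation is done in log space: the inner transform
# g(x) = -H log(1 - H) is catastrophically cancellative at both tails, so
# log(1 - H) is computed as log(-expm1(log H)) when H is close to 1 and as
# log1p(-H) otherwise, directly from log H = -k x^-n.

check_nowiw_params <- function(eta, zeta, k, n) {
  vals <- c(eta, zeta, k, n)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    abort("NOWIW parameters `eta`, `zeta`, `k`, `n` must all be finite and > 0.")
  }
  invisible(TRUE)
}

check_positive_x <- function(x, what = "x") {
  if (!all(is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and strictly positive (NOWIW support is (0, Inf)).", what))
  }
  invisible(TRUE)
}

# log H, log(1 - H), log g and log of the density bracket H/(1-H) - log(1-H),
# all from log H = -k x^-n.  Returns a list of vectors.
nowiw_parts <- function(x, k, n) {
  lH <- -k * x^(-n)
  # log(1 - H): switch representation at H = 1/2
  l1mH <- ifelse(lH > -0.6931472, log(-expm1(lH)), log1p(-exp(lH)))
  # g = H * (-log(1 - H)) > 0
  log_g <- lH + log(-l1mH)
  # bracket = H/(1-H) - log(1-H): sum of two positive terms, no cancellation
  log_brack <- log(exp(lH - l1mH) - l1mH)
  # deep lower tail: H underflows (lH < log(double.xmin)) so -log(1-H) ~ H;
  # then g ~ H^2 and bracket ~ 2H, in logs
  deep <- lH < -700
  if (any(deep)) {
    log_g[deep] <- 2 * lH[deep]
    log_brack[deep] <- log(2) + lH[deep]
  }
  list(lH = lH, l1mH = l1mH, log_g = log_g, log_brack = log_brack)
}

#' The new odd Weibull-inverse Weibull distribution
#'
#' Density, distribution function, survival function, hazard function,
#' quantile function and random generation for the NOWIW distribution with
#' odd-Weibull transform parameters `eta` (scale) and `zeta` (shape) and
#' inverse-Weibull baseline parameters `k` (scale) and `n` (shape).
#'
#' The CDF is \eqn{F(x) = 1 - \exp(-\eta [-H \log(1 - H)]^\zeta)} with
#' baseline \eqn{H(x) = \exp(-k x^{-n})} on \eqn{x > 0}. The survival
#' function is evaluated directly (not as `1 - cdf`) and the hazard uses its
#' closed form \eqn{h = \eta\zeta k n x^{-(n+1)} H [H/(1-H) - \log(1-H)]
#' g^{\zeta - 1}}, where the outer exponential factor of the density cancels
#' against the survival function.
#'
#' The quantile function inverts the CDF numerically: with
#' \eqn{A = (-\log(1-p)/\eta)^{1/\zeta}} the monotone inner equation
#' \eqn{t(1 - e^{-t}) = A} (where \eqn{t = -\log(1 - H)}) is solved by
#' bracketed root-finding on \eqn{[A, A + 1]} followed by Newton polishing,
#' then mapped back through the baseline. [qnowiw_lambert()] evaluates the
#' closed-form Lambert-W expression sometimes quoted for this family purely
#' as a diagnostic; it is never used for simulation or estimation.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param m number of observations to generate.
#' @param eta,zeta,k,n distribution parameters, all strictly positive.
#' @param log,log.p logical; if TRUE, probabilities/densities are returned on
#'   the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed optional integer seed for reproducible generation; the session
#'   RNG state is restored afterwards.
#' @return `dnowiw` gives the density, `pnowiw` the distribution function,
#'   `snowiw` the survival function, `hnowiw` the hazard, `qnowiw` the
#'   quantile function and `rnowiw` generates random deviates.
#' @examples
#' pnowiw(1, 1, 1, 1, 1)   # 0.15527
#' dnowiw(1, 1, 1, 1, 1)   # 0.32339
#' qnowiw(pnowiw(2, 1, 2, 1, 1), 1, 2, 1, 1)
#' @name nowiw
NULL

#' @rdname nowiw
#' @export
pnowiw <- function(q, eta, zeta, k, n, lower.tail = TRUE, log.p = FALSE) {
  check_nowiw_params(eta, zeta, k, n)
  check_positive_x(q, "q")
  parts <- nowiw_parts(q, k, n)
  log_sf <- -eta * exp(zeta * parts$log_g)
  if (lower.tail) {
    if (log.p) log(-expm1(log_sf)) else -expm1(log_sf)
  } else {
    if (log.p) log_sf else exp(log_sf)
  }
}

#' @rdname nowiw
#' @export
dnowiw <- function(x, eta, zeta, k, n, log = FALSE) {
  check_nowiw_params(eta, zeta, k, n)
  check_positive_x(x)
  parts <- nowiw_parts(x, k, n)
  logf <- log(eta) + log(zeta) + log(k) + log(n) - (n + 1) * log(x) +
    parts$lH + parts$log_brack + (zeta - 1) * parts$log_g -
    eta * exp(zeta * parts$log_g)
  # deep lower tail: -k x^-n overflows every other factor
  logf[parts$lH == -Inf] <- -Inf
  if (log) logf else exp(logf)
}

#' @rdname nowiw
#' @export
snowiw <- function(q, eta, zeta, k, n, log.p = FALSE) {
  pnowiw(q, eta, zeta, k, n, lower.tail = FALSE, log.p = log.p)
}

#' @rdname nowiw
#' @export
hnowiw <- function(x, eta, zeta, k, n, log = FALSE) {
  check_nowiw_params(eta, zeta, k, n)
  check_positive_x(x)
  parts <- nowiw_parts(x, k, n)
  logh <- log(eta) + log(zeta) + log(k) + log(n) - (n + 1) * log(x) +
    parts$lH + parts$log_brack + (zeta - 1) * parts$log_g
  logh[parts$lH == -Inf] <- -Inf
  if (log) logh else exp(logh)
}

# Solve t * (1 - exp(-t)) = A for t > 0 (monotone increasing; the root lies
# in [A, A + 1]).  Vectorized bracket-clamped Newton; any entry that fails to
# reach tolerance falls back to uniroot on the same bracket.
solve_inner_t <- function(A) {
  t <- pmax(A, sqrt(A))
  lo <- A; hi <- A + 1
  for (iter in 1:60) {
    e <- exp(-t)
    fval <- t * (1 - e) - A
    step <- fval / ((1 - e) + t * e)
    step[!is.finite(step)] <- 0
    t <- pmin(pmax(t - step, lo), hi)
    if (all(abs(fval) <= 1e-14 * pmax(1, A))) break
  }
  bad <- which(abs(t * (-expm1(-t)) - A) > 1e-10 * pmax(1, A) & A > 0)
  for (idx in bad) {
    a <- A[idx]
    t[idx] <- uniroot(function(s) s * (-expm1(-s)) - a, c(a, a + 1),
                      tol = 1e-13 * max(1, a))$root
  }
  t[A <= 0] <- 0
  t
}

#' @rdname nowiw
#' @export
qnowiw <- function(p, eta, zeta, k, n) {
  check_nowiw_params(eta, zeta, k, n)
  if (!all(is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  A <- (-log1p(-p) / eta)^(1 / zeta)
  t <- solve_inner_t(A)
  # t = -log(1 - H); baseline inversion x = (k / (-log H))^(1/n), carried out
  # in log space since -log H = -log(1 - e^-t) ~ e^-t underflows for large t
  log_neg_logH <- ifelse(t > 30, -t, log(-log1p(-exp(-t))))
  exp((log(k) - log_neg_logH) / n)
}

#' @rdname nowiw
#' @export
rnowiw <- function(m, eta, zeta, k, n, seed = NULL) {
  check_nowiw_params(eta, zeta, k, n)
  stopifnot(length(m) == 1L, m >= 0)
  if (m == 0) return(numeric(0))
  with_seed(seed, qnowiw(runif(m), eta, zeta, k, n))
}

#' Closed-form Lambert-W quantile expression (diagnostic only)
#'
#' Evaluates the closed-form quantile expression for the NOWIW distribution
#' built on the \eqn{W_{-1}} branch of the Lambert W function, and reports
#' the residual \eqn{|F(Q(p)) - p|} against the numerically inverted CDF.
#' With \eqn{A = (-\log(1-p)/\eta)^{1/\zeta}} the expression is
#' \eqn{Q(p) = [\log(A / (A + W_{-1}(A e^{A}))) / k]^{-1/n}}.
#'
#' The argument \eqn{A e^{A}} is positive for every valid `p`, while
#' \eqn{W_{-1}} is only real on \eqn{[-1/e, 0)}; the expression therefore
#' does not generally invert the CDF. Branch-domain violations are reported
#' via the `status` column rather than raised as errors, and [qnowiw()]
#' (bracketed numeric inversion) remains the authoritative quantile.
#'
#' @inheritParams nowiw
#' @return A tibble with columns `p`, `value`, `residual`, `status` where
#'   `status` is one of `"ok"`, `"branch-domain-violation"`,
#'   `"invalid-intermediate"`.
#' @seealso [qnowiw()]
#' @export
qnowiw_lambert <- function(p, eta, zeta, k, n) {
  check_nowiw_params(eta, zeta, k, n)
  if (!all(is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly inside (0, 1).")
  }
  A <- (-log1p(-p) / eta)^(1 / zeta)
  out <- purrr::map2_dfr(p, A, function(pi, a) {
    arg <- a * exp(a)
    if (!is.finite(arg) || arg < -exp(-1) || arg >= 0) {
      return(tibble(p = pi, value = NA_real_, residual = NA_real_,
                    status = "branch-domain-violation"))
    }
    w <- pracma::lambertWn(arg)
    inner <- a / (a + w)
    if (!is.finite(inner) || inner <= 0 || log(inner) / k <= 0) {
      return(tibble(p = pi, value = NA_real_, residual = NA_real_,
                    status = "invalid-intermediate"))
    }
    val <- (log(inner) / k)^(-1 / n)
    tibble(p = pi, value = val,
           residual = abs(pnowiw(val, eta, zeta, k, n) - pi),
           status = "ok")
  })
  out
}

#' Odd-Weibull generated family with a pluggable baseline
#'
#' CDF of the generated family \eqn{F(x) = 1 - \exp(-\eta[-H \log(1-H)]^\zeta)}
#' for an arbitrary baseline CDF \eqn{H}. [pnowiw()] is this family with the
#' inverse-Weibull baseline and a log-space evaluation of the inner transform.
#'
#' @param x vector of points in the baseline support.
#' @param eta,zeta transform parameters, > 0.
#' @param baseline a list with elements `cdf` (function of `(x, params)`),
#'   `pdf` (function of `(x, params)`, optional here) and `params`; see
#'   [baseline_inverse_weibull()].
#' @return Probabilities in \eqn{[0, 1]}. A baseline CDF value of exactly 1
#'   at finite `x` yields 1 with a support-boundary warning.
#' @examples
#' bl <- baseline_inverse_weibull(1, 1)
#' now_family_cdf(1, 1, 1, bl)  # equals pnowiw(1, 1, 1, 1, 1)
#' @export
now_family_cdf <- function(x, eta, zeta, baseline) {
  stopifnot(is.list(baseline), is.function(baseline$cdf))
  if (!all(is.finite(c(eta, zeta))) || eta <= 0 || zeta <= 0) {
    abort("`eta` and `zeta` must be finite and > 0.")
  }
  H <- baseline$cdf(x, baseline$params)
  if (any(!is.finite(H)) || any(H < 0) || any(H > 1)) {
    abort("Baseline CDF returned values outside [0, 1].")
  }
  at_boundary <- H == 1
  if (any(at_boundary)) {
    warn("Baseline CDF equals 1 at a finite point (support boundary); returning 1 there.")
  }
  g <- -H * log1p(-H)
  out <- -expm1(-eta * g^zeta)
  out[at_boundary] <- 1
  if (any(!is.finite(out))) abort("Non-finite intermediate in generated-family CDF.")
  out
}

#' Inverse-Weibull baseline for the generated family
#'
#' @param k,n inverse-Weibull scale and shape, > 0.
#' @return A baseline model list with `cdf`, `pdf` and `params` fields
#'   suitable for [now_family_cdf()].
#' @export
baseline_inverse_weibull <- function(k, n) {
  stopifnot(is.finite(k), is.finite(n), k > 0, n > 0)
  list(
    cdf = function(x, params) exp(-params[["k"]] * x^(-params[["n"]])),
    pdf = function(x, params) {
      params[["k"]] * params[["n"]] * x^(-(params[["n"]] + 1)) *
        exp(-params[["k"]] * x^(-params[["n"]]))
    },
    params = c(k = k, n = n)
  )
}
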