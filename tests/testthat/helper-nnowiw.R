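# Shared fixtures and independent oracle implementations.
#
# Oracles here deliberately avoid the package's numerical machinery: naive
# direct-formula evaluation, dense trapezoid quadrature, and double-loop
# statistics, so that agreement is evidence rather than tautology.

# parameter grid spanning light and heavy tails (eta, zeta, k, n)
param_grid <- function() {
  expand.grid(eta = c(0.5, 1, 2), zeta = c(0.5, 1, 2),
              k = c(0.8, 2.5), n = c(0.8, 1.5))
}

battery <- function() battery_lifetimes()

# naive direct evaluation of the generated-family CDF/PDF (no log-space care)
naive_cdf <- function(x, eta, zeta, k, n) {
  H <- exp(-k * x^(-n))
  g <- -H * log(1 - H)
  1 - exp(-eta * g^zeta)
}

naive_pdf <- function(x, eta, zeta, k, n) {
  H <- exp(-k * x^(-n))
  g <- -H * log(1 - H)
  brack <- H / (1 - H) - log(1 - H)
  eta * zeta * k * n * x^(-(n + 1)) * H * brack * g^(zeta - 1) *
    exp(-eta * g^zeta)
}

# Total mass of a density as integral up to X plus the model's survival at X.
# Heavy-tail parameter sets (zeta < 1) keep appreciable mass beyond any
# double-representable cutoff, so pure (0, Inf) quadrature of the pdf cannot
# reach 1e-8 accuracy; adding the closed-form tail keeps the check exact while
# still comparing the density formula against the independent survival form.
total_mass <- function(pdf_fun, sf_at, X) {
  breaks <- c(0, exp(seq(log(1e-4), log(X), length.out = 100)))
  pieces <- vapply(seq_len(length(breaks) - 1), function(j) {
    integrate(pdf_fun, breaks[j], breaks[j + 1], rel.tol = 1e-11,
              subdivisions = 200L, stop.on.error = FALSE)$value
  }, numeric(1))
  sum(pieces) + sf_at(X)
}

# dense-trapezoid integral of f(x) over (0, Inf) on a log-x grid (the slowly
# decaying upper tails of this family need log-domain resolution)
trapezoid_0inf <- function(f, nodes = 1e6, ymin = -15, ymax = 46) {
  y <- seq(ymin, ymax, length.out = nodes)
  x <- exp(y)
  v <- f(x) * x # d x = x d y
  v[!is.finite(v)] <- 0
  sum((v[-1] + v[-nodes]) / 2 * diff(y))
}

# double-loop goodness-of-fit reference (naive, O(m^2)-ish)
naive_gof <- function(x, u) {
  m <- length(x)
  ord <- order(x)
  u <- u[ord]
  ks <- 0
  for (i in 1:m) {
    ks <- max(ks, i / m - u[i], u[i] - (i - 1) / m)
  }
  cvm <- 1 / (12 * m)
  for (i in 1:m) cvm <- cvm + (u[i] - (2 * i - 1) / (2 * m))^2
  ad <- -m
  for (i in 1:m) {
    ad <- ad - (2 * i - 1) / m * (log(u[i]) + log(1 - u[m + 1 - i]))
  }
  list(ks = ks, cvm = cvm, ad = ad)
}

table3_truth <- function() {
  neutro_params(eta = c(2.3, 2.8), zeta = c(1.1, 1.6),
                k = c(1.5, 2.0), n = c(1.8, 2.3))
}
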