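---
title: "Methods: the neutrosophic new odd Weibull-inverse Weibull model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neutrosophic new odd Weibull-inverse Weibull model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnowiw)
```

## The model

The new odd Weibull-inverse Weibull (NOWIW) distribution composes an
odd-Weibull generator with an inverse-Weibull baseline. Writing
$H(x) = e^{-k x^{-n}}$ for the baseline CDF on $x > 0$ ($k, n > 0$), the
generated CDF is

$$
F(x) = 1 - \exp\!\left(-\eta\,\big[-H(x)\,\log(1 - H(x))\big]^{\zeta}\right),
\qquad \eta, \zeta > 0 .
$$

The inner transform $g(x) = -H \log(1-H)$ increases from 0 to $\infty$ with
$x$, so $F$ is a proper CDF. The density, survival and hazard functions
follow by differentiation; the hazard has a closed form because the outer
exponential factor cancels between density and survival.

**Tail behaviour and moments.** As $x \to \infty$ the baseline saturates,
$1 - H \approx k x^{-n}$, and the survival function behaves like
$\exp(-\eta\,(n \log x - \log k)^{\zeta})$. This single observation governs
almost everything unusual about the family:

* $\zeta > 1$: super-polynomial decay, all moments finite;
* $\zeta = 1$: an exact polynomial tail of order $\eta n$, so $E[X^r]$ is
  finite iff $r < \eta n$;
* $\zeta < 1$: sub-polynomial ("slower than any power") decay, so **every**
  moment of order $r \ge 1$ diverges, and numerically the distribution keeps
  appreciable mass beyond any double-representable point (at
  $\eta = \zeta = 0.5$, $n = 0.8$ about 5% of the mass lies beyond
  $x = 10^{18}$).

`nowiw_moment()` therefore decides existence analytically from this tail
rule and never reports a number for a divergent order. The same analysis
shows that $E[e^{tX}] = \infty$ for every $t > 0$ (the tail is
sub-exponential for all parameter values), which is why no moment generating
function is exposed; the characteristic function `nowiw_cf()` always exists
and is computed by quadrature.

## Interval (neutrosophic) semantics

Observations and parameters may carry an indeterminacy interval
$[\text{lower}, \text{upper}]$; a degenerate interval recovers the classical
quantity bit-for-bit. All interval handling is **endpoint-wise**: curves,
fits and statistics are evaluated at the lower-endpoint parameter slice and
at the upper-endpoint slice, pairing lower with lower and upper with upper.
This matches how interval-valued tables for this model are constructed, but
it is a convention, not interval arithmetic: the two endpoint curves are not
guaranteed to bound the curves obtained from interior parameter values, and
no such claim is made anywhere in the package.

An interval sample is a plain data frame with columns `lower` and `upper`
(`as_interval_sample()` promotes a single column to degenerate intervals),
and `split_sample()` is a pure projection: no sorting, no deduplication.

## Numerical evaluation

The inner transform is catastrophically cancellative at both tails, so all
core functions work from $\log H = -k x^{-n}$: $\log(1-H)$ is computed as
`log(-expm1(log H))` when $H > 1/2$ and `log1p(-exp(log H))` otherwise, and
the density is assembled entirely in log space. When $H$ underflows
($\log H < -700$) the exact small-$H$ asymptotics $g \sim H^2$,
$H/(1-H) - \log(1-H) \sim 2H$ take over, keeping the log-density finite for
every $\zeta$.

**Quantiles.** With $A = (-\log(1-p)/\eta)^{1/\zeta}$, inverting the CDF
reduces to the monotone scalar equation $t\,(1 - e^{-t}) = A$ in
$t = -\log(1-H)$, whose root lies in $[A, A+1]$. A vectorized
bracket-clamped Newton iteration (uniroot fallback) solves it to machine
precision, and the baseline inversion $x = (k/(-\log H))^{1/n}$ is carried
out in log space so extreme tail probabilities do not overflow
prematurely. Round-trip accuracy $|F(Q(p)) - p|$ is at the
$10^{-12}$ level across the tested grid. A Lambert-W closed form is sometimes
quoted for this quantile; `qnowiw_lambert()` evaluates it verbatim as a
diagnostic and reports its residual, because its $W_{-1}$ argument
$A e^{A}$ is positive for every valid $p$ while the real $W_{-1}$ branch
only exists on $[-1/e, 0)$ — the closed form does not invert the CDF, and
numeric inversion is authoritative throughout (including simulation).

**Quadrature.** Integrals over $(0, \infty)$ (moments, incomplete moments,
probability-weighted moments, the $J(c) = \int f^c$ behind all four
entropies, the characteristic function) are accumulated piecewise in
$y = \log x$: fixed-width log-domain pieces are integrated adaptively until
three consecutive pieces are negligible relative to the running total. A
single global transform such as $x = u/(1-u)$ silently loses tail mass for
this family's slowly decaying tails, which is why the piecewise scheme is
used. The test suite checks the density's unit mass as
$\int_0^X f + S(X) = 1$ with the closed-form survival supplying the
(possibly non-representable) tail.

## Series expansions are diagnostics, not the computational path

The CDF and PDF admit formal expansions in powers of $H$, built from the
standard power-of-a-power-series coefficients
$d_{s,0} = 1,\; d_{s,j} = \frac1j \sum_{m=1}^{j} \frac{m(s+1) - j}{m+1}
d_{s,j-m}$. Two corrections were needed to make the printed forms
reproduce the functions they expand: the sign factor reduces to $(-1)^i$
from the exponential series alone (a factor $(-1)^{i\zeta + j}$ is
ill-defined for non-integer $\zeta$ and double-counts the two negative signs
in $g$), and the termwise moment integral evaluates to
$\Gamma((n-r)/n)\,(bk)^{(r-n)/n}/n$, which exists only for $r < n$. With
these conventions the truncated CDF/PDF series converge geometrically for
every $x$ (radius $H < 1$) and agree with the quadrature core within their
remainder estimates; the moment series, however, loses the geometric factor
upon integration, its bracket-index sums decay only algebraically, and no
practical truncation converges — `nowiw_series_moment()` detects the band
growth and returns a `"diverged"` status instead of a value. All series
results carry `(value, remainder, status)` and nothing downstream consumes
them; the CLI exposes them under `diagnose`.

## Estimation

Three estimators are provided for point-valued samples, each optimized over
log-parameters (unconstrained) by a seeded multistart: a Latin-style grid of
starting points on $[\log 0.05, \log 10]^4$ (20 starts by default), a BFGS
search and an iterated Nelder-Mead polish per start.

* **MLE** maximizes $\sum_i \log f(x_i)$. The log-likelihood is assembled
  term by term with the $x$-exponent $-(n+1)\sum \log x_i$ matching the
  density factor $x^{-(n+1)}$, and the identity
  `loglik == sum(dnowiw(log = TRUE))` is enforced by a test.
* **LSE / WLSE** minimize
  $\sum_i w_i\,[F(x_{(i)}) - i/(m+1)]^2$ with $w_i = 1$ (LSE) or
  $w_i = (m+1)^2(m+2)/(i(m-i+1))$ (WLSE), the reciprocal variances of
  uniform order statistics; plotting positions are $i/(m+1)$.

**Admissibility.** The four-parameter family contains a non-identifiable
degenerate regime: as $\eta \to 0$ with $k, n \to \infty$ the baseline
saturates ($H \to 1$ on the data range) and the model collapses to a
three-parameter Weibull in $\log x$, along which the likelihood can creep
upward while parameters diverge. A candidate optimum is accepted only if it
is *stationary* (an additional polish no longer improves the objective) and
its estimates lie inside a generous admissibility box
($[10^{-4}, 10^{4}]$ per parameter, eight orders of magnitude around the
scale of typical lifetime data); fits whose estimates escape are reported
non-converged, mirroring the usual practice of excluding degenerate
solutions. Interval-valued samples are fitted endpoint-wise
(`fit_nnowiw()`), and each parameter is reported as the interval spanned by
the two endpoint estimates.

**Weak identifiability.** Even away from the degenerate regime the
parameters trade off strongly: samples drawn from one parameter point are
routinely best fitted, in likelihood, by a quite different point whose CDF is
nearly indistinguishable on the data range. Estimator quality should
therefore be judged in distribution (sup-distance between fitted and true
CDF, which the tests assert) rather than parameter by parameter; per-parameter
RMSEs in the Monte Carlo harness are large for exactly this reason and
shrink with sample size without converging to zero at realistic sizes.

## Model comparison and goodness of fit

`compare_models()` fits the NOWIW model and six inverse-Weibull-family
competitors (inverse Weibull plus beta, Kumaraswamy,
exponentiated-generalized, log-gamma and Gompertz extensions of it) by the
same multistart MLE, then ranks models by lower-endpoint AIC. Information
criteria use the standard forms
$\mathrm{AIC} = 2\hat\ell^- + 2k$,
$\mathrm{CAIC} = \mathrm{AIC} + 2k(k+1)/(m-k-1)$,
$\mathrm{BIC} = 2\hat\ell^- + k\ln m$,
$\mathrm{HQIC} = 2\hat\ell^- + 2k \ln \ln m$ (natural logs). Two competitor
formulas required repair to be valid CDFs: the Gompertz composition uses the
standard $\exp\{(\eta/\zeta)(1 - (1-G)^{-\zeta})\}$ form, and the log-gamma
composition uses $F = P(\eta, -\zeta\log(1-G))$ with $P$ the regularized
lower incomplete gamma — the variant with an extra $1 - \cdot$ in front
decreases from 1 to 0 and is not a distribution function (fitting by its
companion density while scoring with the decreasing expression reproduces
exactly the kind of pathological goodness-of-fit row such comparisons
sometimes print). On the bundled battery data the exponentiated-generalized
and Gompertz variants have no admissible stationary optimum (their
likelihoods increase along $\eta \to \infty$, resp. $\zeta \to 0$, ridges);
they are reported non-converged and the comparison proceeds with the
survivors.

Goodness of fit uses the standard one-sample statistics with
$u_i = F(x_{(i)})$: Kolmogorov-Smirnov
$D = \max_i \max(i/m - u_i, u_i - (i-1)/m)$, Cramér-von Mises
$W = 1/(12m) + \sum_i (u_i - (2i-1)/(2m))^2$ and Anderson-Darling
$A = -m - \frac1m \sum_i (2i-1)[\ln u_i + \ln(1 - u_{m+1-i})]$, each also in
its small-sample-modified variant since comparison tables rarely say which
was used. The K-S $p$-value uses the exact finite-sample Kolmogorov
distribution (Marsaglia-Tsang-Wang matrix method) for $m \le 100$ and the
asymptotic series beyond; the exact path is verified against
`stats::ks.test`. All statistics are computed against the CDF whose
parameters were estimated from the same data — the usual practice in such
comparisons — so the $p$-values are optimistic; no re-estimation penalty or
bootstrap calibration is attempted.

## Synthetic interval data and the Monte Carlo harness

`rnnowiw()` draws one uniform stream and pushes it through the quantile
functions of both endpoint parameter slices; a per-observation sort then
guarantees `lower <= upper`. Common-uniform coupling was chosen because it
preserves within-observation ordering and makes degenerate parameter
intervals produce exactly degenerate data; it emulates interval-valued
sampling from the model, not any particular physical measurement process
(real interval data would also carry measurement-specific width patterns
and possible dependence between width and level that this generator does not
model — passing tests say nothing about those features).

`run_monte_carlo()` evaluates the estimators at a data-generating truth
(default study configuration $\eta_N = [2.3, 2.8]$, $\zeta_N = [1.1, 1.6]$,
$k_N = [1.5, 2.0]$, $n_N = [1.8, 2.3]$, sample sizes 20-200), reporting per
(size, method, parameter, endpoint) the mean estimate, bias and RMSE over
replications. Non-converged fits (mostly degenerate-regime escapes, which
are frequent at the lower endpoint where $\zeta_L = 1.1$ sits near the
heavy-tail boundary) are dropped and counted, and any cell losing more than
20% of its replications is flagged `unreliable`. The whole summary is
bit-reproducible from `(design, seed)`. The test suite runs the harness at
100 replications with sizes 20 and 200 and MLE only (about 2.5 minutes);
the CLI default is 1000 replications across four sizes and all three
methods.

## Defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| multistart starts | 20 (4 inside the Monte Carlo harness) | the dominant battery-data basin is found by ~3/4 of random starts; 20 gives comfortable margin, and simulated samples additionally seed the truth |
| start range | $[0.05, 10]$ on each parameter (log-uniform) | brackets the magnitudes seen in lifetime applications of this family |
| admissibility box | $[10^{-4}, 10^{4}]$ | excludes the non-identifiable saturated regime while leaving three orders of magnitude around every start |
| stationarity | extra Nelder-Mead polish must improve by < max($10^{-6}$, $10^{-8}|f|$) | separates converged optima from degenerate ridges that keep creeping |
| trimmed mean | 10% per side | the convention of the descriptive table this package reproduces |
| MAD scale | 1.4826 | consistency with the normal SD |
| skewness/kurtosis | moment-based $g_1$, excess $g_2$ in `describe_sample()`; plain (normal = 3) fourth-moment kurtosis in `nowiw_summary()` | conventions are printed in the output because published tables for this model mix them |
| interval display | `[lower, upper]`, 5 decimals | matches the tables this package reproduces |

## Known limitations

* Endpoint-wise interval semantics (no enclosure guarantee for interior
  parameters; no fuzzy/possibilistic calculus).
* No censoring, no standard errors or confidence intervals for the fits,
  no Bayesian estimation.
* Goodness-of-fit $p$-values are not recalibrated for parameter estimation.
* The series module is exploratory: its moment series never converges at
  practical truncation, and its CDF/PDF series exist to cross-check the
  quadrature core, not to replace it.
* Parameter-level interpretation of fitted $(\eta, \zeta, k, n)$ is fragile
  (weak identifiability); interpret fitted CDFs, quantiles and hazards
  instead.
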