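# Interval (neutrosophic) semantics.
#
# A neutrosophic quantity is an ordered pair [lower, upper]; a degenerate
# interval (lower == upper) recovers the classical quantity exactly.
# Interval-valued parameters and observations are handled endpoint-wise:
# every curve, fit or statistic is evaluated at the lower-endpoint slice and
# at the upper-endpoint slice, pairing lower with lower and upper with upper.
# This is a convention, not interval arithmetic: the two endpoint curves need
# not bound the curves obtained from interior parameter values.

#' Construct an interval
#'
#' @param lower,upper finite numerics with `lower <= upper`; `upper` defaults
#'   to `lower` (a degenerate, classical value).
#' @return A length-2 named numeric vector of class `interval`.
#' @export
interval <- function(lower, upper = lower) {
  stopifnot(length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (lower > upper) abort("`lower` must not exceed `upper`.")
  structure(c(lower = lower, upper = upper), class = "interval")
}

#' @export
format.interval <- function(x, digits = 5, ...) {
  sprintf("[%.*f, %.*f]", digits, x[["lower"]], digits, x[["upper"]])
}

#' @export
print.interval <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

as_interval <- function(x) {
  if (inherits(x, "interval")) return(x)
  x <- as.numeric(x)
  if (length(x) == 1L) interval(x) else interval(x[1], x[2])
}

#' Interval-valued NOWIW parameters
#'
#' Bundles one interval per parameter. Each argument may be a single number
#' (a degenerate interval), a length-2 vector, or an [interval()].
#'
#' @param eta,zeta,k,n interval-valued parameters; all lower endpoints must
#'   be strictly positive.
#' @return An object of class `neutro_params`.
#' @examples
#' neutro_params(c(2.3, 2.8), c(1.1, 1.6), c(1.5, 2.0), c(1.8, 2.3))
#' @export
neutro_params <- function(eta, zeta, k, n) {
  p <- list(eta = as_interval(eta), zeta = as_interval(zeta),
            k = as_interval(k), n = as_interval(n))
  lows <- vapply(p, function(iv) iv[["lower"]], numeric(1))
  if (any(lows <= 0)) {
    abort("All parameter intervals must have strictly positive lower endpoints.")
  }
  structure(p, class = "neutro_params")
}

#' @export
print.neutro_params <- function(x, digits = 5, ...) {
  cat("Neutrosophic NOWIW parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-4s %s\n", nm, format(x[[nm]], digits)))
  invisible(x)
}

#' Endpoint slices of interval-valued parameters
#'
#' Projects a `neutro_params` object onto its lower-endpoint and
#' upper-endpoint classical parameter vectors. For degenerate intervals both
#' slices are identical; reassembling the slices with [neutro_params()]
#' round-trips exactly.
#'
#' @param params a [neutro_params()] object.
#' @return A list with named numeric vectors `lower` and `upper`, each with
#'   elements `eta`, `zeta`, `k`, `n`.
#' @export
endpoint_slices <- function(params) {
  stopifnot(inherits(params, "neutro_params"))
  list(
    lower = vapply(params, function(iv) iv[["lower"]], numeric(1)),
    upper = vapply(params, function(iv) iv[["upper"]], numeric(1))
  )
}

#' Validate an interval-valued sample
#'
#' An interval sample is a data frame with columns `lower` and `upper`, one
#' observation per row. A single-column data frame (or bare numeric vector)
#' is promoted to degenerate intervals.
#'
#' @param data a data frame with columns `lower`/`upper`, a one-column data
#'   frame, or a numeric vector.
#' @return A tibble with columns `lower`, `upper`, row order preserved.
#' @export
as_interval_sample <- function(data) {
  if (is.numeric(data)) data <- tibble(lower = data, upper = data)
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("Interval sample must be nonempty.")
  if (ncol(data) == 1L) {
    data <- tibble(lower = data[[1]], upper = data[[1]])
  }
  if (!all(c("lower", "upper") %in% names(data))) {
    abort("Interval sample needs columns `lower` and `upper` (or a single column).")
  }
  data <- data[c("lower", "upper")]
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("Interval sample columns must be numeric.")
  }
  if (any(!is.finite(data$lower)) || any(!is.finite(data$upper))) {
    abort("Interval sample contains non-finite values.")
  }
  bad <- which(data$lower > data$upper)
  if (length(bad)) {
    abort(sprintf("Interval sample rows with lower > upper: %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(data$lower <= 0)) {
    abort("All interval observations must have strictly positive lower endpoints.")
  }
  data
}

#' Split an interval sample into its endpoint series
#'
#' A pure projection: no sorting, no deduplication; both series preserve the
#' original observation order and have the sample's length.
#'
#' @inheritParams as_interval_sample
#' @return A list with numeric vectors `lower` and `upper`.
#' @export
split_sample <- function(data) {
  data <- as_interval_sample(data)
  list(lower = data$lower, upper = data$upper)
}

#' Interval-valued distribution curves
#'
#' Evaluates a NOWIW function at the lower- and upper-endpoint parameter
#' slices over a grid, together with the pointwise min/max envelope. The
#' envelope describes the two endpoint curves only; it is not claimed to
#' enclose curves for interior parameter values.
#'
#' @param fn one of `"cdf"`, `"pdf"`, `"sf"`, `"hazard"`.
#' @param x positive, increasing grid.
#' @param params a [neutro_params()] object.
#' @return A tibble with columns `x`, `fn`, `lower_curve`, `upper_curve`,
#'   `band_min`, `band_max`.
#' @export
neutro_curve <- function(fn = c("cdf", "pdf", "sf", "hazard"), x, params) {
  fn <- match.arg(fn)
  check_positive_x(x)
  if (is.unsorted(x, strictly = FALSE)) abort("`x` grid must be increasing.")
  sl <- endpoint_slices(params)
  f <- switch(fn, cdf = pnowiw, pdf = dnowiw, sf = snowiw, hazard = hnowiw)
  lo <- f(x, sl$lower[["eta"]], sl$lower[["zeta"]], sl$lower[["k"]], sl$lower[["n"]])
  up <- f(x, sl$upper[["eta"]], sl$upper[["zeta"]], sl$upper[["k"]], sl$upper[["n"]])
  tibble(x = x, fn = fn, lower_curve = lo, upper_curve = up,
         band_min = pmin(lo, up), band_max = pmax(lo, up))
}
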