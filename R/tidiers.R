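# broom-style tidiers for fitted objects.

#' Tidy a NOWIW point fit
#'
#' @param x a `nowiw_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.nowiw_fit <- function(x, ...) {
  tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' Glance at a NOWIW point fit
#'
#' @inheritParams tidy.nowiw_fit
#' @return A one-row tibble with `distribution`, `method`, `objective`,
#'   `neg_loglik`, `aic`, `bic`, `converged`, `n_obs`, `starts_tried`, `seed`.
#' @export
glance.nowiw_fit <- function(x, ...) {
  kp <- length(x$estimate)
  tibble(
    distribution = x$distribution, method = x$method,
    objective = x$objective, neg_loglik = x$neg_loglik,
    aic = 2 * x$neg_loglik + 2 * kp,
    bic = 2 * x$neg_loglik + kp * log(x$n_obs),
    converged = x$converged, n_obs = x$n_obs,
    starts_tried = x$starts_tried, seed = x$seed
  )
}

#' Tidy a neutrosophic NOWIW fit
#'
#' @param x an `nnowiw_fit` object.
#' @param ... unused.
#' @return A tibble with one row per parameter: `term`, `lower`, `upper`.
#' @export
tidy.nnowiw_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("eta", "zeta", "k", "n"),
                  lower = NA_real_, upper = NA_real_))
  }
  purrr::imap_dfr(unclass(x$params_hat), function(iv, nm) {
    tibble(term = nm, lower = iv[["lower"]], upper = iv[["upper"]])
  })
}

#' Glance at a neutrosophic NOWIW fit
#'
#' @inheritParams tidy.nnowiw_fit
#' @return A one-row tibble with the method, interval-valued objective and
#'   negative log-likelihood endpoints, convergence and sample size.
#' @export
glance.nnowiw_fit <- function(x, ...) {
  tibble(
    distribution = x$distribution, method = x$method,
    neg_loglik_lower = if (x$converged) x$neg_loglik[["lower"]] else NA_real_,
    neg_loglik_upper = if (x$converged) x$neg_loglik[["upper"]] else NA_real_,
    converged = x$converged, n_obs = x$n_obs, seed = x$seed
  )
}
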