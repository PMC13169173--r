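# ggplot2 graphics for interval-valued curves and fits.

#' Plot an interval-valued distribution curve band
#'
#' Draws the lower- and upper-endpoint curves of [neutro_curve()] with the
#' min/max envelope shaded. The band joins the two endpoint curves; it is
#' not an enclosure for interior parameter values.
#'
#' @inheritParams neutro_curve
#' @return A ggplot object.
#' @examples
#' p <- neutro_params(c(0.5, 1.5), c(1.7, 2.7), c(0.5, 1.5), c(0.8, 1.8))
#' plot_neutro_curve("pdf", seq(0.2, 8, length.out = 200), p)
#' @export
plot_neutro_curve <- function(fn = c("cdf", "pdf", "sf", "hazard"), x, params) {
  fn <- match.arg(fn)
  band <- neutro_curve(fn, x, params)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_min,
                                      ymax = .data$band_max),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower_curve,
                                    colour = "lower endpoint")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper_curve,
                                    colour = "upper endpoint")) +
    ggplot2::scale_colour_manual(values = c("lower endpoint" = "#00441b",
                                            "upper endpoint" = "#7f0000")) +
    ggplot2::labs(x = "x", y = fn, colour = NULL,
                  title = sprintf("Interval-valued NOWIW %s", fn)) +
    ggplot2::theme_minimal()
}

#' Autoplot a neutrosophic NOWIW fit
#'
#' Empirical CDFs of the two endpoint series overlaid with the fitted
#' endpoint CDF curves.
#'
#' @param object an `nnowiw_fit` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.nnowiw_fit <- function(object, ...) {
  if (!object$converged) abort("Cannot plot a non-converged fit.")
  grids <- purrr::imap_dfr(object$fits, function(fit, ep) {
    x <- sort(fit$data)
    grid <- seq(min(x) * 0.8, max(x) * 1.1, length.out = 200)
    e <- fit$estimate
    tibble(endpoint = ep, x = grid,
           fitted = pnowiw(grid, e[["eta"]], e[["zeta"]], e[["k"]], e[["n"]]))
  })
  ecdf_pts <- purrr::imap_dfr(object$fits, function(fit, ep) {
    x <- sort(fit$data)
    tibble(endpoint = ep, x = x, ecdf = seq_along(x) / length(x))
  })
  ggplot2::ggplot() +
    ggplot2::geom_step(data = ecdf_pts,
                       ggplot2::aes(x = .data$x, y = .data$ecdf,
                                    colour = .data$endpoint),
                       alpha = 0.6) +
    ggplot2::geom_line(data = grids,
                       ggplot2::aes(x = .data$x, y = .data$fitted,
                                    colour = .data$endpoint),
                       linewidth = 0.9) +
    ggplot2::labs(x = "x", y = "CDF",
                  title = "Empirical vs fitted endpoint CDFs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
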