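#' Plot a sample autocorrelation function
#'
#' Lollipop ACF plot with the \eqn{\pm 1.96/\sqrt{T}} white-noise bounds.
#'
#' @param object An [sample_acf()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.odn_acf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$upper),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$lower),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "lag", y = "sample ACF") +
    ggplot2::theme_minimal()
}

#' Plot an AIC model-selection table
#'
#' Percent AIC difference to the best-fitting ARMA order, mirroring the
#' standard presentation of residual model comparisons.
#'
#' @param object An [arma_grid_aic()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.odn_aic <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$converged)
  dat$label <- sprintf("(%d,%d,%d)", dat$p, dat$d, dat$q)
  dat$label <- factor(dat$label, levels = dat$label[order(dat$aic)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$delta_aic_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "ARIMA(p,d,q)", y = "% AIC difference to minimum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot study estimates against the autocorrelation grid
#'
#' Point estimates with 95% intervals per replicate, faceted by parameter
#' and coloured by noise model; dashed lines mark the generating values.
#'
#' @param object An [run_study()] result.
#' @param parameters Parameters to show (default `r` and `kappa`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.odn_study <- function(object, parameters = c("r", "kappa"), ...) {
  dat <- dplyr::filter(object$results, .data$term %in% parameters)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(round(.data$rho, 4)),
                                    y = .data$estimate,
                                    colour = .data$noise_model)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$truth),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.2) +
    ggplot2::facet_wrap(~ .data$term, scales = "free_y") +
    ggplot2::labs(x = expression(rho), y = "estimate", colour = "noise model") +
    ggplot2::theme_minimal()
}

#' Empirical versus analytic variance inflation
#'
#' Scatters the per-replicate empirical VIRs from a study against the
#' closed-form AR(1) curve \eqn{(1+\rho)/(1-\rho)}.
#'
#' @param study An [run_study()] result (full MCMC mode).
#' @param parameters Parameters to include.
#' @return A ggplot object.
#' @export
plot_vir_curve <- function(study, parameters = c("r", "kappa")) {
  emp <- study_empirical_vir(study, parameters)
  grid <- tibble::tibble(rho = seq(min(emp$rho), max(emp$rho), length.out = 100))
  grid$vir <- vir_ar1(grid$rho)
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$rho, y = .data$vir)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$term), width = 0.003,
                         alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(rho), y = "variance inflation ratio",
                  colour = "parameter") +
    ggplot2::theme_minimal()
}
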