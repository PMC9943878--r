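#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit
#'
#' One row per parameter. Point fits report the estimate with asymptotic
#' 95% intervals from the observed information; posterior fits report the
#' posterior median, 2.5%/97.5% quantiles and split-\eqn{\hat R}.
#'
#' @param x An `odn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`
#'   (and `rhat` for posterior fits).
#' @export
tidy.odn_fit <- function(x, ...) {
  if (x$mode == "point") {
    point_intervals(x)[, c("term", "estimate", "lower", "upper")]
  } else {
    ps <- posterior_summary(x)
    tibble::tibble(term = ps$term, estimate = ps$median,
                   lower = ps$q2.5, upper = ps$q97.5,
                   rhat = unname(x$rhat[ps$term]))
  }
}

#' Glance at a model fit
#'
#' @param x An `odn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `noise_model`, `n_obs`, `n_par`,
#'   `logLik`, `AIC` (2k - 2 logL) and, for posterior fits, `max_rhat`
#'   and `converged`.
#' @export
glance.odn_fit <- function(x, ...) {
  k <- length(x$transform$names)
  out <- tibble::tibble(
    mode = x$mode, noise_model = x$noise_model, n_obs = x$n_obs,
    n_par = k, logLik = x$loglik, AIC = 2 * k - 2 * x$loglik
  )
  if (x$mode == "posterior") {
    out$max_rhat <- max(x$rhat, na.rm = TRUE)
    out$converged <- x$converged
  }
  out
}
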