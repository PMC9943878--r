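# Parameter transforms: positive parameters are optimised/sampled on the
# log scale, rho on the atanh scale, everything else untransformed.
par_transform_info <- function(model, noise_model, extra = character()) {
  nn <- c(noise_par_names(noise_model), extra)
  names_all <- c(model$par_names, nn)
  kind <- c(
    ifelse(model$positive, "log", "identity"),
    vapply(nn, function(p) switch(p, sigma = "log", rho = "atanh", "identity"), "")
  )
  names(kind) <- names_all
  list(names = names_all, kind = kind)
}

to_unconstrained <- function(x, kind) {
  u <- x
  u[kind == "log"] <- log(x[kind == "log"])
  u[kind == "atanh"] <- atanh(x[kind == "atanh"])
  u
}

to_constrained <- function(u, kind) {
  x <- u
  x[kind == "log"] <- exp(u[kind == "log"])
  x[kind == "atanh"] <- tanh(u[kind == "atanh"])
  x
}

# log |dx/du| for the change of variables (used in MCMC)
log_jacobian <- function(u, kind) {
  j <- 0
  j <- j + sum(u[kind == "log"])
  j <- j + sum(log1p(-tanh(u[kind == "atanh"])^2))
  j
}

# Default starting values: model-specific heuristic for theta, residual
# moments for the noise parameters.
default_start <- function(data, model, noise_model) {
  theta0 <- if (!is.null(model$init)) model$init(data) else {
    stats::setNames(rep(1, length(model$par_names)), model$par_names)
  }
  resid <- data$value - model$simulate(theta0, data$time)
  sigma0 <- max(stats::sd(resid), 1e-6)
  start <- c(theta0, sigma = sigma0)
  if (noise_model %in% c("ar1", "arma11", "arma_kalman")) {
    r1 <- if (stats::sd(resid) > 0) {
      stats::cor(resid[-1], resid[-length(resid)])
    } else 0
    start <- c(start, rho = max(min(r1, 0.98), -0.98))
  }
  if (noise_model %in% c("arma11", "arma_kalman")) start <- c(start, phi = 0)
  start
}

#' Maximum-likelihood / MAP point estimation
#'
#' Step (i) of the diagnostic workflow: fit the deterministic model plus a
#' noise model to an observed time series by maximising the log-likelihood
#' (or, when `priors` are supplied, the posterior density). Optimisation
#' runs on transformed parameters (log for positive parameters,
#' atanh for \eqn{\rho}) with Nelder-Mead followed by a BFGS polish; the
#' best of `restarts` jittered starts is returned.
#'
#' @param data A data frame with numeric columns `time` and `value`.
#' @param model An [new_model()] object.
#' @param noise_model One of `"iid"`, `"ar1"` (conditional AR(1)
#'   likelihood), `"arma11"` (conditional), `"arma_kalman"` (exact
#'   ARMA(1,1) state-space likelihood).
#' @param start Optional named starting vector (model parameters plus
#'   `sigma` and, as applicable, `rho`, `phi`); defaults to a data-driven
#'   heuristic.
#' @param priors Optional named list of prior objects (see [prior_normal()]);
#'   when given, the MAP estimate is returned.
#' @param restarts Number of optimisation restarts from jittered starts.
#' @param seed Optional seed (makes the jittered restarts reproducible).
#' @param maxit Maximum Nelder-Mead iterations per restart.
#' @return An object of class `odn_fit` with `mode = "point"`: estimates,
#'   final log-likelihood, per-restart traces and the inverse-curvature
#'   (observed information) matrix on the transformed scale.
#'   `tidy()` and `glance()` methods are available.
#' @examples
#' d <- generate_dataset(study_design(n_obs = 200), rho = 0.8, replicate = 1)
#' fit <- fit_point_estimate(d, logistic_model(), "ar1", seed = 1)
#' tidy(fit)
#' @export
fit_point_estimate <- function(data, model, noise_model = c("iid", "ar1", "arma11", "arma_kalman"),
                               start = NULL, priors = NULL, restarts = 3,
                               seed = NULL, maxit = 2000) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(model, "odn_model"), is.data.frame(data))
  if (!all(c("time", "value") %in% names(data))) {
    stop("`data` must have `time` and `value` columns.", call. = FALSE)
  }
  tr <- par_transform_info(model, noise_model)
  start <- start %||% default_start(data, model, noise_model)
  start <- start[tr$names]
  if (anyNA(start)) stop("`start` must cover: ", paste(tr$names, collapse = ", "), call. = FALSE)

  times <- data$time
  y <- data$value
  objective <- function(u) {
    x <- to_constrained(u, tr$kind)
    theta <- x[model$par_names]
    f <- tryCatch(model$simulate(theta, times), error = function(e) NULL)
    if (is.null(f) || anyNA(f) || any(!is.finite(f))) return(1e10)
    ll <- eval_loglik(noise_model, y - f, x[setdiff(tr$names, model$par_names)])
    if (!is.null(priors)) ll <- ll + log_prior(priors, x)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  u0 <- to_unconstrained(start, tr$kind)
  jitters <- if (is.null(seed)) {
    matrix(stats::rnorm((restarts - 1) * length(u0), sd = 0.2), ncol = length(u0))
  } else {
    withr::with_seed(as.integer(seed),
                     matrix(stats::rnorm((restarts - 1) * length(u0), sd = 0.2),
                            ncol = length(u0)))
  }
  traces <- vector("list", restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    u_r <- if (r == 1) u0 else u0 + jitters[r - 1, ]
    res <- tryCatch({
      nm <- stats::optim(u_r, objective, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
      bf <- tryCatch(
        stats::optim(nm$par, objective, method = "BFGS",
                     control = list(maxit = 200)),
        error = function(e) nm
      )
      if (bf$value <= nm$value) bf else nm
    }, error = function(e) list(value = Inf, convergence = 99, message = conditionMessage(e)))
    traces[[r]] <- list(restart = r, value = res$value,
                        convergence = res$convergence %||% NA)
    if (is.finite(res$value) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop("All optimisation restarts failed. Traces:\n",
         paste(vapply(traces, function(t) {
           sprintf("  restart %d: value=%g convergence=%s", t$restart, t$value, t$convergence)
         }, ""), collapse = "\n"), call. = FALSE)
  }
  u_hat <- best$par
  hess <- tryCatch(stats::optimHess(u_hat, objective), error = function(e) NULL)
  est <- to_constrained(u_hat, tr$kind)
  names(est) <- tr$names
  structure(
    list(
      mode = "point",
      estimates = est,
      loglik = -best$value - if (!is.null(priors)) log_prior(priors, est) else 0,
      logpost = -best$value,
      model = model, noise_model = noise_model,
      transform = tr, u_hat = u_hat, hessian_u = hess,
      n_obs = length(y), traces = traces, priors = priors,
      data = data
    ),
    class = "odn_fit"
  )
}

# Asymptotic 95% intervals from the observed information at the optimum,
# propagated through the parameter transform.
point_intervals <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tr <- fit$transform
  if (is.null(fit$hessian_u)) {
    se_u <- rep(NA_real_, length(fit$u_hat))
  } else {
    cov_u <- tryCatch(solve(fit$hessian_u), error = function(e) NULL)
    se_u <- if (is.null(cov_u)) rep(NA_real_, length(fit$u_hat)) else {
      d <- diag(cov_u)
      ifelse(d > 0, sqrt(d), NA_real_)
    }
  }
  lower <- to_constrained(fit$u_hat - z * se_u, tr$kind)
  upper <- to_constrained(fit$u_hat + z * se_u, tr$kind)
  # variance on the natural scale via the delta method
  x <- fit$estimates
  deriv <- ifelse(tr$kind == "log", x, ifelse(tr$kind == "atanh", 1 - x^2, 1))
  tibble::tibble(
    term = tr$names,
    estimate = unname(x),
    lower = unname(pmin(lower, upper)),
    upper = unname(pmax(lower, upper)),
    variance = unname((deriv * se_u)^2)
  )
}

#' @export
print.odn_fit <- function(x, ...) {
  cat(sprintf("<odn_fit> %s fit: %s model, %s noise, T = %d\n",
              x$mode, x$model$name, x$noise_model, x$n_obs))
  cat(sprintf("  log-likelihood at estimate: %.3f\n", x$loglik))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Residuals of a fitted deterministic model
#'
#' Step (ii) of the diagnostic workflow:
#' \eqn{\hat\epsilon(t) = x(t) - f(t; \hat\theta)}.
#'
#' @param data Data frame with `time` and `value`.
#' @param model An [new_model()] object (or an `odn_fit`, from which the
#'   model and estimates are taken and `pars` may be omitted).
#' @param pars Named parameter vector \eqn{\hat\theta}.
#' @return A tibble with columns `time` and `residual`.
#' @export
model_residuals <- function(data, model, pars = NULL) {
  if (inherits(model, "odn_fit")) {
    fit <- model
    pars <- pars %||% fit$estimates[fit$model$par_names]
    model <- fit$model
  }
  stopifnot(inherits(model, "odn_model"))
  if (!all(c("time", "value") %in% names(data))) {
    stop("`data` must have `time` and `value` columns.", call. = FALSE)
  }
  pars <- check_pars(model, pars)
  f <- model$simulate(pars, data$time)
  tibble::tibble(time = data$time, residual = data$value - f)
}

#' Sample autocorrelation function
#'
#' Step (iii) of the diagnostic workflow: lag-\eqn{\tau} sample
#' autocorrelations \eqn{\hat\Gamma(\tau)} with the biased (1/T)
#' normalisation, plus \eqn{\pm 1.96/\sqrt{T}} white-noise reference
#' bounds.
#'
#' @param x Numeric series, or a data frame with a `residual` or `value`
#'   column.
#' @param max_lag Largest lag (positive integer, < length of series).
#' @return A tibble of class `odn_acf` with columns `lag`, `acf`, `lower`,
#'   `upper`; `autoplot()` draws the standard ACF plot.
#' @examples
#' sample_acf(simulate_arma(ar1_spec(0.95), 500, seed = 1)$value, max_lag = 10)
#' @export
sample_acf <- function(x, max_lag = 20) {
  if (is.data.frame(x)) {
    col <- intersect(c("residual", "value"), names(x))[1]
    if (is.na(col)) stop("Data frame input needs a `residual` or `value` column.", call. = FALSE)
    x <- x[[col]]
  }
  x <- as.numeric(x)
  T_ <- length(x)
  if (max_lag < 1 || max_lag >= T_) stop("Need 1 <= max_lag < length(x).", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("Constant series: sample autocorrelation is undefined.", call. = FALSE)
  }
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  bound <- 1.96 / sqrt(T_)
  out <- tibble::tibble(
    lag = seq_len(max_lag),
    acf = as.numeric(a$acf)[-1],
    lower = -bound, upper = bound
  )
  attr(out, "n") <- T_
  class(out) <- c("odn_acf", class(out))
  out
}

#' ARMA/ARIMA model-selection grid by AIC
#'
#' Fits ARMA(p, d, q) processes to a residual series for all orders
#' `p <= p_max`, `q <= q_max`, `d` in `d_values` by exact (Kalman-filter)
#' maximum likelihood, and tabulates \eqn{AIC = 2k - 2\log L} with
#' \eqn{k = p + q + 1} (the innovation variance; +1 if a mean is
#' estimated). The exact likelihood is used for every cell so that AICs are
#' comparable across orders. Non-convergent cells are flagged and excluded
#' from the minimum, never silently dropped.
#'
#' @param x Residual series (numeric, or data frame with `residual`/`value`
#'   column).
#' @param p_max,q_max Maximum AR and MA orders (default 3).
#' @param d_values Differencing orders to include (subset of \{0, 1\};
#'   default 0).
#' @param include_mean Estimate a mean for the residual series? Default
#'   `FALSE` (residuals of an ML fit are centred by construction).
#' @return A tibble of class `odn_aic` with columns `p`, `d`, `q`,
#'   `loglik`, `k`, `aic`, `delta_aic_pct` (percent difference to the
#'   minimum AIC) and `converged`.
#' @examples
#' e <- simulate_arma(ar1_spec(0.9), 500, seed = 1)$value
#' arma_grid_aic(e, p_max = 2, q_max = 2)
#' @export
arma_grid_aic <- function(x, p_max = 3, q_max = 3, d_values = 0,
                          include_mean = FALSE) {
  if (is.data.frame(x)) {
    col <- intersect(c("residual", "value"), names(x))[1]
    x <- x[[col]]
  }
  x <- as.numeric(x)
  stopifnot(all(d_values %in% c(0, 1)))
  if (length(x) <= 10 * (p_max + q_max + 1)) {
    stop("Residual series too short for the requested grid.", call. = FALSE)
  }
  grid <- expand.grid(p = 0:p_max, d = d_values, q = 0:q_max)
  rows <- purrr::pmap(grid, function(p, d, q) {
    fit <- tryCatch(
      stats::arima(x, order = c(p, d, q), include.mean = include_mean,
                   method = "ML"),
      error = function(e) NULL, warning = function(w) NULL
    )
    k <- p + q + 1 + as.integer(include_mean)
    if (is.null(fit)) {
      tibble::tibble(p = p, d = d, q = q, loglik = NA_real_, k = k,
                     aic = NA_real_, converged = FALSE)
    } else {
      ll <- as.numeric(stats::logLik(fit))
      tibble::tibble(p = p, d = d, q = q, loglik = ll, k = k,
                     aic = 2 * k - 2 * ll, converged = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  min_aic <- min(out$aic[out$converged], na.rm = TRUE)
  out$delta_aic_pct <- 100 * (out$aic - min_aic) / abs(min_aic)
  out <- dplyr::arrange(out, .data$aic)
  class(out) <- c("odn_aic", class(out))
  out
}

#' Recommend a noise model from an AIC table
#'
#' Picks the most parsimonious (smallest `k`, then lowest AIC) converged
#' model whose AIC lies within `threshold` of the minimum.
#'
#' @param aic_table An [arma_grid_aic()] result.
#' @param threshold AIC tolerance (default 2).
#' @return One-row tibble with the selected `p`, `d`, `q`.
#' @export
recommend_noise_model <- function(aic_table, threshold = 2) {
  ok <- dplyr::filter(aic_table, .data$converged,
                      .data$aic <= min(.data$aic, na.rm = TRUE) + threshold)
  dplyr::slice(dplyr::arrange(ok, .data$k, .data$aic), 1)[, c("p", "d", "q")]
}

#' Residual-autocorrelation diagnostic workflow
#'
#' End-to-end implementation of the four-step workflow: (i) fit the model
#' by maximum likelihood assuming IID Gaussian noise, (ii) extract
#' residuals, (iii) compute their sample ACF against white-noise bounds,
#' and (iv) fit an ARMA grid by AIC and recommend a noise model.
#'
#' @inheritParams fit_point_estimate
#' @param max_lag Largest ACF lag.
#' @param p_max,q_max,d_values Grid bounds, see [arma_grid_aic()].
#' @return A list of class `odn_diagnosis`: `fit`, `residuals`, `acf`,
#'   `aic`, `recommendation`, and `autocorrelated` (TRUE if the lag-1
#'   sample autocorrelation falls outside the white-noise bounds).
#' @examples
#' d <- generate_dataset(study_design(n_obs = 500), rho = 0.9, replicate = 1)
#' diag <- diagnose(d, logistic_model(), p_max = 2, q_max = 2, seed = 1)
#' diag$recommendation
#' @export
diagnose <- function(data, model, max_lag = 20, p_max = 3, q_max = 3,
                     d_values = 0, restarts = 3, seed = NULL) {
  fit <- fit_point_estimate(data, model, "iid", restarts = restarts, seed = seed)
  res <- model_residuals(data, fit)
  acf_tab <- sample_acf(res, max_lag = max_lag)
  aic_tab <- arma_grid_aic(res, p_max = p_max, q_max = q_max, d_values = d_values)
  structure(
    list(
      fit = fit, residuals = res, acf = acf_tab, aic = aic_tab,
      recommendation = recommend_noise_model(aic_tab),
      autocorrelated = abs(acf_tab$acf[1]) > acf_tab$upper[1]
    ),
    class = "odn_diagnosis"
  )
}

#' @export
print.odn_diagnosis <- function(x, ...) {
  rec <- x$recommendation
  cat("<odn_diagnosis>\n")
  cat(sprintf("  lag-1 sample ACF: %.3f (white-noise bound %.3f) -> %s\n",
              x$acf$acf[1], x$acf$upper[1],
              if (x$autocorrelated) "autocorrelated" else "consistent with IID"))
  cat(sprintf("  recommended noise model: ARIMA(%d,%d,%d)\n", rec$p, rec$d, rec$q))
  invisible(x)
}
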