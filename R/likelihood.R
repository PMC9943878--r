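#' Likelihood specification
#'
#' Bundles a noise process with the way its likelihood is evaluated:
#' `"conditional"` fixes the earliest innovations at zero and evaluates the
#' remaining Gaussian terms exactly; `"exact_kalman"` evaluates the full
#' Gaussian likelihood of the residual series through the ARMA state-space
#' representation with stationary initialisation.
#'
#' @param noise A [noise_spec()].
#' @param conditioning `"conditional"` or `"exact_kalman"`.
#' @param conditioned_points For the conditional mode, how many initial
#'   observations are conditioned on (their innovations fixed at zero).
#'   Defaults to `max(p, p + q)` of the noise order, which reproduces the
#'   AR(1) and ARMA(1,1) conventions used throughout.
#' @return An object of class `likelihood_spec`.
#' @export
likelihood_spec <- function(noise, conditioning = c("conditional", "exact_kalman"),
                            conditioned_points = NULL) {
  stopifnot(is_noise_spec(noise))
  conditioning <- match.arg(conditioning)
  ord <- noise_order(noise)
  conditioned_points <- conditioned_points %||% max(ord[["p"]], ord[["p"]] + ord[["q"]])
  if (conditioned_points < 0) stop("`conditioned_points` must be >= 0.", call. = FALSE)
  structure(
    list(noise = noise, conditioning = conditioning,
         conditioned_points = as.integer(conditioned_points)),
    class = "likelihood_spec"
  )
}

check_series_pair <- function(observed, predicted) {
  y <- as_values(observed, "observed")
  f <- as_values(predicted, "predicted")
  if (length(y) != length(f)) {
    stop("`observed` and `predicted` must have equal length.", call. = FALSE)
  }
  if (anyNA(y) || anyNA(f)) stop("Series must not contain missing values.", call. = FALSE)
  list(y = y, f = f, resid = y - f)
}

#' IID Gaussian log-likelihood
#'
#' Sum of independent Gaussian log-densities of the residuals
#' \eqn{\epsilon(t) = y(t) - f(t)}, in nats.
#'
#' @param observed,predicted Numeric vectors (or data frames with a `value`
#'   column) of equal length.
#' @param sigma Noise standard deviation, > 0.
#' @return Log-likelihood (scalar, nats).
#' @examples
#' loglik_iid(0, 0, sigma = 1) # -0.5 * log(2 * pi)
#' @export
loglik_iid <- function(observed, predicted, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a single positive number.", call. = FALSE)
  }
  s <- check_series_pair(observed, predicted)
  sum(stats::dnorm(s$resid, sd = sigma, log = TRUE))
}

#' AR(1) conditional log-likelihood
#'
#' Conditional likelihood of the residual series under AR(1) errors
#' \eqn{\epsilon(t) = \rho\,\epsilon(t-1) + \nu(t)}: the pre-sample error is
#' fixed at zero (so \eqn{\nu(1) = \epsilon(1)}), and
#' \eqn{\nu(t) = \epsilon(t) - \rho\,\epsilon(t-1)} for \eqn{t \ge 2},
#' giving
#' \deqn{L = -\frac{T}{2}\log 2\pi - \frac{T}{2}\log\sigma^2 -
#'   \frac{1}{2\sigma^2}\sum_{t=1}^{T}\nu(t)^2.}
#' At \eqn{\rho = 0} this reduces exactly to [loglik_iid()] with the same
#' number of terms.
#'
#' @inheritParams loglik_iid
#' @param rho AR(1) coefficient, \eqn{|\rho| < 1}.
#' @return Log-likelihood (scalar, nats).
#' @export
loglik_ar1_conditional <- function(observed, predicted, rho, sigma) {
  check_scalar_prob_coef(rho, "rho")
  if (sigma <= 0) stop("`sigma` must be positive.", call. = FALSE)
  s <- check_series_pair(observed, predicted)
  T_ <- length(s$resid)
  if (T_ < 2) stop("AR(1) conditional likelihood needs T >= 2.", call. = FALSE)
  nu <- s$resid - rho * c(0, s$resid[-T_])
  -0.5 * T_ * log(2 * pi) - T_ * log(sigma) - sum(nu^2) / (2 * sigma^2)
}

#' ARMA(1,1) conditional log-likelihood
#'
#' Conditional likelihood under ARMA(1,1) errors
#' \eqn{\epsilon(t) = \rho\,\epsilon(t-1) + \nu(t) + \phi\,\nu(t-1)} with
#' the first two innovations fixed at zero, \eqn{\nu(1) = \nu(2) = 0}:
#' \eqn{\nu(t) = \epsilon(t) - \rho\,\epsilon(t-1) - \phi\,\nu(t-1)} for
#' \eqn{t = 3, \dots, T}, summed into
#' \deqn{L = -\frac{T-2}{2}\log 2\pi - \frac{T-2}{2}\log \sigma^2 -
#'   \frac{1}{2\sigma^2} \sum_{t=3}^{T} \nu(t)^2.}
#'
#' @inheritParams loglik_ar1_conditional
#' @param phi MA(1) coefficient.
#' @return Log-likelihood (scalar, nats).
#' @export
loglik_arma11_conditional <- function(observed, predicted, rho, phi, sigma) {
  check_scalar_prob_coef(rho, "rho")
  check_scalar_prob_coef(phi, "phi", open_unit = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive.", call. = FALSE)
  s <- check_series_pair(observed, predicted)
  T_ <- length(s$resid)
  if (T_ < 3) stop("ARMA(1,1) conditional likelihood needs T >= 3.", call. = FALSE)
  eps <- s$resid
  nu <- numeric(T_)
  for (t in 3:T_) {
    nu[t] <- eps[t] - rho * eps[t - 1] - phi * nu[t - 1]
  }
  n <- T_ - 2
  -0.5 * n * log(2 * pi) - n * log(sigma) - sum(nu[3:T_]^2) / (2 * sigma^2)
}

#' General ARMA(p, q) conditional log-likelihood
#'
#' Generalisation of the conditional approach: the innovations of the first
#' `conditioned_points` observations (default `max(p, p + q)`) are fixed at
#' zero and the remaining \eqn{T - k} innovations are accumulated by the
#' ARMA recursion. At order (1,1) with the default this coincides with
#' [loglik_arma11_conditional()]; note that at order (1,0) it drops the
#' first observation's term, whereas [loglik_ar1_conditional()] keeps all
#' `T` terms (pre-sample-zero convention).
#'
#' @inheritParams loglik_iid
#' @param spec A stationary [noise_spec()].
#' @param conditioned_points Number of initial observations conditioned on.
#' @return Log-likelihood (scalar, nats).
#' @export
loglik_arma_conditional <- function(observed, predicted, spec, conditioned_points = NULL) {
  stopifnot(is_noise_spec(spec))
  s <- check_series_pair(observed, predicted)
  ord <- noise_order(spec)
  p <- ord[["p"]]; q <- ord[["q"]]
  k <- conditioned_points %||% max(p, p + q)
  T_ <- length(s$resid)
  if (T_ <= k) stop("Series too short for the conditioning convention.", call. = FALSE)
  eps <- s$resid
  nu <- numeric(T_)
  for (t in seq.int(k + 1, T_)) {
    ar_part <- if (p > 0) sum(spec$ar * eps[t - seq_len(p)]) else 0
    ma_part <- if (q > 0) sum(spec$ma * nu[t - seq_len(q)]) else 0
    nu[t] <- eps[t] - ar_part - ma_part
  }
  n <- T_ - k
  terms <- if (k == 0) seq_len(T_) else seq.int(k + 1, T_)
  -0.5 * n * log(2 * pi) - n * log(spec$sigma) - sum(nu[terms]^2) / (2 * spec$sigma^2)
}

#' Evaluate a log-likelihood from a likelihood specification
#'
#' Dispatches on the `conditioning` field of a [likelihood_spec()]:
#' the conditional ARMA recursion (with the spec's `conditioned_points`)
#' or the exact state-space likelihood.
#'
#' @inheritParams loglik_iid
#' @param lik A [likelihood_spec()].
#' @return Log-likelihood (scalar, nats).
#' @examples
#' eps <- simulate_arma(ar1_spec(0.5), 100, seed = 1)$value
#' loglik(eps, rep(0, 100), likelihood_spec(ar1_spec(0.5), "exact_kalman"))
#' @export
loglik <- function(observed, predicted, lik) {
  stopifnot(inherits(lik, "likelihood_spec"))
  if (lik$conditioning == "exact_kalman") {
    loglik_arma_kalman(observed, predicted, lik$noise)
  } else if (length(lik$noise$ar) == 0 && length(lik$noise$ma) == 0) {
    loglik_iid(observed, predicted, lik$noise$sigma)
  } else {
    loglik_arma_conditional(observed, predicted, lik$noise,
                            conditioned_points = lik$conditioned_points)
  }
}

#' Exact ARMA log-likelihood via the Kalman filter
#'
#' Evaluates the exact Gaussian log-likelihood of the residual series
#' \eqn{\epsilon(t) = y(t) - f(t)} under the stationary ARMA process in
#' `spec`, using the Harvey state-space representation with state dimension
#' \eqn{m = \max(p, q + 1)} and the stationary solution of the Lyapunov
#' equation as the initial state covariance. For an IID spec this equals
#' [loglik_iid()]; in general it equals the dense multivariate-normal
#' log-density with the ARMA autocovariance matrix.
#'
#' @inheritParams loglik_arma_conditional
#' @return Log-likelihood (scalar, nats).
#' @export
loglik_arma_kalman <- function(observed, predicted, spec) {
  stopifnot(is_noise_spec(spec))
  if (spec$d > 0) {
    stop("Kalman likelihood requires a stationary (d = 0) specification.", call. = FALSE)
  }
  s <- check_series_pair(observed, predicted)
  kalman_loglik(s$resid, spec$ar, spec$ma, spec$sigma)
}

# Harvey ARMA(p,q) state-space: alpha_t = Tm alpha_{t-1} + R nu_t,
# eps_t = alpha_t[1]; stationary initial covariance.
kalman_loglik <- function(eps, ar, ma, sigma) {
  p <- length(ar); q <- length(ma)
  m <- max(p, q + 1L)
  phi <- c(ar, rep(0, m - p))
  Tm <- matrix(0, m, m)
  Tm[, 1] <- phi
  if (m > 1) Tm[seq_len(m - 1), 2:m] <- diag(m - 1)
  R <- c(1, ma, rep(0, m - 1 - q))
  Q <- sigma^2 * tcrossprod(R)
  # stationary covariance: vec(P) = (I - T (x) T)^{-1} vec(Q)
  P <- matrix(solve(diag(m * m) - kronecker(Tm, Tm), as.vector(Q)), m, m)
  P <- (P + t(P)) / 2
  a <- rep(0, m)
  ll <- 0
  for (t in seq_along(eps)) {
    Ft <- P[1, 1]
    v <- eps[t] - a[1]
    ll <- ll - 0.5 * (log(2 * pi) + log(Ft) + v^2 / Ft)
    K <- (Tm %*% P[, 1]) / Ft
    a <- as.vector(Tm %*% a) + as.vector(K) * v
    P <- Tm %*% P %*% t(Tm) + Q - tcrossprod(as.vector(K)) * Ft
    P <- (P + t(P)) / 2
  }
  ll
}

# Dispatch a likelihood evaluation for a named noise model. Used by the
# fitting and MCMC front-ends; `theta_noise` carries sigma and, as needed,
# rho and phi.
eval_loglik <- function(noise_model, resid, theta_noise) {
  switch(
    noise_model,
    iid = {
      T_ <- length(resid)
      -0.5 * T_ * log(2 * pi) - T_ * log(theta_noise[["sigma"]]) -
        sum(resid^2) / (2 * theta_noise[["sigma"]]^2)
    },
    ar1 = {
      T_ <- length(resid)
      e0 <- if ("eps0" %in% names(theta_noise)) theta_noise[["eps0"]] else 0
      nu <- resid - theta_noise[["rho"]] * c(e0, resid[-T_])
      -0.5 * T_ * log(2 * pi) - T_ * log(theta_noise[["sigma"]]) -
        sum(nu^2) / (2 * theta_noise[["sigma"]]^2)
    },
    arma11 = {
      loglik_arma11_conditional(resid, numeric(length(resid)),
                                rho = theta_noise[["rho"]],
                                phi = theta_noise[["phi"]],
                                sigma = theta_noise[["sigma"]])
    },
    arma_kalman = {
      kalman_loglik(resid, ar = theta_noise[["rho"]],
                    ma = if ("phi" %in% names(theta_noise)) theta_noise[["phi"]] else numeric(),
                    sigma = theta_noise[["sigma"]])
    },
    stop("Unknown noise model: ", noise_model, call. = FALSE)
  )
}

noise_par_names <- function(noise_model) {
  switch(noise_model,
         iid = "sigma",
         ar1 = c("sigma", "rho"),
         arma11 = c("sigma", "rho", "phi"),
         arma_kalman = c("sigma", "rho", "phi"),
         stop("Unknown noise model: ", noise_model, call. = FALSE))
}
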