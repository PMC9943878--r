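#' Simulate an ARMA error series
#'
#' Draws a realisation of the process described by `spec` from the recursion
#' \eqn{\epsilon(t) = \sum_i \rho_i \epsilon(t-i) + \nu(t) + \sum_j \phi_j
#' \nu(t-j)} with \eqn{\nu(t) \sim} IID \eqn{N(0, \sigma)}. The recursion is
#' started from zero and the first `burn_in` values are discarded, which
#' removes the initialisation transient so that the retained sample is (to
#' numerical accuracy) a draw from the stationary process. If `spec$d > 0`
#' the stationary draw is cumulatively summed `d` times (integrated).
#'
#' @param spec A stationary [noise_spec()].
#' @param n Number of values to return (positive integer).
#' @param seed Optional integer seed; given the same seed the output is
#'   bit-reproducible and the global RNG state is left untouched.
#' @param burn_in Number of initial values to discard (default 1000).
#' @return A tibble with columns `t` (1..n), `value` (the error series
#'   \eqn{\epsilon(t)}) and `innovation` (the underlying \eqn{\nu(t)}).
#' @examples
#' e <- simulate_arma(ar1_spec(0.95), n = 100, seed = 1)
#' stats::var(simulate_arma(ar1_spec(0.8), n = 1e5, seed = 1)$value)
#' stationary_variance(ar1_spec(0.8))
#' @export
simulate_arma <- function(spec, n, seed = NULL, burn_in = 1000) {
  stopifnot(is_noise_spec(spec))
  n <- as.integer(n)
  if (length(n) != 1 || is.na(n) || n <= 0) stop("`n` must be a positive integer.", call. = FALSE)
  if (burn_in < 0) stop("`burn_in` must be non-negative.", call. = FALSE)
  sim <- sim_arma_impl(spec, n, seed = seed, burn_in = burn_in)
  tibble::tibble(t = seq_len(n), value = sim$value, innovation = sim$innovation)
}

# Internal vector version used throughout the package (fit oracles, studies).
sim_arma_vec <- function(spec, n, seed = NULL, burn_in = 1000) {
  sim_arma_impl(spec, n, seed = seed, burn_in = burn_in)$value
}

sim_arma_impl <- function(spec, n, seed = NULL, burn_in = 1000) {
  total <- n + as.integer(burn_in)
  nu <- if (is.null(seed)) {
    stats::rnorm(total, sd = spec$sigma)
  } else {
    withr::with_seed(as.integer(seed), stats::rnorm(total, sd = spec$sigma))
  }
  x <- nu
  if (length(spec$ma) > 0) {
    x <- as.numeric(stats::filter(nu, c(1, spec$ma), method = "convolution", sides = 1))
    # convolution filter leaves leading NAs where lagged nu are unavailable;
    # the recursion starts from zero innovations
    for (k in seq_along(spec$ma)) {
      x[k] <- nu[k] + sum(spec$ma[seq_len(k - 1)] * rev(nu[seq_len(k - 1)]))
    }
    x[1] <- nu[1]
  }
  if (length(spec$ar) > 0) {
    x <- as.numeric(stats::filter(x, spec$ar, method = "recursive"))
  }
  keep <- seq.int(burn_in + 1L, total)
  value <- x[keep]
  if (spec$d > 0) {
    for (i in seq_len(spec$d)) value <- cumsum(value)
  }
  list(value = value, innovation = nu[keep])
}

#' Theoretical autocorrelation function of an ARMA process
#'
#' Returns \eqn{\Gamma(\tau)} for lags 1..`max_lag`. The AR(1) process has
#' \eqn{\Gamma(\tau) = \rho^\tau}; the MA(1) process has
#' \eqn{\Gamma(1) = \phi / (1 + \phi^2)} and zero beyond lag 1; the general
#' ARMA case is computed by the standard recursion ([stats::ARMAacf()]).
#'
#' @param spec A stationary [noise_spec()] with `d = 0`.
#' @param max_lag Largest lag (positive integer).
#' @param method `"auto"` uses the closed forms for pure AR(1)/MA(1) and the
#'   general recursion otherwise; `"recursion"` forces the general path
#'   (the two agree to ~1e-15, which the test-suite asserts).
#' @return A tibble with columns `lag` (1..max_lag) and `acf`.
#' @examples
#' theoretical_acf(ar1_spec(0.5), max_lag = 3)
#' @export
theoretical_acf <- function(spec, max_lag, method = c("auto", "recursion")) {
  stopifnot(is_noise_spec(spec))
  method <- match.arg(method)
  if (spec$d > 0) {
    stop("Theoretical ACF is undefined for differenced (d > 0) processes.", call. = FALSE)
  }
  max_lag <- as.integer(max_lag)
  if (max_lag < 1) stop("`max_lag` must be a positive integer.", call. = FALSE)
  ord <- noise_order(spec)
  acf <- if (method == "auto" && ord[["p"]] == 1 && ord[["q"]] == 0) {
    spec$ar^seq_len(max_lag)
  } else if (method == "auto" && ord[["p"]] == 0 && ord[["q"]] == 1) {
    c(spec$ma / (1 + spec$ma^2), rep(0, max_lag - 1))[seq_len(max_lag)]
  } else if (ord[["p"]] == 0 && ord[["q"]] == 0) {
    rep(0, max_lag)
  } else {
    out <- stats::ARMAacf(ar = spec$ar, ma = spec$ma, lag.max = max_lag)
    unname(out[-1])
  }
  tibble::tibble(lag = seq_len(max_lag), acf = acf)
}

#' Stationary variance of an ARMA process
#'
#' Closed forms are used for the IID, AR(1), MA(1) and ARMA(1,1) cases:
#' \eqn{\sigma^2}, \eqn{\sigma^2 / (1-\rho^2)}, \eqn{\sigma^2 (1+\phi^2)}
#' and \eqn{\sigma^2 (1+\phi^2+2\phi\rho)/(1-\rho^2)} respectively. The
#' general case is computed numerically from the truncated MA(\eqn{\infty})
#' weights.
#'
#' @param spec A stationary [noise_spec()] with `d = 0`.
#' @param n_terms Truncation length for the general (numeric) path.
#' @return The variance of \eqn{\epsilon(t)} (squared observable units).
#' @examples
#' stationary_variance(ar1_spec(0.8)) # 1 / (1 - 0.64)
#' @export
stationary_variance <- function(spec, n_terms = 10000) {
  stopifnot(is_noise_spec(spec))
  if (spec$d > 0) {
    stop("Stationary variance is undefined for differenced (d > 0) processes.", call. = FALSE)
  }
  ord <- noise_order(spec)
  p <- ord[["p"]]; q <- ord[["q"]]
  s2 <- spec$sigma^2
  if (p == 0 && q == 0) return(s2)
  if (p == 1 && q == 0) return(s2 / (1 - spec$ar^2))
  if (p == 0 && q == 1) return(s2 * (1 + spec$ma^2))
  if (p == 1 && q == 1) {
    return(s2 * (1 + spec$ma^2 + 2 * spec$ma * spec$ar) / (1 - spec$ar^2))
  }
  psi <- stats::ARMAtoMA(ar = spec$ar, ma = spec$ma, lag.max = n_terms)
  s2 * (1 + sum(psi^2))
}

#' Koyck moving-average weights of an AR(1) process
#'
#' The Koyck transformation rewrites a stationary AR(1) process as an
#' MA(\eqn{\infty}) process with geometric weights
#' \eqn{(1, \rho, \rho^2, \dots)}: convolving IID innovations with these
#' weights reproduces the AR(1) autocorrelation function up to truncation
#' error.
#'
#' @param rho AR(1) coefficient with \eqn{|\rho| < 1}.
#' @param n_terms Number of weights to return (positive integer).
#' @return Numeric vector \eqn{(\rho^0, \dots, \rho^{n\_terms - 1})}.
#' @examples
#' koyck_ma_weights(0.5, 4)
#' @export
koyck_ma_weights <- function(rho, n_terms) {
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || abs(rho) >= 1) {
    stop("`rho` must satisfy |rho| < 1.", call. = FALSE)
  }
  n_terms <- as.integer(n_terms)
  if (n_terms < 1) stop("`n_terms` must be a positive integer.", call. = FALSE)
  rho^(seq_len(n_terms) - 1)
}
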