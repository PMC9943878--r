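#' Specify an ARMA(p, q) measurement-noise process
#'
#' A `noise_spec` describes the stochastic process assumed for the
#' measurement errors \eqn{\epsilon(t)} around a deterministic model
#' trajectory,
#' \deqn{\epsilon(t) = \rho_1 \epsilon(t-1) + \dots + \rho_p \epsilon(t-p)
#'   + \nu(t) + \phi_1 \nu(t-1) + \dots + \phi_q \nu(t-q),}
#' with IID Gaussian innovations \eqn{\nu(t) \sim N(0, \sigma)}.
#' `p = q = 0` denotes IID Gaussian noise.
#'
#' Autocorrelation parameters are defined *per sampling interval*: the index
#' `t` counts samples, not absolute time. Resampling a series onto a coarser
#' or finer grid changes the effective `ar`/`ma` coefficients.
#'
#' @param ar Numeric vector of autoregressive coefficients
#'   \eqn{\rho_1, \dots, \rho_p}. The AR lag polynomial
#'   \eqn{\Psi_p(L) = 1 - \rho_1 L - \dots - \rho_p L^p} must have all roots
#'   outside the unit circle (stationarity); for `p = 1` this is
#'   \eqn{|\rho_1| < 1}.
#' @param ma Numeric vector of moving-average coefficients
#'   \eqn{\phi_1, \dots, \phi_q}.
#' @param sigma Innovation standard deviation \eqn{\sigma > 0}, in the units
#'   of the observable.
#' @param d Non-negative integer differencing order (0 = ARMA, 1 = ARIMA
#'   with one round of differencing).
#'
#' @return An object of class `noise_spec`.
#' @seealso [ar1_spec()], [ma1_spec()], [arma11_spec()], [iid_spec()],
#'   [simulate_arma()], [stationary_variance()], [theoretical_acf()]
#' @examples
#' noise_spec(ar = 0.8, sigma = 1)
#' noise_spec(ar = 0.5, ma = 0.5, sigma = 2)
#' @export
noise_spec <- function(ar = numeric(), ma = numeric(), sigma = 1, d = 0L) {
  ar <- as.numeric(ar)
  ma <- as.numeric(ma)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive finite number.", call. = FALSE)
  }
  if (anyNA(ar) || any(!is.finite(ar))) stop("`ar` coefficients must be finite.", call. = FALSE)
  if (anyNA(ma) || any(!is.finite(ma))) stop("`ma` coefficients must be finite.", call. = FALSE)
  d <- as.integer(d)
  if (length(d) != 1 || is.na(d) || d < 0) stop("`d` must be a non-negative integer.", call. = FALSE)
  check_stationary(ar)
  structure(
    list(ar = ar, ma = ma, sigma = sigma, d = d),
    class = "noise_spec"
  )
}

# Stationarity: all roots of 1 - ar_1 z - ... - ar_p z^p strictly outside
# the unit circle (modulus > 1 + 1e-9).
check_stationary <- function(ar) {
  if (length(ar) == 0) return(invisible(TRUE))
  roots <- polyroot(c(1, -ar))
  if (any(Mod(roots) <= 1 + 1e-9)) {
    stop(
      "Non-stationary AR polynomial: all roots of 1 - ar_1 z - ... - ar_p z^p ",
      "must lie outside the unit circle.",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Convenience constructors for common noise processes
#'
#' @param rho AR(1) coefficient, \eqn{|\rho| < 1}.
#' @param phi MA(1) coefficient.
#' @param sigma Innovation standard deviation.
#' @return A [noise_spec()].
#' @name noise_shortcuts
NULL

#' @rdname noise_shortcuts
#' @export
iid_spec <- function(sigma = 1) noise_spec(sigma = sigma)

#' @rdname noise_shortcuts
#' @export
ar1_spec <- function(rho, sigma = 1) noise_spec(ar = rho, sigma = sigma)

#' @rdname noise_shortcuts
#' @export
ma1_spec <- function(phi, sigma = 1) noise_spec(ma = phi, sigma = sigma)

#' @rdname noise_shortcuts
#' @export
arma11_spec <- function(rho, phi, sigma = 1) noise_spec(ar = rho, ma = phi, sigma = sigma)

#' @export
print.noise_spec <- function(x, ...) {
  p <- length(x$ar); q <- length(x$ma)
  if (x$d > 0) {
    cat(sprintf("<noise_spec> ARIMA(%d,%d,%d), sigma = %g\n", p, x$d, q, x$sigma))
  } else if (p == 0 && q == 0) {
    cat(sprintf("<noise_spec> IID Gaussian, sigma = %g\n", x$sigma))
  } else {
    cat(sprintf("<noise_spec> ARMA(%d,%d), sigma = %g\n", p, q, x$sigma))
  }
  if (p > 0) cat("  ar:", paste(signif(x$ar, 6), collapse = ", "), "\n")
  if (q > 0) cat("  ma:", paste(signif(x$ma, 6), collapse = ", "), "\n")
  invisible(x)
}

is_noise_spec <- function(x) inherits(x, "noise_spec")

noise_order <- function(spec) c(p = length(spec$ar), q = length(spec$ma))

#' Serialize a noise specification to JSON
#'
#' Uses the schema `{"ar": [...], "ma": [...], "sigma": ..., "d": 0}`.
#'
#' @param spec A [noise_spec()].
#' @param json A JSON string (or path to a JSON file) in the above schema.
#' @return `noise_spec_to_json()` returns a JSON string;
#'   `noise_spec_from_json()` returns a [noise_spec()].
#' @examples
#' noise_spec_from_json(noise_spec_to_json(ar1_spec(0.8)))
#' @export
noise_spec_to_json <- function(spec) {
  stopifnot(is_noise_spec(spec))
  jsonlite::toJSON(
    list(ar = spec$ar, ma = spec$ma, sigma = spec$sigma, d = spec$d),
    auto_unbox = FALSE, digits = NA
  )
}

#' @rdname noise_spec_to_json
#' @export
noise_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  unknown <- setdiff(names(x), c("ar", "ma", "sigma", "d"))
  if (length(unknown) > 0) {
    stop("Unknown noise_spec fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  noise_spec(
    ar = x$ar %||% numeric(),
    ma = x$ma %||% numeric(),
    sigma = x$sigma %||% 1,
    d = x$d %||% 0L
  )
}
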