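#' Deterministic model objects
#'
#' An `odn_model` bundles a named deterministic mean function
#' \eqn{f(t; \theta)} with everything inference needs: the parameter names,
#' positivity constraints (used to pick sampling/optimisation transforms),
#' and, where the mean is an ODE solution, the right-hand side
#' \eqn{h(t, x, \theta)} and its partial derivatives for forward
#' sensitivity analysis.
#'
#' @param name Model identifier.
#' @param par_names Character vector of unique parameter names.
#' @param simulate `function(pars, times)` returning the observable
#'   \eqn{f(t;\theta)} at each time.
#' @param positive Logical vector (recycled) marking strictly positive
#'   parameters; these are optimised/sampled on the log scale.
#' @param rhs Optional `function(t, x, pars)` giving \eqn{dx/dt}.
#' @param jac_state Optional `function(t, x, pars)` returning
#'   \eqn{\partial h / \partial x} (matrix).
#' @param jac_pars Optional `function(t, x, pars)` returning
#'   \eqn{\partial h / \partial \theta} (state-dim x n-par matrix).
#' @param x0_fn Optional `function(pars)` returning the initial state; the
#'   special parameter name `"x0"` is understood to set the initial state
#'   directly.
#' @param t0 Time at which the initial state is defined (default 0).
#' @param init `function(data)` returning heuristic starting values for
#'   optimisation from a `(time, value)` data frame.
#' @param output Function mapping the state vector to the scalar observable
#'   (default: first state).
#'
#' @return An object of class `odn_model`.
#' @seealso [constant_model()], [logistic_model()], [herg_model()]
#' @export
new_model <- function(name, par_names, simulate, positive = TRUE,
                      rhs = NULL, jac_state = NULL, jac_pars = NULL,
                      x0_fn = NULL, t0 = 0, init = NULL,
                      output = function(x) x[1]) {
  stopifnot(is.character(name), is.character(par_names), is.function(simulate))
  if (anyDuplicated(par_names)) stop("Parameter names must be unique.", call. = FALSE)
  positive <- rep_len(as.logical(positive), length(par_names))
  names(positive) <- par_names
  structure(
    list(
      name = name, par_names = par_names, simulate = simulate,
      positive = positive, rhs = rhs, jac_state = jac_state,
      jac_pars = jac_pars, x0_fn = x0_fn, t0 = t0, init = init,
      output = output
    ),
    class = "odn_model"
  )
}

#' @export
print.odn_model <- function(x, ...) {
  cat(sprintf("<odn_model> %s\n  parameters: %s\n", x$name,
              paste(x$par_names, collapse = ", ")))
  invisible(x)
}

check_pars <- function(model, pars) {
  pars <- pars[model$par_names]
  if (anyNA(names(pars)) || anyNA(pars)) {
    stop("`pars` must be a named vector covering: ",
         paste(model$par_names, collapse = ", "), call. = FALSE)
  }
  bad <- model$positive & pars <= 0
  if (any(bad)) {
    stop("Parameters must be strictly positive: ",
         paste(names(pars)[bad], collapse = ", "), call. = FALSE)
  }
  pars
}

#' Constant-mean model
#'
#' The simplest observation model, \eqn{x(t) = \mu + \epsilon(t)}: the
#' observable equals an unknown constant \eqn{\mu} plus noise. Its
#' sensitivity \eqn{\partial f / \partial \mu} is identically 1, which makes
#' it the reference case for which the closed-form variance inflation ratios
#' hold exactly.
#'
#' @return An `odn_model` with the single (unbounded) parameter `mu`.
#' @export
constant_model <- function() {
  new_model(
    name = "constant",
    par_names = "mu",
    simulate = function(pars, times) rep(unname(pars[["mu"]]), length(times)),
    positive = FALSE,
    init = function(data) c(mu = mean(data$value))
  )
}

#' Logistic growth model
#'
#' Resource-limited growth \eqn{dx/dt = r x (1 - x/\kappa)} with growth rate
#' `r` (1/time), carrying capacity `kappa` (observable units) and initial
#' value `x0 = x(0)`, all strictly positive. The closed-form solution
#' \deqn{x(t) = \kappa / (1 + ((\kappa - x_0)/x_0) e^{-r t})}
#' is used as the mean function; [solve_logistic()] additionally offers a
#' numeric integration path for cross-checking.
#'
#' @return An `odn_model` with parameters `r`, `kappa`, `x0`.
#' @export
logistic_model <- function() {
  new_model(
    name = "logistic",
    par_names = c("r", "kappa", "x0"),
    simulate = function(pars, times) {
      logistic_solution(times, pars[["r"]], pars[["kappa"]], pars[["x0"]])
    },
    positive = TRUE,
    rhs = function(t, x, pars) pars[["r"]] * x * (1 - x / pars[["kappa"]]),
    jac_state = function(t, x, pars) {
      matrix(pars[["r"]] * (1 - 2 * x / pars[["kappa"]]), 1, 1)
    },
    jac_pars = function(t, x, pars) {
      matrix(
        c(x * (1 - x / pars[["kappa"]]),
          pars[["r"]] * x^2 / pars[["kappa"]]^2,
          0),
        nrow = 1, dimnames = list(NULL, c("r", "kappa", "x0"))
      )
    },
    x0_fn = function(pars) unname(pars[["x0"]]),
    init = function(data) {
      kappa0 <- max(data$value)
      x00 <- max(min(data$value[data$time <= stats::quantile(data$time, 0.05)]),
                 kappa0 / 1000)
      t_mid <- data$time[which.min(abs(data$value - kappa0 / 2))]
      r0 <- log(max(kappa0 / x00, 1.5)) / max(t_mid - min(data$time), 1e-3)
      c(r = r0, kappa = kappa0, x0 = x00)
    }
  )
}

# Closed-form logistic solution, written to stay finite for large r*t.
logistic_solution <- function(times, r, kappa, x0) {
  kappa / (1 + ((kappa - x0) / x0) * exp(-r * times))
}

#' Solve the logistic ODE
#'
#' @param pars Named vector with `r`, `kappa`, `x0` (all > 0).
#' @param times Strictly increasing time points (the solution is reported
#'   at these times; integration starts at t = 0).
#' @param method `"analytic"` (closed form, exact) or `"numeric"`
#'   (adaptive Runge-Kutta via [deSolve::ode()]).
#' @param rtol,atol Numeric solver tolerances (numeric path only).
#' @return A tibble with columns `time` and `value`.
#' @examples
#' solve_logistic(c(r = 0.5, kappa = 50, x0 = 1), seq(0, 20, length.out = 5))
#' @export
solve_logistic <- function(pars, times, method = c("analytic", "numeric"),
                           rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  model <- logistic_model()
  pars <- check_pars(model, pars)
  check_times(times)
  value <- if (method == "analytic") {
    logistic_solution(times, pars[["r"]], pars[["kappa"]], pars[["x0"]])
  } else {
    solve_model_ode(model, pars, times, rtol = rtol, atol = atol)
  }
  tibble::tibble(time = times, value = value)
}

check_times <- function(times) {
  if (length(times) < 1 || anyNA(times) || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with no missing values.", call. = FALSE)
  }
  invisible(times)
}

# Integrate model$rhs from model$t0 with deSolve and return the observable
# at `times`. Adds t0 to the grid if needed.
solve_model_ode <- function(model, pars, times, rtol = 1e-8, atol = 1e-10) {
  if (is.null(model$rhs)) stop("Model has no ODE right-hand side.", call. = FALSE)
  x0 <- model$x0_fn(pars)
  grid <- times
  prepend <- times[1] > model$t0
  if (prepend) grid <- c(model$t0, times)
  sol <- deSolve::ode(
    y = x0, times = grid,
    func = function(t, x, p) list(model$rhs(t, x, pars)),
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol
  )
  vals <- apply(sol[, -1, drop = FALSE], 1, model$output)
  if (prepend) vals <- vals[-1]
  vals
}

#' Parameter sensitivities of a model trajectory
#'
#' Computes \eqn{\partial f / \partial \theta_j} at each time point, either
#' by integrating the augmented forward-sensitivity ODE
#' \eqn{dS_j/dt = (\partial h/\partial x) S_j + \partial h/\partial \theta_j}
#' alongside the state (`"forward_ode"`), or by central finite differences
#' on the solution (`"finite_difference"`, step `rel_step * |theta_j|`).
#' The two paths agree for smooth models and are cross-checked in the test
#' suite; models without an ODE right-hand side (e.g. the constant-mean
#' model) fall back to finite differences.
#'
#' @param model An [new_model()] object.
#' @param pars Named parameter vector.
#' @param times Strictly increasing time points.
#' @param method `"forward_ode"` or `"finite_difference"`.
#' @param parameters Subset of parameter names (default: all).
#' @param rel_step Relative finite-difference step.
#' @param rtol,atol ODE solver tolerances.
#' @return A tibble with a `time` column and one column of
#'   \eqn{\partial f/\partial \theta_j} per parameter.
#' @examples
#' sensitivities(logistic_model(), c(r = 0.5, kappa = 50, x0 = 1),
#'               seq(0, 20, length.out = 9))
#' @export
sensitivities <- function(model, pars, times,
                          method = c("forward_ode", "finite_difference"),
                          parameters = NULL, rel_step = 1e-6,
                          rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  pars <- check_pars(model, pars)
  check_times(times)
  parameters <- parameters %||% model$par_names
  stopifnot(all(parameters %in% model$par_names))
  if (method == "forward_ode" && is.null(model$rhs)) method <- "finite_difference"
  S <- if (method == "forward_ode") {
    forward_sensitivities(model, pars, times, parameters, rtol, atol)
  } else {
    fd_sensitivities(model, pars, times, parameters, rel_step)
  }
  out <- tibble::as_tibble(as.data.frame(S))
  names(out) <- parameters
  dplyr::bind_cols(tibble::tibble(time = times), out)
}

fd_sensitivities <- function(model, pars, times, parameters, rel_step) {
  S <- matrix(NA_real_, length(times), length(parameters))
  for (j in seq_along(parameters)) {
    pj <- parameters[j]
    h <- rel_step * max(abs(pars[[pj]]), 1e-8)
    up <- pars; up[[pj]] <- pars[[pj]] + h
    dn <- pars; dn[[pj]] <- pars[[pj]] - h
    S[, j] <- (model$simulate(up, times) - model$simulate(dn, times)) / (2 * h)
  }
  S
}

# Augmented forward-sensitivity system for a scalar-state model (the models
# shipped here are univariate; the hERG model exposes its own solver).
forward_sensitivities <- function(model, pars, times, parameters, rtol, atol) {
  np <- length(parameters)
  x0 <- model$x0_fn(pars)
  s0 <- as.numeric(parameters == "x0")
  grid <- times
  prepend <- times[1] > model$t0
  if (prepend) grid <- c(model$t0, times)
  aug <- function(t, y, p) {
    x <- y[1]
    Jx <- model$jac_state(t, x, pars)[1, 1]
    Jp <- model$jac_pars(t, x, pars)[1, parameters, drop = TRUE]
    list(c(model$rhs(t, x, pars), Jx * y[-1] + Jp))
  }
  sol <- deSolve::ode(
    y = c(x0, s0), times = grid, func = aug, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  )
  S <- sol[, -(1:2), drop = FALSE]
  if (prepend) S <- S[-1, , drop = FALSE]
  unname(S)
}
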