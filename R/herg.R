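#' Piecewise-constant voltage-clamp protocol
#'
#' Patch-clamp stimuli are represented as an ordered list of
#' (duration, holding voltage) segments; the command voltage is constant
#' within each segment.
#'
#' @param duration_ms Segment durations in milliseconds (strictly positive).
#' @param voltage_mV Holding voltages in millivolts.
#' @return A tibble of class `odn_protocol` with columns `duration_ms`,
#'   `voltage_mV`.
#' @seealso [staircase_protocol()], [read_protocol_csv()]
#' @export
voltage_protocol <- function(duration_ms, voltage_mV) {
  duration_ms <- as.numeric(duration_ms)
  voltage_mV <- as.numeric(voltage_mV)
  if (length(duration_ms) != length(voltage_mV) || length(duration_ms) == 0) {
    stop("`duration_ms` and `voltage_mV` must be equal-length, non-empty.", call. = FALSE)
  }
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0)) {
    stop("Segment durations must be strictly positive.", call. = FALSE)
  }
  out <- tibble::tibble(duration_ms = duration_ms, voltage_mV = voltage_mV)
  class(out) <- c("odn_protocol", class(out))
  out
}

#' Synthetic staircase voltage protocol
#'
#' A simple staircase-like stimulus for demonstrations and tests: a holding
#' period, an activating step, then descending 20 mV steps. This is a
#' *synthetic* stand-in — the published staircase protocol has no simple
#' closed form and is not reproduced here; real protocols can be loaded
#' with [read_protocol_csv()].
#'
#' @return A [voltage_protocol()].
#' @export
staircase_protocol <- function() {
  steps <- seq(40, -120, by = -20)
  voltage_protocol(
    duration_ms = c(250, 1000, rep(500, length(steps)), 250),
    voltage_mV = c(-80, 40, steps, -80)
  )
}

#' Read / write voltage protocols as CSV
#'
#' CSV schema: columns `duration_ms`, `voltage_mV`.
#'
#' @param path File path.
#' @param protocol A [voltage_protocol()].
#' @return `read_protocol_csv()` returns a [voltage_protocol()];
#'   `write_protocol_csv()` returns `path` invisibly.
#' @export
read_protocol_csv <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    duration_ms = readr::col_double(), voltage_mV = readr::col_double()
  ))
  voltage_protocol(x$duration_ms, x$voltage_mV)
}

#' @rdname read_protocol_csv
#' @export
write_protocol_csv <- function(protocol, path) {
  readr::write_csv(protocol, path)
  invisible(path)
}

#' Illustrative hERG channel parameters (synthetic)
#'
#' A round-number parameter set of realistic magnitudes for the
#' Hodgkin-Huxley hERG current model, shipped so that examples and tests
#' run self-contained. These are synthetic illustrative values, *not* the
#' parameters fitted to published patch-clamp data. Units: `g_kr` in
#' microsiemens, `e_k` in mV, `p1, p3, p5, p7` in 1/ms, `p2, p4, p6, p8`
#' in 1/mV.
#'
#' @return Named numeric vector with `g_kr`, `e_k`, `p1`..`p8`.
#' @export
herg_parameters <- function() {
  c(g_kr = 0.15, e_k = -85,
    p1 = 2e-4, p2 = 0.07, p3 = 4e-5, p4 = 0.05,
    p5 = 0.09, p6 = 9e-3, p7 = 5e-3, p8 = 0.03)
}

#' hERG (rapid delayed rectifier) current model
#'
#' Hodgkin-Huxley style model of the hERG channel current
#' \deqn{I_{Kr}(t) = g_{Kr} \, a(t) \, r(t) \, (V(t) - E_K),}
#' with activation gate `a` and recovery-from-inactivation gate `r`
#' relaxing to voltage-dependent steady states:
#' \deqn{da/dt = (a_\infty - a)/\tau_a, \quad dr/dt = (r_\infty - r)/\tau_r,}
#' where \eqn{a_\infty = k_1/(k_1+k_2)}, \eqn{\tau_a = 1/(k_1+k_2)},
#' \eqn{r_\infty = k_4/(k_3+k_4)}, \eqn{\tau_r = 1/(k_3+k_4)} and the rates
#' are \eqn{k_1 = p_1 e^{p_2 V}}, \eqn{k_2 = p_3 e^{-p_4 V}},
#' \eqn{k_3 = p_5 e^{p_6 V}}, \eqn{k_4 = p_7 e^{-p_8 V}}. Time is in
#' milliseconds and voltage in millivolts (configurable only through the
#' units of the rate parameters themselves).
#'
#' @param protocol A [voltage_protocol()] driving \eqn{V(t)}.
#' @return An `odn_model` whose `simulate(pars, times)` returns
#'   \eqn{I_{Kr}} at the requested times (ms since protocol start).
#' @export
herg_model <- function(protocol = staircase_protocol()) {
  model <- new_model(
    name = "herg",
    par_names = names(herg_parameters()),
    simulate = function(pars, times) {
      solve_herg(pars, protocol, times)$value
    },
    # e_k is a (possibly negative) reversal potential; all others positive
    positive = c(TRUE, FALSE, rep(TRUE, 8))
  )
  model$protocol <- protocol
  model
}

herg_rates <- function(pars, V) {
  k1 <- pars[["p1"]] * exp(pars[["p2"]] * V)
  k2 <- pars[["p3"]] * exp(-pars[["p4"]] * V)
  k3 <- pars[["p5"]] * exp(pars[["p6"]] * V)
  k4 <- pars[["p7"]] * exp(-pars[["p8"]] * V)
  list(
    a_inf = k1 / (k1 + k2), tau_a = 1 / (k1 + k2),
    r_inf = k4 / (k3 + k4), tau_r = 1 / (k3 + k4)
  )
}

check_herg_pars <- function(pars) {
  pars <- pars[names(herg_parameters())]
  if (anyNA(pars)) {
    stop("hERG parameters must include: ", paste(names(herg_parameters()), collapse = ", "),
         call. = FALSE)
  }
  pos <- setdiff(names(pars), "e_k")
  if (any(pars[pos] <= 0)) {
    stop("hERG conductance and kinetic parameters must be strictly positive.", call. = FALSE)
  }
  pars
}

#' Solve the hERG current model under a voltage protocol
#'
#' Initial gate values are `a(0) = 0`, `r(0) = 1`; before the protocol
#' starts the cell is pre-paced (equilibrated) at a holding potential for
#' `pre_pace_ms` milliseconds. Because the command voltage is constant
#' within each protocol segment, the gating ODEs are linear with constant
#' coefficients and are solved exactly segment-by-segment
#' (`method = "analytic"`); `method = "numeric"` integrates the same system
#' with an adaptive Runge-Kutta solver as a cross-check.
#'
#' @param pars Named parameter vector, see [herg_parameters()].
#' @param protocol A [voltage_protocol()].
#' @param times Strictly increasing observation times in ms (0 = protocol
#'   start); defaults to a 1 ms grid over the protocol.
#' @param pre_pace_ms Pre-pacing duration in ms (default 1e5, i.e. 100 s).
#' @param pre_pace_voltage Pre-pacing holding potential in mV (default -80).
#' @param method `"analytic"` (exact) or `"numeric"` (deSolve RK45,
#'   rtol 1e-8 / atol 1e-10).
#' @return A tibble with columns `time`, `value` (current, same units as
#'   `g_kr * mV`), `a`, `r`, `voltage`.
#' @examples
#' tr <- solve_herg(herg_parameters(), staircase_protocol(),
#'                  times = seq(0, 500, by = 5))
#' range(tr$a); range(tr$r)
#' @export
solve_herg <- function(pars, protocol, times = NULL, pre_pace_ms = 1e5,
                       pre_pace_voltage = -80,
                       method = c("analytic", "numeric")) {
  method <- match.arg(method)
  pars <- check_herg_pars(pars)
  stopifnot(inherits(protocol, "odn_protocol"))
  total <- sum(protocol$duration_ms)
  if (is.null(times)) times <- seq(0, total, by = 1)
  check_times(times)
  if (times[1] < 0 || times[length(times)] > total + 1e-9) {
    stop("`times` must lie within the protocol duration [0, ", total, "] ms.", call. = FALSE)
  }

  gates <- c(a = 0, r = 1)
  if (pre_pace_ms > 0) {
    gates <- step_gates(pars, gates, pre_pace_voltage, pre_pace_ms, method)
  }

  seg_start <- cumsum(c(0, protocol$duration_ms))
  a_out <- r_out <- v_out <- numeric(length(times))
  for (s in seq_len(nrow(protocol))) {
    t0 <- seg_start[s]; t1 <- seg_start[s + 1]
    V <- protocol$voltage_mV[s]
    in_seg <- which(times >= t0 - 1e-9 & (times < t1 - 1e-9 | s == nrow(protocol)))
    if (length(in_seg) > 0) {
      local_t <- times[in_seg] - t0
      gr <- gates_at(pars, gates, V, local_t, method)
      a_out[in_seg] <- gr$a; r_out[in_seg] <- gr$r
      v_out[in_seg] <- V
    }
    gates <- step_gates(pars, gates, V, protocol$duration_ms[s], method)
  }
  value <- pars[["g_kr"]] * a_out * r_out * (v_out - pars[["e_k"]])
  tibble::tibble(time = times, value = value, a = a_out, r = r_out, voltage = v_out)
}

# Gate values after holding at constant V for `dt` ms.
step_gates <- function(pars, gates, V, dt, method) {
  g <- gates_at(pars, gates, V, dt, method)
  c(a = unname(g$a[length(g$a)]), r = unname(g$r[length(g$r)]))
}

# Gate trajectories at local times under constant V. Exact exponential
# relaxation, or deSolve integration for the numeric cross-check path.
gates_at <- function(pars, gates, V, local_t, method) {
  rt <- herg_rates(pars, V)
  if (method == "analytic") {
    list(
      a = rt$a_inf + (gates[["a"]] - rt$a_inf) * exp(-local_t / rt$tau_a),
      r = rt$r_inf + (gates[["r"]] - rt$r_inf) * exp(-local_t / rt$tau_r)
    )
  } else {
    grid <- local_t
    prepend <- grid[1] > 0
    if (prepend) grid <- c(0, grid)
    sol <- deSolve::ode(
      y = c(a = gates[["a"]], r = gates[["r"]]), times = grid,
      func = function(t, y, p) {
        list(c((rt$a_inf - y[1]) / rt$tau_a, (rt$r_inf - y[2]) / rt$tau_r))
      },
      parms = NULL, method = "ode45", rtol = 1e-8, atol = 1e-10
    )
    if (prepend) sol <- sol[-1, , drop = FALSE]
    list(a = unname(sol[, "a"]), r = unname(sol[, "r"]))
  }
}
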