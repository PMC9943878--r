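#' Design of the logistic-growth simulation study
#'
#' Defines the synthetic study that quantifies the cost of falsely
#' assuming IID noise: logistic trajectories (r = 0.5, kappa = 50,
#' x(0) = 1) observed at `n_obs` equally spaced times on `t_span`, with
#' AR(1) measurement noise at innovation scale `sigma` for each value on
#' the `rho` grid, replicated `n_replicates` times. The defaults — five
#' \eqn{\rho} values spanning 0.8 to 0.975, 10 replicates, 2000
#' observations on \[0, 20\], \eqn{\sigma = 1} — are the package's
#' reference study conditions.
#'
#' @param rho Grid of AR(1) coefficients.
#' @param n_replicates Replicate datasets per rho.
#' @param n_obs Observations per dataset.
#' @param t_span Length-2 numeric, time range of the observation grid.
#' @param pars Named generating parameters of the logistic model.
#' @param sigma Innovation standard deviation of the AR(1) noise.
#' @param seed Master seed; every dataset / fit seed in the study is
#'   derived deterministically from it.
#' @return A list of class `odn_design`.
#' @export
study_design <- function(rho = seq(0.8, 0.975, length.out = 5),
                         n_replicates = 10, n_obs = 2000,
                         t_span = c(0, 20),
                         pars = c(r = 0.5, kappa = 50, x0 = 1),
                         sigma = 1, seed = 1L) {
  stopifnot(all(abs(rho) < 1), n_replicates >= 1, n_obs >= 10,
            length(t_span) == 2, t_span[2] > t_span[1], sigma >= 0)
  pars <- check_pars(logistic_model(), pars)
  structure(
    list(rho = rho, n_replicates = as.integer(n_replicates),
         n_obs = as.integer(n_obs), t_span = t_span, pars = pars,
         sigma = sigma, seed = as.integer(seed)),
    class = "odn_design"
  )
}

#' @export
print.odn_design <- function(x, ...) {
  cat(sprintf("<odn_design> logistic study: %d rho values in [%g, %g], %d replicates, T = %d\n",
              length(x$rho), min(x$rho), max(x$rho), x$n_replicates, x$n_obs))
  invisible(x)
}

# Deterministic seed splitting: every (rho index, replicate, purpose) cell
# of the study gets its own 31-bit seed derived from the master seed.
derive_seed <- function(master, rho_index, replicate, purpose = 0L) {
  as.integer((as.numeric(master) * 1000003 + rho_index * 10007 +
                replicate * 101 + purpose * 13) %% 2147483629)
}

design_times <- function(design) {
  seq(design$t_span[1], design$t_span[2], length.out = design$n_obs)
}

#' Generate one synthetic dataset of the study
#'
#' Logistic trajectory plus AR(1) noise on the design's time grid, seeded
#' deterministically by (design seed, rho, replicate): two calls with the
#' same arguments give identical data. With `sigma = 0` the data equal the
#' noiseless trajectory.
#'
#' The error recursion \eqn{\epsilon(t) = \rho\,\epsilon(t-1) + \nu(t)} is
#' started from \eqn{\epsilon(0) = 0} (no burn-in), mirroring the
#' \eqn{\nu(0) = 0} convention of the conditional likelihood: the noise
#' variance grows from \eqn{\sigma^2} at the first observation to its
#' stationary level over roughly \eqn{1/(1-\rho^2)} samples, so early
#' observations are less noisy than late ones. This is the process under
#' which the AR(1) conditional likelihood is exactly correctly specified.
#'
#' @param design A [study_design()].
#' @param rho AR(1) coefficient, \eqn{|\rho| < 1} (need not lie on the
#'   design grid; off-grid values derive their seed from their own value).
#' @param replicate Replicate index (positive integer).
#' @return A tibble with columns `time` and `value`.
#' @export
generate_dataset <- function(design, rho, replicate) {
  stopifnot(inherits(design, "odn_design"))
  check_scalar_prob_coef(rho, "rho")
  times <- design_times(design)
  traj <- logistic_solution(times, design$pars[["r"]], design$pars[["kappa"]],
                            design$pars[["x0"]])
  if (design$sigma == 0) {
    return(tibble::tibble(time = times, value = traj))
  }
  idx <- match(TRUE, abs(design$rho - rho) < 1e-12)
  if (is.na(idx)) idx <- 1000L + as.integer(round(abs(rho) * 1e6)) %% 1000L
  eps <- sim_arma_vec(ar1_spec(rho, design$sigma), design$n_obs,
                      seed = derive_seed(design$seed, idx, replicate),
                      burn_in = 0)
  tibble::tibble(time = times, value = traj + eps)
}

#' Absolute percentage error
#'
#' \eqn{100 |{\hat\theta} - \theta| / |\theta|}; rejected when the true
#' value is zero.
#'
#' @param estimate,truth Numeric (vectorised).
#' @return Percentage(s) in \[0, Inf).
#' @export
abs_percentage_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("`truth` must be non-zero.", call. = FALSE)
  100 * abs(estimate - truth) / abs(truth)
}

#' Run the logistic simulation study
#'
#' For every (rho, replicate) cell, generates the dataset and fits two
#' statistical models — the correct one assuming AR(1) errors, and one
#' falsely assuming IID Gaussian errors. In `"map_only"` mode each fit is
#' a maximum-likelihood point estimate with asymptotic (inverse observed
#' information) 95% intervals; in `"full_mcmc"` mode each fit is a full
#' posterior sampled with [run_mcmc()] (initialised at the MAP), and
#' intervals are 2.5%-97.5% posterior quantiles.
#'
#' @param design A [study_design()].
#' @param mode `"map_only"` or `"full_mcmc"`.
#' @param chains,iterations,warmup MCMC settings (full_mcmc mode).
#' @param restarts Optimiser restarts per fit.
#' @param progress Print one line per (rho, replicate) cell?
#' @return A list of class `odn_study` with elements `design`, `mode`, and
#'   `results`: a tibble with one row per (rho, replicate, noise model,
#'   parameter) holding `estimate`, `lower`, `upper`, `ape` (absolute
#'   percentage error), `success` (interval covers truth), `post_var`
#'   and `rhat`/`converged` (MCMC mode). Fit failures are recorded in
#'   `failures` and excluded from `results`.
#' @seealso [success_rate()], [ar1_closer_fraction()], [study_empirical_vir()]
#' @export
run_study <- function(design, mode = c("map_only", "full_mcmc"),
                      chains = 4, iterations = 1000,
                      warmup = floor(iterations / 2), restarts = 2,
                      progress = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "odn_design"))
  model <- logistic_model()
  truth <- c(design$pars, sigma = design$sigma)
  rows <- list()
  failures <- list()
  for (i in seq_along(design$rho)) {
    rho_i <- design$rho[i]
    for (j in seq_len(design$n_replicates)) {
      data <- generate_dataset(design, rho_i, j)
      for (nm_idx in 1:2) {
        noise_model <- c("iid", "ar1")[nm_idx]
        fit_seed <- derive_seed(design$seed, i, j, purpose = nm_idx)
        cell <- tryCatch(
          study_fit_cell(data, model, noise_model, mode, fit_seed,
                         chains, iterations, warmup, restarts),
          error = function(e) e
        )
        if (inherits(cell, "error")) {
          failures[[length(failures) + 1]] <- tibble::tibble(
            rho = rho_i, replicate = j, noise_model = noise_model,
            message = conditionMessage(cell)
          )
          next
        }
        cell$rho <- rho_i
        cell$replicate <- j
        cell$noise_model <- noise_model
        cell$truth <- unname(truth[cell$term])
        rows[[length(rows) + 1]] <- cell
      }
      if (progress) {
        message(sprintf("rho = %.4f replicate %d done", rho_i, j))
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  results <- dplyr::mutate(
    results,
    ape = ifelse(.data$truth != 0,
                 100 * abs(.data$estimate - .data$truth) / abs(.data$truth),
                 NA_real_),
    success = .data$lower <= .data$truth & .data$truth <= .data$upper
  )
  results <- dplyr::select(
    results, "rho", "replicate", "noise_model", "term", "truth",
    "estimate", "lower", "upper", "ape", "success", "post_var",
    dplyr::any_of(c("rhat", "converged"))
  )
  structure(
    list(design = design, mode = mode, results = results,
         failures = dplyr::bind_rows(failures)),
    class = "odn_study"
  )
}

study_fit_cell <- function(data, model, noise_model, mode, fit_seed,
                           chains, iterations, warmup, restarts) {
  map_fit <- fit_point_estimate(data, model, noise_model,
                                restarts = restarts, seed = fit_seed)
  if (mode == "map_only") {
    iv <- point_intervals(map_fit)
    iv$post_var <- iv$variance
    return(iv[, c("term", "estimate", "lower", "upper", "post_var")])
  }
  post <- run_mcmc(data, model, noise_model, chains = chains,
                   iterations = iterations, warmup = warmup,
                   seed = fit_seed, init_fit = map_fit)
  ps <- posterior_summary(post)
  tibble::tibble(
    term = ps$term, estimate = ps$median, lower = ps$q2.5, upper = ps$q97.5,
    post_var = ps$variance,
    rhat = unname(post$rhat[ps$term]),
    converged = post$converged
  )
}

#' @export
print.odn_study <- function(x, ...) {
  cat(sprintf("<odn_study> mode = %s, %d result rows, %d failures\n",
              x$mode, nrow(x$results), nrow(x$failures)))
  invisible(x)
}

#' Per-rho interval success (coverage) rates
#'
#' Percentage of replicates whose 95% interval for `parameter` contains
#' the generating value — the study's "success" rate — under the given
#' noise model, at each rho.
#'
#' @param study An [run_study()] result.
#' @param parameter Parameter name (e.g. `"r"`).
#' @param noise_model `"iid"` or `"ar1"`.
#' @return A tibble with columns `rho`, `n`, `success_pct`.
#' @export
success_rate <- function(study, parameter, noise_model) {
  stopifnot(inherits(study, "odn_study"))
  rows <- dplyr::filter(study$results, .data$term == parameter,
                        .data$noise_model == !!noise_model)
  if (nrow(rows) == 0 || anyNA(rows$lower)) {
    stop("Interval estimates are missing for this parameter/noise model.", call. = FALSE)
  }
  dplyr::summarise(dplyr::group_by(rows, .data$rho),
                   n = dplyr::n(),
                   success_pct = 100 * mean(.data$success), .groups = "drop")
}

#' Fraction of comparisons where the AR(1) estimate is closer to truth
#'
#' For every (rho, replicate, parameter) cell with both fits available,
#' compares the absolute errors of the AR(1)-model and IID-model point
#' estimates. Reports the percentage of comparisons won by the AR(1)
#' model, both per parameter-comparison (each parameter counted
#' separately) and per replicate jointly (a replicate counts as a win only
#' if AR(1) is closer for every compared parameter).
#'
#' @param study An [run_study()] result.
#' @param parameters Parameters compared. The default compares every
#'   parameter the two statistical models share (`r`, `kappa`, `x0`,
#'   `sigma`); pass `c("r", "kappa")` to restrict to the dynamical
#'   parameters. Note the models see `sigma` differently: the AR(1) model
#'   estimates the innovation scale (the generating value), while the IID
#'   model estimates the (inflated) marginal noise scale.
#' @return A list with `per_comparison_pct`, `per_replicate_joint_pct`,
#'   `n_comparisons`, and the underlying `comparisons` tibble.
#' @export
ar1_closer_fraction <- function(study, parameters = c("r", "kappa", "x0", "sigma")) {
  stopifnot(inherits(study, "odn_study"))
  wide <- tidyr::pivot_wider(
    dplyr::filter(study$results, .data$term %in% parameters),
    id_cols = c("rho", "replicate", "term", "truth"),
    names_from = "noise_model", values_from = "estimate"
  )
  wide <- dplyr::filter(wide, !is.na(.data$iid), !is.na(.data$ar1))
  if (nrow(wide) == 0) stop("No paired fits available.", call. = FALSE)
  wide$ar1_closer <- abs(wide$ar1 - wide$truth) < abs(wide$iid - wide$truth)
  joint <- dplyr::summarise(dplyr::group_by(wide, .data$rho, .data$replicate),
                            all_closer = all(.data$ar1_closer), .groups = "drop")
  list(
    per_comparison_pct = 100 * mean(wide$ar1_closer),
    per_replicate_joint_pct = 100 * mean(joint$all_closer),
    n_comparisons = nrow(wide),
    comparisons = wide
  )
}

#' Empirical VIRs across the study grid
#'
#' Per (rho, replicate, parameter) ratio of the AR(1)-model posterior (or
#' asymptotic) variance to the IID-model variance — the study's empirical
#' variance inflation ratios, comparable to the analytic [vir_ar1()]
#' curve.
#'
#' @param study An [run_study()] result.
#' @param parameters Parameters to include (default `r` and `kappa`).
#' @return A tibble with columns `rho`, `replicate`, `term`, `vir`.
#' @export
study_empirical_vir <- function(study, parameters = c("r", "kappa")) {
  stopifnot(inherits(study, "odn_study"))
  wide <- tidyr::pivot_wider(
    dplyr::filter(study$results, .data$term %in% parameters),
    id_cols = c("rho", "replicate", "term"),
    names_from = "noise_model", values_from = "post_var"
  )
  wide <- dplyr::filter(wide, !is.na(.data$iid), !is.na(.data$ar1), .data$iid > 0)
  tibble::tibble(rho = wide$rho, replicate = wide$replicate,
                 term = wide$term, vir = wide$ar1 / wide$iid)
}
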