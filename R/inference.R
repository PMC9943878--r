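#' Prior specifications
#'
#' Small prior objects used by [fit_point_estimate()] (MAP) and
#' [run_mcmc()]. Each carries a log-density on the natural parameter
#' scale.
#'
#' @param mean,sd Normal location and scale.
#' @param scale Half-normal scale (support x > 0).
#' @param min,max Uniform bounds.
#' @return An object of class `odn_prior`.
#' @name priors
NULL

#' @rdname priors
#' @export
prior_normal <- function(mean = 0, sd = 1) {
  structure(list(logd = function(x) stats::dnorm(x, mean, sd, log = TRUE),
                 desc = sprintf("normal(%g, %g)", mean, sd)),
            class = "odn_prior")
}

#' @rdname priors
#' @export
prior_half_normal <- function(scale = 1) {
  structure(list(logd = function(x) {
    ifelse(x > 0, log(2) + stats::dnorm(x, 0, scale, log = TRUE), -Inf)
  }, desc = sprintf("half-normal(%g)", scale)), class = "odn_prior")
}

#' @rdname priors
#' @export
prior_uniform <- function(min = -1, max = 1) {
  structure(list(logd = function(x) {
    ifelse(x >= min & x <= max, -log(max - min), -Inf)
  }, desc = sprintf("uniform(%g, %g)", min, max)), class = "odn_prior")
}

log_prior <- function(priors, x) {
  lp <- 0
  for (nm in names(priors)) {
    if (nm %in% names(x)) lp <- lp + priors[[nm]]$logd(x[[nm]])
  }
  lp
}

# Weakly-informative defaults: half-normal (scale 10 * max(|init|, 1)) on
# positive parameters, normal(0, same scale) on unbounded ones,
# uniform(-1, 1) on rho, half-normal(5) on phi-type coefficients.
default_priors <- function(start, tr) {
  priors <- list()
  for (nm in names(start)) {
    kind <- tr$kind[[nm]]
    sc <- 10 * max(abs(start[[nm]]), 1)
    priors[[nm]] <- switch(kind,
      log = prior_half_normal(sc),
      atanh = prior_uniform(-1, 1),
      prior_normal(0, sc)
    )
  }
  priors
}

#' Adaptive-covariance Markov chain Monte Carlo
#'
#' Samples the posterior over the model parameters plus the noise
#' parameters (\eqn{\sigma}, and \eqn{\rho}, \eqn{\phi} as the noise model
#' requires) with an adaptive-covariance random-walk Metropolis sampler
#' (Haario-Bardenet style: the proposal covariance tracks the running
#' sample covariance, and a global scale is tuned towards an acceptance
#' rate of 0.234). Positive parameters are sampled on the log scale and
#' \eqn{\rho} on the atanh scale, with the appropriate Jacobian terms.
#' Chains start from a jittered MAP estimate, whose inverse curvature also
#' seeds the proposal covariance.
#'
#' @inheritParams fit_point_estimate
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Total iterations per chain (including warm-up).
#' @param warmup Iterations discarded as warm-up (default half).
#' @param rhat_threshold Convergence threshold for split-\eqn{\hat R}
#'   (default 1.01). A result exceeding it is flagged, not discarded.
#' @param init_fit Optional `odn_fit` from [fit_point_estimate()] to use
#'   as the starting point (skips the internal MAP fit).
#' @param sample_presample_error AR(1) noise model only: instead of fixing
#'   the pre-sample error at zero, treat it as a parameter `eps0` with a
#'   prior (default: normal with the stationary error scale) and sample
#'   it. Off by default; the zero-conditioning bias it removes vanishes
#'   at rate 1/T.
#' @return An `odn_fit` with `mode = "posterior"`: pooled post-warm-up
#'   `draws` (tibble with `.chain`, `.iteration` and one column per
#'   parameter, on the natural scale), per-parameter `rhat`, posterior
#'   medians as `estimates`, log-likelihood at the estimates, and
#'   acceptance rates. Identical seeds give identical draws.
#' @examples
#' d <- generate_dataset(study_design(n_obs = 100), rho = 0.8, replicate = 1)
#' fit <- run_mcmc(d, logistic_model(), "ar1", chains = 2,
#'                 iterations = 400, seed = 1)
#' posterior_summary(fit)
#' @export
run_mcmc <- function(data, model, noise_model = c("iid", "ar1", "arma11", "arma_kalman"),
                     priors = NULL, chains = 4, iterations = 2000,
                     warmup = floor(iterations / 2), seed = NULL,
                     start = NULL, init_fit = NULL, rhat_threshold = 1.01,
                     sample_presample_error = FALSE) {
  noise_model <- match.arg(noise_model)
  stopifnot(chains >= 1, iterations > warmup, warmup >= 0)
  if (sample_presample_error && noise_model != "ar1") {
    stop("`sample_presample_error` is only available for the AR(1) model.", call. = FALSE)
  }
  extra <- if (sample_presample_error) "eps0" else character()
  tr <- par_transform_info(model, noise_model, extra = extra)
  start <- start %||% default_start(data, model, noise_model)
  if (sample_presample_error && !"eps0" %in% names(start)) {
    start <- c(start, eps0 = 0)
  }
  start <- start[tr$names]
  user_eps0_prior <- !is.null(priors) && !is.null(priors[["eps0"]])
  priors <- priors %||% default_priors(start, tr)
  if (sample_presample_error && !user_eps0_prior) {
    # default: the stationary error scale at the starting values
    sc <- start[["sigma"]] / sqrt(max(1 - start[["rho"]]^2, 1e-4))
    priors[["eps0"]] <- prior_normal(0, sc)
  }
  missing_p <- setdiff(tr$names, names(priors))
  if (length(missing_p) > 0) {
    stop("Priors missing for: ", paste(missing_p, collapse = ", "), call. = FALSE)
  }

  map_fit <- init_fit %||% fit_point_estimate(
    data, model, noise_model,
    start = start[setdiff(tr$names, "eps0")],
    priors = priors[setdiff(names(priors), "eps0")],
    restarts = 2, seed = seed
  )
  u_map <- map_fit$u_hat
  if (sample_presample_error) u_map <- c(u_map, 0)
  d_par <- length(u_map)

  # proposal covariance seed: inverse observed information at the MAP
  prop_cov <- NULL
  map_hess <- map_fit$hessian_u
  if (sample_presample_error && !is.null(map_hess)) {
    k <- nrow(map_hess)
    ext <- matrix(0, k + 1, k + 1)
    ext[seq_len(k), seq_len(k)] <- map_hess
    ext[k + 1, k + 1] <- 1
    map_hess <- ext
  }
  if (!is.null(map_hess)) {
    prop_cov <- tryCatch({
      cv <- solve(map_hess)
      cv <- (cv + t(cv)) / 2
      if (all(eigen(cv, symmetric = TRUE, only.values = TRUE)$values > 0)) cv else NULL
    }, error = function(e) NULL)
  }
  if (is.null(prop_cov)) prop_cov <- diag(1e-3, d_par)

  times <- data$time
  y <- data$value
  log_post_u <- function(u) {
    x <- to_constrained(u, tr$kind)
    names(x) <- tr$names
    theta <- x[model$par_names]
    if (any(model$positive & theta <= 0)) return(-Inf)
    f <- tryCatch(model$simulate(theta, times), error = function(e) NULL)
    if (is.null(f) || anyNA(f) || any(!is.finite(f))) return(-Inf)
    ll <- eval_loglik(noise_model, y - f, x[setdiff(tr$names, model$par_names)])
    lp <- ll + log_prior(priors, x) + log_jacobian(u, tr$kind)
    if (!is.finite(lp)) -Inf else lp
  }

  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      u <- u_map + stats::rnorm(d_par, sd = 0.05)
      lp <- log_post_u(u)
      tries <- 0
      while (!is.finite(lp) && tries < 50) {
        u <- u_map + stats::rnorm(d_par, sd = 0.05)
        lp <- log_post_u(u)
        tries <- tries + 1
      }
      if (!is.finite(lp)) stop("Could not initialise chain at finite posterior density.", call. = FALSE)
      draws <- matrix(NA_real_, iterations, d_par)
      mu <- u
      Sig <- prop_cov
      log_lambda <- 0
      accept <- 0L
      base_scale <- 2.38^2 / d_par
      L <- chol(base_scale * Sig + diag(1e-10, d_par))
      for (i in seq_len(iterations)) {
        prop <- u + exp(0.5 * log_lambda) * as.vector(stats::rnorm(d_par) %*% L)
        lp_prop <- log_post_u(prop)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp
        if (acc) { u <- prop; lp <- lp_prop; accept <- accept + 1L }
        draws[i, ] <- u
        # Haario-Bardenet adaptation: running mean/covariance + global scale
        gam <- (i + 10)^-0.6
        du <- u - mu
        mu <- mu + gam * du
        Sig <- Sig + gam * (tcrossprod(du) - Sig)
        log_lambda <- log_lambda + gam * ((if (acc) 1 else 0) - 0.234)
        if (i %% 50 == 0) {
          L <- tryCatch(chol(base_scale * Sig + diag(1e-10, d_par)),
                        error = function(e) L)
        }
      }
      list(draws = draws, acceptance = accept / iterations)
    })
  }

  chain_seeds <- if (is.null(seed)) sample.int(2^30, chains) else {
    withr::with_seed(as.integer(seed) + 1L, sample.int(2^30, chains))
  }
  chain_out <- purrr::map(chain_seeds, run_chain)

  post <- purrr::imap(chain_out, function(ch, idx) {
    keep <- seq.int(warmup + 1L, iterations)
    m <- ch$draws[keep, , drop = FALSE]
    x <- t(apply(m, 1, to_constrained, kind = tr$kind))
    colnames(x) <- tr$names
    dplyr::bind_cols(
      tibble::tibble(.chain = idx, .iteration = seq_along(keep)),
      tibble::as_tibble(x)
    )
  })
  draws <- dplyr::bind_rows(post)

  rhat_vals <- if (chains >= 2) {
    vapply(tr$names, function(nm) {
      m <- matrix(draws[[nm]], ncol = chains)
      rhat_matrix(m)
    }, numeric(1))
  } else {
    stats::setNames(rep(NA_real_, d_par), tr$names)
  }

  est <- vapply(tr$names, function(nm) stats::median(draws[[nm]]), numeric(1))
  f_est <- model$simulate(est[model$par_names], times)
  ll_est <- eval_loglik(noise_model, y - f_est, est[setdiff(tr$names, model$par_names)])

  structure(
    list(
      mode = "posterior",
      estimates = est,
      draws = draws,
      rhat = rhat_vals,
      converged = all(is.na(rhat_vals)) || all(rhat_vals < rhat_threshold, na.rm = TRUE),
      rhat_threshold = rhat_threshold,
      loglik = ll_est,
      model = model, noise_model = noise_model,
      transform = tr, n_obs = length(y),
      chains = chains, iterations = iterations, warmup = warmup,
      acceptance = vapply(chain_out, function(ch) ch$acceptance, numeric(1)),
      priors = priors, map_fit = map_fit, data = data
    ),
    class = "odn_fit"
  )
}

#' Split-\eqn{\hat R} convergence diagnostic
#'
#' Rank-normalised split-\eqn{\hat R}: each chain is split in half, the
#' pooled draws are rank-normalised through the normal quantile function,
#' and the classic between/within variance ratio is computed. Values near
#' 1 indicate convergence (common thresholds: 1.01 strict, 1.1 lenient).
#' Chains with zero total variance return 1 by convention.
#'
#' @param draws A numeric matrix (iterations x chains), or an `odn_fit`
#'   in posterior mode (returns one value per parameter).
#' @return Named numeric vector of \eqn{\hat R} values.
#' @examples
#' rhat(matrix(rnorm(4000), ncol = 4))
#' @export
rhat <- function(draws) {
  if (inherits(draws, "odn_fit")) {
    if (draws$mode != "posterior") stop("`rhat` needs a posterior-mode fit.", call. = FALSE)
    return(draws$rhat)
  }
  m <- as.matrix(draws)
  rhat_matrix(m)
}

rhat_matrix <- function(m) {
  if (ncol(m) < 2) stop("At least two chains are required for R-hat.", call. = FALSE)
  n <- nrow(m)
  if (n < 4) stop("At least four draws per chain are required.", call. = FALSE)
  half <- floor(n / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[seq.int(n - half + 1, n), , drop = FALSE])
  if (stats::sd(as.vector(split)) == 0) return(1)
  z <- stats::qnorm((rank(split, ties.method = "average") - 3 / 8) /
                      (length(split) + 1 / 4))
  z <- matrix(z, nrow = half)
  nchain <- ncol(z)
  chain_means <- colMeans(z)
  B <- half * stats::var(chain_means)
  W <- mean(apply(z, 2, stats::var))
  if (W == 0) return(1)
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Posterior summary
#'
#' Per-parameter posterior medians, 2.5% and 97.5% quantiles (linear
#' interpolation, R's default type 7) and variances, over the pooled
#' post-warm-up draws.
#'
#' @param fit An `odn_fit` with `mode = "posterior"`.
#' @return A tibble with columns `term`, `median`, `q2.5`, `q97.5`,
#'   `variance`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "odn_fit"))
  if (fit$mode != "posterior") {
    stop("`posterior_summary` requires a posterior-mode fit.", call. = FALSE)
  }
  pars <- fit$transform$names
  purrr::map_dfr(pars, function(nm) {
    x <- fit$draws[[nm]]
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(term = nm, median = q[2], q2.5 = q[1], q97.5 = q[3],
                   variance = stats::var(x))
  })
}

#' Empirical VIR from paired posteriors
#'
#' Ratio of posterior variances between a fit under a correlated-noise
#' model and a fit of the *same* deterministic model under IID noise —
#' the empirical counterpart of the analytic variance inflation ratios.
#'
#' @param posterior_correlated,posterior_iid Posterior-mode `odn_fit`
#'   objects over the same model parameters.
#' @param parameters Which parameters to compare (default: the shared
#'   deterministic-model parameters).
#' @return A [vir_report()] tibble (`method = "empirical_posterior"`).
#' @export
empirical_vir <- function(posterior_correlated, posterior_iid, parameters = NULL) {
  for (f in list(posterior_correlated, posterior_iid)) {
    stopifnot(inherits(f, "odn_fit"))
    if (f$mode != "posterior") stop("Both fits must be posterior-mode.", call. = FALSE)
  }
  p1 <- posterior_correlated$model$par_names
  p2 <- posterior_iid$model$par_names
  if (!identical(sort(p1), sort(p2))) {
    stop("Model parameter names do not match between the two posteriors.", call. = FALSE)
  }
  parameters <- parameters %||% p1
  v1 <- vapply(parameters, function(nm) stats::var(posterior_correlated$draws[[nm]]), numeric(1))
  v2 <- vapply(parameters, function(nm) stats::var(posterior_iid$draws[[nm]]), numeric(1))
  est <- posterior_correlated$estimates
  rho <- if ("rho" %in% names(est)) unname(est[["rho"]]) else NULL
  vir_report(parameters, v1 / v2, method = "empirical_posterior", rho = rho)
}
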