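test_that("IID log-likelihood matches hand values and the dense oracle", {
  expect_equal(loglik_iid(0, 0, sigma = 1), -0.5 * log(2 * pi))
  # constant offset: T * (-0.5 log 2pi - c^2 / 2)
  T_ <- 20; c_ <- 0.7
  expect_equal(loglik_iid(rep(c_, T_), rep(0, T_), 1),
               T_ * (-0.5 * log(2 * pi) - c_^2 / 2))
  y <- withr::with_seed(1L, rnorm(50))
  expect_equal(loglik_iid(y, rep(0, 50), 1.3),
               mvn_loglik(y, rep(0, 50), diag(1.3^2, 50)),
               tolerance = 1e-10)
})

test_that("AR(1) conditional likelihood: reduction, worked case, dense oracle", {
  y <- withr::with_seed(2L, rnorm(30))
  f <- rep(0, 30)
  # rho = 0 reduces exactly to IID with the same number of terms
  expect_equal(loglik_ar1_conditional(y, f, 0, 1.2), loglik_iid(y, f, 1.2))
  # 3-point hand recursion: nu = (0.5, 0.45, 0.05)
  nu <- c(0.5, 0.45, 0.05)
  expect_equal(loglik_ar1_conditional(c(0.5, 0.7, 0.4), rep(0, 3), 0.5, 1),
               -1.5 * log(2 * pi) - 0.5 * sum(nu^2))
  # dense-covariance oracle: eps(0) = 0 start implies Sigma = sigma^2 L L'
  rho <- 0.6; sigma <- 0.8; T_ <- 40
  eps <- withr::with_seed(3L, rnorm(T_))
  expect_equal(loglik_ar1_conditional(eps, rep(0, T_), rho, sigma),
               mvn_loglik(eps, rep(0, T_), ar1_zero_start_cov(rho, sigma, T_)),
               tolerance = 1e-8)
})

test_that("the AR(1) likelihood prefers the generating noise parameters", {
  des <- study_design(n_obs = 2000, seed = 9)
  d <- generate_dataset(des, 0.9, 1)
  f <- logistic_closed_form(d$time, 0.5, 50, 1)
  ll_true <- loglik_ar1_conditional(d$value, f, 0.9, 1)
  ll_iid <- loglik_ar1_conditional(d$value, f, 0, 1)
  expect_gt(ll_true, ll_iid)
})

test_that("ARMA(1,1) conditional likelihood: reductions, worked case, oracle", {
  y <- withr::with_seed(4L, rnorm(25))
  f <- rep(0, 25)
  # rho = phi = 0: IID over the last T - 2 residuals
  expect_equal(loglik_arma11_conditional(y, f, 0, 0, 1.1),
               loglik_iid(y[3:25], f[3:25], 1.1))
  # 4-point hand recursion: nu(3) = 0.35, nu(4) = -0.155
  nu <- c(0.35, -0.155)
  expect_equal(loglik_arma11_conditional(c(0.2, -0.1, 0.3, 0.1), rep(0, 4), 0.5, 0.3, 1),
               -log(2 * pi) - 0.5 * sum(nu^2))
  # phi = 0 equals the AR(1) recursion restricted to the t = 3..T terms
  rho <- 0.4
  nu_ar1 <- y - rho * c(0, y[-25])
  manual <- -0.5 * 23 * log(2 * pi) - 0.5 * sum(nu_ar1[3:25]^2)
  expect_equal(loglik_arma11_conditional(y, f, rho, 0, 1), manual, tolerance = 1e-12)
  # dense conditional-normal oracle
  eps <- withr::with_seed(5L, rnorm(30))
  expect_equal(loglik_arma11_conditional(eps, rep(0, 30), 0.5, 0.3, 0.9),
               arma11_conditional_oracle(eps, 0.5, 0.3, 0.9),
               tolerance = 1e-8)
})

test_that("general conditional recursion matches the ARMA(1,1) special case", {
  eps <- withr::with_seed(6L, rnorm(40))
  expect_equal(
    loglik_arma_conditional(eps, rep(0, 40), arma11_spec(0.5, 0.3, 1.2)),
    loglik_arma11_conditional(eps, rep(0, 40), 0.5, 0.3, 1.2),
    tolerance = 1e-12
  )
})

test_that("Kalman likelihood equals dense multivariate-normal oracles", {
  y <- withr::with_seed(7L, rnorm(20))
  f <- rep(0, 20)
  # degenerate state space: IID
  expect_equal(loglik_arma_kalman(y, f, iid_spec(1.5)),
               loglik_iid(y, f, 1.5), tolerance = 1e-10)
  # AR(1): Sigma_ij = sigma^2 rho^|i-j| / (1 - rho^2)
  rho <- 0.7; sigma <- 1.1
  Sig <- sigma^2 * rho^abs(outer(1:20, 1:20, "-")) / (1 - rho^2)
  expect_equal(loglik_arma_kalman(y, f, ar1_spec(rho, sigma)),
               mvn_loglik(y, f, Sig), tolerance = 1e-8)
  # ARMA(1,1) and ARMA(2,1) against the autocovariance oracle
  for (spec in list(arma11_spec(0.5, 0.4, 0.9),
                    noise_spec(ar = c(0.4, 0.2), ma = 0.3, sigma = 1.2))) {
    Sig <- arma_autocov_matrix(spec$ar, spec$ma, spec$sigma, 20)
    expect_equal(loglik_arma_kalman(y, f, spec), mvn_loglik(y, f, Sig),
                 tolerance = 1e-8)
  }
})

test_that("conditional and exact likelihoods converge per observation", {
  spec <- arma11_spec(0.6, 0.3, 1)
  eps <- simulate_arma(spec, 5000, seed = 8)$value
  f <- rep(0, 5000)
  per_obs_gap <- abs(loglik_arma_kalman(eps, f, spec) -
                       loglik_arma11_conditional(eps, f, 0.6, 0.3, 1)) / 5000
  expect_lt(per_obs_gap, 1e-3)
})

test_that("likelihood specifications dispatch to the right evaluator", {
  eps <- withr::with_seed(12L, rnorm(40)); f <- rep(0, 40)
  spec <- arma11_spec(0.5, 0.3, 1.1)
  expect_equal(loglik(eps, f, likelihood_spec(spec)),
               loglik_arma11_conditional(eps, f, 0.5, 0.3, 1.1))
  expect_equal(loglik(eps, f, likelihood_spec(spec, "exact_kalman")),
               loglik_arma_kalman(eps, f, spec))
  expect_equal(loglik(eps, f, likelihood_spec(iid_spec(2))),
               loglik_iid(eps, f, 2))
})

test_that("likelihoods are invariant to a common constant shift", {
  y <- withr::with_seed(9L, rnorm(40)); f <- rep(0, 40)
  for (fn in list(
    function(a, b) loglik_iid(a, b, 1),
    function(a, b) loglik_ar1_conditional(a, b, 0.5, 1),
    function(a, b) loglik_arma11_conditional(a, b, 0.5, 0.3, 1),
    function(a, b) loglik_arma_kalman(a, b, arma11_spec(0.5, 0.3))
  )) {
    expect_equal(fn(y, f), fn(y + 5, f + 5), tolerance = 1e-10)
  }
})

test_that("likelihood preconditions are enforced", {
  expect_error(loglik_iid(1:3, 1:4, 1), "equal length")
  expect_error(loglik_iid(1:3, 1:3, 0), "positive")
  expect_error(loglik_ar1_conditional(1:5, 1:5, 1.2, 1), "rho")
  expect_error(loglik_arma11_conditional(1:2, 1:2, 0.5, 0.3, 1), "T >= 3")
  expect_error(loglik_arma_kalman(1:5, 1:5, noise_spec(ar = 0.5, d = 1)), "stationary")
})
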