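test_that("noiseless logistic data are recovered to within 0.1%", {
  tt <- seq(0, 20, length.out = 300)
  d <- tibble::tibble(time = tt, value = logistic_closed_form(tt, 0.5, 50, 1))
  fit <- fit_point_estimate(d, logistic_model(), "iid", seed = 1)
  est <- fit$estimates
  expect_lt(abs(est[["r"]] - 0.5) / 0.5, 1e-3)
  expect_lt(abs(est[["kappa"]] - 50) / 50, 1e-3)
  expect_lt(abs(est[["x0"]] - 1) / 1, 1e-3)
})

test_that("the AR(1) fit attains at least the IID fit's AR(1) likelihood", {
  des <- study_design(n_obs = 800, seed = 3)
  d <- generate_dataset(des, 0.8, 1)
  f_iid <- fit_point_estimate(d, logistic_model(), "iid", seed = 2)
  f_ar1 <- fit_point_estimate(d, logistic_model(), "ar1", seed = 2)
  # evaluate the IID fit's theta under the AR(1) likelihood at its own
  # optimal noise parameters; the AR(1) optimum must be at least as good
  f_at_iid <- logistic_model()$simulate(f_iid$estimates[c("r", "kappa", "x0")], d$time)
  resid_iid <- d$value - f_at_iid
  r1 <- cor(resid_iid[-1], resid_iid[-length(resid_iid)])
  ll_iid_under_ar1 <- loglik_ar1_conditional(
    d$value, f_at_iid, r1, sd(resid_iid) * sqrt(1 - r1^2))
  expect_gte(f_ar1$loglik + 1e-6, ll_iid_under_ar1)
})

test_that("seeded point estimation is reproducible bit-for-bit", {
  des <- study_design(n_obs = 300, seed = 4)
  d <- generate_dataset(des, 0.8, 2)
  f1 <- fit_point_estimate(d, logistic_model(), "ar1", seed = 7)
  f2 <- fit_point_estimate(d, logistic_model(), "ar1", seed = 7)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("residuals behave for exact, shifted and noisy data", {
  tt <- seq(0, 20, length.out = 500)
  pars <- c(r = 0.5, kappa = 50, x0 = 1)
  f <- logistic_closed_form(tt, 0.5, 50, 1)
  expect_equal(model_residuals(tibble::tibble(time = tt, value = f),
                               logistic_model(), pars)$residual,
               rep(0, 500))
  expect_equal(model_residuals(tibble::tibble(time = tt, value = f + 2.5),
                               logistic_model(), pars)$residual,
               rep(2.5, 500))
  des <- study_design(n_obs = 2000, seed = 5)
  d <- generate_dataset(des, 0.9, 1)
  res <- model_residuals(d, logistic_model(), pars)
  r1 <- sample_acf(res, max_lag = 1)$acf[1]
  expect_lt(abs(r1 - 0.9), 2 / sqrt(2000))
})

test_that("sample ACF satisfies its invariants and white-noise bounds", {
  x <- withr::with_seed(8L, rnorm(1e4))
  a <- sample_acf(x, max_lag = 10)
  expect_true(all(abs(a$acf) < 0.05))
  expect_true(all(a$acf >= -1 & a$acf <= 1))
  expect_equal(sample_acf(x, 10)$acf, sample_acf(-x, 10)$acf)
  y <- simulate_arma(ar1_spec(0.95), 1e5, seed = 9)$value
  a2 <- sample_acf(y, max_lag = 5)
  expect_true(all(abs(a2$acf - 0.95^(1:5)) < 0.02))
  expect_error(sample_acf(rep(3, 100), 5), "Constant")
})

test_that("AIC grid selects white noise for white noise and AR for AR", {
  wn <- withr::with_seed(10L, rnorm(2000))
  tab <- arma_grid_aic(wn, p_max = 2, q_max = 2)
  best <- tab[which.min(tab$aic), ]
  expect_lte(tab$aic[tab$p == 0 & tab$q == 0], min(tab$aic, na.rm = TRUE) + 2)
  ar <- simulate_arma(ar1_spec(0.9), 2000, seed = 11)$value
  tab2 <- arma_grid_aic(ar, p_max = 2, q_max = 2)
  best2 <- tab2[which.min(tab2$aic), ]
  expect_gte(best2$p, 1)
  expect_gt(tab2$aic[tab2$p == 0 & tab2$q == 0], min(tab2$aic, na.rm = TRUE))
  # the percent-difference column is 0 exactly at the argmin row
  expect_equal(tab2$delta_aic_pct[which.min(tab2$aic)], 0)
  # parameter count includes the innovation variance
  expect_equal(tab2$k, tab2$p + tab2$q + 1)
})

test_that("the end-to-end workflow flags autocorrelation for rho >= 0.8", {
  for (rho in c(0.8, 0.9)) {
    des <- study_design(n_obs = 1000, seed = 12)
    d <- generate_dataset(des, rho, 1)
    dg <- diagnose(d, logistic_model(), p_max = 2, q_max = 2, seed = 13)
    expect_true(dg$autocorrelated)
    expect_gte(dg$recommendation$p, 1)
  }
})
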