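test_that("closed-form VIRs take their stated values and reductions", {
  expect_equal(vir_ar1(0), 1)
  expect_equal(vir_ar1(0.5), 3)
  expect_equal(vir_ma1(0), 1)
  expect_equal(vir_ma1(1), 2)
  expect_equal(vir_arma11(0.5, 0), vir_ar1(0.5))
  expect_equal(vir_arma11(0, 0.7), vir_ma1(0.7))
  expect_equal(vir_arma11(0.5, 0.5), 3 * (1 + 0.5 / 1.75))
})

test_that("VIR orderings: AR(1) monotone, dominates MA(1), ARMA dominates AR", {
  grid <- seq(0.01, 0.99, length.out = 99)
  v <- vir_ar1(grid)
  expect_true(all(diff(v) > 0))
  c_grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(vir_ar1(c_grid) > vir_ma1(c_grid)))
  expect_true(all(vir_arma11(c_grid, 0.5) > vir_ar1(c_grid)))
})

test_that("sensitivity-weighted VIR recovers the constant-mean law", {
  expect_equal(vir_nonlinear_ar1(rep(2, 50), 0.6), vir_ar1(0.6))
  s <- sin(seq(0, 3, length.out = 100)) + 2
  expect_equal(vir_nonlinear_ar1(s, 0), 1)
  expect_error(vir_nonlinear_ar1(rep(0, 10), 0.5), "zero")
  expect_error(vir_nonlinear_ar1(rep(1, 10), 1), "rho")
})

test_that("constant-mean CRLB reduces to the AR(1) and IID forms", {
  expect_equal(crlb_arma_constant(ar1_spec(0.5, 2), 100), 4 / (100 * 0.25))
  expect_equal(crlb_arma_constant(iid_spec(2), 50), 4 / 50)
  expect_equal(crlb_arma_constant(ma1_spec(0.5), 1000), 1.5^2 / 1000)
  # phi = -1 cancels the mean information entirely
  expect_equal(crlb_arma_constant(ma1_spec(-1), 10), 0)
})

test_that("Monte-Carlo mean-estimator variances validate the closed forms", {
  # moderate-size check; the acceptance suite runs the full-scale version
  cases <- list(
    list(spec = ar1_spec(0.5), vir = vir_ar1(0.5)),
    list(spec = ma1_spec(0.5), vir = vir_ma1(0.5)),
    list(spec = arma11_spec(0.5, 0.5), vir = vir_arma11(0.5, 0.5))
  )
  for (cs in cases) {
    emp <- empirical_vir_constant(cs$spec, n_rep = 1000, n_obs = 500, seed = 21)
    expect_equal(emp$vir, cs$vir, tolerance = 0.12)
  }
  # MA(1) CRLB against empirical variance of the mean estimator
  x <- replicate(1000, mean(sim <- simulate_arma(ma1_spec(0.5), 500, burn_in = 50)$value))
  expect_equal(var(x), crlb_arma_constant(ma1_spec(0.5), 500), tolerance = 0.15)
})

test_that("numeric FIM reproduces the constant-mean information", {
  T_ <- 1000; rho <- 0.5; sigma <- 1
  tt <- seq_len(T_)
  fim <- fim_numeric(constant_model(), c(mu = 0), tt, ar1_spec(rho, sigma),
                     include = c("mu", "sigma", "rho"), n_sim = 40, seed = 5)
  expect_equal(fim$information["mu", "mu"], T_ * (1 - rho)^2 / sigma^2,
               tolerance = 0.01)
  # off-diagonals coupling mu with sigma and rho vanish
  scale_ms <- sqrt(fim$information["mu", "mu"] * fim$information["sigma", "sigma"])
  scale_mr <- sqrt(fim$information["mu", "mu"] * fim$information["rho", "rho"])
  expect_lt(abs(fim$information["mu", "sigma"]) / scale_ms, 0.05)
  expect_lt(abs(fim$information["mu", "rho"]) / scale_mr, 0.05)
  # inverse information is bounded below by the analytic CRLB
  v <- solve(fim$information)["mu", "mu"]
  expect_gte(v, 0.95 * crlb_arma_constant(ar1_spec(rho, sigma), T_))
})

test_that("logistic FIM couples dynamical parameters with the initial state", {
  tt <- seq(0, 20, length.out = 200)
  fim <- fim_numeric(logistic_model(), c(r = 0.5, kappa = 50, x0 = 1), tt,
                     ar1_spec(0.5, 1), include = c("r", "kappa", "x0"),
                     n_sim = 30, seed = 6)
  corr_rx0 <- fim$information["r", "x0"] /
    sqrt(fim$information["r", "r"] * fim$information["x0", "x0"])
  expect_gt(abs(corr_rx0), 0.1)
})

test_that("numeric-FIM VIR tracks the sensitivity-weighted formula", {
  tt <- seq(0, 20, length.out = 200)
  pars <- c(r = 0.5, kappa = 50, x0 = 1)
  rep_ <- vir_numeric_fim(logistic_model(), pars, tt, rho = 0.5, n_sim = 30,
                          seed = 7)
  expect_true(all(rep_$vir > 1))
  s_kappa <- sensitivities(logistic_model(), pars, tt)$kappa
  analytic <- vir_nonlinear_ar1(s_kappa, 0.5)
  got <- rep_$vir[rep_$parameter == "kappa"]
  expect_equal(got, analytic, tolerance = 0.35)
})

test_that("VIR reports validate their invariants", {
  expect_error(vir_report("a", -1, "analytic_constant"), "positive")
  rep_ <- vir_report(c("a", "b"), c(1, 2), "analytic_constant", rho = 0.5)
  expect_s3_class(rep_, "odn_vir")
  expect_equal(attr(rep_, "rho"), 0.5)
})
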