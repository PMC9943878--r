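test_that("numeric logistic solution matches the closed form on the study grid", {
  pars <- c(r = 0.5, kappa = 50, x0 = 1)
  tt <- seq(0, 20, length.out = 2000)
  num <- solve_logistic(pars, tt, method = "numeric")
  cf <- logistic_closed_form(tt, 0.5, 50, 1)
  expect_lt(max(abs(num$value - cf) / cf), 1e-6)
  # analytic path equals the closed form by construction
  expect_equal(solve_logistic(pars, tt)$value, cf, tolerance = 1e-12)
})

test_that("logistic limits behave: r = 0 freezes, large t reaches kappa", {
  tt <- seq(0, 10, length.out = 11)
  frozen <- logistic_model()$simulate(c(r = 1e-12, kappa = 50, x0 = 3), tt)
  expect_equal(frozen, rep(3, 11), tolerance = 1e-9)
  late <- solve_logistic(c(r = 0.5, kappa = 50, x0 = 1), c(0, 100 / 0.5))
  expect_lt(abs(late$value[2] - 50), 1e-6 * 50)
})

test_that("solver trajectories are converged in tolerance", {
  pars <- c(r = 0.5, kappa = 50, x0 = 1)
  tt <- seq(0, 20, length.out = 200)
  a <- solve_logistic(pars, tt, method = "numeric", rtol = 1e-8, atol = 1e-10)
  b <- solve_logistic(pars, tt, method = "numeric", rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$value - b$value) / pmax(a$value, 1)), 1e-6)
})

test_that("constant-mean sensitivities are the all-ones column", {
  s <- sensitivities(constant_model(), c(mu = 3), seq(0, 5, by = 1))
  expect_equal(s$mu, rep(1, 6), tolerance = 1e-6)
})

test_that("forward-ODE sensitivities agree with central finite differences", {
  pars <- c(r = 0.5, kappa = 50, x0 = 1)
  tt <- seq(0, 20, length.out = 60)
  fo <- sensitivities(logistic_model(), pars, tt, method = "forward_ode")
  fd <- sensitivities(logistic_model(), pars, tt, method = "finite_difference")
  for (p in c("r", "kappa", "x0")) {
    expect_equal(fo[[p]], fd[[p]], tolerance = 1e-4)
  }
  # late-time kappa sensitivity approaches 1 as the solution saturates
  late <- sensitivities(logistic_model(), pars, c(0, 100 / 0.5))
  expect_equal(late$kappa[2], 1, tolerance = 1e-4)
})

test_that("hERG current vanishes when the driving force is zero", {
  pars <- herg_parameters()
  prot <- voltage_protocol(duration_ms = c(500, 500),
                           voltage_mV = c(pars[["e_k"]], pars[["e_k"]]))
  tr <- solve_herg(pars, prot, times = seq(0, 1000, by = 10))
  expect_equal(tr$value, rep(0, nrow(tr)), tolerance = 1e-12)
})

test_that("hERG gates relax to their voltage-dependent steady state", {
  pars <- herg_parameters()
  V <- 0
  k1 <- pars[["p1"]] * exp(pars[["p2"]] * V)
  k2 <- pars[["p3"]] * exp(-pars[["p4"]] * V)
  a_inf <- k1 / (k1 + k2)
  tau_a <- 1 / (k1 + k2)
  prot <- voltage_protocol(duration_ms = 200 * tau_a, voltage_mV = V)
  tr <- solve_herg(pars, prot, times = c(0, 200 * tau_a), pre_pace_ms = 0)
  expect_equal(tr$a[2], a_inf, tolerance = 1e-4)
})

test_that("hERG gates stay in [0, 1] for random positive parameter draws", {
  draws <- withr::with_seed(11L, replicate(10, {
    p <- herg_parameters()
    p[paste0("p", 1:8)] <- p[paste0("p", 1:8)] * exp(runif(8, -1, 1))
    p[["g_kr"]] <- p[["g_kr"]] * exp(runif(1, -1, 1))
    p
  }))
  prot <- voltage_protocol(duration_ms = c(200, 500, 300),
                           voltage_mV = c(-80, 20, -40))
  for (j in seq_len(ncol(draws))) {
    tr <- solve_herg(draws[, j], prot, times = seq(0, 1000, by = 5))
    expect_true(all(tr$a >= 0 & tr$a <= 1))
    expect_true(all(tr$r >= 0 & tr$r <= 1))
  }
})

test_that("analytic and numeric hERG paths agree", {
  pars <- herg_parameters()
  prot <- voltage_protocol(duration_ms = c(100, 300, 100),
                           voltage_mV = c(-80, 20, -60))
  tt <- seq(0, 500, by = 10)
  a <- solve_herg(pars, prot, tt, pre_pace_ms = 1000)
  n <- solve_herg(pars, prot, tt, pre_pace_ms = 1000, method = "numeric")
  expect_equal(a$value, n$value, tolerance = 1e-6)
})

test_that("model input validation rejects bad parameters and grids", {
  expect_error(solve_logistic(c(r = -1, kappa = 50, x0 = 1), 0:5), "positive")
  expect_error(solve_logistic(c(r = 1, kappa = 50, x0 = 1), c(1, 1, 2)), "increasing")
  bad <- herg_parameters(); bad[["p1"]] <- -1
  expect_error(solve_herg(bad, staircase_protocol()), "positive")
  expect_error(voltage_protocol(c(-5, 10), c(0, 0)), "positive")
})
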