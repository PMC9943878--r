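test_that("IID specification reduces simulation to plain Gaussian draws", {
  s <- simulate_arma(iid_spec(sigma = 2), n = 5, seed = 7, burn_in = 0)
  expect_equal(s$value, withr::with_seed(7L, rnorm(5, sd = 2)))
  expect_equal(s$value, s$innovation)
})

test_that("simulation is bit-reproducible given a seed and leaves the RNG alone", {
  set.seed(123)
  before <- .Random.seed
  a <- simulate_arma(arma11_spec(0.5, 0.3), 100, seed = 42)
  expect_identical(before, .Random.seed)
  b <- simulate_arma(arma11_spec(0.5, 0.3), 100, seed = 42)
  expect_identical(a, b)
})

test_that("sample moments of long simulations match stationary theory", {
  specs <- list(
    list(spec = ar1_spec(0.8), var = 1 / (1 - 0.64)),
    list(spec = ma1_spec(0.8), var = 1 + 0.64),
    list(spec = arma11_spec(0.5, 0.5), var = (1 + 0.25 + 0.5) / 0.75)
  )
  for (s in specs) {
    x <- simulate_arma(s$spec, 1e6, seed = 1)$value
    expect_equal(var(x), s$var, tolerance = 0.02)
    expect_equal(var(x), stationary_variance(s$spec), tolerance = 0.02)
  }
})

test_that("sample ACF of a long AR(1) draw follows the geometric law", {
  x <- simulate_arma(ar1_spec(0.95), 1e6, seed = 2)$value
  acf_hat <- sample_acf(x, max_lag = 10)
  expect_true(all(abs(acf_hat$acf - 0.95^(1:10)) < 0.01))
})

test_that("theoretical ACF matches closed forms and the general recursion", {
  expect_equal(theoretical_acf(ar1_spec(0.5), 3)$acf, c(0.5, 0.25, 0.125))
  ma <- theoretical_acf(ma1_spec(0.8), 5)
  expect_equal(ma$acf[1], 0.8 / (1 + 0.64))
  expect_equal(ma$acf[2:5], rep(0, 4))
  # special-case paths agree with the general recursion path
  for (spec in list(ar1_spec(0.7), ma1_spec(-0.4))) {
    expect_equal(theoretical_acf(spec, 8)$acf,
                 theoretical_acf(spec, 8, method = "recursion")$acf,
                 tolerance = 1e-12)
  }
})

test_that("MA(1) theoretical lag-1 ACF matches a long-simulation oracle", {
  # the simulation arbitrates the MA(1) lag-1 autocorrelation formula
  x <- simulate_arma(ma1_spec(0.8), 1e6, seed = 3)$value
  emp <- cor(x[-1], x[-length(x)])
  expect_equal(theoretical_acf(ma1_spec(0.8), 1)$acf, emp, tolerance = 0.01)
})

test_that("stationary variance handles the trivial and closed-form cases", {
  expect_equal(stationary_variance(iid_spec(2)), 4)
  expect_equal(stationary_variance(ar1_spec(0.8)), 1 / 0.36)
  expect_equal(stationary_variance(arma11_spec(0.5, 0.5)), 7 / 3)
  # general-order path agrees with the ARMA(1,1) closed form
  general <- noise_spec(ar = c(0.5, 0), ma = 0.5)
  expect_equal(stationary_variance(general), 7 / 3, tolerance = 1e-6)
})

test_that("Koyck weights are geometric and reproduce the AR(1) ACF", {
  expect_equal(koyck_ma_weights(0, 3), c(1, 0, 0))
  expect_equal(koyck_ma_weights(0.5, 4), c(1, 0.5, 0.25, 0.125))
  w <- koyck_ma_weights(0.9, 200)
  nu <- withr::with_seed(5L, rnorm(2e5))
  x <- as.numeric(stats::filter(nu, w, method = "convolution", sides = 1))
  x <- x[!is.na(x)]
  acf_hat <- sample_acf(x, max_lag = 5)
  expect_true(all(abs(acf_hat$acf - 0.9^(1:5)) < 0.02))
})

test_that("invalid specifications are rejected with clear errors", {
  expect_error(noise_spec(ar = 1.0), "stationary")
  expect_error(noise_spec(ar = c(0.5, 0.6)), "stationary")
  expect_error(noise_spec(sigma = 0), "sigma")
  expect_error(simulate_arma(ar1_spec(0.5), n = 0), "positive")
  expect_error(theoretical_acf(noise_spec(ar = 0.5, d = 1), 3), "differenced")
  expect_error(koyck_ma_weights(1, 5), "rho")
})

test_that("noise specifications round-trip through JSON", {
  spec <- arma11_spec(0.5, -0.3, sigma = 2.5)
  back <- noise_spec_from_json(noise_spec_to_json(spec))
  expect_equal(back$ar, spec$ar)
  expect_equal(back$ma, spec$ma)
  expect_equal(back$sigma, spec$sigma)
  expect_error(noise_spec_from_json('{"ar": [0.5], "rho": 1}'), "Unknown")
})
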