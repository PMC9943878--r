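test_that("split R-hat distinguishes mixed from separated chains", {
  expect_equal(rhat(matrix(5, nrow = 100, ncol = 3)), 1)
  mixed <- withr::with_seed(1L, matrix(rnorm(4000), ncol = 4))
  expect_lt(rhat(mixed), 1.01)
  sep <- withr::with_seed(2L, cbind(rnorm(1000, 0), rnorm(1000, 10)))
  expect_gt(rhat(sep), 1.5)
  expect_error(rhat(matrix(1:10, ncol = 1)), "two chains")
})

test_that("posterior summaries follow the stated quantile conventions", {
  fit <- structure(
    list(mode = "posterior",
         draws = tibble::tibble(.chain = 1, .iteration = 1:100, mu = as.numeric(1:100)),
         transform = list(names = "mu")),
    class = "odn_fit"
  )
  ps <- posterior_summary(fit)
  expect_equal(ps$median, 50.5)
  expect_equal(ps$q2.5, quantile(1:100, 0.025, names = FALSE))
  expect_equal(ps$q2.5, 3.475)
  expect_equal(ps$variance, var(1:100))
})

test_that("the sampler recovers a conjugate-style constant-mean posterior", {
  T_ <- 200; sigma <- 1
  y <- withr::with_seed(3L, rnorm(T_, mean = 4, sd = sigma))
  d <- tibble::tibble(time = seq_len(T_), value = y)
  fit <- run_mcmc(d, constant_model(), "iid",
                  priors = list(mu = prior_normal(0, 100),
                                sigma = prior_half_normal(10)),
                  chains = 4, iterations = 1000, seed = 4)
  # flat-ish prior: posterior for mu is ~ N(ybar, sigma^2 / T)
  post_sd <- sigma / sqrt(T_)
  expect_lt(abs(mean(fit$draws$mu) - mean(y)), 0.5 * post_sd)
  expect_equal(sd(fit$draws$mu), post_sd, tolerance = 0.3)
})

test_that("sampling is deterministic given the seed", {
  des <- study_design(n_obs = 100, seed = 5)
  d <- generate_dataset(des, 0.8, 1)
  f1 <- run_mcmc(d, logistic_model(), "ar1", chains = 2, iterations = 200, seed = 6)
  f2 <- run_mcmc(d, logistic_model(), "ar1", chains = 2, iterations = 200, seed = 6)
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior intervals under the matched AR(1) model cover truth", {
  des <- study_design(n_obs = 400, seed = 7)
  d <- generate_dataset(des, 0.8, 3)
  fit <- run_mcmc(d, logistic_model(), "ar1", chains = 4, iterations = 1000, seed = 8)
  ps <- posterior_summary(fit)
  r_row <- ps[ps$term == "r", ]
  expect_true(r_row$q2.5 <= 0.5 && 0.5 <= r_row$q97.5)
  k_row <- ps[ps$term == "kappa", ]
  expect_true(k_row$q2.5 <= 50 && 50 <= k_row$q97.5)
  # at moderate T the fitted trend absorbs some persistent noise, biasing
  # rho slightly low; require locality rather than exact coverage
  rho_row <- ps[ps$term == "rho", ]
  expect_lt(abs(rho_row$median - 0.8), 0.15)
})

test_that("empirical posterior VIRs satisfy identity and scaling laws", {
  des <- study_design(n_obs = 150, seed = 9)
  d <- generate_dataset(des, 0.8, 1)
  fit <- run_mcmc(d, logistic_model(), "ar1", chains = 2, iterations = 300, seed = 10)
  self <- empirical_vir(fit, fit, parameters = c("r", "kappa"))
  expect_equal(self$vir, c(1, 1))
  scaled <- fit
  scaled$draws <- dplyr::mutate(fit$draws, r = r * 3)
  expect_equal(empirical_vir(scaled, fit, parameters = "r")$vir, 9, tolerance = 1e-10)
  other <- fit
  other$model <- constant_model()
  expect_error(empirical_vir(fit, other), "do not match")
})

test_that("sampling the pre-sample error relaxes the conditioning", {
  d <- generate_dataset(study_design(n_obs = 300, seed = 2), 0.8, 1)
  fit <- run_mcmc(d, logistic_model(), "ar1", chains = 2, iterations = 400,
                  seed = 3, sample_presample_error = TRUE)
  expect_true("eps0" %in% names(fit$draws))
  ps <- posterior_summary(fit)
  r_row <- ps[ps$term == "r", ]
  expect_true(r_row$q2.5 <= 0.5 && 0.5 <= r_row$q97.5)
  expect_error(run_mcmc(d, logistic_model(), "iid", sample_presample_error = TRUE),
               "AR\\(1\\)")
})

test_that("tidy and glance expose fit summaries consistently", {
  des <- study_design(n_obs = 150, seed = 11)
  d <- generate_dataset(des, 0.8, 1)
  fit <- fit_point_estimate(d, logistic_model(), "ar1", seed = 12)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "lower", "upper"))
  expect_true(all(td$lower <= td$estimate & td$estimate <= td$upper))
  gl <- glance(fit)
  expect_equal(gl$AIC, 2 * 5 - 2 * fit$loglik)
})
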