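test_that("split R-hat separates mixed from unmixed chains", {
  x <- matrix(rep(rnorm(500), 3), ncol = 3)
  expect_equal(rhat(x), 1, tolerance = 0.01)
  set.seed(41)
  shifted <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(rhat(shifted), 1.5)
  iid <- matrix(rnorm(30000), ncol = 3)
  expect_lte(rhat(iid), 1.01)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("effective sample size tracks autocorrelation", {
  set.seed(42)
  n <- 20000
  iid <- matrix(rnorm(n), ncol = 1)
  expect_equal(ess(iid), n, tolerance = 0.1)
  # AR(1): ESS ~= n (1 - rho) / (1 + rho)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), n))
  expect_equal(ess(matrix(ar, ncol = 1)), n * (1 - rho) / (1 + rho),
               tolerance = 0.3)
  expect_equal(ess(matrix(rep(3.2, 500), ncol = 1)), 0)
})

test_that("chain initialization respects supports and the jitter contract", {
  sim <- generate_dataset(scenario_presets("small_test"), seed = 8)
  arr <- as_survey_arrays(sim$data)
  pr <- prior_config()
  set.seed(43)
  init0 <- init_chain(pr, arr, jitter = 0)
  expect_equal(init0$r_f, pr$rf$mean)
  expect_equal(init0$m, 0.5)
  i1 <- init_chain(pr, arr); i2 <- init_chain(pr, arr)
  expect_false(identical(i1$r_f, i2$r_f))
  for (k in 1:100) {
    init <- init_chain(pr, arr)
    expect_true(all(init$s > 0 & init$s < 1))
    expect_true(init$m > 0 && init$m < 1)
    expect_true(init$r_f > 0)
    expect_true(init$K_f > pr$K_f_range[1] && init$K_f < pr$K_f_range[2])
    expect_true(sqrt(init$sigma_p2) < pr$sigma_p_range[2])
    expect_true(all(init$d1 > 0))
    expect_equal(rowSums(init$gamma), rep(1, 3))
    expect_true(all(is.finite(init$logn)))
  }
})

test_that("fits are bit-reproducible given the seed", {
  sim <- generate_dataset(scenario_presets("small_test"), seed = 9)
  cfg <- mcmc_config(n_chains = 2, n_burnin = 200, n_samples = 300, seed = 99)
  f1 <- fit_mcmc(sim$data, cfg)
  f2 <- fit_mcmc(sim$data, cfg)
  expect_identical(f1$scalars, f2$scalars)
  expect_identical(f1$logn, f2$logn)
  f3 <- fit_mcmc(sim$data, mcmc_config(n_chains = 2, n_burnin = 200,
                                       n_samples = 300, seed = 100))
  expect_false(identical(f1$scalars, f3$scalars))
})

test_that("with vague data the posterior reproduces the priors", {
  # weak likelihood: huge density SEs, no classified animals
  parks <- data.frame(park_id = c("A", "B"), area_km2 = c(10, 20))
  dens <- data.frame(park_id = rep(c("A", "B"), each = 4),
                     year = rep(2001:2004, 2),
                     density_per_km2 = 30, se = 1000)
  cls <- data.frame(park_id = rep(c("A", "B"), each = 4),
                    year = rep(2001:2004, 2),
                    n_juvenile = 0, n_female = 0, n_male = 0)
  dat <- survey_dataset(parks, dens, cls)
  pr <- prior_config()
  fit <- fit_mcmc(dat, mcmc_config(n_chains = 3, n_burnin = 2000,
                                   n_samples = 6000, seed = 5))
  sm <- summary(fit, pars = c("mu[1]", "mu[2]", "mu[3]", "m", "r_f"))
  lit <- literature_survival()
  expect_equal(sm$mean[1:3], lit$mean, tolerance = 0.1)
  expect_equal(sm$mean[sm$parameter == "m"], 0.5, tolerance = 0.01)
  expect_equal(sm$mean[sm$parameter == "r_f"], pr$rf$mean, tolerance = 0.05)
  # draws never leave support
  expect_true(all(draws_matrix(fit, "K_f") > 1 & draws_matrix(fit, "K_f") < 100))
  expect_true(all(draws_matrix(fit, "sigma_p2") < 4))
  expect_true(all(draws_matrix(fit, "m") > 0 & draws_matrix(fit, "m") < 1))
})

test_that("parameters are recovered when the truth is prior-consistent", {
  truth <- c(s1 = 0.67, s2 = 0.74, s3 = 0.39, m = 0.5, r_f = 1.56,
             K_f = 50, sigma_p2 = 0.5)
  des <- synthetic_design(vitals = do.call(vital_rates, as.list(unname(truth))))
  sim <- generate_dataset(des, seed = 201)
  fit <- fit_mcmc(sim$data, mcmc_config(n_chains = 3, n_burnin = 1000,
                                        n_samples = 2000, seed = 1))
  sm <- summary(fit, pars = c("mu[1]", "mu[2]", "mu[3]", "m", "r_f", "K_f",
                              "sigma_p2"))
  z <- abs(sm$median - truth) / sm$sd
  expect_true(all(z < 3))
  # data reduce uncertainty relative to the prior for the global scalars
  expect_lt(sm$sd[sm$parameter == "K_f"], sqrt(99^2 / 12))
  expect_lt(sm$sd[sm$parameter == "m"], 0.021)
})
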