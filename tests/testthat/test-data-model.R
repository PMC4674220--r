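test_that("classification proportions pool the two female stages", {
  expect_equal(unname(classification_proportions(c(1, 1, 0, 2))),
               c(0.25, 0.25, 0.5))
  expect_equal(unname(classification_proportions(c(0, 5, 0))), c(0, 1, 0))
  # sterile does are indistinguishable from fertile ones in the field
  expect_equal(classification_proportions(c(10, 20, 20, 50))[["female"]], 0.4)
  expect_equal(sum(classification_proportions(c(3, 9, 1, 7))), 1)
  expect_error(classification_proportions(c(0, 0, 0)), "positive")
})

test_that("multinomial log likelihood matches the factorial formula", {
  expect_equal(classification_loglik(c(0, 0, 0), 0, c(0.2, 0.3, 0.5)), 0)
  expect_equal(classification_loglik(c(1, 0, 0), 1, c(0.25, 0.25, 0.5)),
               log(0.25))
  expect_error(classification_loglik(c(3, 4, 5), 11, c(0.3, 0.3, 0.4)),
               "y_N")
  set.seed(31)
  for (k in 1:100) {
    y <- rpois(3, 20)
    p <- rgamma(3, 2); p <- p / sum(p)
    oracle <- lgamma(sum(y) + 1) - sum(lgamma(y + 1)) + sum(y * log(p))
    expect_equal(classification_loglik(y, sum(y), p), oracle,
                 tolerance = 1e-10)
  }
})

test_that("density log likelihood is Gaussian in the latent density", {
  n <- c(30, 50, 20); area <- 10; se <- 2
  at_mode <- density_loglik(sum(n) / area, se, n, area)
  expect_equal(at_mode, log(1 / (se * sqrt(2 * pi))))
  one_se_off <- density_loglik(sum(n) / area + se, se, n, area)
  expect_equal(at_mode - one_se_off, 0.5)
  expect_equal(density_loglik(NA, se, n, area), 0)
  set.seed(32)
  for (k in 1:100) {
    y <- runif(1, 0, 60); s <- runif(1, 0.5, 5); a <- runif(1, 2, 50)
    nn <- runif(3, 5, 300)
    expect_equal(density_loglik(y, s, nn, a),
                 dnorm(y, sum(nn) / a, s, log = TRUE), tolerance = 1e-10)
  }
  expect_error(density_loglik(10, -1, n, area), "positive")
})

test_that("initial state draws follow the Dirichlet/truncated-normal model", {
  set.seed(33)
  draws <- t(replicate(4e4, initial_state_draw(c(10, 20, 10), 30, 3, 12)$gamma))
  expect_equal(unname(colMeans(draws)), c(11, 21, 11) / 43, tolerance = 0.01)
  # zero counts give a uniform Dirichlet
  u <- t(replicate(2e4, initial_state_draw(c(0, 0, 0), 30, 3, 12)$gamma))
  expect_equal(unname(colMeans(u)), rep(1 / 3, 3), tolerance = 0.01)
  # degenerate SE pins the density at the observation
  d <- initial_state_draw(c(5, 5, 5), 30, 1e-9, 12)
  expect_equal(d$d, 30, tolerance = 1e-6)
  expect_equal(sum(d$n), 30 * 12, tolerance = 1e-4)
  expect_true(all(replicate(200, initial_state_draw(c(1, 1, 1), 0.5, 2, 5)$d) >= 0))
  expect_error(initial_state_draw(c(1, 1, 1), NA, 2, 5), "year-1")
})

test_that("the joint log density is additive over observations", {
  sim <- generate_dataset(scenario_presets("small_test"), seed = 5)
  pr <- prior_config()
  set.seed(34)
  st <- random_state(as_survey_arrays(sim$data))
  lp_full <- joint_log_density(st$params, st$logn, sim$data, pr)
  expect_true(is.finite(lp_full))
  # removing one (non-initial-year) park-year of density data changes the
  # value by exactly that observation's log likelihood
  drop <- sim$data
  r <- 9
  arr <- as_survey_arrays(sim$data)
  i <- match(drop$density$park_id[r], arr$park_id)
  t <- match(drop$density$year[r], arr$years)
  term <- density_loglik(arr$yd[i, t], arr$se[i, t], exp(st$logn[i, t, ]),
                         arr$area[i])
  drop$density <- drop$density[-r, ]
  expect_equal(joint_log_density(st$params, st$logn, drop, pr),
               lp_full - term, tolerance = 1e-8)
})

test_that("compiled and reference joint densities agree", {
  sim <- generate_dataset(scenario_presets("small_test"), seed = 6)
  arr <- as_survey_arrays(sim$data)
  pr <- prior_config()
  inp <- deerforecast:::sampler_inputs(sim$data, pr)
  set.seed(35)
  for (k in 1:20) {
    st <- random_state(arr)
    state <- c(st$params, list(logn = as.numeric(st$logn)))
    lpR <- joint_log_density(st$params, st$logn, sim$data, pr)
    lpC <- deerforecast:::joint_lp_cpp(inp$data, inp$priors, state)
    expect_equal(lpC, lpR, tolerance = 1e-9)
  }
})

test_that("survey dataset validation names the offending rows", {
  sim <- generate_dataset(scenario_presets("small_test"), seed = 7)
  d <- sim$data
  bad <- d$density; bad$se[3] <- -1
  expect_error(survey_dataset(d$parks, bad, d$classification), "row\\(s\\): 3")
  badc <- d$classification; badc$n_female[2] <- -4
  expect_error(survey_dataset(d$parks, d$density, badc), "row\\(s\\): 2")
  expect_error(survey_dataset(d$parks[, "park_id", drop = FALSE], d$density,
                              d$classification), "area_km2")
  badp <- d$density; badp$park_id[1] <- "NOPE"
  expect_error(survey_dataset(d$parks, badp, d$classification), "NOPE")
})
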