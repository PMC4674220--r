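test_that("objective probabilities count draws below/within/above the band", {
  fake <- function(dens) structure(
    list(density = matrix(dens, ncol = 1), horizon = 1,
         park_density = array(dens, c(length(dens), 1, 1)),
         treated = array(0, c(length(dens), 1, 1)), park_id = "P01",
         states = NULL, plan = list(treatment_spec("none"))),
    class = "forecast_ensemble")
  obj <- management_objective(5, 15, horizon = 1)
  expect_equal(objective_probabilities(fake(rep(10, 50)), obj),
               c(p_below = 0, p_in = 1, p_above = 0))
  expect_equal(objective_probabilities(fake(c(4, 10, 20)), obj),
               c(p_below = 1, p_in = 1, p_above = 1) / 3)
  # boundaries count as within
  expect_equal(objective_probabilities(fake(c(5, 15)), obj)[["p_in"]], 1)
  # brute-force counting oracle on random ensembles
  set.seed(71)
  for (k in 1:20) {
    dens <- runif(200, 0, 30)
    pr <- objective_probabilities(fake(dens), obj)
    expect_equal(pr[["p_below"]], sum(dens < 5) / 200)
    expect_equal(pr[["p_above"]], sum(dens > 15) / 200)
    expect_equal(sum(pr), 1)
  }
  expect_error(objective_probabilities(fake(c(1, 2)), obj, year = 3),
               "horizon")
})

test_that("net effect is the ratio of objective probabilities", {
  expect_equal(net_effect(0.5, 0.05), 10)
  expect_equal(net_effect(0.37, 0.37), 1)
  expect_equal(net_effect(0, 0.2), 0)
  expect_warning(ne <- net_effect(0.5, 0), "infinite")
  expect_identical(ne, Inf)
})

test_that("program cost multiplies counts by the per-doe rates", {
  expect_equal(program_cost(c(contracept1 = 12900)), 9675000)
  expect_equal(program_cost(c(cull = 3510)), 1298700)
  expect_equal(program_cost(c(contracept1 = 0)), 0)
  expect_equal(program_cost(c(cull = 3200, contracept1 = 680)),
               3200 * 370 + 680 * 750)
  expect_equal(program_cost(c(sterilize = 10), c(cull = 370, fertility = 800)),
               8000)
  expect_error(program_cost(c(cull = -1)), "non-negative")
})

test_that("a degenerate noiseless forecast equals repeated projection", {
  v <- reference_vitals(0)   # zero process variance
  n0 <- matrix(c(40, 60, 20, 100, 150, 50), 2, 3, byrow = TRUE)
  areas <- c(10, 25)
  draws <- make_degenerate_draws(v, n0, areas)
  ens <- forecast(draws, horizon = 4, treatment_spec("none"), max_draws = 1)
  # hand propagation
  for (i in 1:2) {
    n <- n0[i, ]
    for (y in 1:4) {
      f <- fecundity(v$r_f, v$K_f, sum(n) / areas[i])
      n <- project(build_projection_matrix(v, f), n)
      expect_equal(unname(ens$states[1, y, i, c(1, 2, 4)]), unname(n),
                   tolerance = 1e-10)
      expect_equal(ens$states[1, y, i, 3], 0)
    }
  }
  # regional density is total abundance over total area
  expect_equal(ens$density[1, 2],
               sum(ens$states[1, 2, , ]) / sum(areas))
})

test_that("treatment effort matches hand accounting on a two-year toy", {
  v <- reference_vitals(0)
  n0 <- matrix(c(40, 100, 20), 1, 3)
  draws <- make_degenerate_draws(v, n0, areas = 10)
  ens <- forecast(draws, horizon = 2, treatment_spec("sterilize", 0.3),
                  max_draws = 1)
  # year 1: 0.3 * 100 fertile does; survivors stay sterile, year 2 treats
  # only the remaining fertile class
  treated1 <- 0.3 * 100
  n1 <- c(40, 70, 30, 20)
  f1 <- fecundity(v$r_f, v$K_f, sum(n1) / 10)
  A <- build_treated_matrix(v, f1, treatment_spec("sterilize", 0.3))
  n2 <- project(A, n1)
  treated2 <- 0.3 * n2[["n2"]]
  expect_equal(ens$treated[1, 1, 1], treated1)
  expect_equal(ens$treated[1, 2, 1], treated2, tolerance = 1e-10)
  eff <- treatment_effort(ens)
  expect_equal(eff$total_median, treated1 + treated2, tolerance = 1e-10)
  # p = 0 means nothing is ever treated
  ens0 <- forecast(draws, horizon = 3, treatment_spec("sterilize", 0),
                   max_draws = 1)
  expect_equal(treatment_effort(ens0)$total_median, 0)
})

test_that("decision metrics respond to treatment intensity correctly", {
  cf <- cached_fit()
  obj <- management_objective(5, 15, horizon = 5)
  set.seed(72)
  med1 <- sapply(c(0, 0.3, 0.6, 0.9), function(p) {
    set.seed(72)
    ens <- forecast(cf$fit, horizon = 5,
                    plan = treatment_spec("cull", p), max_draws = 300)
    median(ens$density[, 1])
  })
  # year-1 median density never increases with the cull proportion
  expect_true(all(diff(med1) < 0))
  # probabilities always partition
  set.seed(73)
  ens <- forecast(cf$fit, horizon = 5, treatment_spec("cull", 0.4),
                  max_draws = 300)
  pr <- objective_probabilities(ens, obj)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  # culling and sterilization need similar numbers of does handled at equal
  # p (neither re-treats females: culled does are gone, sterile does are
  # marked); density-dependent recruitment keeps the two within a fraction
  # of each other rather than ordering them strictly
  set.seed(74)
  ens_cull <- forecast(cf$fit, 5, treatment_spec("cull", 0.4), max_draws = 200)
  set.seed(74)
  ens_st <- forecast(cf$fit, 5, treatment_spec("sterilize", 0.4),
                     max_draws = 200)
  e_cull <- treatment_effort(ens_cull)$total_median
  e_st <- treatment_effort(ens_st)$total_median
  expect_lt(abs(e_cull - e_st) / e_st, 0.25)
  # contracepted does revert and are re-treated, so contraception always
  # costs strictly more effort than sterilization at equal p
  set.seed(74)
  ens_c1 <- forecast(cf$fit, 5, treatment_spec("contracept1", 0.4),
                     max_draws = 200)
  expect_gt(treatment_effort(ens_c1)$total_median, e_st)
})

test_that("culling first reduces the fertility-control effort needed", {
  cf <- cached_fit()
  p <- 0.4
  set.seed(75)
  alone <- forecast(cf$fit, 5, treatment_spec("contracept1", p),
                    max_draws = 200)
  set.seed(75)
  combined <- forecast(cf$fit, 5, plan = list(
    treatment_spec("cull", p, years = 1),
    treatment_spec("contracept1", p, years = 2:5)), max_draws = 200)
  expect_lt(treatment_effort(combined)$total_median,
            treatment_effort(alone)$total_median)
})
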