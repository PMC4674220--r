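test_that("fecundity follows the exponential density-dependent form", {
  # exponent vanishes at D = K_f, reduces to exp(r_f) at D = 0
  expect_equal(fecundity(0.86, 27.12, 27.12), 1.0)
  expect_equal(fecundity(0.86, 27.12, 0), exp(0.86))
  expect_equal(fecundity(0.86, 27.12, 2 * 27.12), exp(-0.86))
  # scaled alternative peaks at r_f
  expect_equal(fecundity(0.86, 27.12, 0, form = "scaled"), 0.86)
  expect_equal(fecundity(0.86, 27.12, 27.12, form = "scaled"),
               0.86 * exp(-0.86))
  expect_error(fecundity(-1, 27.12, 0), "r_f")
  expect_error(fecundity(0.86, 0, 0), "K_f")
  expect_error(fecundity(0.86, 27.12, -5), "non-negative")
})

test_that("fecundity is positive and strictly decreasing in density", {
  for (form in c("ricker_exp", "scaled")) {
    d <- seq(0, 120, by = 0.5)
    f <- fecundity(1.2, 35, d, form = form)
    expect_true(all(f > 0))
    expect_true(all(diff(f) < 0))
  }
})

test_that("the 3-stage projection matrix has the Lefkovitch structure", {
  A <- build_projection_matrix(vital_rates(1 - 1e-12, 1 - 1e-12, 1 - 1e-12,
                                           0.5, 1, 1), f = 0)
  expect_equal(unname(A),
               matrix(c(0, 0, 0, 0.5, 1, 0, 0.5, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
  # hand products of the reference medians
  A <- build_projection_matrix(reference_vitals(), f = 0.86)
  expect_equal(A["n1", "n2"], 0.68 * 0.86)
  expect_equal(A["n2", "n1"], 0.76 * 0.53)
  expect_equal(A["n3", "n1"], 0.76 * 0.47)
  expect_true(all(A >= 0))
  # without recruitment the matrix is reducible: growth is max survival
  A0 <- build_projection_matrix(reference_vitals(), f = 0)
  expect_equal(dominant_eigenvalue(A0), 0.68)
})

test_that("projection is the matrix-vector product and is linear", {
  A <- build_projection_matrix(reference_vitals(), f = 0.86)
  expect_equal(unname(project(diag(3), c(3, 2, 1))), c(3, 2, 1))
  expect_equal(unname(project(A, c(100, 100, 100))),
               c(58.48, 108.28, 80.72), tolerance = 1e-12)
  n <- c(10, 20, 30)
  expect_equal(project(A, 2.5 * n), 2.5 * project(A, n))
  expect_error(project(A, c(1, 2)), "dimension mismatch")
})

test_that("treated matrix encodes sterile retention and reversion", {
  v <- reference_vitals()
  # sterile class is absorbing: its column is pure survival
  As <- build_treated_matrix(v, 0.86, treatment_spec("sterilize", 0.4))
  expect_equal(unname(As[, "n2s"]), c(0, 0, v$s2, 0))
  # fecundity applies only to the fertile-female column
  expect_equal(As["n1", "n2s"], 0)
  expect_equal(As["n1", "n2"], v$s2 * 0.86)
  # three-year contraceptive: survivors revert at rate 1/3, so the expected
  # effective duration is the geometric mean of 3 years
  A3 <- build_treated_matrix(v, 0.86, treatment_spec("contracept3", 0.4))
  expect_equal(A3["n2", "n2s"], v$s2 / 3)
  expect_equal(A3["n2s", "n2s"], v$s2 * 2 / 3)
  # one-year contraceptive reverts fully
  A1 <- build_treated_matrix(v, 0.86, treatment_spec("contracept1", 0.4))
  expect_equal(A1["n2", "n2s"], v$s2)
  expect_equal(A1["n2s", "n2s"], 0)
  expect_error(build_treated_matrix(v, 0.86, treatment_spec("none")), "none")
})

test_that("treatment events conserve or remove females as specified", {
  n <- c(50, 100, 10, 40)  # n1, n2, n2s, n3
  ev <- apply_treatment_event(n, treatment_spec("sterilize", 0.4))
  expect_equal(unname(ev$state), c(50, 60, 50, 40))
  expect_equal(ev$n_treated, 40)
  expect_equal(sum(ev$state[c("n2", "n2s")]), 110)  # females conserved
  ev <- apply_treatment_event(n, treatment_spec("cull", 1))
  expect_equal(unname(ev$state[c("n2", "n2s")]), c(0, 0))
  expect_equal(ev$n_treated, 110)
  ev <- apply_treatment_event(n, treatment_spec("cull", 0.25))
  expect_equal(unname(ev$state), c(50, 75, 7.5, 40))
  for (ty in c("cull", "sterilize", "contracept1", "contracept3")) {
    ev <- apply_treatment_event(n, treatment_spec(ty, 0))
    expect_equal(unname(ev$state), n)
    expect_equal(ev$n_treated, 0)
  }
  # juveniles and males are never touched
  ev <- apply_treatment_event(n, treatment_spec("contracept3", 0.9))
  expect_equal(unname(ev$state[c("n1", "n3")]), c(50, 40))
  expect_error(treatment_spec("cull", 1.2), "\\[0, 1\\]")
})

test_that("an untreated 4-stage system reproduces the 3-stage trajectories", {
  v <- reference_vitals()
  n3 <- c(120, 200, 90); n4 <- c(120, 200, 0, 90)
  area <- 10
  for (step in 1:8) {
    f <- fecundity(v$r_f, v$K_f, sum(n3) / area)
    expect_equal(fecundity(v$r_f, v$K_f, sum(n4) / area), f)
    n3 <- project(build_projection_matrix(v, f), n3)
    n4 <- project(build_treated_matrix(v, f, treatment_spec("contracept1", 0)),
                  n4)
    expect_equal(unname(n4[c(1, 2, 4)]), unname(n3))
    expect_equal(unname(n4[3]), 0)
  }
})

test_that("process noise is lognormal around the deterministic mean", {
  n_det <- c(80, 140, 60)
  expect_equal(add_process_noise(n_det, 0), n_det)
  set.seed(11)
  draws <- t(replicate(1e5, add_process_noise(n_det, 0.5)))
  expect_true(all(draws > 0))
  # lognormal median is the deterministic state
  expect_equal(unname(apply(draws, 2, median)), n_det, tolerance = 0.02)
  # log-scale mean and variance recover the stated parameters
  expect_equal(unname(colMeans(log(draws))), log(n_det), tolerance = 0.01)
  expect_equal(unname(apply(log(draws), 2, var)), rep(0.5, 3),
               tolerance = 0.02)
  expect_error(add_process_noise(c(1, NaN, 2), 0.1), "non-negative and finite")
})

test_that("long-run deterministic growth matches the dominant eigenvalue", {
  v <- reference_vitals()
  for (f in c(0.4, 0.86, 2.0)) {
    A <- build_projection_matrix(v, f)
    n <- c(100, 100, 100)
    for (k in 1:200) n <- project(A, n) / sum(project(A, n)) * sum(n)
    growth <- sum(project(A, n)) / sum(n)
    expect_equal(growth, dominant_eigenvalue(A), tolerance = 1e-6)
  }
})
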