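# Shared fixtures: reference vital rates, small random-state builders, and a
# lazily-computed cache of replicate fits reused across test files.

# posterior medians of the regional fit (used throughout as a realistic
# parameter set)
reference_vitals <- function(sigma_p2 = 0.5) {
  vital_rates(s1 = 0.76, s2 = 0.68, s3 = 0.45, m = 0.53,
              r_f = 0.86, K_f = 27.12, sigma_p2 = sigma_p2)
}

# random valid parameter set + latent field consistent with a survey array
random_state <- function(arr, priors = prior_config()) {
  I <- length(arr$area); T_ <- length(arr$years)
  s <- matrix(runif(3 * I, 0.2, 0.9), 3, I)
  a <- runif(3, 2, 10); b <- runif(3, 2, 10)
  gamma <- t(sapply(seq_len(I), function(i) {
    g <- rgamma(3, 2); g / sum(g)
  }))
  d1 <- runif(I, 10, 60)
  logn <- array(0, c(I, T_, 3))
  for (i in seq_len(I)) {
    logn[i, 1, ] <- log(d1[i] * gamma[i, ] * arr$area[i])
    if (T_ > 1)
      logn[i, 2:T_, ] <- log(matrix(runif((T_ - 1) * 3, 5, 500), T_ - 1, 3))
  }
  list(params = list(s = s, a = a, b = b, m = runif(1, 0.4, 0.6),
                     r_f = runif(1, 0.5, 2), K_f = runif(1, 10, 80),
                     sigma_p2 = runif(1, 0.1, 1),
                     gamma = gamma, d1 = d1),
       logn = logn)
}

# degenerate single-draw posterior object for deterministic forecast checks
make_degenerate_draws <- function(vitals, n_final, areas,
                                  priors = prior_config()) {
  I <- length(areas)
  stopifnot(is.matrix(n_final), nrow(n_final) == I, ncol(n_final) == 3)
  nms <- deerforecast:::scalar_names(I)
  scalars <- array(NA_real_, c(1, 1, length(nms)),
                   dimnames = list(NULL, NULL, nms))
  for (i in seq_len(I)) {
    scalars[1, 1, sprintf("s1[%d]", i)] <- vitals$s1
    scalars[1, 1, sprintf("s2[%d]", i)] <- vitals$s2
    scalars[1, 1, sprintf("s3[%d]", i)] <- vitals$s3
    scalars[1, 1, sprintf("d1[%d]", i)] <- sum(n_final[i, ]) / areas[i]
    for (j in 1:3)
      scalars[1, 1, sprintf("gamma[%d,%d]", i, j)] <-
        n_final[i, j] / sum(n_final[i, ])
  }
  scalars[1, 1, c("a[1]", "a[2]", "a[3]", "b[1]", "b[2]", "b[3]")] <- 5
  scalars[1, 1, c("mu[1]", "mu[2]", "mu[3]")] <-
    c(vitals$s1, vitals$s2, vitals$s3)
  scalars[1, 1, "m"] <- vitals$m
  scalars[1, 1, "r_f"] <- vitals$r_f
  scalars[1, 1, "K_f"] <- vitals$K_f
  scalars[1, 1, "sigma_p2"] <- vitals$sigma_p2
  logn <- array(0, c(1, 1, I, 1, 3))
  logn[1, 1, , 1, ] <- log(n_final)
  structure(list(scalars = scalars, logn = logn,
                 park_id = sprintf("P%02d", seq_len(I)),
                 years = 2013, area = areas,
                 config = mcmc_config(n_chains = 1, n_burnin = 0,
                                      n_samples = 1),
                 priors = priors),
            class = "posterior_draws")
}

# replicate fits at the study conditions (paper-like synthetic data, reduced
# MCMC), shared by the recovery and calibration acceptance tests
.fit_cache <- new.env(parent = emptyenv())

replicate_fits <- function(n_rep = 20) {
  key <- paste0("fits", n_rep)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  out <- lapply(seq_len(n_rep), function(r) {
    sim <- generate_dataset(scenario_presets("paper_like"), seed = 1000 + r)
    fit <- fit_mcmc(sim$data,
                    mcmc_config(n_chains = 3, n_burnin = 1000,
                                n_samples = 2000, seed = r))
    list(sim = sim, fit = fit)
  })
  .fit_cache[[key]] <- out
  out
}

# one paper-like fit for the downstream-module tests
cached_fit <- function() {
  if (is.null(.fit_cache$single)) {
    sim <- generate_dataset(scenario_presets("paper_like"), seed = 42)
    fit <- fit_mcmc(sim$data,
                    mcmc_config(n_chains = 2, n_burnin = 1000,
                                n_samples = 2000, seed = 7))
    .fit_cache$single <- list(sim = sim, fit = fit)
  }
  .fit_cache$single
}

power_iteration_lambda <- function(A, iters = 200) {
  x <- rep(1, nrow(A))
  for (k in seq_len(iters - 1)) x <- A %*% x / sum(A %*% x)
  sum(A %*% x) / sum(x)
}
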