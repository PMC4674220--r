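#' Posterior sampling and convergence diagnostics
#'
#' The posterior over all scalar parameters and latent log-abundances is
#' sampled with an adaptive Metropolis-within-Gibbs scheme: scalar random
#' walks on transformed scales (logit for probabilities and interval-bounded
#' parameters, log for positive ones) and elementwise updates of the latent
#' log states, with proposal scales adapted toward 44% acceptance during
#' burn-in only. The compiled core lives in `src/sampler.cpp`.
#'
#' @name inference
NULL

#' MCMC configuration
#'
#' Defaults mirror the study design: 3 chains, 40,000 retained samples per
#' chain after 8,000 burn-in iterations, no thinning. Tests and the
#' analysis scripts use reduced settings.
#'
#' @param n_chains Number of chains (>= 1; >= 2 for R-hat).
#' @param n_burnin Burn-in iterations per chain (adaptation happens here).
#' @param n_samples Post-burn-in iterations per chain.
#' @param thin Keep every `thin`-th draw.
#' @param seed Integer seed; fully determines the run.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 8000, n_samples = 40000,
                        thin = 1, seed = 1) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_samples >= thin, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_samples = as.integer(n_samples),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

# flatten a survey dataset + priors into the lists the compiled code expects
sampler_inputs <- function(data, priors) {
  arr <- if (inherits(data, "survey_dataset")) as_survey_arrays(data) else data
  hp <- priors$survival
  list(
    arr = arr,
    data = list(I = length(arr$area), T = length(arr$years), area = arr$area,
                yd = as.numeric(arr$yd), se = as.numeric(arr$se),
                counts = as.numeric(arr$counts), yN = as.numeric(arr$yN)),
    priors = list(a_shape = hp$a_shape, a_rate = hp$a_rate,
                  b_shape = hp$b_shape, b_rate = hp$b_rate,
                  m_a = priors$m_a, m_b = priors$m_b,
                  rf_mean = priors$rf$mean, rf_sd = priors$rf$sd,
                  Kf_lo = priors$K_f_range[1], Kf_hi = priors$K_f_range[2],
                  sp_lo = priors$sigma_p_range[1],
                  sp_hi = priors$sigma_p_range[2],
                  fec_form = if (priors$fecundity_form == "ricker_exp") 0L else 1L)
  )
}

#' Initialize one chain
#'
#' Scalar parameters start at their prior means jittered multiplicatively
#' (lognormal jitter of scale `jitter`, clamped to support); initial stage
#' states come from the year-1 data model and are then propagated
#' deterministically through the projection.
#'
#' @param priors A [prior_config()].
#' @param data A [survey_dataset()] or [as_survey_arrays()] result.
#' @param jitter Overdispersion scale; 0 gives exactly the prior means.
#' @return A named list of initial values (shape expected by the sampler).
#' @export
init_chain <- function(priors, data, jitter = 0.2) {
  arr <- if (inherits(data, "survey_dataset")) as_survey_arrays(data) else data
  I <- length(arr$area); T_ <- length(arr$years)
  hp <- priors$survival
  jit <- function(x) x * exp(stats::rnorm(length(x), 0, jitter))
  clamp01 <- function(x) pmin(pmax(x, 0.02), 0.98)
  a <- jit(hp$a_star); b <- jit(hp$b_star)
  s <- matrix(clamp01(rep(hp$a_star / (hp$a_star + hp$b_star), I) *
                        exp(stats::rnorm(3 * I, 0, jitter / 2))), 3, I)
  m <- clamp01(jit(priors$m_a / (priors$m_a + priors$m_b)))
  r_f <- jit(priors$rf$mean)
  K_f <- min(max(jit(mean(priors$K_f_range)), priors$K_f_range[1] * 1.01),
             priors$K_f_range[2] * 0.99)
  sp_mid <- mean(priors$sigma_p_range)
  sp <- min(max(jit(sp_mid), priors$sigma_p_range[1] + 0.01),
            priors$sigma_p_range[2] * 0.99)
  gamma <- matrix(0, I, 3); d1 <- numeric(I)
  logn <- array(0, c(I, T_, 3))
  for (i in seq_len(I)) {
    cts <- arr$counts[i, 1, ]
    g <- (cts + 1) / sum(cts + 1)
    d <- if (arr$obs_density[i, 1]) arr$yd[i, 1] else 30
    d <- max(jit(d), 0.5)
    gamma[i, ] <- g; d1[i] <- d
    n <- pmax(d * g * arr$area[i], 1e-3)
    logn[i, 1, ] <- log(n)
    vit <- vital_rates(s[1, i], s[2, i], s[3, i], m, r_f, K_f, 0)
    for (t in seq_len(T_ - 1)) {
      f <- fecundity(r_f, K_f, sum(n) / arr$area[i], priors$fecundity_form)
      n <- pmax(project(build_projection_matrix(vit, f), n), 1e-3)
      logn[i, t + 1, ] <- log(n)
    }
  }
  list(s = s, a = a, b = b, m = m, r_f = r_f, K_f = K_f, sigma_p2 = sp^2,
       gamma = gamma, d1 = d1, logn = as.numeric(logn))
}

scalar_names <- function(I) {
  c(as.vector(t(outer(1:I, 1:3, function(i, j) sprintf("s%d[%d]", j, i)))),
    sprintf("a[%d]", 1:3), sprintf("b[%d]", 1:3), sprintf("mu[%d]", 1:3),
    "m", "r_f", "K_f", "sigma_p2",
    sprintf("d1[%d]", 1:I),
    sprintf("gamma[%d,%d]", rep(1:I, 3), rep(1:3, each = I)))
}

#' Fit the state-space model by MCMC
#'
#' @param data A [survey_dataset()].
#' @param config An [mcmc_config()].
#' @param priors A [prior_config()].
#' @return An object of class `posterior_draws`: `scalars` is an
#'   iteration x chain x parameter array, `logn` an iteration x chain x
#'   park x year x stage array of latent log abundances, plus the config,
#'   priors and data dimensions.
#' @export
fit_mcmc <- function(data, config = mcmc_config(), priors = prior_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  inp <- sampler_inputs(data, priors)
  I <- inp$data$I; T_ <- inp$data$T
  n_keep <- config$n_samples %/% config$thin
  nms <- scalar_names(I)
  scalars <- array(NA_real_, c(n_keep, config$n_chains, length(nms)),
                   dimnames = list(NULL, NULL, nms))
  logn <- array(NA_real_, c(n_keep, config$n_chains, I, T_, 3))
  set.seed(config$seed)
  for (ch in seq_len(config$n_chains)) {
    init <- init_chain(priors, inp$arr, jitter = 0.2)
    res <- run_chain_cpp(inp$data, inp$priors, init,
                         config$n_burnin, config$n_samples, config$thin)
    if (!is.finite(res$final_lp))
      stop("non-finite joint density at end of chain ", ch, call. = FALSE)
    scalars[, ch, ] <- res$scalars
    logn[, ch, , , ] <- array(res$logn, c(I, T_, 3, n_keep))[, , ,
                                                             seq_len(n_keep),
                                                             drop = FALSE] |>
      aperm(c(4, 1, 2, 3))
  }
  structure(list(scalars = scalars, logn = logn,
                 park_id = inp$arr$park_id, years = inp$arr$years,
                 area = inp$arr$area, config = config, priors = priors),
            class = "posterior_draws")
}

#' Extract an iteration x chain matrix for one scalar parameter
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name, e.g. `"K_f"`, `"mu[2]"`, `"s2[3]"`.
#' @return Numeric matrix (iterations x chains).
#' @export
draws_matrix <- function(draws, parameter) {
  stopifnot(inherits(draws, "posterior_draws"))
  nms <- dimnames(draws$scalars)[[3]]
  if (!parameter %in% nms)
    stop("unknown parameter: ", parameter, call. = FALSE)
  draws$scalars[, , parameter, drop = TRUE] |>
    matrix(nrow = dim(draws$scalars)[1])
}

#' Posterior summary of the scalar parameters
#'
#' @param object A `posterior_draws` object.
#' @param pars Optional character vector of parameter names.
#' @param ... Unused.
#' @return Data frame with median, mean, sd, 2.5% and 97.5% quantiles and
#'   split R-hat per parameter.
#' @export
summary.posterior_draws <- function(object, pars = NULL, ...) {
  nms <- dimnames(object$scalars)[[3]]
  if (!is.null(pars)) nms <- intersect(pars, nms)
  out <- lapply(nms, function(p) {
    x <- draws_matrix(object, p)
    data.frame(parameter = p, mean = mean(x), median = stats::median(x),
               sd = stats::sd(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               rhat = if (ncol(x) >= 2) rhat(x) else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$scalars)
  cat(sprintf("posterior_draws: %d iterations x %d chains, %d scalar parameters, %d parks x %d years\n",
              d[1], d[2], d[3], length(x$park_id), length(x$years)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic split-chain R-hat (each chain is split in half, so the statistic
#' is sensitive to trends within chains as well as disagreement between
#' them). This is the non-rank-normalized variant.
#'
#' @param x Iterations x chains matrix of draws (>= 2 chains).
#' @param parameter Optional parameter name when `x` is a
#'   `posterior_draws` object.
#' @return R-hat (>= ~1; 1 indicates convergence).
#' @export
rhat <- function(x, parameter = NULL) {
  if (inherits(x, "posterior_draws")) x <- draws_matrix(x, parameter)
  x <- as.matrix(x)
  if (ncol(x) < 2)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  n <- nrow(x) %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(c)
    cbind(x[seq_len(n), c], x[n + seq_len(n), c])))
  if (stats::var(as.numeric(halves)) == 0) return(1)
  W <- mean(apply(halves, 2, stats::var))
  B <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS using Geyer's initial positive sequence: the
#' sum of autocovariances is truncated at the first negative pair. Chains
#' are combined by summing their individual ESS values. A constant chain
#' is degenerate and returns 0.
#'
#' @inheritParams rhat
#' @return Effective number of independent draws (<= total draws).
#' @export
ess <- function(x, parameter = NULL) {
  if (inherits(x, "posterior_draws")) x <- draws_matrix(x, parameter)
  x <- as.matrix(x)
  ess1 <- function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(0)
    rho <- stats::acf(v, lag.max = min(n - 1, 1000),
                      plot = FALSE, demean = TRUE)$acf[-1]
    tau <- 1; k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      tau <- tau + 2 * pair
      k <- k + 2
    }
    min(n, n / tau)
  }
  sum(apply(x, 2, ess1))
}
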