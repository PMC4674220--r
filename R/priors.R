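#' Prior and hyperprior construction
#'
#' Survival probabilities for each park are drawn from class-specific beta
#' distributions whose shape parameters get gamma hyperpriors centred, by
#' moment matching, on a meta-analysis of published survival rates. The
#' juvenile sex ratio has a tight beta prior around 1:1, and maximum
#' fecundity has a normal prior from an allometric scaling of Artiodactyl
#' birth rate with body mass.
#'
#' @name priors
NULL

#' Moment-match a beta distribution
#'
#' Returns shape parameters `(a, b)` such that `Beta(a, b)` has the given
#' mean and standard deviation.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
beta_moment_match <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1)
    stop("`mean` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0 || sd^2 >= mean * (1 - mean))
    stop("infeasible sd: need 0 < sd^2 < mean * (1 - mean)", call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Moment-match a gamma distribution
#'
#' Returns `(shape, rate)` such that `Gamma(shape, rate)` has the given
#' mean and standard deviation: `shape = mean^2 / sd^2`,
#' `rate = mean / sd^2`.
#'
#' @param mean,sd Positive numbers.
#' @return Named numeric vector `c(shape = , rate = )`.
#' @export
gamma_moment_match <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0 || !is.numeric(sd) || sd <= 0)
    stop("`mean` and `sd` must be positive", call. = FALSE)
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Allometric prior for maximum fecundity
#'
#' Prior mean `2 * 3.09 * w^(-0.33)` offspring per female (the allometric
#' birth-rate scaling for Artiodactyls is per individual, so it is doubled),
#' with fixed residual standard error 0.1304.
#'
#' @param body_mass_kg Mean female body mass in kg (default 65 for
#'   white-tailed deer).
#' @return List with `mean` and `sd` of the normal prior on `r_f`.
#' @export
rf_prior <- function(body_mass_kg = 65) {
  if (!is.numeric(body_mass_kg) || body_mass_kg <= 0)
    stop("`body_mass_kg` must be positive", call. = FALSE)
  list(mean = 2 * 3.09 * body_mass_kg^(-0.33), sd = 0.1304)
}

#' Literature summaries of annual survival by stage class
#'
#' Means and standard deviations of published survival probabilities for
#' juvenile, adult female and adult male white-tailed deer, used to centre
#' the survival hyperpriors.
#'
#' @return Data frame with columns `class`, `mean`, `sd`.
#' @export
literature_survival <- function() {
  data.frame(
    class = c("juvenile", "female", "male"),
    mean  = c(0.67, 0.74, 0.39),
    sd    = c(0.20, 0.14, 0.19)
  )
}

#' Gamma hyperprior settings for the survival beta shapes
#'
#' Each class's literature mean/SD is moment-matched to beta shapes
#' `(a*_j, b*_j)`; the gamma hyperpriors on `a_j` and `b_j` are centred
#' there with SD `hyper_cv` times the centre.
#'
#' @param lit Data frame as returned by [literature_survival()].
#' @param hyper_cv Coefficient of variation of the hyperpriors (> 0).
#' @return Data frame with one row per class: the beta centres `a_star`,
#'   `b_star` and the gamma `(shape, rate)` pairs for `a_j` and `b_j`.
#' @export
survival_hyperpriors <- function(lit = literature_survival(), hyper_cv = 0.5) {
  stopifnot(is.data.frame(lit), all(c("class", "mean", "sd") %in% names(lit)))
  if (!is.numeric(hyper_cv) || hyper_cv <= 0)
    stop("`hyper_cv` must be positive", call. = FALSE)
  out <- lapply(seq_len(nrow(lit)), function(k) {
    ab <- beta_moment_match(lit$mean[k], lit$sd[k])
    ga <- gamma_moment_match(ab[["a"]], hyper_cv * ab[["a"]])
    gb <- gamma_moment_match(ab[["b"]], hyper_cv * ab[["b"]])
    data.frame(class = lit$class[k],
               a_star = ab[["a"]], b_star = ab[["b"]],
               a_shape = ga[["shape"]], a_rate = ga[["rate"]],
               b_shape = gb[["shape"]], b_rate = gb[["rate"]])
  })
  do.call(rbind, out)
}

#' Assemble the full prior configuration
#'
#' @param lit Literature survival summaries; see [literature_survival()].
#' @param hyper_cv Hyperprior coefficient of variation.
#' @param m_mean,m_sd Mean and SD of the juvenile sex-ratio beta prior
#'   (defaults moment-match to Beta(312, 312)).
#' @param body_mass_kg Body mass for the allometric fecundity prior.
#' @param K_f_range Uniform prior bounds for `K_f` (deer/km^2).
#' @param sigma_p_range Uniform prior bounds for the process SD
#'   `sigma_p` (log scale).
#' @param fecundity_form See [fecundity()].
#' @return A list of class `prior_config`.
#' @export
prior_config <- function(lit = literature_survival(), hyper_cv = 0.5,
                         m_mean = 0.5, m_sd = 0.02, body_mass_kg = 65,
                         K_f_range = c(1, 100), sigma_p_range = c(0, 2),
                         fecundity_form = c("ricker_exp", "scaled")) {
  fecundity_form <- match.arg(fecundity_form)
  stopifnot(length(K_f_range) == 2L, K_f_range[1] < K_f_range[2],
            K_f_range[1] > 0,
            length(sigma_p_range) == 2L, sigma_p_range[1] >= 0,
            sigma_p_range[1] < sigma_p_range[2])
  m_ab <- beta_moment_match(m_mean, m_sd)
  structure(list(
    survival = survival_hyperpriors(lit, hyper_cv),
    m_a = m_ab[["a"]], m_b = m_ab[["b"]],
    rf = rf_prior(body_mass_kg),
    K_f_range = K_f_range,
    sigma_p_range = sigma_p_range,
    fecundity_form = fecundity_form
  ), class = "prior_config")
}

#' Log prior density of the model's scalar parameters
#'
#' Sums the log densities of the park survival probabilities (beta, given
#' the hyper shapes), the gamma hyperpriors, the sex ratio, maximum
#' fecundity, and the uniform priors for `K_f` and `sigma_p`. Returns
#' `-Inf` for any parameter outside its support.
#'
#' @param params A parameter list as used by the sampler: `s` (3 x n_parks
#'   matrix, rows juvenile/female/male), `a`, `b` (length-3), `m`, `r_f`,
#'   `K_f`, `sigma_p2`.
#' @param priors A [prior_config()].
#' @return A single numeric log density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors = prior_config()) {
  stopifnot(inherits(priors, "prior_config"))
  s <- params$s; a <- params$a; b <- params$b
  sp <- sqrt(params$sigma_p2)
  if (any(a <= 0) || any(b <= 0) || any(s <= 0) || any(s >= 1) ||
      params$r_f <= 0 ||
      params$m <= 0 || params$m >= 1 ||
      params$K_f < priors$K_f_range[1] || params$K_f > priors$K_f_range[2] ||
      sp < priors$sigma_p_range[1] || sp > priors$sigma_p_range[2])
    return(-Inf)
  hp <- priors$survival
  lp <- 0
  for (j in 1:3) {
    lp <- lp + sum(stats::dbeta(s[j, ], a[j], b[j], log = TRUE)) +
      stats::dgamma(a[j], hp$a_shape[j], hp$a_rate[j], log = TRUE) +
      stats::dgamma(b[j], hp$b_shape[j], hp$b_rate[j], log = TRUE)
  }
  lp <- lp + stats::dbeta(params$m, priors$m_a, priors$m_b, log = TRUE) +
    stats::dnorm(params$r_f, priors$rf$mean, priors$rf$sd, log = TRUE) +
    stats::dunif(params$K_f, priors$K_f_range[1], priors$K_f_range[2], log = TRUE) +
    stats::dunif(sp, priors$sigma_p_range[1], priors$sigma_p_range[2], log = TRUE)
  lp
}
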