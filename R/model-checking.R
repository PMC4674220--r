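#' Posterior predictive checking
#'
#' Goodness of fit is assessed with a Bayesian P-value on the squared
#' discrepancy between observed densities and the model-predicted density
#' for each surveyed park-year. For each retained posterior draw the
#' discrepancy is computed for the observed data (`T_obs`) and for a
#' replicated dataset drawn from the observation model (`T_rep`); values of
#' `P_B = Pr(T_rep >= T_obs)` near 0 or 1 indicate lack of fit.
#'
#' @name model_checking
NULL

#' Posterior predictive Bayesian P-value
#'
#' Per draw, the predicted density is the latent total abundance over park
#' area; replicated observations are drawn from
#' `Normal(mu_it, se_it^2)` with the survey's plug-in standard errors.
#' Missing park-years are skipped symmetrically in both sums.
#'
#' @param draws A `posterior_draws` object from [fit_mcmc()].
#' @param data The [survey_dataset()] to check against (usually the one the
#'   model was fitted to).
#' @param max_draws Cap on the number of posterior draws used (draws are
#'   thinned evenly); `Inf` uses all.
#' @return A list of class `ppc_result` with `T_obs`, `T_rep` (one pair per
#'   draw used) and `P_B`.
#' @export
posterior_predictive_pvalue <- function(draws, data, max_draws = 2000) {
  stopifnot(inherits(draws, "posterior_draws"))
  arr <- if (inherits(data, "survey_dataset")) as_survey_arrays(data) else data
  if (!all(dim(arr$yd) == c(length(draws$park_id), length(draws$years))))
    stop("data dimensions do not match the fitted draws", call. = FALSE)
  obs <- which(arr$obs_density)           # linear indices into I x T
  if (!length(obs)) stop("no density observations to check", call. = FALSE)
  d <- dim(draws$logn)                    # keep, chain, I, T, 3
  total <- d[1] * d[2]
  use <- unique(round(seq(1, total, length.out = min(total, max_draws))))
  area_mat <- matrix(draws$area, d[3], d[4])
  T_obs <- T_rep <- numeric(length(use))
  for (k in seq_along(use)) {
    it <- (use[k] - 1) %% d[1] + 1
    ch <- (use[k] - 1) %/% d[1] + 1
    n_tot <- apply(exp(draws$logn[it, ch, , , , drop = FALSE]), c(3, 4), sum)
    mu <- (n_tot / area_mat)[obs]
    y <- arr$yd[obs]; se <- arr$se[obs]
    T_obs[k] <- sum((y - mu)^2)
    y_rep <- stats::rnorm(length(mu), mu, se)
    T_rep[k] <- sum((y_rep - mu)^2)
  }
  structure(list(T_obs = T_obs, T_rep = T_rep,
                 P_B = mean(T_rep >= T_obs), n_draws = length(use)),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("posterior predictive check: P_B = %.3f over %d draws (near 0 or 1 flags lack of fit)\n",
              x$P_B, x$n_draws))
  invisible(x)
}

#' Export a PPC discrepancy table
#'
#' @param x A `ppc_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ppc <- function(x, path) {
  stopifnot(inherits(x, "ppc_result"))
  utils::write.csv(data.frame(T_obs = x$T_obs, T_rep = x$T_rep),
                   path, row.names = FALSE)
  invisible(path)
}
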