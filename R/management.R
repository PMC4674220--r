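#' Forecasting under management and decision metrics
#'
#' Future states are drawn from the posterior predictive process
#' distribution: each retained posterior draw contributes one trajectory,
#' propagated forward from that draw's final-year latent states with that
#' draw's parameters, treatment events applied immediately after each
#' census, and lognormal process noise added each year. Decision metrics
#' summarize the ensemble against a density objective.
#'
#' @name management
NULL

#' A management objective on population density
#'
#' @param lower,upper Density bounds in deer/km^2 (`0 <= lower < upper`).
#' @param horizon Evaluation horizon in years (default 5).
#' @param scope `"regional"` (pooled density = total abundance over total
#'   area) or `"park"`.
#' @return List of class `management_objective`.
#' @export
management_objective <- function(lower = 5, upper = 15, horizon = 5,
                                 scope = c("regional", "park")) {
  scope <- match.arg(scope)
  stopifnot(lower >= 0, lower < upper, horizon >= 1)
  structure(list(lower = lower, upper = upper, horizon = as.integer(horizon),
                 scope = scope), class = "management_objective")
}

plan_as_list <- function(plan) {
  if (inherits(plan, "treatment_spec")) plan <- list(plan)
  stopifnot(all(vapply(plan, inherits, TRUE, "treatment_spec")))
  plan
}

# reversion rate of the treated-female class implied by a plan (at most one
# fertility-control type may appear in a plan)
plan_reversion <- function(plan) {
  fert <- unique(vapply(plan, function(x) x$type, ""))
  fert <- setdiff(fert, c("none", "cull"))
  if (length(fert) > 1)
    stop("a treatment plan may contain at most one fertility-control type",
         call. = FALSE)
  if (length(fert) == 0) 0 else reversion_rate(fert)
}

#' Posterior predictive forecast under a treatment plan
#'
#' @param draws A `posterior_draws` object from [fit_mcmc()].
#' @param horizon Number of forecast years (>= 1).
#' @param plan A [treatment_spec()] or a list of them; each spec's `years`
#'   (default all) selects the forecast years in which it is applied.
#'   Treatments are applied immediately after census, before projection,
#'   and fecundity uses the post-treatment density.
#' @param max_draws Cap on the posterior draws used (thinned evenly).
#' @param process_noise Set `FALSE` for the deterministic skeleton
#'   (process variance forced to zero).
#' @return A list of class `forecast_ensemble`: `states` (draw x year x
#'   park x 4 stages, years 1..horizon), `density` (draw x year regional
#'   density), `park_density` (draw x year x park), `treated` (draw x
#'   year x park newly treated or culled females).
#' @export
forecast <- function(draws, horizon = 5, plan = treatment_spec("none"),
                     max_draws = 1000, process_noise = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (horizon < 1) stop("`horizon` must be at least 1", call. = FALSE)
  plan <- plan_as_list(plan)
  rev_type <- plan_reversion(plan)
  fert_type <- if (rev_type == 1) "contracept1" else
    if (rev_type == 0) "sterilize" else "contracept3"
  form <- draws$priors$fecundity_form
  d <- dim(draws$logn)                 # keep, chain, I, T, 3
  I <- d[3]; T_ <- d[4]
  total <- d[1] * d[2]
  use <- unique(round(seq(1, total, length.out = min(total, max_draws))))
  nd <- length(use)
  area <- draws$area
  scal <- function(p) as.numeric(draws_matrix(draws, p))[use]
  s <- lapply(1:3, function(j)
    matrix(vapply(seq_len(I), function(i) scal(sprintf("s%d[%d]", j, i)),
                  numeric(nd)), nrow = nd))
  m <- scal("m"); rf <- scal("r_f"); Kf <- scal("K_f")
  sp2 <- if (process_noise) scal("sigma_p2") else rep(0, nd)
  states <- array(0, c(nd, horizon, I, 4))
  treated <- array(0, c(nd, horizon, I))
  for (k in seq_len(nd)) {
    it <- (use[k] - 1) %% d[1] + 1
    ch <- (use[k] - 1) %/% d[1] + 1
    for (i in seq_len(I)) {
      n <- as_stage4(exp(draws$logn[it, ch, i, T_, ]))
      vit <- vital_rates(s[[1]][k, i], s[[2]][k, i], s[[3]][k, i],
                         m[k], rf[k], Kf[k], sp2[k])
      # matrix structure is fixed within a draw except for fecundity
      A <- build_treated_matrix(vit, 0, treatment_spec(fert_type, 0))
      for (y in seq_len(horizon)) {
        for (spec in plan) {
          if (is.null(spec$years) || y %in% spec$years) {
            ev <- apply_treatment_event(n, spec)
            n <- ev$state
            treated[k, y, i] <- treated[k, y, i] + ev$n_treated
          }
        }
        f <- fecundity(rf[k], Kf[k], sum(n) / area[i], form)
        A["n1", "n2"] <- vit$s2 * f
        n_det <- project(A, n)
        n <- as_stage4(add_process_noise(n_det, sp2[k]))
        states[k, y, i, ] <- n
      }
    }
  }
  totals <- apply(states, c(1, 2, 3), sum)          # draw x year x park
  structure(list(
    states = states,
    density = apply(totals, c(1, 2), sum) / sum(area),
    park_density = sweep(totals, 3, area, "/"),
    treated = treated, horizon = horizon, plan = plan,
    park_id = draws$park_id
  ), class = "forecast_ensemble")
}

#' Probability of being below, within, or above the objective
#'
#' Fractions of ensemble draws whose density at the evaluation year falls
#' below, within (boundaries inclusive) or above the objective band.
#'
#' @param ens A [forecast()] ensemble.
#' @param objective A [management_objective()].
#' @param year Evaluation year (default the objective horizon, capped at
#'   the ensemble horizon).
#' @return Named vector `c(p_below, p_in, p_above)` summing to 1.
#' @export
objective_probabilities <- function(ens, objective = management_objective(),
                                    year = NULL) {
  stopifnot(inherits(ens, "forecast_ensemble"),
            inherits(objective, "management_objective"))
  if (is.null(year)) year <- min(objective$horizon, ens$horizon)
  if (year < 1 || year > ens$horizon)
    stop("evaluation year outside the forecast horizon", call. = FALSE)
  dens <- if (objective$scope == "regional") ens$density[, year]
          else as.numeric(ens$park_density[, year, ])
  if (!length(dens)) stop("empty ensemble", call. = FALSE)
  p_below <- mean(dens < objective$lower)
  p_above <- mean(dens > objective$upper)
  c(p_below = p_below, p_in = 1 - p_below - p_above, p_above = p_above)
}

#' Net effect of a management action
#'
#' Ratio of the probability of meeting the objective under the action to
#' the probability under no action ("you are ten times more likely to
#' achieve your goal").
#'
#' @param p_action,p_no_action Probabilities in \[0, 1\].
#' @return The ratio; `Inf` with a warning when `p_no_action` is 0.
#' @export
net_effect <- function(p_action, p_no_action) {
  stopifnot(p_action >= 0, p_action <= 1, p_no_action >= 0, p_no_action <= 1)
  if (p_no_action == 0) {
    warning("probability of objective under no action is 0; net effect is infinite")
    return(Inf)
  }
  p_action / p_no_action
}

#' Treatment effort: how many does must be handled
#'
#' @param ens A [forecast()] ensemble produced under a treatment.
#' @return List with `total_median` (median over draws of the cumulative
#'   number treated across all parks and years), `per_year` (median annual
#'   totals) and `per_park` (median per-park cumulative totals).
#' @export
treatment_effort <- function(ens) {
  stopifnot(inherits(ens, "forecast_ensemble"))
  cum <- apply(ens$treated, 1, sum)               # per draw
  list(total_median = stats::median(cum),
       per_year = apply(apply(ens$treated, c(1, 2), sum), 2, stats::median),
       per_park = stats::setNames(
         apply(apply(ens$treated, c(1, 3), sum), 2, stats::median),
         ens$park_id))
}

#' Program cost of a management plan
#'
#' @param effort_by_type Named non-negative counts of does handled, names
#'   in `none/cull/sterilize/contracept1/contracept3` (fertility-control
#'   types share one unit cost).
#' @param unit_costs Dollars per doe: `c(cull = 370, fertility = 750)`.
#' @return Total cost in dollars.
#' @export
program_cost <- function(effort_by_type,
                         unit_costs = c(cull = 370, fertility = 750)) {
  if (any(effort_by_type < 0))
    stop("treatment counts must be non-negative", call. = FALSE)
  if (is.null(names(effort_by_type)))
    stop("`effort_by_type` must be a named vector", call. = FALSE)
  rate <- function(type) {
    switch(type,
      cull = unit_costs[["cull"]],
      sterilize = , contracept1 = , contracept3 = unit_costs[["fertility"]],
      none = 0,
      stop("unknown treatment type: ", type, call. = FALSE))
  }
  sum(vapply(names(effort_by_type),
             function(ty) rate(ty) * effort_by_type[[ty]], numeric(1)))
}

#' Decision table over a grid of treatments
#'
#' For each treatment type and proportion: the linearized growth rate
#' median, below/in/above probabilities at the horizon, median effort and
#' program cost, and the net effect relative to no action.
#'
#' @param draws A `posterior_draws` object.
#' @param objective A [management_objective()].
#' @param types,props Treatment grid (defaults: the four treatment types
#'   at 20/40/60/90%).
#' @param max_draws Cap on posterior draws per forecast.
#' @return Data frame, one row per treatment x proportion plus no action.
#' @export
experiment_grid <- function(draws, objective = management_objective(),
                            types = c("cull", "sterilize", "contracept1",
                                      "contracept3"),
                            props = c(0.2, 0.4, 0.6, 0.9),
                            max_draws = 500) {
  run1 <- function(spec) {
    ens <- forecast(draws, horizon = objective$horizon, plan = spec,
                    max_draws = max_draws)
    pr <- objective_probabilities(ens, objective)
    eff <- treatment_effort(ens)
    lam <- lambda_posterior(draws, spec, max_draws = max_draws)
    data.frame(treatment = spec$type, p = spec$p,
               lambda_median = lam$summary$median,
               p_below = pr[["p_below"]], p_in = pr[["p_in"]],
               p_above = pr[["p_above"]],
               effort_median = eff$total_median,
               cost = program_cost(stats::setNames(eff$total_median,
                                                   spec$type)))
  }
  rows <- list(run1(treatment_spec("none")))
  for (p in props) for (ty in types)
    rows[[length(rows) + 1L]] <- run1(treatment_spec(ty, p))
  out <- do.call(rbind, rows)
  p_na <- out$p_in[out$treatment == "none"]
  out$net_effect <- ifelse(p_na > 0, out$p_in / p_na, Inf)
  rownames(out) <- NULL
  out
}
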