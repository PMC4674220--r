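#' Survey data container and observation likelihoods
#'
#' Two data streams inform the latent states: annual distance-sampling
#' density estimates (with plug-in standard errors from the upstream
#' survey analysis) and age/sex classification counts. Missing park-years
#' are allowed; their likelihood terms are simply skipped while the latent
#' process keeps propagating.
#'
#' @name data_model
NULL

#' Construct a survey dataset
#'
#' @param parks Data frame with columns `park_id`, `area_km2`.
#' @param density Data frame with columns `park_id`, `year`,
#'   `density_per_km2`, `se`. One row per surveyed park-year.
#' @param classification Data frame with columns `park_id`, `year`,
#'   `n_juvenile`, `n_female`, `n_male` and optionally `n_unknown`
#'   (excluded from the likelihood: the multinomial total is the number of
#'   animals actually categorized).
#' @return A list of class `survey_dataset`.
#' @export
survey_dataset <- function(parks, density, classification) {
  check_cols <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop(sprintf("%s is missing column(s): %s", name,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_cols(parks, c("park_id", "area_km2"), "parks")
  check_cols(density, c("park_id", "year", "density_per_km2", "se"), "density")
  check_cols(classification,
             c("park_id", "year", "n_juvenile", "n_female", "n_male"),
             "classification")
  if (anyDuplicated(parks$park_id))
    stop("duplicated park_id in parks table", call. = FALSE)
  if (any(parks$area_km2 <= 0))
    stop("park areas must be positive", call. = FALSE)
  bad <- which(!is.na(density$se) & density$se <= 0)
  if (length(bad))
    stop("non-positive SE in density table, row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  cnt <- as.matrix(classification[, c("n_juvenile", "n_female", "n_male")])
  bad <- which(apply(cnt, 1, function(x) any(x < 0) || any(x != round(x))))
  if (length(bad))
    stop("classification counts must be non-negative integers, row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (df in list(density, classification)) {
    unknown <- setdiff(unique(df$park_id), parks$park_id)
    if (length(unknown))
      stop("park_id not in parks table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  structure(list(parks = parks, density = density,
                 classification = classification),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  yrs <- range(c(x$density$year, x$classification$year))
  cat(sprintf("survey_dataset: %d parks, years %d-%d, %d density rows, %d classification rows\n",
              nrow(x$parks), yrs[1], yrs[2], nrow(x$density),
              nrow(x$classification)))
  invisible(x)
}

#' Convert a survey dataset to dense park-by-year arrays
#'
#' Internal workhorse used by the sampler, the model-checking module and
#' the forecasters. Cells with no survey are NA (density) or zero counts.
#'
#' @param data A [survey_dataset()].
#' @return List with `park_id`, `years`, `area` (length I), `yd`, `se`
#'   (I x T), `counts` (I x T x 3), `yN` (I x T), and observation flags.
#' @export
as_survey_arrays <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  park_id <- data$parks$park_id
  years <- sort(unique(c(data$density$year, data$classification$year)))
  years <- seq(min(years), max(years))
  I <- length(park_id); T_ <- length(years)
  yd <- se <- matrix(NA_real_, I, T_, dimnames = list(park_id, years))
  counts <- array(0, c(I, T_, 3),
                  dimnames = list(park_id, years, c("juvenile", "female", "male")))
  for (r in seq_len(nrow(data$density))) {
    i <- match(data$density$park_id[r], park_id)
    t <- match(data$density$year[r], years)
    yd[i, t] <- data$density$density_per_km2[r]
    se[i, t] <- data$density$se[r]
  }
  for (r in seq_len(nrow(data$classification))) {
    i <- match(data$classification$park_id[r], park_id)
    t <- match(data$classification$year[r], years)
    counts[i, t, ] <- as.numeric(data$classification[r, c("n_juvenile", "n_female", "n_male")])
  }
  list(park_id = park_id, years = years, area = data$parks$area_km2,
       yd = yd, se = se, counts = counts, yN = apply(counts, c(1, 2), sum),
       obs_density = !is.na(yd))
}

#' Stage proportions for the classification likelihood
#'
#' Observers classify animals as juvenile, adult female or adult male;
#' sterile/contracepted does are indistinguishable from fertile ones in
#' the field, so the two female stages are pooled.
#'
#' @param n Stage vector of length 3 or 4.
#' @return Simplex 3-vector (juvenile, female, male).
#' @export
classification_proportions <- function(n) {
  n <- as_stage4(n)
  tot <- sum(n)
  if (!is.finite(tot) || tot <= 0)
    stop("total abundance must be positive", call. = FALSE)
  c(juvenile = n[["n1"]], female = n[["n2"]] + n[["n2s"]],
    male = n[["n3"]]) / tot
}

#' Multinomial log likelihood of classification counts
#'
#' @param y_alpha Length-3 count vector (juvenile, female, male).
#' @param y_N Total classified; must equal `sum(y_alpha)`.
#' @param prob Simplex 3-vector from [classification_proportions()].
#' @return Multinomial log pmf; `-Inf` if a positive count has zero
#'   probability; 0 for an empty observation.
#' @export
classification_loglik <- function(y_alpha, y_N, prob) {
  if (!isTRUE(all.equal(sum(y_alpha), y_N)))
    stop("`y_N` must equal sum(y_alpha)", call. = FALSE)
  if (y_N == 0) return(0)
  stats::dmultinom(y_alpha, size = y_N, prob = prob, log = TRUE)
}

#' Normal log likelihood of a density estimate
#'
#' The latent density is total abundance over park area; the survey SE is
#' a fixed plug-in from the upstream distance-sampling analysis, not an
#' estimated parameter. A missing observation contributes 0.
#'
#' @param y_d Observed density (deer/km^2) or NA.
#' @param se Its standard error (> 0).
#' @param n Latent stage vector.
#' @param area Park area in km^2 (> 0).
#' @return Normal log density (0 when `y_d` is NA).
#' @export
density_loglik <- function(y_d, se, n, area) {
  if (is.na(y_d)) return(0)
  if (!is.numeric(se) || se <= 0) stop("`se` must be positive", call. = FALSE)
  if (!is.numeric(area) || area <= 0) stop("`area` must be positive", call. = FALSE)
  stats::dnorm(y_d, mean = sum(n) / area, sd = se, log = TRUE)
}

#' Draw initial stage abundances from year-1 data
#'
#' Stage proportions get a Dirichlet(y_alpha + 1) draw, density a normal
#' draw around the year-1 estimate truncated below at zero, and the two
#' combine as `n = d * gamma * area`.
#'
#' @param y_alpha Year-1 classification counts (length 3).
#' @param y_d,se Year-1 density estimate and SE.
#' @param area Park area (km^2).
#' @return List with `gamma` (simplex), `d` (density) and `n` (length-3
#'   stage abundances).
#' @export
initial_state_draw <- function(y_alpha, y_d, se, area) {
  if (is.na(y_d) || any(is.na(y_alpha)))
    stop("year-1 survey data are required for the initial state; supply a ",
         "fallback via the configuration for parks first surveyed later",
         call. = FALSE)
  g <- rdirichlet1(y_alpha + 1)
  d <- -1
  while (d < 0) d <- stats::rnorm(1, y_d, se)
  list(gamma = g, d = d, n = d * g * area)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

ddirichlet_log <- function(x, alpha) {
  if (any(x <= 0) || abs(sum(x) - 1) > 1e-8) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

#' Joint log density of parameters, latent states and data
#'
#' Pure-R reference composition of the full model: scalar-parameter priors
#' ([log_prior()]), the Dirichlet/normal initial-condition terms, the
#' lognormal process transitions, and the multinomial and normal data
#' likelihoods over all observed park-years. The compiled sampler evaluates
#' the identical quantity; this function is the readable specification and
#' the cross-check oracle.
#'
#' @param params List with `s` (3 x I), `a`, `b`, `m`, `r_f`, `K_f`,
#'   `sigma_p2`, `gamma` (I x 3), `d1` (length I).
#' @param logn I x T x 3 array of latent log abundances; `logn[, 1, ]`
#'   must equal `log(d1 * gamma * area)`.
#' @param data A [survey_dataset()] or the result of [as_survey_arrays()].
#' @param priors A [prior_config()].
#' @return Single numeric log density (`-Inf` out of support).
#' @export
joint_log_density <- function(params, logn, data, priors = prior_config()) {
  arr <- if (inherits(data, "survey_dataset")) as_survey_arrays(data) else data
  I <- length(arr$area); T_ <- length(arr$years)
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(lp)
  if (any(params$d1 <= 0)) return(-Inf)
  sp <- sqrt(params$sigma_p2)
  for (i in seq_len(I)) {
    # initial conditions (year-1 data inform gamma and d as priors)
    alpha1 <- arr$counts[i, 1, ] + 1
    lp <- lp + ddirichlet_log(params$gamma[i, ], alpha1)
    if (arr$obs_density[i, 1])
      lp <- lp + stats::dnorm(params$d1[i], arr$yd[i, 1], arr$se[i, 1], log = TRUE)
    vit <- vital_rates(params$s[1, i], params$s[2, i], params$s[3, i],
                       params$m, params$r_f, params$K_f, params$sigma_p2)
    for (t in seq_len(T_)) {
      n_t <- exp(logn[i, t, ])
      # data terms
      if (arr$yN[i, t] > 0)
        lp <- lp + classification_loglik(arr$counts[i, t, ], arr$yN[i, t],
                                         classification_proportions(n_t))
      lp <- lp + density_loglik(arr$yd[i, t], arr$se[i, t], n_t, arr$area[i])
      # process transition t -> t+1
      if (t < T_) {
        f <- fecundity(params$r_f, params$K_f, sum(n_t) / arr$area[i],
                       priors$fecundity_form)
        mu <- pmax(project(build_projection_matrix(vit, f), n_t), 1e-6)
        lp <- lp + sum(stats::dnorm(logn[i, t + 1, ], log(mu), sp, log = TRUE))
      }
    }
  }
  lp
}
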