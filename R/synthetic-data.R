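#' Synthetic survey data with known truth
#'
#' Generates park-by-year density estimates and classification counts with
#' exactly the statistical structure the model assumes: latent stage
#' abundances follow the density-dependent Lefkovitch projection with
#' lognormal process noise; density observations are normal around the
#' true density with survey-like coefficients of variation; classification
#' counts are multinomial draws from the true stage proportions. A truth
#' record of all latent states and parameters accompanies the data so that
#' every downstream stage is testable without any external file.
#'
#' @name synthetic_data
NULL

#' Design of a synthetic survey
#'
#' @param n_parks,n_years Survey dimensions.
#' @param areas Park areas in km^2 (length `n_parks`).
#' @param vitals True [vital_rates()]; defaults to the regional posterior
#'   means of the fitted model (s1 = 0.75, s2 = 0.67, s3 = 0.45,
#'   m = 0.53, r_f = 0.86, K_f = 27.12, sigma_p2 = 0.50).
#' @param init_density_range Range of true initial densities (deer/km^2).
#' @param class_n_range Range of animals classified per park-year.
#' @param density_cv_range Range of the density-estimate coefficient of
#'   variation.
#' @param missingness Probability that a park-year after the first has no
#'   survey.
#' @param fecundity_form See [fecundity()].
#' @return List of class `synthetic_design`.
#' @export
synthetic_design <- function(n_parks = 8, n_years = 13,
                             areas = NULL,
                             vitals = vital_rates(0.75, 0.67, 0.45, 0.53,
                                                  0.86, 27.12, 0.50),
                             init_density_range = c(30, 70),
                             class_n_range = c(100, 500),
                             density_cv_range = c(0.10, 0.20),
                             missingness = 0,
                             fecundity_form = c("ricker_exp", "scaled")) {
  fecundity_form <- match.arg(fecundity_form)
  if (is.null(areas))
    areas <- round(seq(2, 50, length.out = n_parks), 1)
  stopifnot(n_parks >= 1, n_years >= 2, length(areas) == n_parks,
            all(areas > 0), inherits(vitals, "vital_rates"),
            all(density_cv_range > 0), all(density_cv_range < 1),
            missingness >= 0, missingness < 1)
  structure(list(n_parks = n_parks, n_years = n_years, areas = areas,
                 vitals = vitals, init_density_range = init_density_range,
                 class_n_range = class_n_range,
                 density_cv_range = density_cv_range,
                 missingness = missingness,
                 fecundity_form = fecundity_form),
            class = "synthetic_design")
}

#' Named study designs
#'
#' `"paper_like"` reproduces the survey scale of the motivating study
#' (8 parks x 13 years); `"small_test"` is a 3-park x 6-year design for
#' fast checks; `"high_noise"` doubles process noise and uses the upper
#' end of the survey CV range.
#'
#' @param name Preset name.
#' @return A [synthetic_design()].
#' @export
scenario_presets <- function(name) {
  presets <- c("paper_like", "small_test", "high_noise")
  if (!is.character(name) || length(name) != 1L || !name %in% presets)
    stop("unknown preset; available presets: ",
         paste(presets, collapse = ", "), call. = FALSE)
  switch(name,
    paper_like = synthetic_design(),
    small_test = synthetic_design(n_parks = 3, n_years = 6,
                                  areas = c(5, 15, 40)),
    high_noise = {
      d <- synthetic_design(
        vitals = vital_rates(0.75, 0.67, 0.45, 0.53, 0.86, 27.12, 1.0),
        density_cv_range = c(0.20, 0.30))
      d
    })
}

#' Generate a synthetic survey dataset and its truth record
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed; the dataset is byte-identical given
#'   (design, seed).
#' @return List with `data` (a [survey_dataset()]) and `truth` (true
#'   parameters, latent stage abundances `n` as park x year x 3 array,
#'   true densities, and the design).
#' @export
generate_dataset <- function(design = synthetic_design(), seed = 1) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(seed)
  v <- design$vitals
  I <- design$n_parks; T_ <- design$n_years
  areas <- design$areas
  park_id <- sprintf("P%02d", seq_len(I))
  n <- array(0, c(I, T_, 3), dimnames = list(park_id, NULL, STAGES3))
  for (i in seq_len(I)) {
    d0 <- stats::runif(1, design$init_density_range[1],
                       design$init_density_range[2])
    # start at the stable stage structure of the matrix at that density
    f0 <- fecundity(v$r_f, v$K_f, d0, design$fecundity_form)
    A0 <- build_projection_matrix(v, f0)
    w <- Re(eigen(A0)$vectors[, 1]); w <- abs(w) / sum(abs(w))
    n[i, 1, ] <- d0 * w * areas[i]
    for (t in seq_len(T_ - 1)) {
      f <- fecundity(v$r_f, v$K_f, sum(n[i, t, ]) / areas[i],
                     design$fecundity_form)
      n_det <- project(build_projection_matrix(v, f), n[i, t, ])
      n[i, t + 1, ] <- add_process_noise(n_det, v$sigma_p2)
    }
  }
  if (any(apply(n, 1, sum) < 1e-3))
    warning("a simulated park went effectively extinct; consider regenerating")
  years <- seq(2001, length.out = T_)
  observed <- matrix(TRUE, I, T_)
  if (design$missingness > 0 && T_ > 1)
    observed[, -1] <- stats::runif(I * (T_ - 1)) >= design$missingness
  dens_rows <- list(); class_rows <- list()
  for (i in seq_len(I)) for (t in seq_len(T_)) {
    if (!observed[i, t]) next
    true_d <- sum(n[i, t, ]) / areas[i]
    cv <- stats::runif(1, design$density_cv_range[1],
                       design$density_cv_range[2])
    sehat <- cv * true_d
    yd <- -1
    while (yd < 0) yd <- stats::rnorm(1, true_d, sehat)  # resample negatives
    dens_rows[[length(dens_rows) + 1L]] <-
      data.frame(park_id = park_id[i], year = years[t],
                 density_per_km2 = yd, se = sehat)
    yN <- sample(design$class_n_range[1]:design$class_n_range[2], 1)
    cts <- as.integer(stats::rmultinom(1, yN, n[i, t, ] / sum(n[i, t, ])))
    class_rows[[length(class_rows) + 1L]] <-
      data.frame(park_id = park_id[i], year = years[t],
                 n_juvenile = cts[1], n_female = cts[2], n_male = cts[3])
  }
  data <- survey_dataset(
    parks = data.frame(park_id = park_id, area_km2 = areas),
    density = do.call(rbind, dens_rows),
    classification = do.call(rbind, class_rows))
  truth <- list(vitals = unclass(v), n = n,
                density = sweep(apply(n, c(1, 2), sum), 1, areas, "/"),
                areas = areas, years = years, seed = seed,
                fecundity_form = design$fecundity_form)
  list(data = data, truth = truth)
}
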