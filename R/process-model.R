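#' Stage-structured projection model for white-tailed deer
#'
#' The population is censused once a year, six months after the birth pulse,
#' in three stages: juveniles of both sexes (`n1`), adult females (`n2`) and
#' adult males (`n3`). Management experiments add a fourth stage, sterile or
#' contracepted adult females (`n2s`), inserted between `n2` and `n3`.
#' Projection is by a Lefkovitch matrix whose fecundity entry declines with
#' total deer density, and annual stochasticity enters as lognormal process
#' error around the deterministic projection.
#'
#' @name process_model
NULL

STAGES3 <- c("n1", "n2", "n3")
STAGES4 <- c("n1", "n2", "n2s", "n3")

#' Construct a set of vital rates
#'
#' @param s1,s2,s3 Annual survival probabilities in (0,1) for juveniles,
#'   adult females and adult males.
#' @param m Juvenile sex ratio: proportion of juveniles that are female,
#'   in (0,1).
#' @param r_f Maximum-fecundity parameter (> 0); see [fecundity()].
#' @param K_f Density (deer/km^2, > 0) at which the fecundity exponent
#'   vanishes.
#' @param sigma_p2 Process variance on the log scale (>= 0).
#' @return A list of class `vital_rates`.
#' @export
vital_rates <- function(s1, s2, s3, m, r_f, K_f, sigma_p2 = 0) {
  stopifnot(
    is.numeric(s1), is.numeric(s2), is.numeric(s3),
    all(c(s1, s2, s3) > 0), all(c(s1, s2, s3) < 1),
    m > 0, m < 1, r_f > 0, K_f > 0, sigma_p2 >= 0
  )
  structure(list(s1 = s1, s2 = s2, s3 = s3, m = m,
                 r_f = r_f, K_f = K_f, sigma_p2 = sigma_p2),
            class = "vital_rates")
}

#' Density-dependent fecundity
#'
#' Fawns per adult female surviving to census, as a declining function of
#' total deer density `D` (all stages pooled, divided by park area). The
#' default form is the exponential (Ricker-type) decline
#' `exp(r_f - (r_f / K_f) * D)`, which equals 1 exactly at `D = K_f`; the
#' `scaled` form `r_f * exp(-(r_f / K_f) * D)` instead has maximum `r_f`
#' at zero density. Both share the same slope parameter `r_f / K_f` on the
#' log scale.
#'
#' @param r_f Maximum-fecundity parameter (> 0).
#' @param K_f Density at which the exponent vanishes (> 0, deer/km^2).
#' @param density Total deer density (>= 0, deer/km^2); vectorised.
#' @param form `"ricker_exp"` (default) or `"scaled"`.
#' @return Fawns per doe surviving to census; strictly positive and
#'   strictly decreasing in `density`.
#' @export
fecundity <- function(r_f, K_f, density, form = c("ricker_exp", "scaled")) {
  form <- match.arg(form)
  if (!is.numeric(r_f) || length(r_f) != 1L || !is.finite(r_f) || r_f <= 0)
    stop("`r_f` must be a single positive number", call. = FALSE)
  if (!is.numeric(K_f) || length(K_f) != 1L || !is.finite(K_f) || K_f <= 0)
    stop("`K_f` must be a single positive number", call. = FALSE)
  if (any(density < 0)) stop("`density` must be non-negative", call. = FALSE)
  if (form == "ricker_exp") exp(r_f - (r_f / K_f) * density)
  else r_f * exp(-(r_f / K_f) * density)
}

#' Build the 3-stage Lefkovitch projection matrix
#'
#' Stage order (n1, n2, n3). Recruitment enters through the adult-female
#' column as `s2 * f` (the doe must survive the year to produce fawns
#' counted at the next census); juveniles mature into adult females with
#' probability `s1 * m` and adult males with probability `s1 * (1 - m)`.
#'
#' @param vitals A [vital_rates()] object.
#' @param f Fawns per doe surviving to census (>= 0), typically from
#'   [fecundity()].
#' @return A 3x3 non-negative matrix with dimnames (n1, n2, n3).
#' @export
build_projection_matrix <- function(vitals, f) {
  stopifnot(inherits(vitals, "vital_rates"), is.numeric(f), f >= 0)
  with(vitals, matrix(
    c(0,            s2 * f, 0,
      s1 * m,       s2,     0,
      s1 * (1 - m), 0,      s3),
    nrow = 3, byrow = TRUE, dimnames = list(STAGES3, STAGES3)
  ))
}

#' Specify a management treatment
#'
#' @param type One of `"none"`, `"cull"`, `"sterilize"`, `"contracept1"`
#'   (one-year fixed duration) or `"contracept3"` (three-year average
#'   duration, modelled as geometric reversion at annual rate 1/3).
#' @param p Proportion of adult females treated each application year,
#'   in \[0, 1\]. Ignored when `type = "none"`.
#' @param years Integer vector of forecast years (1-based) in which the
#'   treatment is applied; defaults to every year.
#' @return A list of class `treatment_spec`.
#' @export
treatment_spec <- function(type = c("none", "cull", "sterilize",
                                    "contracept1", "contracept3"),
                           p = 0, years = NULL) {
  type <- match.arg(type)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("treatment proportion `p` must be in [0, 1]", call. = FALSE)
  structure(list(type = type, p = p, years = years), class = "treatment_spec")
}

# annual probability that a surviving treated doe reverts to fertile
reversion_rate <- function(type) {
  switch(type,
    sterilize   = 0,
    contracept1 = 1,
    contracept3 = 1 / 3,
    stop("unknown treatment type: ", type, call. = FALSE)
  )
}

#' Build the 4-stage projection matrix with a treated-female class
#'
#' Stage order (n1, n2 fertile females, n2s treated females, n3). Treated
#' females survive at `s2` with zero fecundity; a surviving treated doe
#' reverts to the fertile class with annual probability 0 (sterilization),
#' 1 (one-year contraceptive) or 1/3 (three-year average contraceptive).
#'
#' @inheritParams build_projection_matrix
#' @param treatment A [treatment_spec()] with `type != "none"`.
#' @return A 4x4 non-negative matrix with dimnames (n1, n2, n2s, n3).
#' @export
build_treated_matrix <- function(vitals, f, treatment) {
  stopifnot(inherits(vitals, "vital_rates"), inherits(treatment, "treatment_spec"))
  if (treatment$type == "none")
    stop("`build_treated_matrix` requires a treatment type other than \"none\"",
         call. = FALSE)
  # culling changes the state, not the matrix; the treated class is still
  # carried so culled systems share one stage layout
  rev <- if (treatment$type == "cull") 0 else reversion_rate(treatment$type)
  with(vitals, matrix(
    c(0,            s2 * f, 0,            0,
      s1 * m,       s2,     rev * s2,     0,
      0,            0,      (1 - rev) * s2, 0,
      s1 * (1 - m), 0,      0,            s3),
    nrow = 4, byrow = TRUE, dimnames = list(STAGES4, STAGES4)
  ))
}

#' Apply a treatment event to a census state
#'
#' Treatments are administered immediately after census. Culling removes a
#' fraction `p` of all adult females (fertile and previously treated);
#' sterilization and contraception move a fraction `p` of currently fertile
#' females into the treated class. Juveniles and males are never treated.
#'
#' @param n Stage vector, length 3 (n1, n2, n3) or 4 (n1, n2, n2s, n3).
#' @param treatment A [treatment_spec()].
#' @return A list with `state` (length-4 stage vector) and `n_treated`
#'   (number of does culled or newly treated).
#' @export
apply_treatment_event <- function(n, treatment) {
  stopifnot(inherits(treatment, "treatment_spec"))
  n <- as_stage4(n)
  if (any(!is.finite(n)) || any(n < 0))
    stop("stage vector must be finite and non-negative", call. = FALSE)
  p <- treatment$p
  out <- n
  n_treated <- 0
  if (treatment$type == "cull") {
    n_treated <- p * (n[["n2"]] + n[["n2s"]])
    out[["n2"]] <- n[["n2"]] * (1 - p)
    out[["n2s"]] <- n[["n2s"]] * (1 - p)
  } else if (treatment$type != "none") {
    moved <- p * n[["n2"]]
    out[["n2"]] <- n[["n2"]] - moved
    out[["n2s"]] <- n[["n2s"]] + moved
    n_treated <- moved
  }
  list(state = out, n_treated = n_treated)
}

as_stage4 <- function(n) {
  n <- as.numeric(n)
  if (length(n) == 3L) n <- c(n[1], n[2], 0, n[3])
  if (length(n) != 4L)
    stop("stage vector must have length 3 or 4", call. = FALSE)
  names(n) <- STAGES4
  n
}

#' Deterministic one-year projection
#'
#' @param A Projection matrix (3x3 or 4x4).
#' @param n Stage vector matching the matrix dimension.
#' @return The matrix-vector product `A %*% n` as a named vector.
#' @export
project <- function(A, n) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix", call. = FALSE)
  if (length(n) != nrow(A))
    stop("dimension mismatch: matrix is ", nrow(A), "x", ncol(A),
         " but state has length ", length(n), call. = FALSE)
  drop(A %*% as.numeric(n))
}

#' Add lognormal process noise to a deterministic projection
#'
#' Draws `exp(z)` with `z ~ Normal(log(n_det), sigma_p2 * I)`, so the
#' median of the draws is the deterministic state. Deterministic means are
#' floored at `floor` before taking logs so that extreme culls cannot
#' produce `log(0)`.
#'
#' @param n_det Deterministic stage means (all > 0 after flooring).
#' @param sigma_p2 Process variance on the log scale (>= 0); 0 returns
#'   `n_det` unchanged.
#' @param floor Positivity floor applied to `n_det`.
#' @return A strictly positive stage vector of the same length.
#' @export
add_process_noise <- function(n_det, sigma_p2, floor = 1e-6) {
  stopifnot(is.numeric(n_det), sigma_p2 >= 0)
  n_det <- as.numeric(n_det)
  if (any(!is.finite(n_det)) || any(n_det < 0))
    stop("deterministic stage means must be non-negative and finite",
         call. = FALSE)
  if (sigma_p2 == 0) return(n_det)
  n_det <- pmax(n_det, floor)   # protect log() after extreme culls
  exp(stats::rnorm(length(n_det), mean = log(n_det), sd = sqrt(sigma_p2)))
}
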