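#' Eigenanalysis of posterior projection matrices
#'
#' The asymptotic growth rate lambda of the linearized system (fecundity
#' evaluated at zero density, i.e. its maximum) is a derived quantity of
#' the MCMC output: one lambda is computed from the projection matrix at
#' each retained draw, so lambda has its own posterior. Because fecundity
#' declines with density, these lambdas bound realized growth at positive
#' density from above and put all treatments on a common scale.
#'
#' @name eigenanalysis
NULL

#' Dominant eigenvalue of a projection matrix
#'
#' @param A Square non-negative matrix with finite entries.
#' @return The spectral radius (real for these non-negative matrices).
#' @export
dominant_eigenvalue <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix", call. = FALSE)
  if (any(!is.finite(A)))
    stop("`A` has non-finite entries", call. = FALSE)
  ev <- eigen(A, only.values = TRUE)$values
  max(Mod(ev))
}

#' Sensitivities of lambda to the matrix entries
#'
#' `d lambda / d a_kl = v_k * w_l / <v, w>` where `w` and `v` are the
#' right and left eigenvectors of the dominant eigenvalue.
#'
#' @param A Square non-negative matrix with a simple dominant eigenvalue.
#' @return Matrix of the same dimension as `A`.
#' @export
sensitivities <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("`A` must be a square matrix", call. = FALSE)
  er <- eigen(A)
  el <- eigen(t(A))
  kr <- which.max(Mod(er$values))
  kl <- which.max(Mod(el$values))
  w <- Re(er$vectors[, kr])
  v <- Re(el$vectors[, kl])
  denom <- sum(v * w)
  if (abs(denom) < 1e-12)
    stop("defective matrix: left/right eigenvectors are orthogonal",
         call. = FALSE)
  S <- outer(v, w) / denom
  dimnames(S) <- dimnames(A)
  S
}

#' Annual projection matrix with the treatment folded in
#'
#' Treatment acts immediately after census, so the annually repeated
#' system is `A %*% M` with `M` the treatment transfer operator: culling
#' scales both adult-female stages by `1 - p`; sterilization and
#' contraception move a fraction `p` of fertile females into the treated
#' class of the 4-stage matrix. Fecundity is evaluated at the supplied
#' density (zero for the linearized lambda).
#'
#' @param vitals A [vital_rates()] object.
#' @param treatment A [treatment_spec()].
#' @param density Density at which fecundity is evaluated (default 0).
#' @param form Fecundity form; see [fecundity()].
#' @return A 3x3 (`none`/`cull`) or 4x4 annual matrix.
#' @export
annual_treated_matrix <- function(vitals, treatment, density = 0,
                                  form = c("ricker_exp", "scaled")) {
  form <- match.arg(form)
  f <- fecundity(vitals$r_f, vitals$K_f, density, form)
  if (treatment$type == "none")
    return(build_projection_matrix(vitals, f))
  if (treatment$type == "cull") {
    A <- build_projection_matrix(vitals, f)
    A[, "n2"] <- A[, "n2"] * (1 - treatment$p)
    return(A)
  }
  A <- build_treated_matrix(vitals, f, treatment)
  M <- diag(4)
  dimnames(M) <- dimnames(A)
  M["n2", "n2"] <- 1 - treatment$p
  M["n2s", "n2"] <- treatment$p
  A %*% M
}

#' Posterior distribution of the asymptotic growth rate
#'
#' One lambda per retained draw, built from the regional survival means
#' `mu_j = a_j / (a_j + b_j)`, the draw's sex ratio and its maximum
#' fecundity (density term set to zero).
#'
#' @param draws A `posterior_draws` object.
#' @param treatment A [treatment_spec()] (default no action).
#' @param max_draws Cap on the number of draws used.
#' @return List of class `lambda_posterior`: `lambda` samples, quantile
#'   `summary`, and `diff_no_action` samples (no-action lambda minus
#'   treated lambda, per draw).
#' @export
lambda_posterior <- function(draws, treatment = treatment_spec("none"),
                             max_draws = 4000) {
  stopifnot(inherits(draws, "posterior_draws"),
            inherits(treatment, "treatment_spec"))
  form <- draws$priors$fecundity_form
  grab <- function(p) as.numeric(draws_matrix(draws, p))
  mu1 <- grab("mu[1]"); mu2 <- grab("mu[2]"); mu3 <- grab("mu[3]")
  m <- grab("m"); rf <- grab("r_f"); Kf <- grab("K_f")
  total <- length(mu1)
  use <- unique(round(seq(1, total, length.out = min(total, max_draws))))
  lam <- lam0 <- numeric(length(use))
  none <- treatment_spec("none")
  for (k in seq_along(use)) {
    d <- use[k]
    vit <- vital_rates(mu1[d], mu2[d], mu3[d], m[d], rf[d], Kf[d])
    lam[k] <- dominant_eigenvalue(annual_treated_matrix(vit, treatment,
                                                        density = 0, form = form))
    lam0[k] <- if (treatment$type == "none") lam[k] else
      dominant_eigenvalue(annual_treated_matrix(vit, none, density = 0,
                                                form = form))
  }
  qs <- stats::quantile(lam, c(0.025, 0.5, 0.975))
  structure(list(
    lambda = lam,
    summary = data.frame(treatment = treatment$type, p = treatment$p,
                         q2.5 = qs[[1]], median = qs[[2]], q97.5 = qs[[3]]),
    diff_no_action = lam0 - lam
  ), class = "lambda_posterior")
}

#' Table of lambda summaries over a treatment grid
#'
#' One row per treatment x proportion: lambda quantiles and the median and
#' 95% interval of the difference relative to no action.
#'
#' @param draws A `posterior_draws` object.
#' @param types Treatment types to evaluate.
#' @param props Proportions treated.
#' @param max_draws Cap on draws per cell.
#' @return Data frame.
#' @export
lambda_table <- function(draws,
                         types = c("cull", "sterilize", "contracept1",
                                   "contracept3"),
                         props = c(0.2, 0.4, 0.6, 0.9),
                         max_draws = 4000) {
  none <- lambda_posterior(draws, treatment_spec("none"), max_draws)
  rows <- list(cbind(none$summary,
                     diff_q2.5 = NA, diff_median = NA, diff_q97.5 = NA))
  for (p in props) for (ty in types) {
    lp <- lambda_posterior(draws, treatment_spec(ty, p), max_draws)
    dq <- stats::quantile(lp$diff_no_action, c(0.025, 0.5, 0.975))
    rows[[length(rows) + 1L]] <- cbind(lp$summary, diff_q2.5 = dq[[1]],
                                       diff_median = dq[[2]],
                                       diff_q97.5 = dq[[3]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
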