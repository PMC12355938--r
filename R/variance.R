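# Plug-in design-variance estimators and confidence intervals.
#
# Two routes: a closed-form route for SRS-within-SRS designs (plug-in R^2 and
# V_yy with a degrees-of-freedom-corrected residual variance), and a general
# route built from second-order inclusion probabilities, in Horvitz-Thompson
# or Sen-Yates-Grundy (pairwise-difference, nonnegative for fixed-size
# designs) form. Confidence intervals for the phase-II mean use quantiles of
# the truncated-chi mixture law; intervals for the regression estimator use
# normal quantiles.

new_variance_components <- function(path, form, meta, variance,
                                    V1 = NA_real_, V2 = NA_real_, V3 = NA_real_,
                                    Vee_hat = NA_real_, Vyy_hat = NA_real_,
                                    R2_hat = NA_real_, which = "mean") {
  structure(
    list(path = path, form = form, meta = meta, variance = variance,
         V1 = V1, V2 = V2, V3 = V3, Vee_hat = Vee_hat, Vyy_hat = Vyy_hat,
         R2_hat = R2_hat, which = which),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s path, %s): variance = %.4g\n",
              x$path, x$form, x$variance))
  invisible(x)
}

#' Phase-II sample covariance
#'
#' Centered cross-moment over the phase-II sample with divisor `n_II - 1`,
#' the plug-in estimator of the population covariance under two-phase SRS.
#'
#' @param sampleII a `phase_sample` with at least 2 units.
#' @param u,v value vectors or matrices (population-length or sample-aligned).
#' @return the covariance matrix.
#' @export
sample_cov_hat <- function(sampleII, u, v = u) {
  U <- .sample_values(sampleII, u)
  V <- .sample_values(sampleII, v)
  n <- nrow(U)
  if (n < 2) stop("need at least 2 phase-II units")
  crossprod(sweep(U, 2, colMeans(U)), sweep(V, 2, colMeans(V))) / (n - 1)
}

#' Residual variance, total variance and R-squared plug-ins
#'
#' Computes `Vee_hat` as the centered residual sum of squares divided by
#' `n_II - p - 1` (the degrees-of-freedom correction accounts for estimating
#' the slope), the decomposition plug-in `Vyy_hat = beta' Vxx_hat beta +
#' Vee_hat`, and `R2_hat` from the raw (divisor `n_II - 1`) cross-moments.
#' `R2_hat` is clipped to `[0, 1 - 1e-10]` so downstream mixture-law
#' components never degenerate.
#'
#' @param sampleII phase-II sample with `n_II > p + 1`.
#' @param x auxiliary matrix; `y` study values.
#' @param beta_hat optional precomputed slope; default unweighted phase-II
#'   fit.
#' @return list with `Vee_hat`, `Vyy_hat`, `R2_hat`, `beta_hat`.
#' @export
residual_variance_hat <- function(sampleII, x, y, beta_hat = NULL) {
  X <- .sample_values(sampleII, x)
  yv <- drop(.sample_values(sampleII, y))
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop("insufficient degrees of freedom: n_II <= p + 1")
  if (is.null(beta_hat)) {
    beta_hat <- regression_coefficient(sampleII, X, yv, "unweighted")$beta_hat
  }
  e <- yv - drop(X %*% beta_hat)
  Vee <- sum((e - mean(e))^2) / (n - p - 1)
  Vxx <- sample_cov_hat(sampleII, X)
  Vxy <- sample_cov_hat(sampleII, X, yv)
  Vyy_raw <- drop(sample_cov_hat(sampleII, yv))
  Vyy <- drop(t(beta_hat) %*% Vxx %*% beta_hat) + Vee
  R2 <- drop(t(Vxy) %*% solve(Vxx, Vxy)) / Vyy_raw
  R2 <- min(max(R2, 0), 1 - 1e-10)
  list(Vee_hat = Vee, Vyy_hat = Vyy, R2_hat = R2, beta_hat = beta_hat)
}

#' Closed-form variance estimator for SRS-within-SRS designs
#'
#' For the phase-II mean:
#' `n_II^-1 [(1 - n_II/n_I)(1 - (1 - v_{p,gamma^2}) R2_hat) +
#' (n_II/n_I)(1 - n_I/N)] Vyy_hat`; for the regression estimator:
#' `n_II^-1 [(n_II/n_I)(1 - n_I/N) Vyy_hat + (1 - n_II/n_I) Vee_hat]`.
#'
#' @param sampleI,sampleII SRS phase samples.
#' @param x auxiliary matrix; `y` study values.
#' @param popN population size N.
#' @param gamma2 rejection threshold used by the design (`Inf` if none).
#' @param which `"mean"` or `"regression"`.
#' @return a `variance_components` object; `$variance` is the variance of
#'   the estimator itself (not the `sqrt(n_II)`-scaled error).
#' @export
var_hat_srs <- function(sampleI, sampleII, x, y, popN, gamma2,
                        which = c("mean", "regression")) {
  which <- match.arg(which)
  if (sampleI$design_kind != "srs" || sampleII$design_kind != "srs") {
    stop("var_hat_srs requires SRS in both phases; use ht_components/syg_components")
  }
  nI <- length(sampleI$selected)
  nII <- length(sampleII$selected)
  p <- ncol(.sample_values(sampleII, x))
  rv <- residual_variance_hat(sampleII, x, y)
  f <- nII / nI
  f0 <- nI / popN
  v <- v_p_gamma(p, gamma2)
  var_mean <- ((1 - f) * (1 - (1 - v) * rv$R2_hat) + f * (1 - f0)) *
    rv$Vyy_hat / nII
  var_reg <- (f * (1 - f0) * rv$Vyy_hat + (1 - f) * rv$Vee_hat) / nII
  new_variance_components(
    path = "srs", form = "closed_form",
    meta = list(nII = nII, nI = nI, N = popN, gamma2 = gamma2, p = p,
                f = f, f0 = f0),
    variance = if (which == "mean") var_mean else var_reg,
    Vee_hat = rv$Vee_hat, Vyy_hat = rv$Vyy_hat, R2_hat = rv$R2_hat,
    which = which
  )
}

# Shared setup for the double-sum variance components over the phase-II
# sample: residuals, Hajek means, and the pairwise probability matrices.
.component_setup <- function(sampleI, sampleII, x, y, beta_hat) {
  pop <- .parent_population(sampleI)
  B <- sampleII$selected
  X <- if (is.matrix(x) && nrow(x) == pop$N) x else .pop_vars(pop, x)
  yfull <- if (length(y) == pop$N) y else stop("y must be population-length here")
  if (is.null(beta_hat)) {
    beta_hat <- regression_coefficient(sampleII, X, yfull, "pistar")$beta_hat
  }
  eB <- yfull[B] - drop(X[B, , drop = FALSE] %*% beta_hat)
  w <- 1 / sampleII$cum_pistar
  ebar <- sum(eB * w) / sum(w)
  ybar <- sum(yfull[B] * w) / sum(w)
  pi_I <- .design_pi(sampleI, B)              # first-order phase-I pi for B
  pi_II <- sampleII$cond_pi                   # conditional phase-II pi
  pistar <- sampleII$cum_pistar
  piI_mat <- .joint_matrix(sampleI, B)
  piII_mat <- .joint_matrix(sampleII, B)
  list(pop = pop, B = B, X = X, y = yfull, beta_hat = beta_hat,
       e = eB - ebar, yc = yfull[B] - ybar,
       pi_I = pi_I, pi_II = pi_II, pistar = pistar,
       piI_mat = piI_mat, piII_mat = piII_mat)
}

.v1_component <- function(sampleI, sampleII, X, beta_hat) {
  nII <- length(sampleII$selected)
  VxxI <- .phase2_cov_general(sampleI, sampleII$design_kind,
                              sampleII$design_info, X)
  nII * drop(t(beta_hat) %*% VxxI %*% beta_hat)
}

#' Horvitz-Thompson variance components for general two-phase designs
#'
#' The three components of `n_II * var`: `V1 = n_II beta' V_xx,I beta` with
#' `V_xx,I` the linearised phase-II design covariance of the auxiliary Hajek
#' means; `V2` the double sum over phase-II pairs in the residuals
#' `e_i = y_i - x_i' beta`; `V3` the double sum over phase-II pairs in y with
#' phase-I pairwise probabilities, inverse-weighted so phase-II sampling is
#' integrated out.
#'
#' @param sampleI,sampleII phase samples (SRS, Poisson or stratified phases).
#' @param x auxiliary matrix (population-length); `y` study values
#'   (population-length).
#' @param popN population size (defaults to the population the samples were
#'   drawn from).
#' @param gamma2 threshold used by the design, for the mean-variance
#'   assembly.
#' @param beta_hat optional slope; default pi*-weighted phase-II fit.
#' @param which `"mean"` or `"regression"`.
#' @return a `variance_components` with `V1`, `V2`, `V3` (components of
#'   `n_II * var`) and `$variance` for the requested estimator.
#' @export
ht_components <- function(sampleI, sampleII, x, y, popN = NULL, gamma2 = Inf,
                          beta_hat = NULL, which = c("mean", "regression")) {
  which <- match.arg(which)
  s <- .component_setup(sampleI, sampleII, x, y, beta_hat)
  N <- if (is.null(popN)) s$pop$N else popN
  nII <- length(s$B)
  V1 <- .v1_component(sampleI, sampleII, s$X, s$beta_hat)
  # V2: phase-II conditional variance of the residual mean
  W2 <- (s$piII_mat - outer(s$pi_II, s$pi_II)) /
    (outer(s$pistar, s$pistar) * s$piII_mat)
  V2 <- (nII / N^2) * drop(t(s$e) %*% W2 %*% s$e)
  # V3: phase-I variance of the y mean, inverse-weighted over phase-II pairs
  W3 <- (s$piI_mat - outer(s$pi_I, s$pi_I)) /
    (outer(s$pi_I, s$pi_I) * s$piI_mat * s$piII_mat)
  V3 <- (nII / N^2) * drop(t(s$yc) %*% W3 %*% s$yc)
  .assemble_components(sampleI, sampleII, "ht", V1, V2, V3, N, gamma2,
                       ncol(s$X), which)
}

#' Sen-Yates-Grundy variance components
#'
#' Pairwise-difference forms of the two double-sum components, nonnegative
#' by construction for fixed-size phases (SRS, stratified). Not defined for
#' Poisson phases (random size).
#'
#' @inheritParams ht_components
#' @export
syg_components <- function(sampleI, sampleII, x, y, popN = NULL, gamma2 = Inf,
                           beta_hat = NULL, which = c("mean", "regression")) {
  which <- match.arg(which)
  if (sampleI$design_kind == "poisson" || sampleII$design_kind == "poisson") {
    stop("Sen-Yates-Grundy components require fixed-size phases (not Poisson)")
  }
  s <- .component_setup(sampleI, sampleII, x, y, beta_hat)
  N <- if (is.null(popN)) s$pop$N else popN
  nII <- length(s$B)
  V1 <- .v1_component(sampleI, sampleII, s$X, s$beta_hat)
  d2 <- s$e / s$pistar
  D2 <- outer(d2, d2, "-")^2
  C2 <- (s$piII_mat - outer(s$pi_II, s$pi_II)) / s$piII_mat
  V2 <- -(nII / (2 * N^2)) * sum(C2 * D2)
  d3 <- s$yc / s$pi_I
  D3 <- outer(d3, d3, "-")^2
  C3 <- (s$piI_mat - outer(s$pi_I, s$pi_I)) / (s$piI_mat * s$piII_mat)
  V3 <- -(nII / (2 * N^2)) * sum(C3 * D3)
  .assemble_components(sampleI, sampleII, "syg", V1, V2, V3, N, gamma2,
                       ncol(s$X), which)
}

.assemble_components <- function(sampleI, sampleII, form, V1, V2, V3, N,
                                 gamma2, p, which) {
  nI <- length(sampleI$selected)
  nII <- length(sampleII$selected)
  v <- v_p_gamma(p, gamma2)
  var_mean <- (V1 * v + V2 + V3) / nII
  var_reg <- (V2 + V3) / nII
  new_variance_components(
    path = "general", form = form,
    meta = list(nII = nII, nI = nI, N = N, gamma2 = gamma2, p = p,
                f = nII / nI, f0 = nI / N),
    variance = if (which == "mean") var_mean else var_reg,
    V1 = V1, V2 = V2, V3 = V3, which = which
  )
}

#' Confidence interval for a rejective-design estimator
#'
#' For the phase-II mean the interval uses quantiles of the truncated-chi
#' mixture law with plug-in components: on the SRS path the coefficients are
#' `sqrt((1-f) R2_hat)`, `sqrt((1-f)(1-R2_hat))`, `sqrt(f (1-f0))` scaled by
#' `sqrt(Vyy_hat / n_II)`; on the general path `sqrt(V1)`, `sqrt(V2)`,
#' `sqrt(V3)` scaled by `1 / sqrt(n_II)`. For the regression estimator the
#' limit is normal and the interval uses z-quantiles with the plug-in
#' variance.
#'
#' @param point the point estimate.
#' @param components a `variance_components` from [var_hat_srs],
#'   [ht_components] or [syg_components].
#' @param alpha nominal error rate (default 0.05 for a 95% interval).
#' @param estimator_kind `"mean"` or `"regression"`; defaults to the kind
#'   the components were computed for.
#' @param mc_draws,mc_seed Monte Carlo settings for the mixture quantiles.
#' @return an `estimate_result` with `point`, `variance`, `ci`, `alpha`,
#'   `method`, `components`.
#' @export
confidence_interval <- function(point, components, alpha = 0.05,
                                estimator_kind = NULL,
                                mc_draws = 2e6, mc_seed = 20240229L) {
  stopifnot(inherits(components, "variance_components"))
  if (is.null(estimator_kind)) estimator_kind <- components$which
  m <- components$meta
  if (estimator_kind == "regression") {
    if (components$path == "srs") {
      vr <- (m$f * (1 - m$f0) * components$Vyy_hat +
               (1 - m$f) * components$Vee_hat) / m$nII
    } else {
      if (components$V2 + components$V3 < 0) {
        stop("negative plug-in variance; use the Sen-Yates-Grundy form")
      }
      vr <- (components$V2 + components$V3) / m$nII
    }
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(point - z * sqrt(vr), point + z * sqrt(vr))
    method <- sprintf("regression estimator, normal interval (%s path)",
                      components$path)
    variance <- vr
  } else {
    if (components$path == "srs") {
      co <- c(sqrt((1 - m$f) * components$R2_hat),
              sqrt((1 - m$f) * (1 - components$R2_hat)),
              sqrt(m$f * (1 - m$f0)))
      scale <- sqrt(components$Vyy_hat / m$nII)
    } else {
      if (any(c(components$V1, components$V2, components$V3) < 0)) {
        stop("negative plug-in variance component; use the Sen-Yates-Grundy form")
      }
      co <- sqrt(c(components$V1, components$V2, components$V3))
      scale <- 1 / sqrt(m$nII)
    }
    law <- mixture_law(m$p, m$gamma2, co, mc_draws = mc_draws,
                       mc_seed = mc_seed)
    q <- mixture_quantile(law, c(alpha / 2, 1 - alpha / 2))
    ci <- c(point - q[2] * scale, point - q[1] * scale)
    variance <- ((co[1]^2 * v_p_gamma(m$p, m$gamma2) + co[2]^2 + co[3]^2) *
                   scale^2)
    method <- sprintf("phase-II mean, mixture-law interval (%s path)",
                      components$path)
  }
  structure(
    list(point = point, variance = variance, components = components,
         ci = ci, alpha = alpha, method = method, acceptance = NULL),
    class = "estimate_result"
  )
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s\n  point = %.6g, variance = %.4g, %d%% CI = [%.6g, %.6g]\n",
              x$method, x$point, x$variance, round(100 * (1 - x$alpha)),
              x$ci[1], x$ci[2]))
  invisible(x)
}
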