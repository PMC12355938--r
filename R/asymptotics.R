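# The non-normal limit law of the balanced component under rejective
# sampling, its variance, Monte Carlo mixture quantiles, and closed-form
# asymptotic variances / variance-reduction formulas for the SRS-within-SRS
# design.
#
# The balanced component L_{p,gamma^2} is a chi_p variable truncated to
# {chi^2_p <= gamma^2}, times a random sign and the first coordinate of a
# uniform point on the unit sphere in R^p. Its variance is the chi-square CDF
# ratio P(chi^2_{p+2} <= gamma^2) / P(chi^2_p <= gamma^2).

#' Variance of the truncated balance limit law
#'
#' `v_{p,gamma^2} = P(chi^2_{p+2} <= gamma^2) / P(chi^2_p <= gamma^2)`, the
#' variance of the limit law of the balanced component; it lies in (0, 1],
#' is strictly increasing in `gamma2`, and equals 1 for `gamma2 = Inf`
#' (no rejection).
#'
#' @param p number of balance covariates (integer >= 1).
#' @param gamma2 positive threshold, possibly `Inf`.
#' @return the variance (scalar in (0, 1]).
#' @export
v_p_gamma <- function(p, gamma2) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer")
  if (!(gamma2 > 0)) stop("gamma2 must be positive")
  if (is.infinite(gamma2)) return(1)
  stats::pchisq(gamma2, df = p + 2) / stats::pchisq(gamma2, df = p)
}

#' Draw from the truncated balance limit law
#'
#' Samples `L = chi_{p,gamma} * S * sqrt(Gamma_p)`, where `chi_{p,gamma}` is
#' chi_p conditioned on `chi^2_p <= gamma^2` (inverse-CDF on a uniform
#' restricted to `[0, F(gamma^2)]`), `S` is a random sign, and `Gamma_p ~
#' Beta(1/2, (p-1)/2)`. For `p = 1` the Beta factor is the point mass at 1
#' (the 0-sphere has coordinates +-1), so `L` is a standard normal truncated
#' to `(-gamma, gamma)`.
#'
#' RNG consumption order given `seed`: the truncation uniforms, then the
#' signs, then (for p > 1) the Beta draws.
#'
#' @param p degrees of freedom (>= 1).
#' @param gamma2 truncation threshold (`Inf` allowed: untruncated, L is
#'   standard normal).
#' @param n_draws number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of draws, all with `L^2 <= gamma2`.
#' @export
sample_L <- function(p, gamma2, n_draws, seed = NULL) {
  if (p < 1 || p != round(p)) stop("p must be a positive integer")
  if (!(gamma2 > 0)) stop("gamma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  Fmax <- if (is.infinite(gamma2)) 1 else stats::pchisq(gamma2, df = p)
  u <- stats::runif(n_draws, 0, Fmax)
  chi <- sqrt(stats::qchisq(u, df = p))
  s <- sample(c(-1, 1), n_draws, replace = TRUE)
  g <- if (p == 1) 1 else stats::rbeta(n_draws, 1 / 2, (p - 1) / 2)
  chi * s * sqrt(g)
}

#' Mixture limit law of the rejective-sampling estimator
#'
#' The limiting distribution `a * L_{p,gamma^2} + b * Z1 + c * Z2` of the
#' (suitably scaled) estimator error: one truncated balanced component plus
#' two independent standard normal components. Quantiles are computed by
#' Monte Carlo with a fixed documented seed so reported intervals are
#' reproducible.
#'
#' @param p balance dimension.
#' @param gamma2 threshold (possibly `Inf`).
#' @param coeffs nonnegative length-3 vector `(a, b, c)` scaling
#'   `(L, Z1, Z2)`.
#' @param mc_draws Monte Carlo size for quantiles (default 2e6).
#' @param mc_seed seed used for the quantile Monte Carlo.
#' @return an object of class `mixture_law`.
#' @export
mixture_law <- function(p, gamma2, coeffs, mc_draws = 2e6, mc_seed = 20240229L) {
  if (length(coeffs) != 3 || any(coeffs < 0)) {
    stop("coeffs must be three nonnegative numbers (a, b, c)")
  }
  if (all(coeffs == 0)) stop("degenerate mixture law: all coefficients zero")
  structure(
    list(p = p, gamma2 = gamma2, coeffs = as.numeric(coeffs),
         mc_draws = mc_draws, mc_seed = mc_seed),
    class = "mixture_law"
  )
}

.mixture_draws <- function(law) {
  set.seed(law$mc_seed)
  n <- law$mc_draws
  a <- law$coeffs[1]; b <- law$coeffs[2]; cc <- law$coeffs[3]
  out <- numeric(n)
  if (a > 0) out <- a * sample_L(law$p, law$gamma2, n)
  if (b > 0) out <- out + b * stats::rnorm(n)
  if (cc > 0) out <- out + cc * stats::rnorm(n)
  out
}

#' Quantiles of the mixture limit law
#'
#' Monte Carlo quantiles with linear interpolation between adjacent order
#' statistics (the interpolation choice affects only the last reported
#' digit). The law is symmetric about zero, so `q(alpha) = -q(1 - alpha)`
#' up to Monte Carlo error.
#'
#' @param law a [mixture_law].
#' @param alpha probability (vectorised), in (0, 1).
#' @return numeric quantile(s).
#' @export
mixture_quantile <- function(law, alpha) {
  stopifnot(inherits(law, "mixture_law"))
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must be in (0, 1)")
  v <- .mixture_draws(law)
  unname(stats::quantile(v, probs = alpha, type = 7))
}

#' Theoretical percentage reduction in asymptotic design variance
#'
#' The closed-form percentage by which rejective sampling reduces the
#' asymptotic design variance of the phase-II sample mean relative to the
#' same two-phase SRS design without rejection:
#' `100 * (1 - f_II,I) / (1 - f_II,I * f_I,0) * (1 - v_{p,gamma^2}) * R^2`.
#' Zero when the composed design is a census (`f_II,I * f_I,0 = 1`).
#'
#' @param p balance dimension.
#' @param gamma2 threshold.
#' @param R2 squared correlation between x and y, in `[0, 1]`.
#' @param fII_I phase-II sampling fraction `n_II / n_I`.
#' @param fI_0 phase-I sampling fraction `n_I / N`.
#' @return the reduction in percent.
#' @export
theoretical_reduction <- function(p, gamma2, R2, fII_I, fI_0) {
  if (R2 < 0 || R2 > 1) stop("R2 must be in [0, 1]")
  if (fII_I < 0 || fII_I > 1 || fI_0 < 0 || fI_0 > 1) {
    stop("sampling fractions must be in [0, 1]")
  }
  if (fII_I * fI_0 == 1) return(0)
  v <- v_p_gamma(p, gamma2)
  100 * (1 - fII_I) / (1 - fII_I * fI_0) * (1 - v) * R2
}

#' Closed-form asymptotic variances under two-phase SRS with rejection
#'
#' Variances of the `sqrt(n_II)`-scaled estimator errors:
#' the phase-II sample mean has asymptotic variance
#' `[(1 - f)(1 - (1 - v) R^2) + f (1 - f0)] V_yy` (shrinking toward the
#' regression estimator's as `gamma2 -> 0`), and the regression estimator has
#' `f (1 - f0) V_yy + (1 - f) V_ee` with `V_ee = V_yy (1 - R^2)`,
#' independent of `gamma2`.
#'
#' @inheritParams theoretical_reduction
#' @param Vyy population variance of y.
#' @return list with `var_yII` and `var_yreg`.
#' @export
asymptotic_variance_srs <- function(p, gamma2, R2, Vyy, fII_I, fI_0) {
  if (R2 < 0 || R2 > 1) stop("R2 must be in [0, 1]")
  if (fII_I < 0 || fII_I > 1 || fI_0 < 0 || fI_0 > 1) {
    stop("sampling fractions must be in [0, 1]")
  }
  v <- v_p_gamma(p, gamma2)
  Vee <- Vyy * (1 - R2)
  list(
    var_yII = ((1 - fII_I) * (1 - (1 - v) * R2) + fII_I * (1 - fI_0)) * Vyy,
    var_yreg = fII_I * (1 - fI_0) * Vyy + (1 - fII_I) * Vee
  )
}
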