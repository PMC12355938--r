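# Point estimators of the finite-population mean under multi-phase designs:
# Hajek / double-expansion (pi*) means, the reweighted expansion estimator for
# stratified second phases, and the regression estimator with its implied
# per-unit weights.

.sample_values <- function(sample, values) {
  pop <- .parent_population(sample)
  v <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  if (nrow(v) == pop$N) {
    v[sample$selected, , drop = FALSE]
  } else if (nrow(v) == length(sample$selected)) {
    v
  } else {
    stop("values length matches neither the population nor the sample")
  }
}

#' Hajek (normalized inverse-probability) mean
#'
#' `sum(w_i u_i) / sum(w_i)` with `w_i = 1 / pi*_i`, the inverse cumulative
#' product of the per-phase conditional inclusion probabilities. For a
#' phase-I sample this is the ordinary Hajek estimator; for later phases it
#' is the Hajek form of the double-expansion estimator.
#'
#' @param sample a `phase_sample`.
#' @param values study values: a full population-length vector (subset
#'   internally) or a vector aligned with the sample.
#' @return the weighted mean (scalar, or vector for matrix values).
#' @export
hajek_mean <- function(sample, values) {
  if (length(sample$selected) == 0) stop("empty sample")
  u <- .sample_values(sample, values)
  w <- 1 / sample$cum_pistar
  sw <- sum(w)
  if (sw <= 0) stop("zero weight sum")
  drop(colSums(u * w) / sw)
}

#' Double-expansion (pi*) estimator of the population mean
#'
#' The Hajek-normalized double-expansion estimator: phase-II (or later)
#' observations weighted by the inverse of the cumulative inclusion
#' probability `pi* = pi_I * pi_II|A * ...`. Under two-phase simple random
#' sampling the weights are equal and the estimator reduces exactly to the
#' unweighted phase-II mean.
#'
#' @inheritParams hajek_mean
#' @export
pistar_mean <- function(sample, values) {
  if (sample$phase_index < 2) {
    stop("pistar_mean is defined for phase >= 2 samples; use hajek_mean for phase I")
  }
  hajek_mean(sample, values)
}

#' Reweighted expansion estimator (REE)
#'
#' Stratum-wise ratio estimator for stratified second phases: the estimated
#' phase-I stratum size (expanded by 1/pi_I) multiplies the phase-II weighted
#' stratum mean of y, summed over strata and divided by the known N.
#'
#' @param sampleI phase-I `phase_sample`.
#' @param sampleII phase-II `phase_sample` drawn from `sampleI`.
#' @param stratum_labels stratum label per unit (population-length or aligned
#'   with the phase-I sample).
#' @param values study variable (population-length or phase-II aligned).
#' @return the REE point estimate.
#' @export
ree_mean <- function(sampleI, sampleII, stratum_labels, values) {
  pop <- .parent_population(sampleI)
  lab_I <- .resolve_labels(sampleI, stratum_labels)      # aligned with A
  yB <- drop(.sample_values(sampleII, values))
  lab_B_full <- if (length(stratum_labels) == pop$N) {
    stratum_labels[sampleII$selected]
  } else {
    lab_I[match(sampleII$selected, sampleI$selected)]
  }
  wI <- 1 / sampleI$cond_pi
  wB <- 1 / sampleII$cum_pistar
  total <- 0
  for (h in unique(lab_I)) {
    Nh_hat <- sum(wI[lab_I == h])
    inB <- lab_B_full == h
    if (!any(inB)) {
      if (Nh_hat > 0) {
        stop(sprintf("stratum '%s' has phase-I weight but no phase-II units", h))
      }
      next
    }
    total <- total + Nh_hat * sum(wB[inB] * yB[inB]) / sum(wB[inB])
  }
  total / pop$N
}

#' Phase-II regression coefficient
#'
#' Solves the centered (optionally pi*-weighted) normal equations
#' `beta = {sum w (x - xbar)^2}^-1 sum w (x - xbar)(y - ybar)`, with the
#' centering means matching the weighting.
#'
#' @param sample a `phase_sample`.
#' @param x auxiliary matrix (population-length or sample-aligned).
#' @param y study values.
#' @param weighting `"unweighted"` (SRS phases) or `"pistar"` (weights
#'   `1/pi*`).
#' @return an object of class `regression_fit` with `beta_hat`, `xbar_used`,
#'   `ybar_used`, `weights_used`.
#' @export
regression_coefficient <- function(sample, x, y,
                                   weighting = c("unweighted", "pistar")) {
  weighting <- match.arg(weighting)
  X <- .sample_values(sample, x)
  yv <- drop(.sample_values(sample, y))
  w <- if (weighting == "pistar") 1 / sample$cum_pistar else rep(1, nrow(X))
  xbar <- colSums(X * w) / sum(w)
  ybar <- sum(yv * w) / sum(w)
  Xc <- sweep(X, 2, xbar)
  Sxx <- crossprod(Xc * w, Xc)
  if (rcond(Sxx) < 1e-12) {
    ev <- eigen(Sxx, symmetric = TRUE)
    dir <- paste(sprintf("%.3f", ev$vectors[, ncol(Sxx)]), collapse = ", ")
    stop(sprintf("collinear regressors: null direction approximately (%s)", dir))
  }
  beta <- drop(solve(Sxx, crossprod(Xc * w, yv - ybar)))
  structure(
    list(beta_hat = beta, xbar_used = xbar, ybar_used = ybar, weights_used = w),
    class = "regression_fit"
  )
}

#' Two-phase regression estimator of the population mean
#'
#' `ybar_reg = ybar_II - (xbar_II - xbar_I)' beta_II`, adjusting the phase-II
#' mean by the auxiliary-mean discrepancy between phases times the phase-II
#' regression slope. Phase means are unweighted under `"unweighted"` and
#' Hajek means under `"pistar"`.
#'
#' @inheritParams regression_coefficient
#' @param sampleI phase-I sample.
#' @param sampleII phase-II sample.
#' @return the regression point estimate.
#' @export
regression_estimate <- function(sampleI, sampleII, x, y,
                                weighting = c("unweighted", "pistar")) {
  weighting <- match.arg(weighting)
  fit <- regression_coefficient(sampleII, x, y, weighting)
  XI <- .sample_values(sampleI, x)
  if (weighting == "pistar") {
    wI <- 1 / sampleI$cum_pistar
    xbarI <- colSums(XI * wI) / sum(wI)
  } else {
    xbarI <- colMeans(XI)
  }
  fit$ybar_used - drop(t(fit$xbar_used - xbarI) %*% fit$beta_hat)
}

#' Implied regression weights (SRS case)
#'
#' Expresses the SRS regression estimator as a weighted average of the
#' phase-II outcomes: `omega_i = 1 + n_II (xbar_I - xbar_II)' Sxx^-1 (x_i -
#' xbar_II)` where `Sxx` is the sum of squared deviations in the phase-II
#' sample (the `n_II` factor makes the exact identity `sum(omega_i y_i) /
#' n_II = ybar_reg` hold; it does not affect which weights are negative).
#' Negative omega flag influential auxiliary values, and rejective sampling
#' makes them rarer.
#'
#' @param sampleI,sampleII phase samples (SRS weighting assumed).
#' @param x auxiliary matrix.
#' @return a list with `omega` (per-unit weights, phase-II order) and
#'   `n_negative`.
#' @export
regression_weights <- function(sampleI, sampleII, x) {
  XB <- .sample_values(sampleII, x)
  XI <- .sample_values(sampleI, x)
  xbarII <- colMeans(XB)
  xbarI <- colMeans(XI)
  Xc <- sweep(XB, 2, xbarII)
  Sxx <- crossprod(Xc)
  if (rcond(Sxx) < 1e-12) stop("collinear auxiliaries in regression_weights")
  omega <- 1 + nrow(XB) * drop(Xc %*% solve(Sxx, xbarI - xbarII))
  list(omega = omega, n_negative = sum(omega < 0))
}
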