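# Three-phase rejective sampling: phase-I SRS, phase-II Poisson
# probability-proportional-to-x with rejection on x-balance, block-wise
# orthogonalization of the second-tier auxiliaries z against x, and phase-III
# Poisson with rejection on the balance of the residualized block.
#
# Balancing only the residual block at phase III follows the block-wise
# Gram-Schmidt idea: x is already balanced at phase II, so the information z
# adds is its component orthogonal to x. Joint (x, a) balancing is available
# by flag.

#' Three-phase sampling plan
#'
#' @param nI phase-I SRS size.
#' @param expected_nII,expected_nIII expected Poisson sample sizes for phases
#'   II and III.
#' @param gamma1_2 balance threshold for the phase-II x-balance (`Inf`
#'   disables rejection).
#' @param gamma2_2 threshold for the phase-III balance on the residualized z
#'   block.
#' @param max_draws candidate cap per rejective phase.
#' @param balance_mode `"residual"` balances only the orthogonalized z block
#'   at phase III; `"joint"` balances `(x, a)` jointly.
#' @return an object of class `three_phase_plan`.
#' @export
three_phase_plan <- function(nI, expected_nII, expected_nIII,
                             gamma1_2 = Inf, gamma2_2 = Inf,
                             max_draws = 1e6,
                             balance_mode = c("residual", "joint")) {
  balance_mode <- match.arg(balance_mode)
  if (!(gamma1_2 > 0) || !(gamma2_2 > 0)) stop("thresholds must be positive or Inf")
  structure(
    list(nI = as.integer(nI), expected_nII = expected_nII,
         expected_nIII = expected_nIII, gamma1_2 = gamma1_2,
         gamma2_2 = gamma2_2, max_draws = max_draws,
         balance_mode = balance_mode),
    class = "three_phase_plan"
  )
}

#' Residualize second-tier auxiliaries against x
#'
#' For each column of z, subtracts the pi*-weighted phase-II regression on x:
#' `a_i = z_i - zbar_II - (x_i - xbar_II)' beta_zx,II`. By construction the
#' residual block has pi*-weighted mean zero and zero pi*-weighted
#' correlation with x on the phase-II sample.
#'
#' @param sampleII phase-II `phase_sample`.
#' @param z second-tier auxiliary matrix (population-length); defaults to the
#'   population's z block.
#' @param x auxiliary matrix (population-length); defaults to the
#'   population's x.
#' @return matrix of residuals aligned with `sampleII$selected`.
#' @export
residualize <- function(sampleII, z = NULL, x = NULL) {
  pop <- .parent_population(sampleII)
  if (is.null(z)) z <- pop$z
  if (is.null(z)) stop("no z variables to residualize")
  if (is.null(x)) x <- pop$x
  Z <- .sample_values(sampleII, z)
  X <- .sample_values(sampleII, x)
  w <- 1 / sampleII$cum_pistar
  wn <- w / sum(w)
  xbar <- colSums(X * wn)
  Xc <- sweep(X, 2, xbar)
  Sxx <- crossprod(Xc * w, Xc)
  if (rcond(Sxx) < 1e-12) stop("singular x cross-moments in residualize")
  zbar <- colSums(Z * wn)
  Zc <- sweep(Z, 2, zbar)
  beta <- solve(Sxx, crossprod(Xc * w, Zc))
  A <- Zc - Xc %*% beta
  colnames(A) <- paste0("a", seq_len(ncol(A)))
  A
}

#' Draw a three-phase rejective sample
#'
#' Phase I: SRS of size `nI`. Phase II: Poisson sampling with inclusion
#' probabilities proportional to x (which must be positive), accepted when
#' the general-design balance statistic on x against phase I is below
#' `gamma1_2`. The z block observed on phase II is residualized against x.
#' Phase III: Poisson sampling with probabilities proportional to the row
#' sums of z (shifted to positivity if needed; the shift is reported),
#' accepted when the balance statistic on the residual block (or on `(x, a)`
#' under `balance_mode = "joint"`) against phase II is below `gamma2_2`.
#'
#' @param pop a [finite_population] with positive single-column x and a z
#'   block.
#' @param plan a [three_phase_plan].
#' @param seed optional seed (one generator serves all phases sequentially).
#' @return list with `sampleI`, `sampleII`, `sampleIII`, `a` (residual block
#'   aligned with phase II), `balanceII`, `balanceIII`, `size_shift`.
#' @export
draw_three_phase <- function(pop, plan, seed = NULL) {
  stopifnot(inherits(pop, "finite_population"), inherits(plan, "three_phase_plan"))
  if (!is.null(seed)) set.seed(seed)
  if (any(pop$x <= 0)) stop("phase-II pps sampling needs strictly positive x")
  sI <- draw_srs(pop, plan$nI)
  ruleII <- rejection_rule(plan$gamma1_2, variance_mode = "general_eq17",
                           max_draws = plan$max_draws)
  resII <- tryCatch(
    rejective_draw(sI, list(kind = "poisson", expected_n = plan$expected_nII,
                            size_measure = drop(pop$x[, 1])),
                   ruleII),
    error = function(e) stop("phase-II acceptance failed: ", conditionMessage(e))
  )
  sII <- resII$sample
  a <- residualize(sII)
  # Embed the phase-II residual block into a population-length matrix so the
  # balance machinery (which indexes population rows) can use it.
  Afull <- matrix(0, pop$N, ncol(a))
  Afull[sII$selected, ] <- a
  bal_vals <- if (plan$balance_mode == "joint") cbind(pop$x, Afull) else Afull

  sm <- rowSums(pop$z)[sII$selected]
  shift <- 0
  if (min(sm) <= 0) {
    shift <- -min(sm) + 0.01 * (max(sm) - min(sm) + 1)
    sm <- sm + shift
  }
  ruleIII <- rejection_rule(plan$gamma2_2, variance_mode = "general_eq17",
                            max_draws = plan$max_draws)
  resIII <- tryCatch(
    rejective_draw(sII, list(kind = "poisson", expected_n = plan$expected_nIII,
                             size_measure = sm),
                   ruleIII, balance_values = bal_vals),
    error = function(e) stop("phase-III acceptance failed: ", conditionMessage(e))
  )
  list(sampleI = sI, sampleII = sII, sampleIII = resIII$sample, a = a,
       balanceII = resII$balance, balanceIII = resIII$balance,
       size_shift = shift)
}

#' Triple-expansion and regression estimates from a three-phase sample
#'
#' `y_III` is the Hajek mean with weights `1/pi***` (the cumulative product
#' over three phases). The regression estimator adjusts by both blocks:
#' `y_III_reg = y_III - (xbar_III - xbar_I)' beta_x - (abar_III - abar_II)'
#' beta_a`, with `(beta_x, beta_a)` from one pi***-weighted phase-III
#' regression of y on the orthogonalized blocks `(x, a)`.
#'
#' @param samples the list returned by [draw_three_phase].
#' @param y study values (population-length); defaults to the population y.
#' @return list with `y_III` and `y_III_reg`.
#' @export
three_phase_estimates <- function(samples, y = NULL) {
  sI <- samples$sampleI; sII <- samples$sampleII; sIII <- samples$sampleIII
  pop <- .parent_population(sI)
  if (is.null(y)) y <- pop$y
  if (length(sIII$selected) == 0) stop("empty phase-III sample")
  y_III <- hajek_mean(sIII, y)

  a <- samples$a
  idx3 <- match(sIII$selected, sII$selected)
  aIII <- a[idx3, , drop = FALSE]
  XIII <- pop$x[sIII$selected, , drop = FALSE]
  reg_mat <- cbind(XIII, aIII)
  w3 <- 1 / sIII$cum_pistar
  wn3 <- w3 / sum(w3)
  mbar <- colSums(reg_mat * wn3)
  Mc <- sweep(reg_mat, 2, mbar)
  Smm <- crossprod(Mc * w3, Mc)
  if (rcond(Smm) < 1e-12) stop("singular phase-III regression")
  yb <- y[sIII$selected]
  ybar3 <- sum(yb * wn3)
  beta <- drop(solve(Smm, crossprod(Mc * w3, yb - ybar3)))
  px <- ncol(XIII)
  beta_x <- beta[seq_len(px)]
  beta_a <- beta[-seq_len(px)]

  xbarI <- .hajek_cols(sI, pop$x)
  xbarIII <- mbar[seq_len(px)]
  abarIII <- mbar[-seq_len(px)]
  w2 <- 1 / sII$cum_pistar
  abarII <- colSums(a * (w2 / sum(w2)))
  y_III_reg <- y_III - drop(t(xbarIII - xbarI) %*% beta_x) -
    drop(t(abarIII - abarII) %*% beta_a)
  list(y_III = y_III, y_III_reg = y_III_reg)
}
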