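# Exhaustive-enumeration oracle for tiny two-phase designs and the Monte
# Carlo harness that replicates the simulation comparisons (bias, variance,
# variance estimates, coverage, variance reduction) and the closed-form
# theory table.

#' Exhaustively enumerate a tiny two-phase SRS design
#'
#' Enumerates every (phase-I, phase-II) outcome of SRS-within-SRS, computes
#' the balance statistic for each, and returns the exact acceptance
#' probability and the exact unconditional and conditional (on acceptance)
#' moments of the phase-II mean and regression estimators. This is the
#' ground-truth oracle the rejective sampler is validated against.
#'
#' @param pop a small [finite_population].
#' @param nI,nII phase sizes.
#' @param gamma2 threshold (possibly `Inf`).
#' @return an object of class `enumeration_result`: a data frame `outcomes`
#'   (one row per (A, B) pair with its probability, Q, and estimator
#'   values), `accept_prob`, and exact means/variances `ybarII_*`,
#'   `ybarreg_*` both unconditional and conditional.
#' @export
enumerate_two_phase_oracle <- function(pop, nI, nII, gamma2) {
  stopifnot(inherits(pop, "finite_population"))
  N <- pop$N
  n_outcomes <- choose(N, nI) * choose(nI, nII)
  if (n_outcomes > 1e5) {
    stop(sprintf("combinatorial bound exceeded: %g outcomes", n_outcomes))
  }
  X <- pop$x
  y <- pop$y
  fac <- 1 / nII - 1 / nI
  A_sets <- utils::combn(N, nI)
  B_rel <- utils::combn(nI, nII)
  prob <- 1 / n_outcomes
  rows <- vector("list", n_outcomes)
  k <- 0L
  for (ai in seq_len(ncol(A_sets))) {
    A <- A_sets[, ai]
    XA <- X[A, , drop = FALSE]
    xbarI <- colMeans(XA)
    V <- stats::cov(XA)
    Minv <- .solve_spd(fac * V)
    for (bi in seq_len(ncol(B_rel))) {
      Bset <- A[B_rel[, bi]]
      XB <- X[Bset, , drop = FALSE]
      d <- colMeans(XB) - xbarI
      Q <- drop(t(d) %*% Minv %*% d)
      ybarII <- mean(y[Bset])
      Xc <- sweep(XB, 2, colMeans(XB))
      Sxx <- crossprod(Xc)
      ybarreg <- if (rcond(Sxx) > 1e-12) {
        beta <- drop(solve(Sxx, crossprod(Xc, y[Bset] - ybarII)))
        ybarII - drop(t(colMeans(XB) - xbarI) %*% beta)
      } else NA_real_
      k <- k + 1L
      rows[[k]] <- c(Q = Q, ybarII = ybarII, ybarreg = ybarreg)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$prob <- prob
  out$accepted <- out$Q < gamma2
  accept_prob <- sum(out$prob[out$accepted])
  wmean <- function(v, w) sum(v * w) / sum(w)
  wvar <- function(v, w) {
    m <- wmean(v, w)
    sum(w * (v - m)^2) / sum(w)
  }
  cond <- out[out$accepted, ]
  structure(
    list(
      outcomes = out, accept_prob = accept_prob,
      ybarII_mean = wmean(out$ybarII, out$prob),
      ybarII_var = wvar(out$ybarII, out$prob),
      ybarII_mean_cond = wmean(cond$ybarII, cond$prob),
      ybarII_var_cond = wvar(cond$ybarII, cond$prob),
      ybarreg_mean_cond = if (all(is.finite(cond$ybarreg)))
        wmean(cond$ybarreg, cond$prob) else NA_real_,
      ybarreg_var_cond = if (all(is.finite(cond$ybarreg)))
        wvar(cond$ybarreg, cond$prob) else NA_real_
    ),
    class = "enumeration_result"
  )
}

#' Draw a two-phase SRS sample from the joint conditional law
#'
#' Redraws the entire two-phase chain (phase I and phase II) until the
#' balance statistic is accepted, so the accepted pair `(A, B)` is
#' distributed exactly as the unconditional two-phase design conditioned on
#' `{Q < gamma2}` — the law the enumeration oracle tabulates and the
#' asymptotic theory conditions on. By contrast, [rejective_draw()] holds
#' the phase-I sample fixed (the operational procedure: auxiliaries already
#' collected on phase I are not discarded) and therefore samples the per-A
#' conditional law; the two agree asymptotically but differ on tiny
#' populations because the acceptance probability varies with A.
#'
#' @param pop a [finite_population].
#' @param nI,nII phase sizes.
#' @param gamma2 threshold.
#' @param max_draws candidate cap (each candidate is a full (A, B) pair).
#' @param seed optional seed.
#' @return as [rejective_draw()]: list with `sample` (the phase-II
#'   `phase_sample`, whose `parent` is the accepted phase-I sample) and
#'   `balance`.
#' @export
rejective_two_phase <- function(pop, nI, nII, gamma2, max_draws = 1e6,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(pop, "finite_population"))
  X <- pop$x
  fac <- 1 / nII - 1 / nI
  if (!is.infinite(gamma2) && fac <= 0) stop("need n_II < n_I")
  for (k in seq_len(max_draws)) {
    A <- sample.int(pop$N, nI)
    rel <- sample.int(nI, nII)
    if (is.infinite(gamma2)) {
      Q <- 0
    } else {
      XA <- X[A, , drop = FALSE]
      d <- colMeans(XA[rel, , drop = FALSE]) - colMeans(XA)
      Q <- drop(t(d) %*% .solve_spd(fac * stats::cov(XA)) %*% d)
    }
    if (Q < gamma2) {
      sI <- new_phase_sample(A, rep(nI / pop$N, nI), pop, "srs",
                             list(n = as.integer(nI), M = pop$N))
      sII <- new_phase_sample(A[rel], rep(nII / nI, nII), sI, "srs",
                              list(n = as.integer(nII), M = nI))
      return(list(sample = sII, balance = new_balance_result(Q, TRUE, k)))
    }
  }
  stop(sprintf("no acceptance within %d joint draws", max_draws))
}

# Precompute mixture-law quantiles on a grid of R^2 values, reusing one draw
# set of (L, Z1, Z2), so per-replicate intervals cost an interpolation.
.srs_quantile_grid <- function(p, gamma2, f, f0, alpha, mc_draws = 1e6,
                               mc_seed = 20240229L, r2_grid = seq(0, 1, by = 0.02)) {
  set.seed(mc_seed)
  L <- sample_L(p, gamma2, mc_draws)
  Z1 <- stats::rnorm(mc_draws)
  Z2 <- stats::rnorm(mc_draws)
  s1 <- sqrt(1 - f)
  s2 <- sqrt(f * (1 - f0))
  qlo <- qhi <- numeric(length(r2_grid))
  for (i in seq_along(r2_grid)) {
    r2 <- min(r2_grid[i], 1 - 1e-10)
    v <- s1 * (sqrt(r2) * L + sqrt(1 - r2) * Z1) + s2 * Z2
    qq <- stats::quantile(v, c(alpha / 2, 1 - alpha / 2), type = 7)
    qlo[i] <- qq[1]; qhi[i] <- qq[2]
  }
  list(r2 = r2_grid, qlo = qlo, qhi = qhi)
}

.grid_ci <- function(grid, R2, point, Vyy, nII) {
  ql <- stats::approx(grid$r2, grid$qlo, xout = R2, rule = 2)$y
  qh <- stats::approx(grid$r2, grid$qhi, xout = R2, rule = 2)$y
  sc <- sqrt(Vyy / nII)
  c(point - qh * sc, point - ql * sc)
}

#' Monte Carlo comparison of rejective and non-rejective two-phase SRS
#'
#' For each threshold in `gamma2s` (use `Inf` for the plain design), runs
#' `n_mc` replicates of two-phase SRS from one fixed simulation population
#' and reports, for the phase-II mean and the regression estimator: bias
#' (x 1e-2), Monte Carlo variance (x 1e-3), mean of the variance estimates
#' (x 1e-3), 95% CI coverage (%), and the percentage variance reduction
#' relative to the plain design. The finite population is generated once per
#' call and held fixed; all randomness is the sampling.
#'
#' @param beta slope of the simulation population.
#' @param gamma2s thresholds; include `Inf` first to anchor the reduction
#'   column (if absent, VarRed is `NA`).
#' @param n_mc number of Monte Carlo replicates per threshold.
#' @param seed integer seed for population generation and sampling.
#' @param N,nI,nII design sizes.
#' @param alpha CI error rate.
#' @param ci compute variance estimates and intervals (slower when `FALSE`
#'   is not much faster; kept for harness reuse).
#' @return a data frame with one row per (gamma2, estimator).
#' @export
replicate_table1 <- function(beta, gamma2s = c(Inf, 0.01, 0.05, 0.1),
                             n_mc = 1000, seed = 1L, N = 1e5, nI = 5000,
                             nII = 200, alpha = 0.05, ci = TRUE) {
  if (n_mc < 2) stop("n_mc too small")
  pop <- make_simulation_population(N, beta, seed = seed)
  ybar0 <- mean(pop$y)
  p <- 1L
  res <- list()
  var_plain <- c(mean = NA_real_, reg = NA_real_)
  for (g in gamma2s) {
    grid <- if (ci) .srs_quantile_grid(p, g, nII / nI, nI / N, alpha) else NULL
    est_m <- est_r <- ve_m <- ve_r <- numeric(n_mc)
    cov_m <- cov_r <- logical(n_mc)
    set.seed(seed + 1L)
    rule <- rejection_rule(g, variance_mode = "srs_closed_form",
                           max_draws = 1e6)
    for (r in seq_len(n_mc)) {
      sI <- draw_srs(pop, nI)
      rd <- rejective_draw(sI, list(kind = "srs", n = nII), rule)
      sII <- rd$sample
      Bidx <- sII$selected
      ym <- mean(pop$y[Bidx])
      est_m[r] <- ym
      est_r[r] <- regression_estimate(sI, sII, pop$x, pop$y, "unweighted")
      if (ci) {
        vc <- var_hat_srs(sI, sII, pop$x, pop$y, N, g, "mean")
        ve_m[r] <- vc$variance
        vreg <- (vc$meta$f * (1 - vc$meta$f0) * vc$Vyy_hat +
                   (1 - vc$meta$f) * vc$Vee_hat) / nII
        ve_r[r] <- vreg
        ci_m <- .grid_ci(grid, vc$R2_hat, ym, vc$Vyy_hat, nII)
        cov_m[r] <- ci_m[1] <= ybar0 && ybar0 <= ci_m[2]
        z <- stats::qnorm(1 - alpha / 2)
        half <- z * sqrt(vreg)
        cov_r[r] <- abs(est_r[r] - ybar0) <= half
      }
    }
    vm <- stats::var(est_m)
    vr <- stats::var(est_r)
    if (is.infinite(g)) var_plain <- c(mean = vm, reg = vr)
    res[[length(res) + 1]] <- data.frame(
      gamma2 = g,
      estimator = c("ybarII", "ybarII_reg"),
      bias_x100 = 100 * c(mean(est_m) - ybar0, mean(est_r) - ybar0),
      var_x1000 = 1000 * c(vm, vr),
      ve_x1000 = if (ci) 1000 * c(mean(ve_m), mean(ve_r)) else NA_real_,
      cvg_pct = if (ci) 100 * c(mean(cov_m), mean(cov_r)) else NA_real_,
      varred_pct = if (is.infinite(g)) NA_real_ else
        100 * c(1 - vm / var_plain["mean"], 1 - vr / var_plain["reg"])
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Closed-form theory table for the simulation design
#'
#' Deterministic table of the limit-law variance `v_{1,gamma^2}` and the
#' theoretical percentage variance reduction for the standard simulation
#' design (`f_II,I = 200/5000`, `f_I,0 = 5000/1e5`) over thresholds
#' `gamma^2 in {0.01, 0.05, 0.1}` and `R^2 in {0.2, 0.5, 0.8}`. The
#' reduction increases with `R^2` and decreases with `gamma^2`.
#'
#' @param gamma2s thresholds; `R2s` squared correlations.
#' @param fII_I,fI_0 sampling fractions.
#' @return data frame with columns `gamma2`, `v`, and one reduction column
#'   per R^2 value.
#' @export
theory_table2 <- function(gamma2s = c(0.01, 0.05, 0.1),
                          R2s = c(0.2, 0.5, 0.8),
                          fII_I = 200 / 5000, fI_0 = 5000 / 1e5) {
  out <- data.frame(gamma2 = gamma2s,
                    v = vapply(gamma2s, function(g) v_p_gamma(1, g), 0))
  for (r2 in R2s) {
    out[[sprintf("red_R2_%.1f", r2)]] <- vapply(
      gamma2s, function(g) theoretical_reduction(1, g, r2, fII_I, fI_0), 0)
  }
  out
}
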