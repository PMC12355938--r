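# Parameters defined by general estimating equations: the population root of
# an averaged estimating function (mean, proportion, variance, quantile),
# estimated from the pi*-weighted phase-II estimating equation, with a
# sandwich-type variance built from the same double-sum components as the
# mean pipeline.

#' Built-in estimating functions
#'
#' Returns the standard estimating functions for survey parameters:
#' * `"mean"`: `s(y; xi) = y - xi` (root: population mean);
#' * `"proportion"`: `s(y; xi) = I(y < c) - xi` (root: proportion below `c`);
#' * `"variance_pair"`: `s = (y - xi1, (y - xi1)^2 - xi2)` (second root:
#'   population variance);
#' * `"quantile"`: `s(y; xi) = I(y <= xi) - tau`, nonsmooth; the root is the
#'   generalized inverse `inf{xi : sbar(xi) >= 0}`.
#'
#' @param kind one of `"mean"`, `"proportion"`, `"variance_pair"`,
#'   `"quantile"`.
#' @param c threshold for `"proportion"`.
#' @param tau quantile level in (0, 1) for `"quantile"`.
#' @return an object of class `estimating_function` with fields `dim_q`,
#'   `evaluate(y, xi)`, `derivative(y, xi)` (analytic kinds), `smooth`,
#'   `kind`.
#' @export
builtin_ee <- function(kind = c("mean", "proportion", "variance_pair", "quantile"),
                       c = NULL, tau = NULL) {
  kind <- match.arg(kind)
  ef <- switch(kind,
    mean = list(
      dim_q = 1L, smooth = TRUE,
      evaluate = function(y, xi) cbind(y - xi[1]),
      derivative = function(y, xi) matrix(-1, 1, 1)
    ),
    proportion = {
      if (is.null(c)) stop("proportion kind needs a threshold c")
      force(c)
      list(
        dim_q = 1L, smooth = TRUE,
        evaluate = function(y, xi) cbind(as.numeric(y < c) - xi[1]),
        derivative = function(y, xi) matrix(-1, 1, 1)
      )
    },
    variance_pair = list(
      dim_q = 2L, smooth = TRUE,
      evaluate = function(y, xi) cbind(y - xi[1], (y - xi[1])^2 - xi[2]),
      derivative = function(y, xi) {
        rbind(c(-1, 0), c(-2 * (mean(y) - xi[1]), -1))
      }
    ),
    quantile = {
      if (is.null(tau) || tau <= 0 || tau >= 1) stop("quantile kind needs tau in (0,1)")
      force(tau)
      list(
        dim_q = 1L, smooth = FALSE, tau = tau,
        evaluate = function(y, xi) cbind(as.numeric(y <= xi[1]) - tau),
        derivative = NULL
      )
    }
  )
  ef$kind <- kind
  structure(ef, class = "estimating_function")
}

#' Solve the phase-II weighted estimating equation
#'
#' Smooth kinds: the root of the pi*-weighted (Hajek) phase-II estimating
#' equation, found in closed form where available and otherwise by bracketed
#' root-finding to 1e-10. The quantile kind uses the exact generalized
#' inverse on the sorted phase-II support: the smallest observed y whose
#' cumulative normalized weight reaches tau (no iteration).
#'
#' @param sampleII phase-II (or later) `phase_sample`.
#' @param y study values (population-length or sample-aligned).
#' @param ee an [builtin_ee] estimating function.
#' @return the solution `xi` (length `dim_q`).
#' @export
solve_ee <- function(sampleII, y, ee) {
  stopifnot(inherits(ee, "estimating_function"))
  yv <- drop(.sample_values(sampleII, y))
  if (!length(yv)) stop("empty sample")
  w <- 1 / sampleII$cum_pistar
  w <- w / sum(w)
  if (ee$kind == "mean") return(sum(w * yv))
  if (ee$kind == "proportion") return(sum(w * ee$evaluate(yv, 0)[, 1]))
  if (ee$kind == "variance_pair") {
    xi1 <- sum(w * yv)
    xi2 <- sum(w * (yv - xi1)^2)
    return(c(xi1, xi2))
  }
  if (ee$kind == "quantile") {
    o <- order(yv)
    cw <- cumsum(w[o])
    k <- which(cw >= ee$tau - 1e-12)[1]
    return(yv[o][k])
  }
  # generic smooth scalar kind: bracketed root-finding
  sbar <- function(xi) sum(w * ee$evaluate(yv, xi)[, 1])
  lo <- min(yv) - 1
  hi <- max(yv) + 1
  span <- hi - lo
  while (sign(sbar(lo)) == sign(sbar(hi))) {
    lo <- lo - span
    hi <- hi + span
    span <- 2 * span
    if (span > 1e12 * (diff(range(yv)) + 1)) stop("no sign change in bracket")
  }
  stats::uniroot(sbar, c(lo, hi), tol = 1e-10)$root
}

#' Variance and confidence interval for an estimating-equation parameter
#'
#' Sandwich variance for the phase-II weighted estimating-equation solution:
#' the double-sum components of the mean pipeline applied to
#' `s_i(xi_hat)` in place of `y` and to the x-projection residuals
#' `e^s_i = s_i - B' x_i` in place of `e`, pre- and post-multiplied by the
#' inverse derivative of the limiting estimating function. For smooth kinds
#' the derivative is the weighted mean of the analytic derivative; for the
#' quantile kind it is a Gaussian-kernel density estimate of y at the
#' solution (Silverman bandwidth, pi*-weighted). The projection coefficient
#' `B` is computed from pi*-weighted phase-II sums, the plug-in counterpart
#' of its population definition. Confidence intervals use the mixture law
#' with the transformed components.
#'
#' @param sampleI,sampleII the phase samples.
#' @param x auxiliary matrix (population-length); `y` study values
#'   (population-length).
#' @param ee the [builtin_ee] estimating function.
#' @param xi_hat solution from [solve_ee] (computed if `NULL`).
#' @param gamma2 design threshold; `p` balance dimension (default from x).
#' @param form `"ht"` or `"syg"` double sums.
#' @param alpha interval error rate.
#' @param mc_draws,mc_seed Monte Carlo settings for mixture quantiles.
#' @return an `estimate_result` for the first component of `xi` (for
#'   `variance_pair`, the list carries `xi_hat` and the full component
#'   matrices; interval is for `xi_1`).
#' @export
ee_variance <- function(sampleI, sampleII, x, y, ee, xi_hat = NULL,
                        gamma2 = Inf, p = NULL, form = c("ht", "syg"),
                        alpha = 0.05, mc_draws = 2e6, mc_seed = 20240229L) {
  form <- match.arg(form)
  stopifnot(inherits(ee, "estimating_function"))
  pop <- .parent_population(sampleI)
  if (is.null(xi_hat)) xi_hat <- solve_ee(sampleII, y, ee)
  X <- if (is.matrix(x) && nrow(x) == pop$N) x else .pop_vars(pop, x)
  if (is.null(p)) p <- ncol(X)
  B <- sampleII$selected
  yB <- y[B]
  nII <- length(B)
  w <- 1 / sampleII$cum_pistar
  wn <- w / sum(w)
  S <- ee$evaluate(yB, xi_hat)                 # nII x q
  q <- ncol(S)

  # Gamma_s: derivative of the limiting estimating function at the root.
  if (ee$smooth) {
    Gs <- ee$derivative(yB, xi_hat)
    if (ee$kind %in% c("mean", "proportion")) Gs <- matrix(-1, 1, 1)
  } else {
    # quantile: d/dxi E I(y <= xi) = density of y at xi (weighted KDE)
    sd_w <- sqrt(sum(wn * (yB - sum(wn * yB))^2))
    bw <- 0.9 * sd_w * nII^(-1 / 5)            # Silverman rule
    Gs <- matrix(sum(wn * stats::dnorm((xi_hat - yB) / bw)) / bw, 1, 1)
  }
  if (rcond(Gs) < 1e-12) stop("singular derivative matrix Gamma_s")
  Ginv <- solve(Gs)

  # Projection of s on x with pi*-weighted phase-II sums.
  xbar <- colSums(X[B, , drop = FALSE] * wn)
  Xc <- sweep(X[B, , drop = FALSE], 2, xbar)
  sbar <- colSums(S * wn)
  Sc <- sweep(S, 2, sbar)
  Sxx <- crossprod(Xc * w, Xc)
  Bhat <- solve(Sxx, crossprod(Xc * w, Sc))    # p x q
  Es <- S - X[B, , drop = FALSE] %*% Bhat      # e^s_i
  ebar_s <- colSums(Es * wn)
  Esc <- sweep(Es, 2, ebar_s)

  pi_I <- .design_pi(sampleI, B)
  pi_II <- sampleII$cond_pi
  pistar <- sampleII$cum_pistar
  piI_mat <- .joint_matrix(sampleI, B)
  piII_mat <- .joint_matrix(sampleII, B)
  N <- pop$N

  VxxI <- .phase2_cov_general(sampleI, sampleII$design_kind,
                              sampleII$design_info, X)
  V1s <- nII * t(Bhat) %*% VxxI %*% Bhat
  if (form == "ht") {
    W2 <- (piII_mat - outer(pi_II, pi_II)) / (outer(pistar, pistar) * piII_mat)
    V2s <- (nII / N^2) * t(Esc) %*% W2 %*% Esc
    W3 <- (piI_mat - outer(pi_I, pi_I)) / (outer(pi_I, pi_I) * piI_mat * piII_mat)
    V3s <- (nII / N^2) * t(Sc) %*% W3 %*% Sc
  } else {
    if (sampleI$design_kind == "poisson" || sampleII$design_kind == "poisson") {
      stop("Sen-Yates-Grundy components require fixed-size phases")
    }
    V2s <- V3s <- matrix(0, q, q)
    C2 <- (piII_mat - outer(pi_II, pi_II)) / piII_mat
    C3 <- (piI_mat - outer(pi_I, pi_I)) / (piI_mat * piII_mat)
    for (a in seq_len(q)) for (b in seq_len(q)) {
      d2a <- Esc[, a] / pistar; d2b <- Esc[, b] / pistar
      V2s[a, b] <- -(nII / (2 * N^2)) *
        sum(C2 * outer(d2a, d2a, "-") * outer(d2b, d2b, "-"))
      d3a <- Sc[, a] / pi_I; d3b <- Sc[, b] / pi_I
      V3s[a, b] <- -(nII / (2 * N^2)) *
        sum(C3 * outer(d3a, d3a, "-") * outer(d3b, d3b, "-"))
    }
  }

  # Sandwich: var(xi_hat) = Ginv' (V1 v + V2 + V3) Ginv / nII
  v <- v_p_gamma(p, gamma2)
  Vtot <- t(Ginv) %*% (V1s * v + V2s + V3s) %*% Ginv / nII
  # Interval for the first component via the mixture law.
  g1 <- Ginv[, 1]
  a2 <- drop(t(g1) %*% V1s %*% g1)
  b2 <- drop(t(g1) %*% V2s %*% g1)
  c2 <- drop(t(g1) %*% V3s %*% g1)
  if (any(c(a2, b2, c2) < 0)) {
    stop("negative plug-in variance component; use form = 'syg'")
  }
  law <- mixture_law(p, gamma2, sqrt(c(a2, b2, c2)), mc_draws = mc_draws,
                     mc_seed = mc_seed)
  qq <- mixture_quantile(law, c(alpha / 2, 1 - alpha / 2))
  point <- xi_hat[1]
  ci <- c(point - qq[2] / sqrt(nII), point - qq[1] / sqrt(nII))
  comp <- new_variance_components(
    path = "general", form = form,
    meta = list(nII = nII, nI = length(sampleI$selected), N = N,
                gamma2 = gamma2, p = p, f = nII / length(sampleI$selected),
                f0 = length(sampleI$selected) / N),
    variance = Vtot[1, 1],
    V1 = a2, V2 = b2, V3 = c2, which = "mean"
  )
  structure(
    list(point = point, xi_hat = xi_hat, variance = Vtot[1, 1],
         variance_matrix = Vtot, components = comp, ci = ci, alpha = alpha,
         method = sprintf("estimating equation (%s), mixture-law interval",
                          ee$kind),
         acceptance = NULL),
    class = "estimate_result"
  )
}
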