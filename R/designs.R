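# Phase samplers, inclusion probabilities, balance statistics and the
# rejective accept/reject loop.
#
# A phase sample records, for each selected unit, its conditional first-order
# inclusion probability for that phase (pi_I or pi_II|A) and the cumulative
# product across phases (pi*), which is what the double-expansion estimators
# weight by. Second-order probabilities are derivable from the stored design
# metadata, in closed form for SRS, Poisson and stratified phases.

.parent_ids <- function(parent) {
  if (inherits(parent, "finite_population")) seq_len(parent$N) else parent$selected
}

.parent_pistar <- function(parent) {
  if (inherits(parent, "finite_population")) rep(1, parent$N) else parent$cum_pistar
}

.parent_population <- function(parent) {
  while (!inherits(parent, "finite_population")) parent <- parent$parent
  parent
}

new_phase_sample <- function(selected, cond_pi, parent, design_kind, design_info) {
  phase_index <- if (inherits(parent, "finite_population")) 1L else parent$phase_index + 1L
  pids <- .parent_ids(parent)
  ppistar <- .parent_pistar(parent)
  cum <- ppistar[match(selected, pids)] * cond_pi
  stopifnot(all(cond_pi > 0), all(cond_pi <= 1 + 1e-12))
  structure(
    list(
      selected = as.integer(selected), cond_pi = cond_pi, cum_pistar = cum,
      design_kind = design_kind, parent = parent, phase_index = phase_index,
      design_info = design_info
    ),
    class = "phase_sample"
  )
}

#' @export
print.phase_sample <- function(x, ...) {
  cat(sprintf("Phase-%d sample: n = %d unit(s), design = %s\n",
              x$phase_index, length(x$selected), x$design_kind))
  invisible(x)
}

#' Rejection rule for rejective sampling
#'
#' Bundles the balance threshold `gamma2`, the auxiliary columns entering the
#' balance statistic, the variance mode used to standardise the mean
#' difference, and the cap on candidate draws.
#'
#' @param gamma2 positive threshold (or `Inf` for no rejection); a candidate
#'   sample is accepted when the balance statistic satisfies `Q < gamma2`
#'   (strict inequality).
#' @param balance_columns columns of the population `x` entering the balance
#'   statistic (names or indices); default all.
#' @param variance_mode `"srs_closed_form"` standardises by the closed-form
#'   SRS-within-SRS design variance `(1/n_II - 1/n_I) V_xx,I`;
#'   `"general_eq17"` uses the Hajek-linearised design covariance built from
#'   second-order inclusion probabilities and works for any supported phase
#'   design.
#' @param max_draws cap on candidate draws before giving up.
#' @param record_draws if `TRUE`, keep the Q value of every candidate draw.
#' @return an object of class `rejection_rule`.
#' @export
rejection_rule <- function(gamma2, balance_columns = NULL,
                           variance_mode = c("srs_closed_form", "general_eq17"),
                           max_draws = 1e6, record_draws = FALSE) {
  variance_mode <- match.arg(variance_mode)
  if (!(gamma2 > 0)) stop("gamma2 must be positive (use Inf for no rejection)")
  if (max_draws < 1) stop("max_draws must be >= 1")
  structure(
    list(gamma2 = gamma2, balance_columns = balance_columns,
         variance_mode = variance_mode, max_draws = max_draws,
         record_draws = record_draws),
    class = "rejection_rule"
  )
}

new_balance_result <- function(Q, accepted, draws_used, q_trace = NULL) {
  structure(list(Q = Q, accepted = accepted, draws_used = as.integer(draws_used),
                 q_trace = q_trace),
            class = "balance_result")
}

# ---- samplers ---------------------------------------------------------------

#' Draw a simple random sample without replacement
#'
#' Uniform over all size-`n` subsets of the parent (a population for phase I,
#' or an earlier phase sample). Every unit's conditional inclusion probability
#' is `n / M` where `M` is the parent size.
#'
#' @param parent a [finite_population] or [phase_sample].
#' @param n sample size, `1 <= n <= M`.
#' @param seed optional integer seed; when `NULL` the ambient RNG stream is
#'   consumed (one `sample.int` call).
#' @return a `phase_sample`.
#' @export
draw_srs <- function(parent, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pids <- .parent_ids(parent)
  M <- length(pids)
  if (n < 1 || n > M) stop(sprintf("SRS size n = %d out of range [1, %d]", n, M))
  sel <- pids[sample.int(M, n)]
  new_phase_sample(sel, rep(n / M, n), parent, "srs", list(n = as.integer(n), M = M))
}

#' Draw a Poisson sample
#'
#' Independent Bernoulli inclusion with `pi_i = expected_n * p_i`, where
#' `p_i` is the size measure normalised to sum 1 within the parent. The
#' realized size is random and may be zero (flagged by a warning; the
#' rejective loop re-draws empty candidates internally).
#'
#' @param parent parent population or sample.
#' @param expected_n expected sample size.
#' @param size_measure per-unit positive sizes: a numeric vector aligned with
#'   the parent's units, or the name of a population `x`/`z` column.
#' @param seed optional seed (consumes one `runif(M)` call).
#' @return a `phase_sample` (possibly with zero units).
#' @export
draw_poisson <- function(parent, expected_n, size_measure, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pids <- .parent_ids(parent)
  M <- length(pids)
  sm <- .resolve_size_measure(parent, size_measure)
  if (any(sm <= 0)) stop("size_measure must be strictly positive")
  pi_i <- expected_n * sm / sum(sm)
  if (any(pi_i > 1)) {
    bad <- pids[pi_i > 1]
    stop(sprintf("infeasible Poisson design: pi_i > 1 for unit(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  keep <- stats::runif(M) < pi_i
  if (!any(keep)) warning("Poisson sampling returned an empty sample")
  new_phase_sample(pids[keep], pi_i[keep], parent, "poisson",
                   list(pi = pi_i, ids = pids))
}

.resolve_size_measure <- function(parent, size_measure) {
  pids <- .parent_ids(parent)
  if (is.character(size_measure) && length(size_measure) == 1L) {
    pop <- .parent_population(parent)
    sm <- drop(.pop_vars(pop, size_measure))[pids]
  } else {
    sm <- as.numeric(size_measure)
    if (length(sm) == length(pids)) {
      # aligned with parent
    } else {
      pop <- .parent_population(parent)
      if (length(sm) == pop$N) sm <- sm[pids]
      else stop("size_measure length matches neither parent nor population")
    }
  }
  sm
}

#' Draw a stratified simple random sample
#'
#' Independent SRS within each stratum; a unit in stratum h has conditional
#' inclusion probability `r_h / m_h` where `m_h` is the stratum size in the
#' parent and `r_h` the stratum take.
#'
#' @param parent parent population or sample.
#' @param stratum_labels stratum label per unit (aligned with the parent's
#'   units or with the full population).
#' @param per_stratum_n named vector of stratum sample sizes `r_h`.
#' @param seed optional seed.
#' @return a `phase_sample`.
#' @export
draw_stratified <- function(parent, stratum_labels, per_stratum_n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pids <- .parent_ids(parent)
  M <- length(pids)
  lab <- .resolve_labels(parent, stratum_labels)
  strata <- sort(unique(lab))
  if (is.null(names(per_stratum_n))) {
    if (length(per_stratum_n) != length(strata)) {
      stop("per_stratum_n must be named or match the number of strata")
    }
    names(per_stratum_n) <- strata
  }
  sel <- integer(0)
  cp <- numeric(0)
  m_h <- table(lab)
  for (h in strata) {
    idx <- which(lab == h)
    r <- per_stratum_n[[as.character(h)]]
    m <- length(idx)
    if (r < 1 || r > m) {
      stop(sprintf("stratum '%s': requested %d of %d units", h, r, m))
    }
    take <- idx[sample.int(m, r)]
    sel <- c(sel, pids[take])
    cp <- c(cp, rep(r / m, r))
  }
  new_phase_sample(sel, cp, parent, "stratified",
                   list(labels = lab, ids = pids,
                        r_h = per_stratum_n, m_h = as.vector(m_h),
                        strata = strata))
}

.resolve_labels <- function(parent, stratum_labels) {
  pids <- .parent_ids(parent)
  if (length(stratum_labels) == length(pids)) return(stratum_labels)
  pop <- .parent_population(parent)
  if (length(stratum_labels) == pop$N) return(stratum_labels[pids])
  stop("stratum_labels length matches neither parent nor population")
}

# ---- second-order inclusion probabilities -----------------------------------

#' Second-order conditional inclusion probabilities
#'
#' Closed-form pairwise (conditional) inclusion probabilities for the phase
#' that produced `sample`: SRS `pi_ij = n(n-1)/(M(M-1))` for `i != j`;
#' Poisson `pi_ij = pi_i pi_j` (independence); stratified uses the
#' within-stratum SRS form and the product across strata. `pi_ii = pi_i`.
#'
#' @param sample a `phase_sample`.
#' @param i,j unit ids (in the sample's parent); vectorised, recycled.
#' @return numeric vector of probabilities.
#' @export
joint_inclusion <- function(sample, i, j) {
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  di <- sample$design_info
  switch(sample$design_kind,
    srs = {
      p1 <- di$n / di$M
      p2 <- di$n * (di$n - 1) / (di$M * (di$M - 1))
      ifelse(i == j, p1, p2)
    },
    poisson = {
      pi_i <- di$pi[match(i, di$ids)]
      pi_j <- di$pi[match(j, di$ids)]
      ifelse(i == j, pi_i, pi_i * pi_j)
    },
    stratified = {
      hi <- di$labels[match(i, di$ids)]
      hj <- di$labels[match(j, di$ids)]
      r <- di$r_h; names(r) <- as.character(names(di$r_h))
      m <- stats::setNames(di$m_h, as.character(di$strata))
      ri <- r[as.character(hi)]; mi <- m[as.character(hi)]
      rj <- r[as.character(hj)]; mj <- m[as.character(hj)]
      out <- (ri / mi) * (rj / mj)                      # across strata
      same <- hi == hj
      out[same] <- (ri[same] * (ri[same] - 1)) / (mi[same] * (mi[same] - 1))
      out[i == j] <- (ri / mi)[i == j]
      unname(out)
    },
    stop(sprintf("unsupported design kind '%s'", sample$design_kind))
  )
}

# Dense matrix of pairwise conditional probabilities for the given units.
.joint_matrix <- function(sample, ids) {
  n <- length(ids)
  di <- sample$design_info
  switch(sample$design_kind,
    srs = {
      p2 <- di$n * (di$n - 1) / (di$M * (di$M - 1))
      m <- matrix(p2, n, n)
      diag(m) <- di$n / di$M
      m
    },
    poisson = {
      p <- di$pi[match(ids, di$ids)]
      m <- outer(p, p)
      diag(m) <- p
      m
    },
    stratified = {
      p1 <- joint_inclusion(sample, ids, ids)
      m <- matrix(0, n, n)
      for (a in seq_len(n)) m[a, ] <- joint_inclusion(sample, ids[a], ids)
      diag(m) <- p1
      m
    },
    stop(sprintf("unsupported design kind '%s'", sample$design_kind))
  )
}

# First-order conditional pi for arbitrary units of the parent (not only the
# realized sample), derived from the design metadata.
.design_pi <- function(sample, ids) {
  di <- sample$design_info
  switch(sample$design_kind,
    srs = rep(di$n / di$M, length(ids)),
    poisson = di$pi[match(ids, di$ids)],
    stratified = {
      r <- di$r_h
      m <- stats::setNames(di$m_h, as.character(di$strata))
      h <- di$labels[match(ids, di$ids)]
      unname(r[as.character(h)] / m[as.character(h)])
    },
    stop("unsupported design kind")
  )
}

# ---- balance statistics -----------------------------------------------------

.solve_spd <- function(V) {
  if (rcond(V) < 1e-12) {
    stop("balance metric V_xx,I is numerically singular (condition number > 1e12)")
  }
  solve(V)
}

# Hajek mean of the rows of U over a phase sample, weights 1/pi*.
.hajek_cols <- function(sample, U) {
  w <- 1 / sample$cum_pistar
  idx <- sample$selected
  colSums(U[idx, , drop = FALSE] * w) / sum(w)
}

# Linearised phase-II design covariance of the Hajek means given the phase-I
# sample, computed from second-order conditional probabilities. Exploits the
# exchangeable structure of SRS/stratified phases and the independence of
# Poisson phases so the double sum over the parent costs O(M), not O(M^2).
.phase2_cov_general <- function(sampleI, pi2_kind, pi2_info, U) {
  pop <- .parent_population(sampleI)
  A <- sampleI$selected
  M <- length(A)
  ubarI <- .hajek_cols(sampleI, U)
  a <- sweep(U[A, , drop = FALSE], 2, ubarI)      # centered at phase-I Hajek mean
  pistarI <- sampleI$cum_pistar                   # aligned with A
  Nsq <- pop$N^2
  if (pi2_kind == "poisson") {
    p <- pi2_info$pi                              # aligned with A
    pistar2 <- pistarI * p
    wdiag <- p * (1 - p) / pistar2^2
    return(crossprod(a * sqrt(wdiag)) / Nsq)
  }
  if (pi2_kind == "srs") {
    n <- pi2_info$n
    c1 <- n / M
    c2 <- n * (n - 1) / (M * (M - 1))
    pistar2 <- pistarI * c1
    aw <- a / pistar2
    s1 <- colSums(aw)
    off <- (c2 - c1^2)
    dia <- (c1 - c1^2) - off
    return((off * tcrossprod(s1) + dia * crossprod(a / pistar2, a / pistar2)) / Nsq)
  }
  if (pi2_kind == "stratified") {
    lab <- pi2_info$labels
    out <- 0
    for (h in unique(lab)) {
      idx <- which(lab == h)
      m <- length(idx)
      r <- pi2_info$r_h[[as.character(h)]]
      c1 <- r / m
      c2 <- if (m > 1) r * (r - 1) / (m * (m - 1)) else c1
      pistar2 <- pistarI[idx] * c1
      aw <- a[idx, , drop = FALSE] / pistar2
      s1 <- colSums(aw)
      off <- (c2 - c1^2)
      dia <- (c1 - c1^2) - off
      out <- out + off * tcrossprod(s1) + dia * crossprod(aw, aw)
    }
    return(out / Nsq)
  }
  stop(sprintf("unsupported phase-II design kind '%s'", pi2_kind))
}

#' Covariate balance statistic between two phases
#'
#' The normalized (Mahalanobis) distance between the phase-II and phase-I
#' auxiliary means, standardised by the phase-II design variance of the mean
#' difference given the phase-I sample. In `"srs_closed_form"` mode the means
#' are unweighted and the metric is `(1/n_II - 1/n_I) V_xx,I` with `V_xx,I`
#' the phase-I sample covariance (divisor `n_I - 1`). In `"general_eq17"`
#' mode the means are Hajek means and the metric is the linearised design
#' covariance built from second-order inclusion probabilities. Without
#' rejection the statistic is asymptotically chi-square with p degrees of
#' freedom.
#'
#' @param sampleII later-phase `phase_sample` drawn from `sampleI`.
#' @param sampleI earlier-phase `phase_sample`.
#' @param rule a [rejection_rule] (supplies columns and variance mode).
#' @return a `balance_result` with the Q value (`accepted` is `NA`).
#' @export
balance_statistic <- function(sampleII, sampleI, rule) {
  pop <- .parent_population(sampleI)
  cols <- if (is.null(rule$balance_columns)) seq_len(ncol(pop$x)) else rule$balance_columns
  X <- pop$x[, cols, drop = FALSE]
  Q <- .balance_Q(sampleII, sampleI, X, rule$variance_mode)
  new_balance_result(Q, NA, 1L)
}

.balance_Q <- function(sampleII, sampleI, X, variance_mode) {
  A <- sampleI$selected
  B <- sampleII$selected
  if (variance_mode == "srs_closed_form") {
    nI <- length(A); nII <- length(B)
    fac <- 1 / nII - 1 / nI
    if (fac <= 0) stop("srs_closed_form balance needs n_II < n_I (zero variance factor)")
    xbarI <- colMeans(X[A, , drop = FALSE])
    xbarII <- colMeans(X[B, , drop = FALSE])
    V <- stats::cov(X[A, , drop = FALSE])
    d <- xbarII - xbarI
    drop(t(d) %*% .solve_spd(fac * V) %*% d)
  } else {
    xbarI <- .hajek_cols(sampleI, X)
    xbarII <- .hajek_cols(sampleII, X)
    V <- .phase2_cov_general(sampleI, sampleII$design_kind,
                             sampleII$design_info, X)
    d <- xbarII - xbarI
    drop(t(d) %*% .solve_spd(V) %*% d)
  }
}

# ---- the rejective loop -----------------------------------------------------

#' Draw a phase sample rejectively
#'
#' Repeats candidate draws of the phase sampler until the balance statistic
#' between the candidate and the parent sample satisfies `Q < gamma2`
#' (strict), or until `max_draws` candidates have been tried. The accepted
#' sample is distributed as the candidate design conditioned on the balance
#' event. Empty Poisson candidates are re-drawn inside the loop and counted
#' in `draws_used`.
#'
#' One seeded generator serves the whole call; candidate draws consume it
#' sequentially, so the realized draw count is reproducible given the seed.
#'
#' @param parent the earlier-phase `phase_sample` whose auxiliaries are being
#'   balanced against.
#' @param sampler a list describing the phase design: `list(kind = "srs",
#'   n = ...)`, `list(kind = "poisson", expected_n = ..., size_measure = ...)`,
#'   or `list(kind = "stratified", stratum_labels = ..., per_stratum_n = ...)`.
#' @param rule a [rejection_rule].
#' @param seed optional integer seed.
#' @param balance_values optional population-length matrix of balance
#'   variables overriding the `x` columns named by the rule (used e.g. to
#'   balance residualized second-tier auxiliaries in later phases).
#' @return a list with elements `sample` (the accepted `phase_sample`) and
#'   `balance` (a `balance_result` with the accepted Q and `draws_used`).
#' @export
rejective_draw <- function(parent, sampler, rule, seed = NULL,
                           balance_values = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- .parent_population(parent)
  if (is.null(balance_values)) {
    cols <- if (is.null(rule$balance_columns)) seq_len(ncol(pop$x)) else rule$balance_columns
    X <- pop$x[, cols, drop = FALSE]
  } else {
    X <- .as_var_matrix(balance_values, "b")
    if (nrow(X) != pop$N) stop("balance_values must be population-length")
  }
  A <- .parent_ids(parent)
  M <- length(A)
  XA <- X[A, , drop = FALSE]
  trace <- if (isTRUE(rule$record_draws)) numeric(0) else NULL

  if (sampler$kind == "srs" && rule$variance_mode == "srs_closed_form") {
    # Fast path: precompute the metric once; candidates are index draws.
    n <- sampler$n
    if (n < 1 || n > M) stop("SRS size out of range")
    fac <- 1 / n - 1 / M
    xbarI <- colMeans(XA)
    if (is.infinite(rule$gamma2)) {
      Minv <- NULL
    } else {
      if (fac <= 0) stop("srs_closed_form balance needs n_II < n_I")
      Minv <- .solve_spd(fac * stats::cov(XA))
    }
    for (k in seq_len(rule$max_draws)) {
      idx <- sample.int(M, n)
      if (is.null(Minv)) {
        Q <- 0
      } else {
        d <- colMeans(XA[idx, , drop = FALSE]) - xbarI
        Q <- drop(t(d) %*% Minv %*% d)
      }
      if (!is.null(trace)) trace <- c(trace, Q)
      if (Q < rule$gamma2) {
        s <- new_phase_sample(A[idx], rep(n / M, n), parent, "srs",
                              list(n = as.integer(n), M = M))
        return(list(sample = s, balance = new_balance_result(Q, TRUE, k, trace)))
      }
    }
    stop(sprintf(
      "rejective sampling failed to accept within %d draws (acceptance rate so far: 0)",
      rule$max_draws))
  }

  # General path: the phase design (inclusion probabilities, balance metric)
  # is candidate-invariant, so precompute it and draw candidates as bare
  # index sets; the phase_sample object is only built for the accepted draw.
  pi2_info <- .sampler_design_info(parent, sampler)
  general <- rule$variance_mode == "general_eq17"
  if (!is.infinite(rule$gamma2)) {
    if (general) {
      V <- .phase2_cov_general(parent, sampler$kind, pi2_info, X)
      Minv <- .solve_spd(V)
      xbarI <- .hajek_cols(parent, X)
    } else {
      xbarI <- colMeans(XA)
    }
  }
  ppistar <- .parent_pistar(parent)
  for (k in seq_len(rule$max_draws)) {
    idx <- switch(sampler$kind,
      srs = sample.int(M, pi2_info$n),
      poisson = which(stats::runif(M) < pi2_info$pi),
      stratified = {
        out <- integer(0)
        for (h in pi2_info$strata) {
          ih <- which(pi2_info$labels == h)
          out <- c(out, ih[sample.int(length(ih),
                                      pi2_info$r_h[[as.character(h)]])])
        }
        out
      })
    if (!length(idx)) next  # empty Poisson draw: redraw, counted
    if (is.infinite(rule$gamma2)) {
      Q <- 0
    } else if (general) {
      wII <- 1 / (ppistar[idx] * .info_pi(pi2_info, sampler$kind, idx, M))
      d <- colSums(XA[idx, , drop = FALSE] * wII) / sum(wII) - xbarI
      Q <- drop(t(d) %*% Minv %*% d)
    } else {
      nc <- length(idx)
      fac <- 1 / nc - 1 / M
      if (fac <= 0) stop("srs_closed_form balance needs n_II < n_I")
      d <- colMeans(XA[idx, , drop = FALSE]) - xbarI
      Q <- drop(t(d) %*% .solve_spd(fac * stats::cov(XA)) %*% d)
    }
    if (!is.null(trace)) trace <- c(trace, Q)
    if (Q < rule$gamma2) {
      cp <- .info_pi(pi2_info, sampler$kind, idx, M)
      s <- new_phase_sample(A[idx], cp, parent, sampler$kind, pi2_info)
      return(list(sample = s, balance = new_balance_result(Q, TRUE, k, trace)))
    }
  }
  stop(sprintf(
    "rejective sampling failed to accept within %d draws (acceptance rate so far: 0/%d)",
    rule$max_draws, rule$max_draws))
}

# Conditional first-order probabilities for parent positions idx.
.info_pi <- function(info, kind, idx, M) {
  switch(kind,
    srs = rep(info$n / M, length(idx)),
    poisson = info$pi[idx],
    stratified = {
      r <- info$r_h
      m <- stats::setNames(info$m_h, as.character(info$strata))
      h <- info$labels[idx]
      unname(unlist(r[as.character(h)]) / m[as.character(h)])
    })
}

.sampler_design_info <- function(parent, sampler) {
  pids <- .parent_ids(parent)
  M <- length(pids)
  switch(sampler$kind,
    srs = list(n = as.integer(sampler$n), M = M),
    poisson = {
      sm <- .resolve_size_measure(parent, sampler$size_measure)
      if (any(sm <= 0)) stop("size_measure must be strictly positive")
      pi_i <- sampler$expected_n * sm / sum(sm)
      if (any(pi_i > 1)) stop("infeasible Poisson design: some pi_i > 1")
      list(pi = pi_i, ids = pids)
    },
    stratified = {
      lab <- .resolve_labels(parent, sampler$stratum_labels)
      strata <- sort(unique(lab))
      r_h <- sampler$per_stratum_n
      if (is.null(names(r_h))) names(r_h) <- strata
      list(labels = lab, ids = pids, r_h = r_h,
           m_h = as.vector(table(lab)), strata = strata)
    },
    stop(sprintf("unsupported sampler kind '%s'", sampler$kind))
  )
}

#' Balance threshold from a target acceptance rate
#'
#' Without rejection the balance statistic is asymptotically chi-square with
#' p degrees of freedom, so setting `gamma2` to the `accept_prob` quantile of
#' that distribution yields an asymptotic acceptance rate of `accept_prob`.
#' The recommended default for tight balance is `accept_prob = 0.001`.
#'
#' @param p number of balance covariates.
#' @param accept_prob target acceptance probability in (0, 1).
#' @return the threshold `gamma2`.
#' @export
gamma_from_acceptance <- function(p, accept_prob) {
  if (!(accept_prob > 0 && accept_prob < 1)) stop("accept_prob must be in (0,1)")
  stats::qchisq(accept_prob, df = p)
}
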