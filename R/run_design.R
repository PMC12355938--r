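# Config-driven runner: read a population CSV and a design configuration,
# execute the phases (with rejection where configured), and return the
# estimates with variance decomposition and confidence interval. This is the
# engine behind the command-line interface.

#' Run a configured multi-phase design on a population
#'
#' The configuration (a list, or a path to a YAML file) has the shape:
#' ```
#' seed: 1
#' alpha: 0.05
#' estimator: mean        # or "regression"
#' phases:
#'   - kind: srs
#'     n: 400
#'   - kind: srs          # or poisson / stratified
#'     n: 80               # or expected_n + size_measure_column
#'     rejection:
#'       gamma2: 0.05      # or accept_prob
#'       variance_mode: srs_closed_form
#'       max_draws: 100000
#' ```
#' Only the second phase may carry a rejection block; its balance uses all x
#' columns unless `columns` is given.
#'
#' @param pop a [finite_population] or a path to a population CSV.
#' @param config a list or a YAML file path.
#' @return a list with `estimate` (an `estimate_result`), `samples`, and
#'   `balance`.
#' @export
run_design <- function(pop, config) {
  if (is.character(pop)) pop <- read_population(pop)
  if (is.character(config)) config <- .fix_yaml_n(yaml::read_yaml(config))
  if (!is.null(config$seed)) set.seed(config$seed)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  estimator <- if (is.null(config$estimator)) "mean" else config$estimator
  phases <- config$phases
  if (length(phases) != 2) stop("run_design supports two-phase configurations")

  ph1 <- phases[[1]]
  sI <- switch(ph1$kind,
    srs = draw_srs(pop, ph1$n),
    poisson = draw_poisson(pop, ph1$expected_n,
                           if (!is.null(ph1$size_measure_column))
                             ph1$size_measure_column else drop(pop$x[, 1])),
    stratified = draw_stratified(pop, pop$x[, ph1$stratum_column],
                                 unlist(ph1$per_stratum_n)),
    stop("unsupported phase-1 kind")
  )

  ph2 <- phases[[2]]
  rej <- ph2$rejection
  gamma2 <- Inf
  vmode <- "srs_closed_form"
  max_draws <- 1e6
  cols <- NULL
  if (!is.null(rej)) {
    cols <- rej$columns
    p_bal <- if (is.null(cols)) ncol(pop$x) else length(cols)
    gamma2 <- if (!is.null(rej$gamma2)) rej$gamma2 else
      gamma_from_acceptance(p_bal, rej$accept_prob)
    if (!is.null(rej$variance_mode)) vmode <- rej$variance_mode
    if (!is.null(rej$max_draws)) max_draws <- rej$max_draws
  }
  if (ph2$kind != "srs" && vmode == "srs_closed_form") vmode <- "general_eq17"
  rule <- rejection_rule(gamma2, balance_columns = cols,
                         variance_mode = vmode, max_draws = max_draws)
  sampler <- switch(ph2$kind,
    srs = list(kind = "srs", n = ph2$n),
    poisson = list(kind = "poisson", expected_n = ph2$expected_n,
                   size_measure = if (!is.null(ph2$size_measure_column))
                     ph2$size_measure_column else drop(pop$x[, 1])),
    stratified = list(kind = "stratified",
                      stratum_labels = pop$x[, ph2$stratum_column],
                      per_stratum_n = unlist(ph2$per_stratum_n)),
    stop("unsupported phase-2 kind")
  )
  rd <- rejective_draw(sI, sampler, rule)
  sII <- rd$sample

  srs_path <- sI$design_kind == "srs" && sII$design_kind == "srs"
  if (estimator == "mean") {
    point <- pistar_mean(sII, pop$y)
    comp <- if (srs_path) {
      var_hat_srs(sI, sII, pop$x, pop$y, pop$N, gamma2, "mean")
    } else if (sII$design_kind == "poisson" || sI$design_kind == "poisson") {
      ht_components(sI, sII, pop$x, pop$y, gamma2 = gamma2, which = "mean")
    } else {
      syg_components(sI, sII, pop$x, pop$y, gamma2 = gamma2, which = "mean")
    }
  } else {
    weighting <- if (srs_path) "unweighted" else "pistar"
    point <- regression_estimate(sI, sII, pop$x, pop$y, weighting)
    comp <- if (srs_path) {
      var_hat_srs(sI, sII, pop$x, pop$y, pop$N, gamma2, "regression")
    } else if (sII$design_kind == "poisson" || sI$design_kind == "poisson") {
      ht_components(sI, sII, pop$x, pop$y, gamma2 = gamma2, which = "regression")
    } else {
      syg_components(sI, sII, pop$x, pop$y, gamma2 = gamma2, which = "regression")
    }
  }
  est <- confidence_interval(point, comp, alpha = alpha)
  est$acceptance <- rd$balance
  list(estimate = est, samples = list(phaseI = sI, phaseII = sII),
       balance = rd$balance)
}

# YAML 1.1 implicit typing turns a bare `n:` key into boolean FALSE; restore
# the intended name recursively.
.fix_yaml_n <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) names(x) <- ifelse(nm %in% c("FALSE", "F"), "n", nm)
  lapply(x, .fix_yaml_n)
}

#' Serialize an estimate result to a plain list (for JSON output)
#'
#' @param est an `estimate_result`.
#' @return a named list of scalars.
#' @export
estimate_as_record <- function(est) {
  comp <- est$components
  list(
    point = est$point, variance = est$variance,
    V1 = comp$V1, V2 = comp$V2, V3 = comp$V3,
    R2_hat = comp$R2_hat, Vyy_hat = comp$Vyy_hat, Vee_hat = comp$Vee_hat,
    ci_low = est$ci[1], ci_high = est$ci[2], alpha = est$alpha,
    method = est$method, gamma2 = comp$meta$gamma2,
    draws_used = if (!is.null(est$acceptance)) est$acceptance$draws_used else NA
  )
}
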