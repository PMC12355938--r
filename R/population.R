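# Finite-population container and synthetic population generators.
#
# All design-based randomness in the package targets a fixed finite population:
# a table of N units carrying a p-dimensional auxiliary vector x, a study
# variable y, and optionally a second tier of auxiliaries z used by the
# three-phase designs.

#' Construct a finite population
#'
#' A `finite_population` is a fixed table of `N` units with auxiliary
#' variables `x` (an `N x p` matrix), a study variable `y`, and optionally a
#' second tier of auxiliaries `z` (an `N x q` matrix) used by three-phase
#' designs. All design-based inference in this package treats these values as
#' fixed; the only randomness is the sampling mechanism.
#'
#' @param x numeric vector or matrix of auxiliary variables (one row per unit).
#' @param y numeric vector, the study variable.
#' @param z optional numeric vector or matrix of second-tier auxiliaries.
#' @param unit_id optional integer ids; defaults to `1:N`. Must be unique.
#' @return an object of class `finite_population` with elements `unit_id`,
#'   `x`, `y`, `z`, `N`, `p`.
#' @export
finite_population <- function(x, y, z = NULL, unit_id = NULL) {
  x <- .as_var_matrix(x, "x")
  y <- as.numeric(y)
  N <- length(y)
  if (nrow(x) != N) stop("x and y imply different population sizes")
  if (!is.null(z)) {
    z <- .as_var_matrix(z, "z")
    if (nrow(z) != N) stop("z and y imply different population sizes")
    if (any(!is.finite(z))) stop("non-finite values in z")
  }
  if (is.null(unit_id)) unit_id <- seq_len(N)
  unit_id <- as.integer(unit_id)
  if (anyDuplicated(unit_id)) stop("unit_id values must be unique")
  if (length(unit_id) != N) stop("unit_id has wrong length")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in population variables")
  }
  structure(
    list(unit_id = unit_id, x = x, y = y, z = z, N = N, p = ncol(x)),
    class = "finite_population"
  )
}

.as_var_matrix <- function(v, prefix) {
  if (is.data.frame(v)) v <- as.matrix(v)
  if (!is.matrix(v)) v <- matrix(as.numeric(v), ncol = 1L)
  storage.mode(v) <- "double"
  if (is.null(colnames(v))) colnames(v) <- paste0(prefix, seq_len(ncol(v)))
  v
}

#' @export
print.finite_population <- function(x, ...) {
  cat(sprintf(
    "Finite population: N = %d, p = %d auxiliary column(s)%s\n",
    x$N, x$p,
    if (is.null(x$z)) "" else sprintf(", %d second-tier column(s)", ncol(x$z))
  ))
  invisible(x)
}

# Resolve variable selectors ("y", "x1", "z2", or all of "x"/"z") to a matrix.
.pop_vars <- function(pop, sel) {
  if (is.matrix(sel) || is.numeric(sel) && length(sel) == pop$N && !is.character(sel)) {
    return(.as_var_matrix(sel, "u"))
  }
  sel <- as.character(sel)
  cols <- lapply(sel, function(s) {
    if (s == "y") return(matrix(pop$y, ncol = 1, dimnames = list(NULL, "y")))
    if (s == "x") return(pop$x)
    if (s == "z") {
      if (is.null(pop$z)) stop("population has no z variables")
      return(pop$z)
    }
    if (s %in% colnames(pop$x)) return(pop$x[, s, drop = FALSE])
    if (!is.null(pop$z) && s %in% colnames(pop$z)) return(pop$z[, s, drop = FALSE])
    stop(sprintf("unknown variable selector '%s'", s))
  })
  do.call(cbind, cols)
}

#' Exact finite-population mean and covariance
#'
#' Computes the finite-population mean vector and the covariance matrix with
#' divisor `N - 1` for the selected variables.
#'
#' @param pop a [finite_population].
#' @param u variable selector for the first block: variable names
#'   (`"y"`, `"x"`, `"x1"`, `"z2"`, ...) or a numeric matrix/vector of length N.
#' @param v selector for the second block; defaults to `u`.
#' @return a list with `mean` (mean vector of `u`), `cov` (cross-covariance of
#'   `u` and `v`, divisor `N - 1`), and `mean_v`.
#' @export
population_moments <- function(pop, u = "y", v = u) {
  stopifnot(inherits(pop, "finite_population"))
  if (pop$N < 2) stop("degenerate population: N < 2")
  U <- .pop_vars(pop, u)
  V <- .pop_vars(pop, v)
  mu <- colMeans(U)
  mv <- colMeans(V)
  cc <- crossprod(sweep(U, 2, mu), sweep(V, 2, mv)) / (pop$N - 1)
  list(mean = mu, cov = cc, mean_v = mv)
}

#' Generate the simulation population for the two-phase designs
#'
#' One scalar auxiliary `x` drawn as `sqrt(0.5) * (chisq_1 - 1)` (mean 0,
#' variance 1), and `y = 1 + beta * x + e` with `e ~ N(0, 1)`. Under this
#' superpopulation the squared correlation between x and y is
#' `R^2 = beta^2 / (beta^2 + 1)`.
#'
#' RNG consumption order given `seed`: first the N chi-square draws for x,
#' then the N normal draws for e.
#'
#' @param N population size (>= 2).
#' @param beta regression slope tying y to x.
#' @param seed integer seed; the generation is reproducible given the seed.
#' @return a [finite_population] with p = 1.
#' @export
make_simulation_population <- function(N, beta, seed = NULL) {
  if (N < 2) stop("degenerate population: N < 2")
  if (!is.null(seed)) set.seed(seed)
  x <- sqrt(0.5) * (stats::rchisq(N, df = 1) - 1)
  e <- stats::rnorm(N)
  y <- 1 + beta * x + e
  finite_population(x = x, y = y)
}

#' Generate a synthetic three-phase population
#'
#' A synthetic analogue of a school-performance style population: one strictly
#' positive auxiliary `x` (so probability-proportional-to-x sampling is valid),
#' a 3-vector of second-tier auxiliaries `z` correlated with x, and a study
#' variable y linearly related to both. The positive x is built from a shifted
#' gamma variable: real assessment scores are positive and bounded well away
#' from zero, with a moderate coefficient of variation, which also keeps
#' probability-proportional-to-x designs feasible (`pi_i <= 1`) at realistic
#' sampling fractions. This population is a synthetic stand-in, not a
#' replication of any real survey frame.
#'
#' RNG consumption order given `seed`: the N gamma draws for x, then column by
#' column the N normal draws for each z column, then the N normal draws for e.
#'
#' @param N population size.
#' @param coef list of coefficients: `x_shift`, `x_shape`, `x_scale` for the
#'   shifted-gamma x; `z_slope` (length-3) and `z_sd` for z given x;
#'   `beta_x`, `beta_z` (length-3), `sd_e` for y given (x, z).
#' @param seed integer seed.
#' @return a [finite_population] with p = 1 and a 3-column z block.
#' @export
make_threephase_population <- function(N, coef = list(), seed = NULL) {
  if (N < 2) stop("degenerate population: N < 2")
  d <- list(
    x_shift = 5, x_shape = 2, x_scale = 1,
    z_slope = c(0.5, 0.4, 0.3), z_sd = 1,
    beta_x = 0.6, beta_z = c(0.3, 0.3, 0.3), sd_e = 1
  )
  d[names(coef)] <- coef
  if (!is.null(seed)) set.seed(seed)
  x <- d$x_shift + stats::rgamma(N, shape = d$x_shape, scale = d$x_scale)
  if (any(x <= 0)) stop("three-phase x must be strictly positive; increase x_shift")
  q <- length(d$z_slope)
  z <- matrix(0, N, q)
  for (k in seq_len(q)) {
    z[, k] <- d$z_slope[k] * x + stats::rnorm(N, sd = d$z_sd)
  }
  colnames(z) <- paste0("z", seq_len(q))
  e <- stats::rnorm(N, sd = d$sd_e)
  y <- 1 + d$beta_x * x + drop(z %*% d$beta_z) + e
  finite_population(x = x, y = y, z = z)
}

#' Read / write a finite population as CSV
#'
#' The CSV schema is a header row with columns `unit_id`, `x1..xp`, `y`, and
#' optionally `z1..zq`; UTF-8 with '.' as the decimal separator. `write` then
#' `read` round-trips the values up to text-float conversion.
#'
#' @param path file path.
#' @return [read_population] returns a [finite_population].
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("unit_id", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("population CSV is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  zcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  if (!length(xcols)) stop("population CSV is missing auxiliary columns x1..xp")
  for (cn in c("unit_id", xcols, "y", zcols)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[cn]])))))
      stop(sprintf("non-numeric values in column '%s' (e.g. row %d)",
                   cn, if (length(bad)) bad[1] else 1L))
    }
  }
  if (anyDuplicated(df$unit_id)) {
    stop(sprintf("duplicate unit_id at row %d", anyDuplicated(df$unit_id)))
  }
  finite_population(
    x = as.matrix(df[xcols]),
    y = df$y,
    z = if (length(zcols)) as.matrix(df[zcols]) else NULL,
    unit_id = df$unit_id
  )
}

#' @rdname read_population
#' @param pop a [finite_population].
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "finite_population"))
  df <- data.frame(unit_id = pop$unit_id)
  x <- pop$x
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  df <- cbind(df, as.data.frame(x))
  df$y <- pop$y
  if (!is.null(pop$z)) {
    z <- pop$z
    colnames(z) <- paste0("z", seq_len(ncol(z)))
    df <- cbind(df, as.data.frame(z))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
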