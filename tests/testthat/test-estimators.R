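test_that("Hajek and pi-star means match hand arithmetic and SRS special cases", {
  pop <- finite_population(x = c(1, 1), y = c(2, 4))
  sI <- census_phase1(pop)
  sII <- force_sample(sI, c(1, 2), c(0.5, 0.25), design_kind = "poisson")
  # weights 2 and 4: (2*2 + 4*4) / 6 = 10/3
  expect_equal(pistar_mean(sII, pop$y), 10 / 3, tolerance = 1e-12)

  # two-phase SRS: pi* weights are equal, so the estimator is the plain mean
  pop2 <- make_simulation_population(100, 1, seed = 1)
  sI2 <- draw_srs(pop2, 40, seed = 2)
  sII2 <- draw_srs(sI2, 10, seed = 3)
  expect_equal(pistar_mean(sII2, pop2$y), mean(pop2$y[sII2$selected]),
               tolerance = 1e-12)

  # census in all phases recovers the population mean exactly
  cI <- census_phase1(pop2)
  cII <- draw_srs(cI, 100, seed = 4)
  expect_equal(pistar_mean(cII, pop2$y), mean(pop2$y), tolerance = 1e-12)

  # degenerate y
  expect_equal(pistar_mean(sII2, rep(3, 100)), 3)
  expect_error(pistar_mean(sI2, pop2$y), "phase")
})

test_that("pi-star mean is design-consistent under non-rejective two-phase SRS", {
  pop <- make_simulation_population(2000, 1, seed = 5)
  set.seed(6)
  reps <- 2000
  est <- replicate(reps, {
    sI <- draw_srs(pop, 200)
    sII <- draw_srs(sI, 40)
    pistar_mean(sII, pop$y)
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - mean(pop$y)), 5 * se)
})

test_that("REE matches hand arithmetic and SRS special cases", {
  pop <- finite_population(x = 1:5, y = 1:5)
  lab <- c("a", "a", "a", "b", "b")
  sI <- census_phase1(pop)
  sII <- force_sample(sI, c(1, 2, 4), c(2 / 3, 2 / 3, 1 / 2),
                      design_kind = "poisson")
  # (1/5) * [3 * (1+2)/2 + 2 * 4] = 2.5
  expect_equal(ree_mean(sI, sII, lab, pop$y), 2.5, tolerance = 1e-12)

  # single stratum, SRS both phases: equals the phase-II mean
  pop2 <- make_simulation_population(60, 1, seed = 7)
  sI2 <- draw_srs(pop2, 30, seed = 8)
  sII2 <- draw_srs(sI2, 10, seed = 9)
  expect_equal(ree_mean(sI2, sII2, rep("s", 60), pop2$y),
               mean(pop2$y[sII2$selected]), tolerance = 1e-12)

  # constant y with every stratum sampled returns the constant under SRS
  expect_equal(ree_mean(sI2, sII2, rep("s", 60), rep(4, 60)), 4,
               tolerance = 1e-12)

  # empty phase-II stratum with phase-I weight is an error
  lab2 <- rep(c("a", "b"), each = 30)
  sIc <- census_phase1(pop2)
  sIIa <- force_sample(sIc, 1:5, rep(1 / 2, 5))
  expect_error(ree_mean(sIc, sIIa, lab2, pop2$y), "stratum")
})

test_that("regression coefficient solves the weighted normal equations", {
  pop <- finite_population(x = c(1, 2, 4), y = 2 + 3 * c(1, 2, 4))
  sII <- force_sample(census_phase1(pop), 1:3, rep(1, 3))
  expect_equal(regression_coefficient(sII, pop$x, pop$y)$beta_hat, 3,
               tolerance = 1e-12, ignore_attr = TRUE)

  # weighted 3-point toy vs direct 1x1 normal-equation solve
  popw <- finite_population(x = c(1, 2, 4), y = c(1, 5, 2))
  sw <- force_sample(census_phase1(popw), 1:3, c(0.5, 0.25, 0.8),
                     design_kind = "poisson")
  w <- 1 / c(0.5, 0.25, 0.8)
  xb <- sum(w * popw$x) / sum(w); yb <- sum(w * popw$y) / sum(w)
  bref <- sum(w * (popw$x - xb) * (popw$y - yb)) / sum(w * (popw$x - xb)^2)
  expect_equal(regression_coefficient(sw, popw$x, popw$y, "pistar")$beta_hat,
               bref, tolerance = 1e-12, ignore_attr = TRUE)

  # orthogonalized toy: y uncorrelated with x in sample
  popo <- finite_population(x = c(-1, 0, 1), y = c(1, -2, 1))
  so <- force_sample(census_phase1(popo), 1:3, rep(1, 3))
  expect_equal(regression_coefficient(so, popo$x, popo$y)$beta_hat, 0,
               tolerance = 1e-12, ignore_attr = TRUE)

  # collinear x errors
  popc <- finite_population(x = cbind(1:4, 2 * (1:4)), y = rnorm(4))
  sc <- force_sample(census_phase1(popc), 1:4, rep(1, 4))
  expect_error(regression_coefficient(sc, popc$x, popc$y), "collinear")
})

test_that("regression estimator matches hand values and exact-fit identities", {
  # SRS toy: phase I = 4 units, phase II = 2
  pop <- toy_pop()                           # x = (1,2,3,5), y = (2,4,1,3)
  sI <- census_phase1(pop)
  sII <- force_sample(sI, c(1, 2), rep(1 / 2, 2))
  # beta = (4-3)/(2-1.5) = 2; ybar_reg = 3 - (1.5 - 2.75)*2 = 5.5
  expect_equal(regression_estimate(sI, sII, pop$x, pop$y), 5.5,
               tolerance = 1e-12)

  # exact linear y: estimator equals a + b * xbar_I exactly
  popl <- finite_population(x = c(1, 2, 3, 5), y = 1 + 2 * c(1, 2, 3, 5))
  sIl <- census_phase1(popl)
  sIIl <- force_sample(sIl, c(2, 4), rep(1 / 2, 2))
  expect_equal(regression_estimate(sIl, sIIl, popl$x, popl$y),
               1 + 2 * mean(popl$x), tolerance = 1e-12)

  # balanced phases: reduces to the phase-II mean
  popb <- finite_population(x = c(1, 2, 3, 4), y = c(5, 1, 4, 2))
  sIb <- census_phase1(popb)
  sIIb <- force_sample(sIb, c(1, 4), rep(1 / 2, 2))
  expect_equal(regression_estimate(sIb, sIIb, popb$x, popb$y),
               mean(popb$y[c(1, 4)]), tolerance = 1e-12)
})

test_that("regression estimator is invariant to affine recoding of x", {
  pop <- make_simulation_population(300, 1, seed = 10)
  sI <- draw_srs(pop, 100, seed = 11)
  sII <- draw_srs(sI, 25, seed = 12)
  base <- regression_estimate(sI, sII, pop$x, pop$y)
  recoded <- regression_estimate(sI, sII, 3 + 10 * pop$x, pop$y)
  expect_equal(recoded, base, tolerance = 1e-10)
})

test_that("regression weights reproduce the estimator and flag imbalance", {
  pop <- make_simulation_population(500, 2, seed = 13)
  sI <- draw_srs(pop, 100, seed = 14)
  sII <- draw_srs(sI, 20, seed = 15)
  rw <- regression_weights(sI, sII, pop$x)
  yB <- pop$y[sII$selected]
  expect_equal(sum(rw$omega * yB) / length(yB),
               regression_estimate(sI, sII, pop$x, pop$y),
               tolerance = 1e-12)

  # balanced phases: all weights are exactly 1
  popb <- finite_population(x = c(1, 2, 3, 4), y = rnorm(4))
  sIb <- census_phase1(popb)
  sIIb <- force_sample(sIb, c(1, 4), rep(1 / 2, 2))
  expect_equal(regression_weights(sIb, sIIb, popb$x)$omega, c(1, 1),
               tolerance = 1e-12)
})

test_that("rejective sampling makes negative regression weights rarer", {
  pop <- make_simulation_population(20000, 2, seed = 16)
  nI <- 2000; nII <- 100; reps <- 1000
  neg_freq <- function(g, seed) {
    set.seed(seed)
    rule <- rejection_rule(g)
    mean(replicate(reps, {
      sI <- draw_srs(pop, nI)
      sII <- rejective_draw(sI, list(kind = "srs", n = nII), rule)$sample
      regression_weights(sI, sII, pop$x)$n_negative > 0
    }))
  }
  f_plain <- neg_freq(Inf, 17)
  f_rej <- neg_freq(0.01, 17)
  expect_gt(f_plain, 0)
  expect_lt(f_rej, f_plain)
})

test_that("regression estimate is design-consistent under non-rejective designs", {
  pop <- make_simulation_population(2000, 2, seed = 18)
  set.seed(19)
  reps <- 1500
  est <- replicate(reps, {
    sI <- draw_srs(pop, 200)
    sII <- draw_srs(sI, 40)
    regression_estimate(sI, sII, pop$x, pop$y)
  })
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - mean(pop$y)), 5 * se)
})
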