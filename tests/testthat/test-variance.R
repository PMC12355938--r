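test_that("phase-II sample covariance uses divisor n-1", {
  pop <- finite_population(x = rep(0, 3), y = c(1, 2, 3))
  s <- force_sample(census_phase1(pop), 1:3, rep(1, 3))
  expect_equal(drop(sample_cov_hat(s, pop$y)), 1, ignore_attr = TRUE)
  expect_equal(drop(sample_cov_hat(s, rep(2, 3))), 0, ignore_attr = TRUE)
  s2 <- force_sample(census_phase1(pop), 1:1, 1)
  expect_error(sample_cov_hat(s2, pop$y), "at least 2")
})

test_that("residual variance plug-ins match an independent least-squares fit", {
  # exact linear fit
  pop <- finite_population(x = c(1, 2, 3, 5, 6), y = 2 + 3 * c(1, 2, 3, 5, 6))
  s <- force_sample(census_phase1(pop), 1:5, rep(1, 5))
  rv <- residual_variance_hat(s, pop$x, pop$y)
  expect_equal(rv$Vee_hat, 0, tolerance = 1e-20)
  expect_equal(rv$R2_hat, 1 - 1e-10)

  # 5-point toy vs lm residual sum of squares / (n - p - 1)
  set.seed(1)
  popt <- finite_population(x = c(1, 2, 4, 7, 9), y = c(2, 1, 5, 4, 9))
  st <- force_sample(census_phase1(popt), 1:5, rep(1, 5))
  fit <- stats::lm(popt$y ~ popt$x[, 1])
  rvt <- residual_variance_hat(st, popt$x, popt$y)
  expect_equal(rvt$Vee_hat, sum(stats::resid(fit)^2) / (5 - 2),
               tolerance = 1e-10)
  expect_equal(rvt$R2_hat, summary(fit)$r.squared, tolerance = 1e-10)

  # beta = 0 imposed: Vyy_hat collapses to the df-inflated residual variance
  rv0 <- residual_variance_hat(st, popt$x, popt$y, beta_hat = 0)
  e <- popt$y - mean(popt$y)
  expect_equal(rv0$Vyy_hat, sum((popt$y - mean(popt$y))^2) / (5 - 2),
               tolerance = 1e-10)

  expect_error(residual_variance_hat(
    force_sample(census_phase1(popt), 1:2, rep(1, 2)), popt$x, popt$y),
    "degrees of freedom")
})

test_that("closed-form SRS variance estimator has the stated special cases", {
  pop <- make_simulation_population(200, 1, seed = 2)
  # census phase I: regression variance reduces to (1 - nII/nI) Vee / nII
  sI <- census_phase1(pop)
  sII <- draw_srs(sI, 50, seed = 3)
  vc <- var_hat_srs(sI, sII, pop$x, pop$y, pop$N, 0.05, "regression")
  rv <- residual_variance_hat(sII, pop$x, pop$y)
  expect_equal(vc$variance, (1 - 50 / 200) * rv$Vee_hat / 50, tolerance = 1e-12)

  # gamma2 = Inf: mean variance loses the R^2 term entirely
  pop2 <- make_simulation_population(1000, 1, seed = 4)
  sI2 <- draw_srs(pop2, 300, seed = 5)
  sII2 <- draw_srs(sI2, 60, seed = 6)
  vm <- var_hat_srs(sI2, sII2, pop2$x, pop2$y, pop2$N, Inf, "mean")
  f <- 60 / 300; f0 <- 300 / 1000
  expect_equal(vm$variance,
               ((1 - f) + f * (1 - f0)) * vm$Vyy_hat / 60, tolerance = 1e-12)

  expect_error(var_hat_srs(sI2,
    force_sample(sI2, sII2$selected, sII2$cond_pi, design_kind = "poisson"),
    pop2$x, pop2$y, pop2$N, Inf), "SRS")
})

test_that("general HT components agree with the closed form under two-phase SRS", {
  pop <- make_simulation_population(5000, 1, seed = 7)
  sI <- draw_srs(pop, 1000, seed = 8)
  sII <- draw_srs(sI, 200, seed = 9)
  eq13 <- var_hat_srs(sI, sII, pop$x, pop$y, pop$N, Inf, "regression")$variance
  ht <- ht_components(sI, sII, pop$x, pop$y, gamma2 = Inf, which = "regression")
  expect_lt(abs(ht$variance - eq13) / eq13, 0.10)

  # beta_hat = 0 kills V1
  ht0 <- ht_components(sI, sII, pop$x, pop$y, beta_hat = 0)
  expect_equal(ht0$V1, 0, tolerance = 1e-20)
})

test_that("the V3 double sum estimates the phase-I design variance", {
  pop <- make_simulation_population(2000, 1, seed = 10)
  nI <- 200; nII <- 80
  target <- (1 / nI - 1 / pop$N) * drop(population_moments(pop, "y")$cov)
  set.seed(11)
  v3s <- replicate(400, {
    sI <- draw_srs(pop, nI)
    sII <- draw_srs(sI, nII)
    ht_components(sI, sII, pop$x, pop$y)$V3 / nII
  })
  expect_lt(abs(mean(v3s) - target) / target, 0.15)
})

test_that("Sen-Yates-Grundy components are nonnegative and match HT under SRS", {
  pop <- make_simulation_population(3000, 1, seed = 12)
  sI <- draw_srs(pop, 600, seed = 13)
  sII <- draw_srs(sI, 150, seed = 14)
  ht <- ht_components(sI, sII, pop$x, pop$y, which = "regression")
  syg <- syg_components(sI, sII, pop$x, pop$y, which = "regression")
  expect_gte(syg$V2, 0)
  expect_gte(syg$V3, 0)
  expect_lt(abs(syg$variance - ht$variance) / ht$variance, 0.15)

  # constant residuals: exact linear y kills V2
  popl <- finite_population(x = 1:40, y = 2 + 3 * (1:40))
  sIl <- draw_srs(popl, 20, seed = 15)
  sIIl <- draw_srs(sIl, 8, seed = 16)
  sygl <- syg_components(sIl, sIIl, popl$x, popl$y)
  expect_lt(abs(sygl$V2), 1e-16)

  # nonnegativity across random draws
  set.seed(17)
  ok <- replicate(300, {
    sI <- draw_srs(pop, 100)
    sII <- draw_srs(sI, 25)
    v <- syg_components(sI, sII, pop$x, pop$y)
    v$V2 >= 0 && v$V3 >= 0
  })
  expect_true(all(ok))

  # Poisson phases are rejected
  sP <- suppressWarnings(draw_poisson(sI, 30, rep(1, 600), seed = 18))
  expect_error(syg_components(sI, sP, pop$x, pop$y), "fixed-size")
})

test_that("confidence intervals reduce to normal theory when the balanced part vanishes", {
  pop <- make_simulation_population(1000, 0, seed = 19)  # R^2 ~ 0
  sI <- draw_srs(pop, 300, seed = 20)
  sII <- draw_srs(sI, 60, seed = 21)
  vc <- var_hat_srs(sI, sII, pop$x, pop$y, pop$N, Inf, "mean")
  pt <- pistar_mean(sII, pop$y)
  est <- confidence_interval(pt, vc, alpha = 0.05, mc_draws = 5e5)
  # with gamma2 = Inf the mixture is normal with the closed-form variance
  zhalf <- stats::qnorm(0.975) * sqrt(vc$variance)
  expect_lt(abs((est$ci[2] - est$ci[1]) / 2 - zhalf) / zhalf, 0.02)
  expect_true(est$ci[1] <= pt && pt <= est$ci[2])

  # alpha = 0.5 collapses toward the point by symmetry
  est50 <- confidence_interval(pt, vc, alpha = 0.999, mc_draws = 5e5)
  expect_lt(est50$ci[2] - est50$ci[1], 0.01 * sqrt(vc$variance))
})
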