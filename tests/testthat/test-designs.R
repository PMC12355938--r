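test_that("SRS draws have the right conditional probabilities and frequencies", {
  pop <- make_simulation_population(10, 1, seed = 1)
  s <- draw_srs(pop, 4, seed = 2)
  expect_equal(s$cond_pi, rep(0.4, 4))
  expect_equal(s$cum_pistar, rep(0.4, 4))

  census <- draw_srs(pop, 10, seed = 3)
  expect_equal(census$cond_pi, rep(1, 10))
  expect_setequal(census$selected, 1:10)

  expect_error(draw_srs(pop, 11), "out of range")

  # per-unit selection frequency ~ n/N
  N <- 20; n <- 5; reps <- 4000
  pop2 <- make_simulation_population(N, 1, seed = 4)
  set.seed(5)
  counts <- integer(N)
  for (r in seq_len(reps)) {
    counts[draw_srs(pop2, n)$selected] <- counts[draw_srs(pop2, n)$selected] + 1L
  }
  p <- n / N
  se <- sqrt(p * (1 - p) / reps)
  expect_true(all(abs(counts / reps - p) < 5 * se))
})

test_that("Poisson draws respect the size measure and flag infeasible designs", {
  pop <- make_simulation_population(50, 1, seed = 6)
  s <- draw_poisson(pop, 10, rep(1, 50), seed = 7)
  expect_true(all(abs(s$cond_pi - 0.2) < 1e-12))

  sm <- c(100, rep(1, 49))
  expect_error(draw_poisson(pop, 10, sm), "infeasible")

  # realized size averages to expected_n
  set.seed(8)
  sizes <- replicate(2000, length(suppressWarnings(
    draw_poisson(pop, 10, runif(50, 0.5, 1.5))$selected)))
  se <- sd(sizes) / sqrt(2000)
  expect_lt(abs(mean(sizes) - 10), 5 * se)
})

test_that("stratified draws are within-stratum SRS with correct probabilities", {
  pop <- make_simulation_population(5, 1, seed = 9)
  lab <- c("a", "a", "a", "b", "b")
  s <- draw_stratified(pop, lab, c(a = 2, b = 1), seed = 10)
  expect_setequal(unique(s$cond_pi), c(2 / 3, 1 / 2))
  expect_equal(sum(s$cond_pi == 2 / 3), 2)

  # every within-stratum subset equiprobable: 3 subsets of stratum a x 2 of b
  set.seed(11)
  keys <- replicate(3000, paste(sort(draw_stratified(pop, lab,
                                                     c(a = 2, b = 1))$selected),
                                collapse = "-"))
  tab <- table(keys)
  expect_equal(length(tab), 6)
  gof <- stats::chisq.test(tab, p = rep(1 / 6, 6))
  expect_gt(gof$p.value, 0.001)
})

test_that("joint inclusion probabilities match closed forms and enumeration", {
  pop <- make_simulation_population(4, 1, seed = 12)
  s <- draw_srs(pop, 2, seed = 13)
  expect_equal(joint_inclusion(s, 1, 2), 1 / 6)
  expect_equal(joint_inclusion(s, 3, 3), 1 / 2)

  popP <- make_simulation_population(6, 1, seed = 14)
  sp <- suppressWarnings(draw_poisson(popP, 3, 1:6, seed = 15))
  pi_i <- 3 * (1:6) / sum(1:6)
  expect_equal(joint_inclusion(sp, 2, 5), pi_i[2] * pi_i[5])

  # enumeration oracle: pairwise frequencies over all C(6,3) subsets
  M <- 6; n <- 3
  pop6 <- make_simulation_population(M, 1, seed = 16)
  s6 <- draw_srs(pop6, n, seed = 17)
  subsets <- utils::combn(M, n)
  pair_freq <- matrix(0, M, M)
  for (k in seq_len(ncol(subsets))) {
    idx <- subsets[, k]
    pair_freq[idx, idx] <- pair_freq[idx, idx] + 1
  }
  pair_freq <- pair_freq / ncol(subsets)
  for (i in 1:M) for (j in 1:M) {
    expect_equal(joint_inclusion(s6, i, j), pair_freq[i, j], tolerance = 1e-12)
  }
  # sum identity over the enumeration: sum_{j != i} pi_ij = (n-1) pi_i
  expect_equal(sum(pair_freq[1, -1]), (n - 1) * pair_freq[1, 1], tolerance = 1e-12)

  # stratified cross/within forms
  popS <- make_simulation_population(5, 1, seed = 18)
  lab <- c("a", "a", "a", "b", "b")
  ss <- draw_stratified(popS, lab, c(a = 2, b = 1), seed = 19)
  expect_equal(joint_inclusion(ss, 1, 2), 2 * 1 / (3 * 2))   # within a
  expect_equal(joint_inclusion(ss, 1, 4), (2 / 3) * (1 / 2)) # across
})

test_that("balance statistic matches the hand example and is zero at exact balance", {
  pop <- finite_population(x = c(1, 2, 3, 5), y = rep(0, 4))
  sI <- census_phase1(pop)
  sII <- force_sample(sI, c(1, 2), rep(1 / 2, 2))
  rule <- rejection_rule(1, variance_mode = "srs_closed_form")
  Q <- balance_statistic(sII, sI, rule)$Q
  # d = 1.5 - 2.75, V = 35/12, factor = 1/2 - 1/4
  expect_equal(Q, 1.5625 / (0.25 * 35 / 12), tolerance = 1e-12)

  popb <- finite_population(x = c(1, 2, 3, 4), y = rep(0, 4))
  sIb <- census_phase1(popb)
  sIIb <- force_sample(sIb, c(1, 4), rep(1 / 2, 2))
  expect_equal(balance_statistic(sIIb, sIb, rule)$Q, 0, tolerance = 1e-14)

  # general mode agrees with the closed form under SRS-within-SRS
  popg <- make_simulation_population(400, 1, seed = 20)
  sIg <- draw_srs(popg, 100, seed = 21)
  sIIg <- draw_srs(sIg, 20, seed = 22)
  Qs <- balance_statistic(sIIg, sIg, rule)$Q
  Qg <- balance_statistic(sIIg, sIg,
                          rejection_rule(1, variance_mode = "general_eq17"))$Q
  expect_equal(Qg, Qs, tolerance = 1e-8)
})

test_that("without rejection the balance statistic is asymptotically chi-square(p)", {
  pop <- make_simulation_population(5000, 1, seed = 23)
  rule <- rejection_rule(Inf, variance_mode = "srs_closed_form",
                         record_draws = TRUE)
  set.seed(24)
  Qs <- replicate(1500, {
    sI <- draw_srs(pop, 500)
    sII <- draw_srs(sI, 50)
    balance_statistic(sII, sI, rule)$Q
  })
  ks <- stats::ks.test(Qs, stats::pchisq, df = 1)
  expect_gt(ks$p.value, 0.001)
})

test_that("the rejective loop accepts on the balance event with the expected effort", {
  pop <- make_simulation_population(1000, 1, seed = 25)
  sI <- draw_srs(pop, 200, seed = 26)
  res <- rejective_draw(sI, list(kind = "srs", n = 40),
                        rejection_rule(Inf), seed = 27)
  expect_equal(res$balance$draws_used, 1L)
  expect_true(res$balance$accepted)

  # acceptance rate ~ P(chi2_1 < 0.01): mean draws ~ 12.55
  set.seed(28)
  rule <- rejection_rule(0.01)
  draws <- replicate(500, {
    sI <- draw_srs(pop, 200)
    rejective_draw(sI, list(kind = "srs", n = 40), rule)$balance$draws_used
  })
  expected <- 1 / stats::pchisq(0.01, 1)
  se <- sd(draws) / sqrt(500)
  expect_lt(abs(mean(draws) - expected), 5 * se + 1)
  # accepted Q always below the threshold
  set.seed(29)
  sI <- draw_srs(pop, 200)
  acc <- rejective_draw(sI, list(kind = "srs", n = 40), rule)
  expect_lt(acc$balance$Q, 0.01)
})

test_that("rejection reduces the Monte Carlo variance of the auxiliary-correlated mean", {
  pop <- make_simulation_population(2000, 2, seed = 30)
  nI <- 400; nII <- 50; reps <- 800
  est <- function(g, seed) {
    set.seed(seed)
    rule <- rejection_rule(g)
    replicate(reps, {
      sI <- draw_srs(pop, nI)
      mean(pop$y[rejective_draw(sI, list(kind = "srs", n = nII),
                                rule)$sample$selected])
    })
  }
  v_plain <- var(est(Inf, 31))
  v_rej <- var(est(0.05, 31))
  # ~70% theoretical reduction at R^2 = 0.8 dwarfs the MC noise
  expect_lt(v_rej, v_plain)
  expect_lt(v_rej / v_plain, 0.7)
})

test_that("given a fixed phase-I sample, rejective_draw samples the conditional law", {
  # enumerate all C(5,2) = 10 phase-II subsets of one fixed phase-I sample,
  # condition on the balance event, and compare frequencies
  pop <- make_simulation_population(9, 1, seed = 32)
  sI <- draw_srs(pop, 5, seed = 33)
  g2 <- 1
  A <- sI$selected
  XA <- pop$x[A, , drop = FALSE]
  fac <- 1 / 2 - 1 / 5
  Minv <- 1 / (fac * stats::var(XA[, 1]))
  subs <- utils::combn(5, 2)
  key_all <- apply(subs, 2, function(rel) paste(sort(A[rel]), collapse = "-"))
  Q_all <- apply(subs, 2, function(rel) {
    d <- mean(XA[rel, 1]) - mean(XA[, 1])
    d^2 * Minv
  })
  keep <- Q_all < g2
  cond_p <- rep(1 / sum(keep), sum(keep))
  names(cond_p) <- key_all[keep]

  set.seed(34)
  rule <- rejection_rule(g2)
  draws <- replicate(4000, {
    s <- rejective_draw(sI, list(kind = "srs", n = 2), rule)$sample
    paste(sort(s$selected), collapse = "-")
  })
  obs <- table(factor(draws, levels = names(cond_p)))
  expect_equal(sum(obs), 4000)
  expect_gt(stats::chisq.test(obs, p = cond_p)$p.value, 0.001)
})

test_that("thresholds map to chi-square quantiles", {
  expect_equal(gamma_from_acceptance(1, 0.5), stats::qchisq(0.5, 1))
  expect_equal(round(gamma_from_acceptance(1, 0.5), 4), 0.4549)
  expect_gt(gamma_from_acceptance(2, 0.9), gamma_from_acceptance(2, 0.1))
  expect_error(gamma_from_acceptance(1, 1.2), "accept_prob")
})

test_that("singular balance metrics are a hard error, not a pseudo-inverse", {
  pop <- finite_population(x = cbind(1:6, 2 * (1:6)), y = rep(0, 6))
  sI <- census_phase1(pop)
  sII <- force_sample(sI, c(1, 2, 3), rep(1 / 2, 3))
  expect_error(balance_statistic(sII, sI, rejection_rule(1)), "singular")
})
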