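test_that("decomposition identities hold exactly for arbitrary inputs", {
  set.seed(20)
  for (i in 1:25) {
    b1 <- rnorm(1); b2 <- rnorm(1); tot <- rnorm(1)
    d <- two_step_mediation(b1, abs(rnorm(1)), b2, abs(rnorm(1)),
                            tot, abs(rnorm(1)))
    expect_identical(d$mediation, b1 * b2)
    expect_equal(d$direct + d$mediation, d$total, tolerance = 1e-14)
    expect_equal(d$proportion * d$total, 100 * d$mediation, tolerance = 1e-10)
  }
})

test_that("worked-example chains reproduce the published decomposition", {
  fx <- make_table1_fixture()
  expect_equal(round(fx$beta[fx$role == "step1" & fx$chain == "copper-GCST90027490"], 3),
               0.118)
  dec <- mediate_chains(fx)
  expect_equal(nrow(dec), 3)
  expect_equal(round(dec$mediation, 3), c(0.071, 0.263, 0.332))
  expect_equal(dec$proportion, c(27.665, 25.544, 32.166), tolerance = 1e-4)
  # the published intervals for the copper chain span zero; so do ours
  expect_lt(dec$med_ci_low[1], 0)
  expect_gt(dec$med_ci_high[1], dec$mediation[1])
})

test_that("degenerate mediation inputs are handled explicitly", {
  d <- two_step_mediation(0, 0.1, 0.5, 0.1, 0.4, 0.05)
  expect_equal(d$mediation, 0)
  expect_equal(d$direct, 0.4)
  expect_equal(d$proportion, 0)
  expect_warning(dz <- two_step_mediation(0.1, 0.1, 0.5, 0.1, 0, 0.05),
                 "proportion undefined")
  expect_true(is.na(dz$proportion))
  expect_equal(dz$mediation, 0.05)
})

test_that("sign algebra: concordant negative steps give positive mediation", {
  neg <- two_step_mediation(-0.523, 0.1, -0.503, 0.1, 1.031, 0.2)
  expect_gt(neg$mediation, 0)
  expect_gt(neg$proportion, 0)
  pos <- two_step_mediation(0.118, 0.04, 0.600, 0.29, 0.255, 0.09)
  expect_gt(pos$mediation, 0)
  # discordant steps: mediated path opposes the total effect
  mix <- two_step_mediation(-0.3, 0.1, 0.4, 0.1, 0.5, 0.1)
  expect_lt(mix$mediation, 0)
  expect_lt(mix$proportion, 0)
})

test_that("Monte-Carlo intervals are seeded and agree with the delta method", {
  d1 <- two_step_mediation(0.118, 0.037, 0.600, 0.288, 0.255, 0.094,
                           ci_method = "montecarlo", seed = 99)
  d2 <- two_step_mediation(0.118, 0.037, 0.600, 0.288, 0.255, 0.094,
                           ci_method = "montecarlo", seed = 99)
  expect_identical(d1$med_ci_low, d2$med_ci_low)
  dd <- two_step_mediation(0.118, 0.037, 0.600, 0.288, 0.255, 0.094)
  expect_lt(abs(d1$med_ci_low - dd$med_ci_low), 0.03)
  expect_lt(abs(d1$med_ci_high - dd$med_ci_high), 0.03)
})

test_that("total_effect switches the effects model on heterogeneity", {
  sim <- simulate_triplet(calibration_config(seed = 51))
  set <- harmonize(sim$exposure, sim$outcome)
  expect_equal(total_effect(set)$method, "ivw_fixed")
  het <- simulate_triplet(simulation_config(
    n_snp = 100, n_snp_med = 3, n_exp = 4e5, n_out = 2e5,
    maf_range = c(0.1, 0.5), gamma_sd = 0.15, b1 = 0, b2 = 0, d = 0.1,
    pleiotropy_mean = 0, pleiotropy_sd = 0.02, seed = 51))
  seth <- harmonize(het$exposure, het$outcome)
  expect_equal(total_effect(seth)$method, "ivw_random")
})

test_that("a null chain's total-effect CI covers zero at the nominal rate", {
  hits <- logical(200)
  for (r in 1:200) {
    sim <- simulate_triplet(simulation_config(
      n_snp = 30, n_snp_med = 3, n_exp = 2e5, n_out = 2e5,
      maf_range = c(0.1, 0.5), gamma_sd = 0.15, b1 = 0, b2 = 0, d = 0,
      seed = 6000 + r))
    est <- total_effect(harmonize(sim$exposure, sim$outcome))
    hits[r] <- est$ci_low <= 1 && 1 <= est$ci_high
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("mediator screening retains the planted path and rejects nulls", {
  focal <- 0L; nulls <- 0L; n_null_tests <- 0L
  for (r in 1:30) {
    sim <- simulate_triplet(recovery_config(seed = 9000 + r,
                                            n_snp = 15, n_snp_med = 15,
                                            n_null_mediators = 9))
    dec <- suppressMessages(
      screen_mediators(sim$exposure, sim$mediators, sim$outcome))
    sc <- attr(dec, "screen")
    focal <- focal + sc$retained[sc$mediator == "mediator_1"]
    nulls <- nulls + sum(sc$retained[sc$mediator != "mediator_1"])
    n_null_tests <- n_null_tests + sum(sc$mediator != "mediator_1")
    if (r == 1) {
      expect_equal(nrow(dec), sum(sc$retained))
      if (nrow(dec)) {
        expect_equal(dec$total[1], attr(dec, "total")$beta)
      }
    }
  }
  expect_gte(focal, 27)        # >= 90% of replicates keep the true mediator
  # both-leg screening at 0.05 implies a ~0.0025 false-retention rate;
  # 270 null tests should stay within the binomial 99% envelope
  expect_lte(nulls, qbinom(0.995, n_null_tests, 0.05^2) + 1)
})

test_that("reverse-direction analysis is calibrated and powered", {
  # forward-only causation: the reverse estimate should be null, because the
  # outcome's own instruments (mediator-driven disease loci) do not touch
  # the exposure
  consistent <- logical(60)
  for (r in 1:60) {
    sim <- simulate_triplet(simulation_config(
      n_snp = 20, n_snp_med = 20, gamma_sd = 0.05, delta_sd = 0.25,
      b1 = 0, b2 = 0.6, d = 0.25, seed = 7000 + r))
    rev <- suppressMessages(reverse_mr(sim$outcome, sim$exposure))
    consistent[r] <- isTRUE(rev$directionally_consistent) || !rev$assessable
  }
  expect_gte(mean(consistent), 0.85)

  # when a true causal path runs from the putative outcome trait, the check
  # rejects with high power (role reversal of the same generator)
  rejects <- logical(30)
  for (r in 1:30) {
    sim <- simulate_triplet(simulation_config(
      n_snp = 20, n_snp_med = 3, n_exp = 2e5, n_out = 2e5,
      maf_range = c(0.1, 0.5), gamma_sd = 0.15, b1 = 0, b2 = 0, d = 0.3,
      seed = 7500 + r))
    rev <- suppressMessages(reverse_mr(sim$exposure, sim$outcome))
    rejects[r] <- rev$assessable && !rev$directionally_consistent
  }
  expect_gte(mean(rejects), 0.8)

  # degenerate sanity check: a trait instrumented on itself has unit effect
  sim <- simulate_triplet(simulation_config(seed = 77, gamma_sd = 0.1))
  rev <- suppressMessages(reverse_mr(sim$exposure, sim$exposure))
  expect_true(rev$assessable)
  expect_equal(rev$estimate$beta, 1)

  # too few reverse instruments: non-assessable, not an error
  weak <- make_records(beta = c(0.001, 0.001, 0.3), se = 0.01)
  rev0 <- suppressMessages(reverse_mr(weak, weak))
  expect_false(rev0$assessable)
  expect_match(rev0$reason, "fewer than 2")
})
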