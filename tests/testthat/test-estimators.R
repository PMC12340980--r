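test_that("Wald ratio arithmetic and error handling", {
  est <- wald_ratio(1, 0.1, 0.5, 0.1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  est <- wald_ratio(-2, 0.1, 1, 0.2)
  expect_equal(est$beta, -0.5)
  expect_equal(est$se, 0.1)
  est <- wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_error(wald_ratio(0, 0.1, 0.5, 0.1), "exposure effect is zero")
  # second-order SE adds the exposure-noise term, so it is never smaller
  expect_gt(wald_ratio(0.5, 0.05, 0.25, 0.1, second_order = TRUE)$se, 0.2)
})

test_that("IVW equals origin-constrained weighted least squares", {
  set <- make_set(beta_exp = c(0.1, 0.2, 0.15), se_exp = 0.01 + numeric(3),
                  beta_out = c(0.05, 0.12, 0.06), se_out = 0.01 + numeric(3))
  fit <- lm(set$beta_out ~ 0 + set$beta_exp, weights = 1 / set$se_out^2)
  expect_equal(mr_ivw(set, "fixed")$beta, unname(coef(fit)), tolerance = 1e-10)

  # 6-SNP fixture against the explicit normal-equations solution
  set6 <- make_set(beta_exp = c(0.11, 0.23, 0.08, 0.31, 0.17, 0.26),
                   se_exp = rep(0.01, 6),
                   beta_out = c(0.021, 0.055, 0.012, 0.080, 0.034, 0.061),
                   se_out = c(0.010, 0.012, 0.008, 0.015, 0.011, 0.013))
  w <- 1 / set6$se_out^2
  oracle <- sum(w * set6$beta_exp * set6$beta_out) / sum(w * set6$beta_exp^2)
  expect_equal(mr_ivw(set6, "fixed")$beta, oracle, tolerance = 1e-10)
})

test_that("single-SNP IVW degenerates to the Wald ratio", {
  set <- make_set(0.2, 0.02, 0.1, 0.05)
  ivw <- mr_ivw(set)
  wald <- wald_ratio(0.2, 0.02, 0.1, 0.05)
  expect_identical(ivw$beta, wald$beta)
  expect_identical(ivw$se, wald$se)
})

test_that("homogeneous Wald ratios give Q = 0 and equal fixed/random SEs", {
  set <- make_set(beta_exp = c(0.1, 0.2, 0.4), se_exp = 0.01 + numeric(3),
                  beta_out = c(0.05, 0.10, 0.20), se_out = 0.01 + numeric(3))
  fixed <- mr_ivw(set, "fixed")
  random <- mr_ivw(set, "random")
  expect_equal(fixed$beta, 0.5)
  expect_equal(attr(fixed, "q"), 0, tolerance = 1e-20)
  expect_equal(random$se, fixed$se)
})

test_that("Egger regression recovers an exact affine relationship", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  set <- make_set(bx, rep(0.01, 4), 0.03 + 0.7 * bx, rep(0.02, 4))
  e <- mr_egger(set)
  expect_equal(e$slope$beta, 0.7, tolerance = 1e-12)
  expect_equal(e$intercept, 0.03, tolerance = 1e-12)
})

test_that("Egger slope and intercept match a normal-equations oracle", {
  set <- make_set(beta_exp = c(0.12, 0.25, 0.08, 0.31),
                  se_exp = rep(0.01, 4),
                  beta_out = c(0.030, 0.061, 0.025, 0.070),
                  se_out = c(0.010, 0.014, 0.009, 0.016))
  w <- 1 / set$se_out^2
  X <- cbind(1, set$beta_exp)
  xtwx <- t(X) %*% (w * X)
  coefs <- solve(xtwx, t(X) %*% (w * set$beta_out))
  res <- set$beta_out - X %*% coefs
  sigma <- sqrt(sum(w * res^2) / 2)
  se <- sqrt(diag(solve(xtwx))) * max(1, sigma)
  e <- mr_egger(set)
  expect_equal(e$intercept, coefs[1], tolerance = 1e-10)
  expect_equal(e$slope$beta, coefs[2], tolerance = 1e-10)
  expect_equal(e$intercept_se, se[1], tolerance = 1e-10)
  expect_equal(e$slope$se, se[2], tolerance = 1e-10)
})

test_that("without pleiotropy the Egger slope agrees with IVW", {
  sim <- simulate_triplet(simulation_config(
    n_snp = 200, n_snp_med = 3, n_exp = 4e5, n_out = 4e5,
    maf_range = c(0.1, 0.5), gamma_sd = 0.15, b1 = 0, b2 = 0, d = 0.15,
    seed = 31))
  set <- harmonize(sim$exposure, sim$outcome)
  e <- mr_egger(set)
  ivw <- mr_ivw(set, "fixed")
  expect_lt(abs(e$intercept), 3 * e$intercept_se)
  expect_lt(abs(e$slope$beta - ivw$beta), 2 * e$slope$se)
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights: plain median
  set <- make_set(rep(1, 3), rep(0.01, 3), c(1, 2, 9), rep(0.1, 3))
  est <- mr_weighted_median(set, mode_settings(n_boot = 50))
  expect_equal(est$beta, 2)

  # all ratios identical: exact value, near-zero bootstrap SE
  setc <- make_set(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.05, 0.10, 0.20),
                   0.1 * c(0.1, 0.2, 0.4))
  est <- mr_weighted_median(setc, mode_settings(n_boot = 200, seed = 5))
  expect_equal(est$beta, 0.5)
  expect_lt(est$se, 0.5)

  # dominant weight pulls the estimate toward its ratio; compare with an
  # independent step-function-inversion oracle
  w <- c(0.9, 0.05, 0.05)
  ratios <- c(1, 5, 9)
  set2 <- make_set(beta_exp = sqrt(w) * 0.1, se_exp = rep(0.01, 3),
                   beta_out = sqrt(w) * 0.1 * ratios,
                   se_out = rep(0.1 * sqrt(0.1), 3))
  oracle <- local({
    cw <- cumsum(w / sum(w)) - (w / sum(w)) / 2
    k <- which(cw >= 0.5)[1]
    ratios[k - 1] + (ratios[k] - ratios[k - 1]) *
      (0.5 - cw[k - 1]) / (cw[k] - cw[k - 1])
  })
  est2 <- mr_weighted_median(set2, mode_settings(n_boot = 50))
  expect_equal(est2$beta, oracle, tolerance = 1e-12)
  expect_lt(est2$beta, 2)
})

test_that("mode estimators find the dominant ratio cluster", {
  set <- make_set(rep(1, 4), rep(0.01, 4), c(1, 1, 1, 5), rep(0.1, 4))
  st <- mode_settings(n_boot = 50)
  expect_equal(mr_mode(set, weighted = FALSE, st)$beta, 1, tolerance = 0.05)

  # identical ratios short-circuit the density search
  setc <- make_set(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.05, 0.10, 0.20),
                   0.1 * c(0.1, 0.2, 0.4))
  expect_equal(mr_mode(setc, weighted = FALSE, st)$beta, 0.5)

  # bimodal ratios: precision weights decide the cluster, and the exactly
  # symmetric unweighted tie resolves to the smaller candidate
  set2 <- make_set(beta_exp = c(1, 1, 10, 10), se_exp = rep(0.01, 4),
                   beta_out = c(-1.05, -0.95, 9.5, 10.5), se_out = rep(0.5, 4))
  expect_gt(mr_mode(set2, weighted = TRUE, st)$beta, 0.5)
  tie <- make_set(rep(1, 4), rep(0.01, 4), c(-1, -1, 1, 1), rep(0.1, 4))
  expect_lt(mr_mode(tie, weighted = FALSE, st)$beta, 0)
})

test_that("log-scale effects convert to the reported odds-ratio scale", {
  # printed log-effects are themselves rounded, so allow one unit in the
  # third decimal of the odds ratio
  expect_equal(beta_to_or(0.255, 0.09)$or, 1.291, tolerance = 2e-3)
  expect_equal(beta_to_or(1.031, 0.1)$or, 2.805, tolerance = 2e-3)
  conv <- beta_to_or(0, 0.1)
  expect_equal(conv$or, 1)
  expect_equal(conv$ci_low, exp(-qnorm(0.975) * 0.1))
  expect_equal(round(conv$ci_low, 3), 0.822)
  expect_equal(round(conv$ci_high, 3), 1.217)
  est <- mr_ivw(make_set(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.12),
                         c(0.01, 0.01)))
  expect_equal(est$or, exp(est$beta))
  expect_true(est$ci_low < est$or && est$or < est$ci_high)
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(8)
  J <- 30
  bx <- rnorm(J, 0, 0.2); bx <- bx + sign(bx) * 0.05
  set <- make_set(bx, rep(0.01, J), 0.4 * bx + rnorm(J, 0, 0.02), rep(0.02, J))
  st <- mode_settings(n_boot = 20)
  points <- function(s) c(
    ivw = mr_ivw(s, "fixed")$beta,
    egger = mr_egger(s)$slope$beta,
    wmed = mr_weighted_median(s, st)$beta,
    smode = mr_mode(s, FALSE, st)$beta,
    wmode = mr_mode(s, TRUE, st)$beta)
  base <- points(set)

  cc <- 2.5
  scaled <- harmonized_set(cc * set$beta_exp, cc * set$se_exp,
                           set$beta_out, set$se_out)
  expect_equal(points(scaled), base / cc, tolerance = 1e-8)

  flipped <- harmonized_set(set$beta_exp, set$se_exp,
                            -set$beta_out, set$se_out)
  expect_equal(points(flipped), -base, tolerance = 1e-8)
})

test_that("IVW is order-invariant and bootstrap SEs are seed-reproducible", {
  set.seed(9)
  J <- 25
  bx <- rnorm(J, 0, 0.2); bx <- bx + sign(bx) * 0.05
  set <- make_set(bx, rep(0.01, J), 0.3 * bx + rnorm(J, 0, 0.02), rep(0.02, J))
  perm <- sample(J)
  expect_equal(mr_ivw(set[perm], "fixed")$beta, mr_ivw(set, "fixed")$beta)
  expect_equal(attr(mr_ivw(set[perm], "fixed"), "q"),
               attr(mr_ivw(set, "fixed"), "q"))

  st <- mode_settings(n_boot = 100, seed = 77)
  rng_before <- .Random.seed
  a <- mr_weighted_median(set, st)
  expect_identical(.Random.seed, rng_before)  # caller RNG untouched
  b <- mr_weighted_median(set, st)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, mr_weighted_median(set, mode_settings(
    n_boot = 100, seed = 78))$se))
})

test_that("with strong valid instruments all five estimators agree", {
  sim <- simulate_triplet(calibration_config(seed = 101))
  set <- harmonize(sim$exposure, sim$outcome)
  est <- mr_all(set, mode_settings(n_boot = 200, seed = 1))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_lt(abs(est$beta[i] - est$beta[j]),
              2 * sqrt(est$se[i]^2 + est$se[j]^2))
  }
})

test_that("the Egger intercept estimates the mean directional pleiotropy", {
  # directional pleiotropy is defined relative to the exposure-increasing
  # orientation, so the instrument effects are generated on that side
  set.seed(13)
  J <- 2000
  g <- abs(rnorm(J, 0, 0.15)) + 0.02
  alpha <- rnorm(J, 0.05, 0.01)
  set <- make_set(g, rep(0.004, J), 0.1 * g + alpha + rnorm(J, 0, 0.004),
                  rep(0.004, J))
  e <- mr_egger(set)
  expect_lt(abs(e$intercept - 0.05), 0.01)
  expect_lt(e$intercept_pval, 1e-6)
})
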