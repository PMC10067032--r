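# Random-intercept linear model: closed-form oracles, likelihood equality,
# Wald behaviour, and the arm-difference wrapper.

test_that("balanced-design fits match the closed-form ANOVA/GLS oracle", {
  set.seed(10)
  J <- 30; m <- 5
  arm <- rep(c("algorithm", "clinician"), each = J / 2)
  u <- rnorm(J, 0, 0.15)
  d <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:J), each = m),
    arm = rep(arm, each = m),
    woa = rep(c(0.45, 0.3)[(arm == "clinician") + 1] + u, each = m) +
      rnorm(J * m, 0, 0.12))
  fit <- fit_random_intercept(d, woa ~ arm)
  oracle <- oracle_balanced_fit(d$woa, d$participant_id, d$arm)
  expect_equal(unname(fit$beta), unname(oracle$beta), tolerance = 1e-6)
  expect_equal(fit$sigma_e2, oracle$sigma_e2, tolerance = 1e-6)
  expect_equal(fit$sigma_u2, oracle$sigma_u2, tolerance = 1e-6)
})

test_that("with independent errors the fit collapses to ordinary least squares", {
  set.seed(11)
  J <- 40; m <- 5
  d <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:J), each = m),
    arm = rep(rep(c("algorithm", "clinician"), each = J / 2), each = m),
    woa = rnorm(J * m, 0.4, 0.2))  # truly independent: sigma_u^2 = 0
  fit <- fit_random_intercept(d, woa ~ arm)
  ols <- stats::lm(woa ~ factor(arm), d)
  # balanced cluster-level design: GLS equals OLS for any variance ratio
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("structured likelihood equals brute-force dense evaluation", {
  set.seed(12)
  id <- rep(1:5, times = c(3, 5, 2, 5, 4))
  X <- cbind(1, rnorm(length(id)), rep(c(0, 1), length.out = length(id)))
  y <- 0.4 + 0.2 * X[, 2] + rep(rnorm(5, 0, 0.5), times = c(3, 5, 2, 5, 4)) +
    rnorm(length(id), 0, 0.3)
  for (th in list(c(0.25, 0.09), c(0.0, 0.2), c(1.3, 0.02))) {
    beta <- c(0.4, 0.2, -0.1)
    expect_equal(lmm_loglik(y, X, id, th[1], th[2], beta = beta),
                 oracle_mvn_loglik(y, X, id, th[1], th[2], beta),
                 tolerance = 1e-10)
    expect_equal(lmm_loglik(y, X, id, th[1], th[2], reml = TRUE),
                 oracle_reml_loglik(y, X, id, th[1], th[2]),
                 tolerance = 1e-10)
  }
})

test_that("fits agree with an independent mixed-model implementation", {
  cfg <- recovery_config(n_participants = 60, response_sd = 0.15,
                         weight_sd = 0.2, initial_sd = 10,
                         integer_estimates = TRUE, seed = 4)
  rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
  d <- rec[!rec$excluded, ]
  fit <- fit_random_intercept(d, woa ~ arm + strength)
  lf <- lme4::lmer(woa ~ arm + factor(strength) + (1 | participant_id), d,
                   REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(fit$sigma_u2,
               as.numeric(lme4::VarCorr(lf)$participant_id), tolerance = 1e-4)
  expect_equal(fit$sigma_e2, stats::sigma(lf)^2, tolerance = 1e-4)
  expect_equal(-2 * fit$loglik, lme4::REMLcrit(lf), tolerance = 1e-7)
})

test_that("the reported optimum is the best profile value seen", {
  cfg <- recovery_config(n_participants = 40, response_sd = 0.15,
                         weight_sd = 0.15, seed = 6)
  rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
  fit <- fit_random_intercept(rec[!rec$excluded, ], woa ~ arm)
  expect_true(fit$converged)
  expect_lte(-2 * fit$loglik, min(fit$history[, "m2l"]) + 1e-6)
  expect_gte(fit$sigma_u2, 0)
  expect_gt(fit$sigma_e2, 0)
})

test_that("Wald machinery: single term definitional, joint terms by label", {
  cfg <- recovery_config(n_participants = 50, response_sd = 0.15,
                         weight_sd = 0.2, initial_sd = 10, seed = 13)
  rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
  d <- rec[!rec$excluded, ]
  fit <- fit_random_intercept(d, woa ~ arm * strength)
  w1 <- wald_test(fit, "armclinician")
  expect_equal(w1$statistic,
               (fit$beta[["armclinician"]] / fit$se[["armclinician"]])^2)
  expect_equal(w1$df, 1)
  expect_equal(w1$p, stats::pchisq(w1$statistic, 1, lower.tail = FALSE))
  wj <- wald_test(fit, "arm:strength")
  expect_equal(wj$df, 2)
  expect_gte(wj$statistic, 0)
  expect_error(wald_test(fit, character(0)), "non-empty")
  expect_error(wald_test(fit, "no_such_term"), "terms")
})

test_that("null-interaction Wald p-values are close to uniform", {
  ps <- vapply(1:150, function(seed) {
    cfg <- recovery_config(n_participants = 40, response_sd = 0.15,
                           weight_sd = 0.15, initial_sd = 10,
                           integer_estimates = TRUE, seed = 1000 + seed)
    rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
    d <- rec[!rec$excluded, ]
    # generator weights do not depend on strength: interaction is null
    fit <- fit_random_intercept(d, woa ~ arm * strength)
    wald_test(fit, "arm:strength")$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
})

test_that("arm_difference is symmetric, identifiable, and validates arms", {
  # duplicated data across arms: difference exactly zero
  d1 <- make_records(c(0.2, 0.5, 0.7, 0.4), arm = "algorithm", id = 1:4)
  d2 <- d1; d2$arm <- "clinician"; d2$participant_id <- sprintf("q%03d", 1:4)
  both <- rbind(d1, d2)
  expect_equal(arm_difference(both)$estimate, 0, tolerance = 1e-12)
  expect_error(arm_difference(d1), "both study arms")
  # noise-free generator: estimate equals w_C - w_A
  cfg <- recovery_config(n_participants = 40, seed = 2)
  rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
  expect_equal(arm_difference(rec)$estimate, -0.13, tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear term named", {
  d <- make_records(runif(10), arm = rep(c("algorithm", "clinician"), 5),
                    id = 1:10)
  d$dup <- as.numeric(d$arm == "clinician")
  expect_error(fit_random_intercept(d, woa ~ arm + dup), "dup")
})
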