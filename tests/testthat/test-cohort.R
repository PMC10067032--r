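# Synthetic cohort generator: covariate calibration, response model, dropout.

test_that("cohort covariates calibrate to the configured marginals", {
  cfg <- sim_config(n_participants = 10000, seed = 42)
  cohort <- sample_cohort(cfg)
  # 3-sigma binomial bounds at n = 10000 are well inside +/- 0.02
  expect_equal(mean(cohort$profession == "doctor"), 0.49, tolerance = 0.02 / 0.49)
  expect_equal(mean(cohort$total_experience == "15+"), 0.65, tolerance = 0.02 / 0.65)
  expect_equal(mean(cohort$gender == "female"), 0.92, tolerance = 0.02)
  arms <- table(cohort$arm)
  expect_lte(abs(arms[["algorithm"]] - arms[["clinician"]]), 4)
})

test_that("degenerate covariate proportions give point masses", {
  props <- default_covariate_proportions()
  props$profession <- c(doctor = 1.0, nurse = 0, other = 0)
  cohort <- sample_cohort(sim_config(n_participants = 50, seed = 1,
                                     covariate_proportions = props))
  expect_true(all(cohort$profession == "doctor"))
  props$profession <- c(doctor = 0.6, nurse = 0.6, other = 0.1)
  expect_error(sim_config(covariate_proportions = props), "sum to 1")
})

test_that("initial estimates follow the anchored truncated normal", {
  cfg0 <- sim_config(initial_sd = 0, tie_probability = 0, seed = 1)
  set.seed(1)
  expect_equal(generate_initial(c("v1", "v5"), cfg0), c(75, 55))
  cfg1 <- sim_config(tie_probability = 1, seed = 1)
  set.seed(1)
  expect_true(all(generate_initial(rep("v3", 50), cfg1) == 75))
  # moments against the numeric-integration truncated-normal oracle
  cfg <- sim_config(vignette_anchors = c(v1 = 65, v2 = 65, v3 = 65, v4 = 65,
                                         v5 = 65),
                    initial_sd = 19, tie_probability = 0,
                    integer_estimates = FALSE, seed = 1)
  set.seed(99)
  draws <- generate_initial(rep("v1", 10000), cfg)
  mom <- oracle_truncnorm_moments(65, 19)
  # truncation at 100 sits only 1.84 sd above the anchor, so the true mean is
  # pulled below 65; compare against the oracle's integrated moments
  expect_equal(mean(draws), mom[["mean"]], tolerance = 0.5 / mom[["mean"]])
  expect_lt(abs(sd(draws) - mom[["sd"]]) / mom[["sd"]], 0.05)
  expect_true(all(draws >= 0 & draws <= 100))
})

test_that("final estimates implement the linear advice-combination rule", {
  cfg <- sim_config(response_sd = 0, seed = 1)
  expect_equal(generate_final(60, 90, 0.5, cfg), 75)
  expect_equal(generate_final(60, 90, 0, cfg), 60)
  expect_equal(generate_final(60, 90, 1, cfg), 90)
  expect_error(generate_final(60, 90, 1.2, cfg), "w")
})

test_that("dropout marks strict subsets of a participant's records", {
  tr <- simulate_trial(sim_config(n_participants = 30, dropout_probability = 0,
                                  seed = 5))
  expect_true(all(tr$responses$completed))
  cfg1 <- sim_config(n_participants = 30, dropout_probability = 1, seed = 5)
  set.seed(7)
  r <- apply_dropout(simulate_trial(cfg1)$responses, cfg1)
  done <- tapply(r$completed, r$participant_id, sum)
  expect_true(all(done >= 0 & done <= 4))
})

test_that("expected completers track the dropout probability", {
  completers <- vapply(1:10, function(seed) {
    tr <- simulate_trial(sim_config(n_participants = 323, seed = seed))
    sum(tapply(tr$responses$completed, tr$responses$participant_id, all))
  }, numeric(1))
  # E = 323 * (1 - 0.124) = 283.1; 3-sigma band for the mean of 10 trials
  expect_lt(abs(mean(completers) - 283.1), 3 * sqrt(323 * 0.876 * 0.124 / 10))
})

test_that("simulated trials are byte-identical for identical configs and in range", {
  cfg <- sim_config(n_participants = 40, seed = 77)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$responses, t2$responses)
  expect_identical(t1$participants, t2$participants)
  expect_true(all(t1$responses$initial >= 0 & t1$responses$initial <= 100))
  expect_true(all(t1$responses$final >= 0 & t1$responses$final <= 100))
  expect_true(all(t1$responses$advice %in% c(50, 75, 90)))
  expect_true(all(table(t1$responses$participant_id) == 5))
})

test_that("trial datasets round-trip through CSV with provenance sidecar", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_participants = 15, seed = 3)
  tr <- simulate_trial(cfg)
  path <- file.path(dir, "trial.csv")
  write_trial(tr, path)
  expect_true(file.exists(file.path(dir, "trial_config.json")))
  back <- read_trial(path)
  expect_equal(nrow(back$responses), nrow(tr$responses))
  merged <- merge(tr$responses, back$responses,
                  by = c("participant_id", "vignette_id"))
  expect_equal(merged$final.x, merged$final.y)
  expect_equal(back$config$seed, 3)
})
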