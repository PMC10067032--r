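# Weight-of-advice statistic: formula, capping, exclusion, binning, summaries.

test_that("compute_woa reproduces the worked examples and tie exclusion", {
  expect_equal(compute_woa(60, 90, 75), 0.5)
  expect_equal(compute_woa(60, 90, 60), 0)
  expect_true(is.na(compute_woa(90, 90, 80)))
  expect_error(compute_woa(-1, 90, 60), "\\[0, 100\\]")
  expect_error(compute_woa(60, 101, 60), "\\[0, 100\\]")
})

test_that("compute_woa keeps the literal sign structure of the formula", {
  # denominator is absolute, numerator is not: with advice below the initial
  # estimate, movement toward the advice yields a NEGATIVE raw value
  expect_equal(compute_woa(80, 50, 65), -0.5)
  # overshooting past the advice exceeds 1 before capping
  expect_equal(compute_woa(60, 90, 95), 35 / 30)
  # translation invariance
  set.seed(1)
  for (rep in 1:20) {
    i <- sample(10:60, 1); a <- sample(10:60, 1); f <- sample(10:60, 1)
    if (a == i) next
    cc <- sample(1:30, 1)
    expect_equal(compute_woa(i + cc, a + cc, f + cc), compute_woa(i, a, f))
  }
})

test_that("truncation policies cap at 1 and handle negatives as configured", {
  expect_equal(truncate_woa(35 / 30), 1)
  expect_equal(truncate_woa(0.42), 0.42)
  expect_equal(truncate_woa(-0.5), 0)
  expect_equal(truncate_woa(-0.5, policy = "keep"), -0.5)
  expect_true(is.na(truncate_woa(-0.5, policy = "drop")))
  expect_equal(truncate_woa(1.8, policy = "keep"), 1)
})

test_that("binning partitions [0,1] into the five ordinal categories", {
  expect_equal(bin_woa(c(0, 0.19, 0.2, 0.39, 0.4, 0.6, 0.79, 0.8, 1)),
               c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_error(bin_woa(1.01), "\\[0, 1\\]")
  set.seed(2)
  w <- runif(500)
  b <- bin_woa(w)
  expect_true(all(b %in% 1:5))
  expect_equal(b, findInterval(w, c(0, 0.2, 0.4, 0.6, 0.8)))
})

test_that("records flag ties exactly when initial equals advice", {
  tr <- simulate_trial(sim_config(n_participants = 80, tie_probability = 0.3,
                                  seed = 8))
  rec <- woa_records(tr)
  expect_equal(rec$excluded, tr$responses$initial == tr$responses$advice)
  expect_true(all(rec$reason[rec$excluded] == "tie"))
  expect_true(all(rec$woa[!rec$excluded] >= 0 & rec$woa[!rec$excluded] <= 1))
  expect_true(all(!is.na(rec$bin[!rec$excluded])))
})

test_that("per-protocol filter drops whole incomplete participants and is idempotent", {
  tr <- simulate_trial(sim_config(n_participants = 100, seed = 21))
  rec <- per_protocol_filter(woa_records(tr))
  done <- tapply(rec$completed, rec$participant_id, sum)
  for (pid in names(done)) {
    rows <- rec[rec$participant_id == pid, ]
    if (done[[pid]] < 5) {
      expect_true(all(rows$excluded))
      expect_true(all(rows$reason == "incomplete"))
    }
  }
  expect_identical(per_protocol_filter(rec), rec)
  # with no dropout and no ties, the filter is the identity
  tr2 <- simulate_trial(sim_config(n_participants = 20, dropout_probability = 0,
                                   tie_probability = 0,
                                   integer_estimates = FALSE, seed = 2))
  rec2 <- woa_records(tr2)
  expect_identical(per_protocol_filter(rec2), rec2)
})

test_that("an enrolled cohort of 323 leaves about 283 analysed participants", {
  tr <- simulate_trial(sim_config(n_participants = 323, seed = 14))
  rec <- per_protocol_filter(woa_records(tr))
  done <- tapply(rec$completed, rec$participant_id, sum)
  expect_lt(abs(sum(done == 5) - 283), 20)
})

test_that("summaries reproduce hand-computed moments", {
  rec <- make_records(rep(0.5, 6), arm = rep("algorithm", 6))
  s <- summarize_woa(rec, "overall")
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  rec2 <- make_records(c(0, 1, 0.5),
                       arm = c("algorithm", "algorithm", "clinician"))
  s2 <- summarize_woa(rec2, "arm")
  expect_equal(s2$mean, c(0.5, 0.5))
  expect_equal(s2$sd, c(sqrt(0.5), NA))
  expect_equal(s2$n, c(2L, 1L))
})

test_that("noise-free cohorts reproduce the generative arm weights", {
  cfg <- recovery_config(n_participants = 60, seed = 31)
  rec <- per_protocol_filter(woa_records(simulate_trial(cfg)))
  s <- summarize_woa(rec, "arm")
  expect_equal(s$mean[s$arm == "algorithm"], 0.44, tolerance = 0.01 / 0.44)
  expect_equal(s$mean[s$arm == "clinician"], 0.31, tolerance = 0.01 / 0.31)
})
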