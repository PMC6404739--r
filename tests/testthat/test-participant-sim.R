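test_that("responder accuracy is non-increasing in load with correct limits", {
  m <- responder_model(4, slope = 1.2, lapse = 0.05, bias_negative = 0.03)
  acc <- responder_accuracy(m, 1:15)
  expect_true(all(diff(acc) <= 0))
  expect_true(all(acc >= 0 & acc <= 1))
  m0 <- responder_model(4, lapse = 0)
  expect_equal(responder_accuracy(m0, 4), 0.75)
  expect_lt(responder_accuracy(m0, 100), 0.51)
})

test_that("baseline severity draws respect the eligibility window", {
  set.seed(31)
  draws <- replicate(500, sample_participant("EFMT")$baseline_hamd)
  expect_true(all(draws >= 16L & draws <= 27L))
  expect_true(all(draws == round(draws)))
})

test_that("zero-SD config collapses baselines to the rounded group mean", {
  cfg <- participant_config(hamd_sd = c(EFMT = 0, CT = 0))
  set.seed(32)
  expect_equal(sample_participant("EFMT", cfg)$baseline_hamd, 19L)
  expect_equal(sample_participant("CT", cfg)$baseline_hamd, 19L)
})

test_that("baseline Monte-Carlo mean matches the truncated-normal oracle", {
  # oracle: E[round(X) | 16 <= round(X) <= 27], X ~ N(19.25, 2.55), by
  # direct summation over the integer lattice
  k <- 16:27
  pk <- pnorm(k + 0.5, 19.25, 2.55) - pnorm(k - 0.5, 19.25, 2.55)
  mu_oracle <- sum(k * pk) / sum(pk)
  set.seed(33)
  draws <- replicate(10000, sample_participant("EFMT")$baseline_hamd)
  expect_lt(abs(mean(draws) - mu_oracle), 0.1)
  # truncation pulls the realized mean above the configured center
  expect_gt(mu_oracle, 19.25)
})

test_that("discontinuation matches the brute-force rule oracle", {
  set.seed(34)
  for (i in 1:2000) {
    raw <- sample(0:3, 6, replace = TRUE, prob = c(1, 2, 4, 8))
    expect_identical(discontinuation_week(raw), oracle_discontinuation(raw))
  }
  # forced examples
  expect_identical(discontinuation_week(c(3L, 3L, 1L, 3L, 3L, 3L)), 3L)
  expect_identical(discontinuation_week(c(2L, 2L, 2L, 2L, 3L, 3L)), 4L)
  expect_identical(discontinuation_week(rep(3L, 6L)), NA_integer_)
})

test_that("simulated adherence is consistent with its own flag", {
  set.seed(35)
  for (i in 1:500) {
    a <- simulate_adherence(runif(1, 0.5, 1))
    expect_identical(a$discontinued, !is.na(a$discontinuation_week))
    if (a$discontinued) {
      w <- a$discontinuation_week
      if (w < 6L) expect_true(all(a$sessions_by_week[(w + 1):6] == 0L))
      expect_identical(
        oracle_discontinuation(a$sessions_by_week[seq_len(w)]), w)
    } else {
      expect_equal(sum(a$sessions_by_week >= 2L), 6L)
      expect_lte(sum(3L - a$sessions_by_week), 3L)
    }
  }
  perfect <- simulate_adherence(1)
  expect_equal(sum(perfect$sessions_by_week), 18L)
  expect_false(perfect$discontinued)
})

test_that("item decomposition conserves the total within instrument ranges", {
  mx <- hamd_item_ranges()
  expect_equal(sum(mx), 52L)
  set.seed(36)
  for (total in c(0L, 1L, 17L, 30L, 52L)) {
    for (rep in 1:20) {
      items <- decompose_hamd_items(total)
      expect_equal(sum(items), total)
      expect_true(all(items >= 0L & items <= mx))
    }
  }
  expect_equal(decompose_hamd_items(0L), rep(0L, 17L))
  expect_error(decompose_hamd_items(53L), "instrument maximum")
})

test_that("a uniform profile spreads points evenly in expectation", {
  set.seed(37)
  sims <- replicate(4000, decompose_hamd_items(17L, rep(1, 17)))
  expect_lt(max(abs(rowMeans(sims) - 1.0)), 0.05)
})

test_that("zero-noise trajectories reproduce the configured means exactly", {
  model <- trajectory_model(residual_cov = matrix(0, 7, 7), dose_effect = 0)
  cfg <- participant_config(hamd_sd = c(EFMT = 0, CT = 0))
  set.seed(38)
  for (g in c("EFMT", "CT")) {
    prof <- sample_participant(g, cfg, model)
    traj <- simulate_trajectory(prof, model, rep(3L, 6L))
    expect_equal(traj$hamd_total, as.integer(round(model$weekly_means[[g]])))
    expect_equal(rowSums(traj[, names(hamd_item_ranges())]),
                 as.numeric(traj$hamd_total), ignore_attr = TRUE)
  }
})

test_that("non-positive-semidefinite residual covariance is rejected", {
  bad <- diag(7); bad[1, 1] <- -1
  expect_error(trajectory_model(residual_cov = bad), "semi-definite")
})

test_that("Monte-Carlo week-6 completer mean approaches the configured value", {
  model <- trajectory_model(dose_effect = 0)
  set.seed(39)
  w6 <- replicate(1000, {
    prof <- sample_participant("EFMT", model = model)
    traj <- simulate_trajectory(prof, model, rep(3L, 6L), items = FALSE)
    traj$hamd_total[7]
  })
  # screening truncation propagates ~ +0.2 into follow-up; 0.5 covers it
  expect_lt(abs(mean(w6) - 10.60), 0.5)
})

test_that("negative dose effects induce a negative session-response correlation", {
  set.seed(40)
  cfg <- trial_config(n_participants = 300L, simulate_task = FALSE,
                      simulate_items = FALSE)
  tr <- run_trial(cfg)
  tr <- apply_locf(tr)
  resp <- responder_flags(tr)
  p <- tr$participants[tr$participants$mitt & tr$participants$arm == "EFMT", ]
  r <- resp[match(p$participant_id, resp$participant_id), ]
  ct <- corr_with_p(p$sessions_completed, r$pct_change)
  expect_lt(ct$r, 0)
})

test_that("the working-memory composite is the mean scaled score", {
  expect_equal(wais_composite(10, 10, 10), 10.0)
  expect_equal(wais_composite(12, 10, 11), 11.0)
  expect_equal(round(wais_composite(11, 11, 12), 2), 11.33)
})
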