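test_that("generated sequences have exact target/lure counts under re-scan", {
  set.seed(11)
  grid <- expand.grid(n = c(1L, 2L, 3L, 5L), lure_rate = c(0, 0.2))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]
    spec <- block_spec(n, 15L, target_rate = 1 / 3,
                       lure_rate = grid$lure_rate[g])
    for (rep in 1:5) {
      items <- generate_block_sequence(spec)
      expect_equal(nrow(items), 15L + n)
      oracle <- oracle_rescan(items, n)
      expect_equal(items$is_target, oracle$is_target)
      expect_equal(items$is_lure, oracle$is_lure)
      expect_equal(sum(oracle$is_target), round(15 / 3))
      expect_equal(sum(oracle$is_lure), round(grid$lure_rate[g] * 15))
      # fillers differ from all near-lag labels, targets/lures exclusive
      expect_false(any(items$is_target & items$is_lure))
      expect_false(any(items$is_target[!items$scored]))
    }
  }
})

test_that("stimuli run 1 s with a 1 s fixation and are reproducible", {
  spec <- block_spec(2L)
  set.seed(99)
  a <- generate_block_sequence(spec)
  set.seed(99)
  b <- generate_block_sequence(spec)
  expect_identical(a, b)
  expect_true(all(a$stim_dur_s == 1.0))
  expect_true(all(a$fixation_dur_s == 1.0))
  expect_equal(diff(a$onset_s), rep(2.0, nrow(a) - 1L))
})

test_that("a single-label degenerate set forces every scored item to match", {
  set.seed(3)
  spec <- block_spec(1L, 15L, target_rate = 1, lure_rate = 0)
  items <- generate_block_sequence(spec, category_set = "happy",
                                   allow_degenerate = TRUE)
  expect_true(all(items$is_target[items$scored]))
  expect_error(generate_block_sequence(spec, category_set = c("a", "b")),
               "at least 3 labels")
})

test_that("block scoring matches a hand-enumerated 6-item N=1 block", {
  # positions 0..6: lead-in + 6 scored, 2 targets; all responses correct
  spec <- block_spec(1L, 6L, target_rate = 2 / 6, lure_rate = 0)
  set.seed(5)
  items <- generate_block_sequence(spec)
  truth <- ifelse(items$is_target[items$scored], "match", "nonmatch")
  items$response[items$scored] <- truth
  res <- score_block(items, spec)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$hits, 2L)
  expect_equal(res$misses, 0L)
  expect_equal(res$false_alarms, 0L)
  expect_equal(res$correct_rejections, 4L)

  # omitted responses count as incorrect everywhere
  items$response[items$scored] <- "none"
  res0 <- score_block(items, spec)
  expect_equal(res0$accuracy, 0.0)
  expect_equal(res0$hits + res0$misses + res0$false_alarms +
                 res0$correct_rejections, 6L)

  items$response[items$scored][3] <- NA
  expect_error(score_block(items, spec), "positions")
})

test_that("difficulty updates follow the threshold policy and clamp", {
  pol <- adaptive_policy()
  expect_equal(update_difficulty(pol, list(n_level = 2L, accuracy = 1.0)), 3L)
  expect_equal(update_difficulty(pol, list(n_level = 1L, accuracy = 0.0)), 1L)
  expect_equal(update_difficulty(pol, list(n_level = 4L, accuracy = 0.75)), 4L)
  expect_equal(update_difficulty(pol, list(n_level = 15L, accuracy = 1.0)), 15L)
  # boundary semantics: at-threshold moves
  expect_equal(update_difficulty(pol, list(n_level = 3L, accuracy = 0.85)), 4L)
  expect_equal(update_difficulty(pol, list(n_level = 3L, accuracy = 0.60)), 2L)
})

test_that("monotone policy: higher accuracy never lowers the next level", {
  pol <- adaptive_policy()
  for (n in c(1L, 3L, 7L, 15L)) {
    nxt <- vapply(seq(0, 1, by = 0.05), function(a) {
      update_difficulty(pol, list(n_level = n, accuracy = a))
    }, integer(1))
    expect_true(all(diff(nxt) >= 0))
  }
})

test_that("a perfect responder climbs the staircase one level per block", {
  set.seed(21)
  s <- run_session(1L, 1L, perfect_responder())
  expect_s3_class(s, "efmt_session")
  expect_equal(nrow(s$blocks), 15L)
  expect_equal(s$blocks$n_level, 1:15)
  expect_equal(s$end_n, 15L)  # clamped at n_max
  expect_equal(s$mean_n, 8.0)
  expect_true(all(s$blocks$accuracy == 1))
})

test_that("a chance responder stays pinned at N = 1", {
  set.seed(22)
  s <- run_session(1L, 1L, random_responder(0.5))
  expect_equal(unique(s$blocks$n_level), 1L)
})

test_that("face and shape variants produce identical dynamics", {
  model <- responder_model(3.0)
  set.seed(77)
  face <- run_session(1L, 1L, simulated_responder(model), modality = "face")
  set.seed(77)
  shape <- run_session(1L, 1L, simulated_responder(model), modality = "shape")
  expect_equal(face$blocks$n_level, shape$blocks$n_level)
  expect_equal(face$blocks$accuracy, shape$blocks$accuracy)
  expect_equal(face$end_n, shape$end_n)
})

test_that("session 1 must start at N = 1 and levels stay in bounds", {
  expect_error(run_session(1L, 3L, perfect_responder()), "N = 1")
  set.seed(8)
  s <- run_session(2L, 5L, simulated_responder(responder_model(4)))
  expect_true(all(s$blocks$n_level >= 1L & s$blocks$n_level <= 15L))
  expect_true(s$mean_n >= 1 && s$mean_n <= 15)
})

test_that("carryover rules map the previous session to the next start", {
  set.seed(21)
  s <- run_session(1L, 1L, perfect_responder())
  expect_equal(next_session_start(s, adaptive_policy(carryover_rule = "last")),
               15L)
  expect_equal(next_session_start(
    s, adaptive_policy(carryover_rule = "rounded_mean")), 8L)
  set.seed(22)
  flat <- run_session(1L, 1L, random_responder(0.5))
  for (rule in c("last", "modal", "rounded_mean")) {
    expect_equal(next_session_start(
      flat, adaptive_policy(carryover_rule = rule)), 1L)
  }
})

test_that("an erroring responder yields a flagged partial session", {
  boom <- local({
    k <- 0L
    function(items, n) {
      k <<- k + 1L
      if (k >= 4L) stop("device disconnected")
      ifelse(items$is_target[items$scored], "match", "nonmatch")
    }
  })
  set.seed(9)
  expect_warning(s <- run_session(1L, 1L, boom), "incomplete")
  expect_false(s$complete)
  expect_equal(nrow(s$blocks), 3L)
  expect_message(n0 <- next_session_start(s), "restarting")
  expect_equal(n0, 1L)
})

test_that("staircase equilibrium tracks the responder's capacity", {
  # long-run mean block level should settle within 1 of capacity
  for (kappa in c(2.5, 4, 6)) {
    model <- responder_model(kappa, slope = 1.5, lapse = 0)
    set.seed(round(100 * kappa))
    levels <- integer(0)
    start <- 1L
    for (s in 1:12) {
      res <- simulate_session_levels(model, start)
      levels <- c(levels, res$n_levels)
      start <- res$end_n
    }
    burn <- levels[-(1:30)]  # discard approach to equilibrium
    expect_lt(abs(mean(burn) - kappa), 1)
  }
})
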