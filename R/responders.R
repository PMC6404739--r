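#' Psychometric model of a simulated trainee
#'
#' Accuracy on the match/non-match judgment is a decreasing logistic function
#' of the working-memory load N:
#' \deqn{acc(n) = (1 - b) [0.5 + (0.5 - \lambda)\,\mathrm{logit}^{-1}(s(\kappa - n))]}
#' where \eqn{\kappa} (`capacity`) is the load at which accuracy crosses
#' 75\% (for lapse 0 and bias 0), `slope` \eqn{s > 0} controls how fast
#' performance degrades, `lapse` \eqn{\lambda} caps ceiling performance at
#' \eqn{1 - \lambda}, and `bias_negative` \eqn{b} is an additional
#' multiplicative error rate on emotion labels (0 for shape stimuli). The
#' floor is chance performance (0.5) on the two-alternative judgment.
#'
#' @param capacity Load at 75% accuracy.
#' @param slope Positive logistic slope (per N unit).
#' @param lapse Lapse rate in [0, 0.5).
#' @param bias_negative Additional error proportion on emotional stimuli.
#' @return An object of class `efmt_responder_model`.
#' @export
responder_model <- function(capacity, slope = 1, lapse = 0.02,
                            bias_negative = 0) {
  stopifnot(slope > 0, lapse >= 0, lapse < 0.5,
            bias_negative >= 0, bias_negative < 1)
  structure(
    list(capacity = capacity, slope = slope, lapse = lapse,
         bias_negative = bias_negative),
    class = "efmt_responder_model"
  )
}

#' Expected accuracy at load N under a responder model
#'
#' @param model An [responder_model()].
#' @param n Vector of N levels.
#' @return Accuracies in [0, 1], monotonically non-increasing in `n`.
#' @export
responder_accuracy <- function(model, n) {
  stopifnot(inherits(model, "efmt_responder_model"))
  base <- 0.5 + (0.5 - model$lapse) * stats::plogis(model$slope * (model$capacity - n))
  pmin(pmax((1 - model$bias_negative) * base, 0), 1)
}

#' Simulated responder for [run_session()]
#'
#' Each scored item is answered correctly with probability
#' [responder_accuracy()] at the block's N level; an incorrect answer is the
#' opposite judgment (simulated trainees always respond).
#'
#' @param model An [responder_model()].
#' @return A function `f(items, n_level)` usable as the `responder` argument
#'   of [run_session()].
#' @export
simulated_responder <- function(model) {
  force(model)
  function(items, n_level) {
    truth <- ifelse(items$is_target[items$scored], "match", "nonmatch")
    ok <- stats::runif(length(truth)) < responder_accuracy(model, n_level)
    ifelse(ok, truth, ifelse(truth == "match", "nonmatch", "match"))
  }
}

#' Deterministically perfect responder
#' @return A responder function that always answers correctly.
#' @export
perfect_responder <- function() {
  function(items, n_level) {
    ifelse(items$is_target[items$scored], "match", "nonmatch")
  }
}

#' Chance-level responder
#'
#' Guesses `"match"` with probability `p_match` regardless of the stimulus.
#' @param p_match Probability of responding `"match"`.
#' @return A responder function.
#' @export
random_responder <- function(p_match = 0.5) {
  function(items, n_level) {
    ifelse(stats::runif(sum(items$scored)) < p_match, "match", "nonmatch")
  }
}

#' Fast staircase simulation without item-level bookkeeping
#'
#' Simulates the per-block accuracy of a responder directly as a binomial
#' draw at the model's expected accuracy, then applies the adaptive policy.
#' Produces the same staircase dynamics as [run_session()] with
#' [simulated_responder()] at a fraction of the cost; used for whole-trial
#' simulation where only session-level summaries (mean N, end N) matter.
#'
#' @param model An [responder_model()].
#' @param start_n Starting N level.
#' @param policy An [adaptive_policy()].
#' @param n_blocks,n_scored_items Session design.
#' @return List with `n_levels` (vector per block), `mean_n`, `end_n`.
#' @export
simulate_session_levels <- function(model, start_n, policy = adaptive_policy(),
                                    n_blocks = 15L, n_scored_items = 15L) {
  n <- as.integer(start_n)
  levels <- integer(n_blocks)
  for (b in seq_len(n_blocks)) {
    levels[b] <- n
    acc <- stats::rbinom(1L, n_scored_items, responder_accuracy(model, n)) /
      n_scored_items
    n <- update_difficulty(policy, list(n_level = n, accuracy = acc))
  }
  list(n_levels = levels, mean_n = mean(levels), end_n = n)
}

#' Simulate a participant's whole training regimen
#'
#' Runs `n_sessions` consecutive adaptive sessions with the fast staircase
#' simulator; session 1 starts at N = 1 and each later session starts at the
#' previous session's carried-over level.
#'
#' @param model An [responder_model()].
#' @param n_sessions Number of sessions attended.
#' @param policy An [adaptive_policy()].
#' @return List with `session_mean_n` (one entry per session), `mean_n`
#'   (mean over sessions, NA when no session was attended), `end_n`.
#' @export
simulate_regimen <- function(model, n_sessions, policy = adaptive_policy()) {
  n_sessions <- as.integer(n_sessions)
  if (n_sessions < 1L) {
    return(list(session_mean_n = numeric(0), mean_n = NA_real_,
                end_n = NA_integer_))
  }
  start <- policy$n_min
  out <- numeric(n_sessions)
  end_n <- start
  for (s in seq_len(n_sessions)) {
    res <- simulate_session_levels(model, start, policy)
    out[s] <- res$mean_n
    end_n <- res$end_n
    start <- end_n  # "last" carryover on the fast path
  }
  list(session_mean_n = out, mean_n = mean(out), end_n = end_n)
}
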