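#' Default stimulus category sets
#'
#' The emotional-faces task labels each stimulus with a facial emotion; the
#' control task uses neutral geometric shapes. Both sets have six categories
#' so the two task variants consume the random-number stream identically and
#' differ only in the labels attached to stimuli.
#'
#' @param modality `"face"` or `"shape"`.
#' @return Character vector of category labels.
#' @export
default_category_set <- function(modality = c("face", "shape")) {
  modality <- match.arg(modality)
  switch(modality,
    face  = c("happy", "sad", "angry", "fearful", "surprised", "neutral"),
    shape = c("circle", "square", "triangle", "star", "diamond", "hexagon")
  )
}

#' Specification of a single adaptive N-back block
#'
#' A block presents `n_scored_items + n_level` stimuli: the first `n_level`
#' items are lead-in items that cannot be scored (there is no item N positions
#' earlier to compare against). Targets are items whose category matches the
#' item `n_level` positions back; lures match at lag `n_level +/- 1` but not at
#' lag `n_level`.
#'
#' @param n_level Working-memory load N (integer >= 1).
#' @param n_scored_items Number of scored items per block (default 15).
#' @param target_rate Fraction of scored items that are targets, in (0, 1].
#' @param lure_rate Fraction of scored items that are lures, in [0, 1).
#' @return An object of class `efmt_block_spec`.
#' @export
block_spec <- function(n_level, n_scored_items = 15L, target_rate = 1 / 3,
                       lure_rate = 0.2) {
  n_level <- as.integer(n_level)
  n_scored_items <- as.integer(n_scored_items)
  stopifnot(n_level >= 1L, n_scored_items >= 1L)
  if (!(target_rate > 0 && target_rate <= 1)) {
    stop("target_rate must lie in (0, 1]")
  }
  if (!(lure_rate >= 0 && lure_rate < 1)) {
    stop("lure_rate must lie in [0, 1)")
  }
  if (round(target_rate * n_scored_items) + round(lure_rate * n_scored_items) >
        n_scored_items) {
    stop("target_rate + lure_rate infeasible for n_scored_items")
  }
  structure(
    list(n_level = n_level, n_scored_items = n_scored_items,
         target_rate = target_rate, lure_rate = lure_rate),
    class = "efmt_block_spec"
  )
}

#' Adaptive difficulty policy
#'
#' After every block the load N moves up one level when block accuracy reaches
#' `up_threshold`, down one level when it falls to `down_threshold` or below,
#' and is otherwise unchanged; N is clamped to `[n_min, n_max]`. The
#' `carryover_rule` decides the starting N of the next session from the
#' previous session's block levels.
#'
#' @param up_threshold Accuracy at or above which N increases (default 0.85).
#' @param down_threshold Accuracy at or below which N decreases (default 0.60).
#' @param n_min,n_max Bounds on N (defaults 1 and 15).
#' @param carryover_rule One of `"last"`, `"modal"`, `"rounded_mean"`.
#' @return An object of class `efmt_policy`.
#' @export
adaptive_policy <- function(up_threshold = 0.85, down_threshold = 0.60,
                            n_min = 1L, n_max = 15L,
                            carryover_rule = c("last", "modal", "rounded_mean")) {
  carryover_rule <- match.arg(carryover_rule)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  stopifnot(n_min >= 1L, n_max >= n_min)
  if (!(down_threshold >= 0 && down_threshold < up_threshold &&
          up_threshold <= 1)) {
    stop("need 0 <= down_threshold < up_threshold <= 1")
  }
  structure(
    list(up_threshold = up_threshold, down_threshold = down_threshold,
         n_min = n_min, n_max = n_max, carryover_rule = carryover_rule),
    class = "efmt_policy"
  )
}

# sample one element without the length-1 surprise of sample()
sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate the stimulus sequence for one block
#'
#' Stimuli are presented for 1 s each, followed by a 1 s fixation cross.
#' Target and lure counts are exact: `round(target_rate * n_scored_items)`
#' targets and `round(lure_rate * n_scored_items)` lures. Scored items that
#' are neither target nor lure receive a label differing from the labels at
#' lags N and N +/- 1 so they cannot be accidental (near-)matches.
#'
#' @param spec An [block_spec()].
#' @param category_set Labels to draw from; at least 3 unless
#'   `allow_degenerate = TRUE`.
#' @param modality `"face"` or `"shape"`; faces additionally carry an
#'   `actor_id` so the same emotion recurs on different identities.
#' @param n_actors Size of the face-identity pool.
#' @param allow_degenerate Permit category sets smaller than 3 (used for
#'   forced-match constructions in testing and demonstration).
#' @return A data.frame with one row per presented item: `position` (0-based),
#'   `stimulus_id`, `modality`, `label`, `actor_id`, `scored`, `is_target`,
#'   `is_lure`, `response`, `correct`, `onset_s`, `stim_dur_s`,
#'   `fixation_dur_s`.
#' @export
generate_block_sequence <- function(spec, category_set = default_category_set("face"),
                                    modality = c("face", "shape"),
                                    n_actors = 8L, allow_degenerate = FALSE) {
  stopifnot(inherits(spec, "efmt_block_spec"))
  modality <- match.arg(modality)
  k <- length(category_set)
  if (k < 3L && !allow_degenerate) {
    stop("category_set must contain at least 3 labels to guarantee that ",
         "non-target items can differ from the lag-N and lag-N±1 labels")
  }
  n <- spec$n_level
  ns <- spec$n_scored_items
  total <- ns + n
  n_targets <- round(spec$target_rate * ns)
  n_lures <- round(spec$lure_rate * ns)
  if (n_targets + n_lures > ns) stop("target/lure counts exceed scored items")

  scored_pos <- seq(n, total - 1L)            # 0-based positions
  # positions at which at least one lure lag (N-1 >= 1 or N+1) reaches into
  # the sequence
  lure_ok <- scored_pos[(n >= 2L) | (scored_pos - (n + 1L) >= 0L)]
  if (n_lures > length(lure_ok)) {
    stop("lure_rate infeasible: not enough positions admit a lag-N±1 lure")
  }

  for (attempt in seq_len(100L)) {
    tpos <- sort(sample1_vec(scored_pos, n_targets))
    avail <- setdiff(lure_ok, tpos)
    if (length(avail) < n_lures) {
      if (attempt == 100L) stop("lure positions infeasible for this design")
      next
    }
    lpos <- sort(sample1_vec(avail, n_lures))
    lab <- character(total)
    ok <- TRUE
    for (p in 0:(total - 1L)) {
      i <- p + 1L
      if (p < n) {
        lab[i] <- sample1(category_set)
      } else if (p %in% tpos) {
        lab[i] <- lab[i - n]
      } else if (p %in% lpos) {
        cand <- character(0)
        if (n >= 2L) cand <- c(cand, lab[i - (n - 1L)])
        if (p - (n + 1L) >= 0L) cand <- c(cand, lab[i - (n + 1L)])
        cand <- unique(cand[cand != lab[i - n]])
        if (!length(cand)) { ok <- FALSE; break }
        lab[i] <- sample1(cand)
      } else {
        forbid <- lab[i - n]
        if (n >= 2L) forbid <- c(forbid, lab[i - (n - 1L)])
        if (p - (n + 1L) >= 0L) forbid <- c(forbid, lab[i - (n + 1L)])
        allowed <- setdiff(category_set, forbid)
        if (!length(allowed)) { ok <- FALSE; break }
        lab[i] <- sample1(allowed)
      }
    }
    if (ok) break
    if (attempt == 100L) {
      stop("could not construct a sequence satisfying the target/lure ",
           "constraints with this category set")
    }
  }

  pos <- 0:(total - 1L)
  # actor indices are drawn for both modalities so face and shape sessions
  # consume the random stream identically and share staircase dynamics
  actors <- sample.int(n_actors, total, replace = TRUE)
  data.frame(
    position = pos,
    stimulus_id = sprintf("s%02d", pos),
    modality = modality,
    label = lab,
    actor_id = if (modality == "face") {
      sprintf("actor%02d", actors)
    } else NA_character_,
    scored = pos >= n,
    is_target = pos %in% tpos,
    is_lure = pos %in% lpos,
    response = NA_character_,
    correct = NA,
    onset_s = pos * 2.0,
    stim_dur_s = 1.0,
    fixation_dur_s = 1.0,
    stringsAsFactors = FALSE
  )
}

# sample size-many elements; tolerates length(x) == size
sample1_vec <- function(x, size) {
  if (size == 0L) return(x[0])
  x[sample.int(length(x), size)]
}

#' Score one completed block
#'
#' Accuracy is the fraction of scored items answered correctly:
#' `(hits + correct_rejections) / n_scored_items`. An omitted response
#' (`"none"`) is always incorrect; on a target it counts as a miss, on a
#' non-target it is tallied in the false-alarm bucket so the four counts
#' always sum to the number of scored items.
#'
#' @param items Item data.frame from [generate_block_sequence()] with the
#'   `response` column filled in for all scored items
#'   (`"match"`, `"nonmatch"` or `"none"`).
#' @param spec The [block_spec()] the block was generated from.
#' @return An object of class `efmt_block_result` with fields `n_level`,
#'   `accuracy`, `hits`, `misses`, `false_alarms`, `correct_rejections`.
#' @export
score_block <- function(items, spec) {
  stopifnot(inherits(spec, "efmt_block_spec"))
  sc <- items[items$scored, , drop = FALSE]
  bad <- is.na(sc$response) | !(sc$response %in% c("match", "nonmatch", "none"))
  if (any(bad)) {
    stop("missing or invalid responses at scored positions: ",
         paste(sc$position[bad], collapse = ", "))
  }
  hits <- sum(sc$is_target & sc$response == "match")
  misses <- sum(sc$is_target & sc$response != "match")
  cr <- sum(!sc$is_target & sc$response == "nonmatch")
  fa <- sum(!sc$is_target & sc$response != "nonmatch")
  stopifnot(hits + misses + cr + fa == spec$n_scored_items)
  structure(
    list(n_level = spec$n_level,
         accuracy = (hits + cr) / spec$n_scored_items,
         hits = hits, misses = misses,
         false_alarms = fa, correct_rejections = cr),
    class = "efmt_block_result"
  )
}

#' Next difficulty level from a block result
#'
#' @param policy An [adaptive_policy()].
#' @param result An `efmt_block_result` (or any list with `n_level` and
#'   `accuracy`).
#' @return Integer next N, clamped to `[n_min, n_max]`.
#' @export
update_difficulty <- function(policy, result) {
  stopifnot(inherits(policy, "efmt_policy"))
  n <- result$n_level
  nxt <- if (result$accuracy >= policy$up_threshold) n + 1L
         else if (result$accuracy <= policy$down_threshold) n - 1L
         else n
  as.integer(min(max(nxt, policy$n_min), policy$n_max))
}

#' Run one 15-block adaptive training session
#'
#' Blocks are run sequentially; each block's N comes from applying the
#' adaptive policy to the previous block's accuracy. The first session of a
#' regimen must start at N = 1. The session's `end_n` is the difficulty the
#' participant earned after the final block (the level a 16th block would
#' use), which the default carryover rule hands to the next session.
#'
#' @param session_index Position of the session in the regimen (1-based).
#' @param start_n Starting N; must be 1 when `session_index == 1`.
#' @param responder A function `f(items, n_level)` returning a character
#'   vector of responses (`"match"`/`"nonmatch"`/`"none"`), one per scored
#'   item. See [simulated_responder()], [perfect_responder()].
#' @param policy An [adaptive_policy()].
#' @param n_blocks Number of blocks per session (default 15).
#' @param n_scored_items,target_rate,lure_rate Per-block design, see
#'   [block_spec()].
#' @param modality,category_set Stimulus set, see
#'   [generate_block_sequence()].
#' @return An object of class `efmt_session`: `session_index`, `start_n`,
#'   `modality`, `blocks` (one row per block with n-level, accuracy and
#'   counts), `items` (full item-level log), `mean_n`, `end_n`, `complete`.
#' @export
run_session <- function(session_index, start_n, responder,
                        policy = adaptive_policy(), n_blocks = 15L,
                        n_scored_items = 15L, target_rate = 1 / 3,
                        lure_rate = 0.2, modality = c("face", "shape"),
                        category_set = NULL) {
  modality <- match.arg(modality)
  if (is.null(category_set)) category_set <- default_category_set(modality)
  session_index <- as.integer(session_index)
  start_n <- as.integer(start_n)
  if (session_index == 1L && start_n != 1L) {
    stop("the first session must start at N = 1")
  }
  stopifnot(start_n >= policy$n_min, start_n <= policy$n_max)

  n <- start_n
  blocks <- vector("list", n_blocks)
  item_logs <- vector("list", n_blocks)
  complete <- TRUE
  for (b in seq_len(n_blocks)) {
    spec <- block_spec(n, n_scored_items, target_rate, lure_rate)
    items <- generate_block_sequence(spec, category_set, modality = modality)
    resp <- tryCatch(responder(items, n), error = function(e) e)
    if (inherits(resp, "error")) {
      complete <- FALSE
      blocks <- blocks[seq_len(b - 1L)]
      item_logs <- item_logs[seq_len(b - 1L)]
      warning("responder failed in block ", b, ": ", conditionMessage(resp),
              "; session flagged incomplete")
      break
    }
    items$response[items$scored] <- resp
    items$correct[items$scored] <-
      (items$is_target[items$scored] & resp == "match") |
      (!items$is_target[items$scored] & resp == "nonmatch")
    res <- score_block(items, spec)
    items$block <- b
    items$n_level <- n
    item_logs[[b]] <- items
    blocks[[b]] <- data.frame(
      block = b, n_level = res$n_level, accuracy = res$accuracy,
      hits = res$hits, misses = res$misses,
      false_alarms = res$false_alarms,
      correct_rejections = res$correct_rejections
    )
    n <- update_difficulty(policy, res)
  }
  blocks <- do.call(rbind, blocks)
  structure(
    list(session_index = session_index, start_n = start_n,
         modality = modality,
         blocks = blocks,
         items = do.call(rbind, item_logs),
         mean_n = if (nrow(blocks)) mean(blocks$n_level) else NA_real_,
         end_n = n, complete = complete),
    class = "efmt_session"
  )
}

#' @export
print.efmt_session <- function(x, ...) {
  cat("Adaptive N-back session", x$session_index,
      sprintf("(%s stimuli)\n", x$modality))
  cat("  blocks:", nrow(x$blocks),
      if (!x$complete) "(INCOMPLETE)" else "", "\n")
  cat(sprintf("  start N = %d, end N = %d, mean N = %.2f\n",
              x$start_n, x$end_n, x$mean_n))
  invisible(x)
}

#' Starting difficulty for the next session
#'
#' @param prev The previous `efmt_session`.
#' @param policy An [adaptive_policy()]; its `carryover_rule` selects how the
#'   previous session's levels map to the next start: `"last"` (the earned
#'   end-of-session level), `"modal"` (most frequent block level, highest on
#'   ties), or `"rounded_mean"`.
#' @return Integer starting N, clamped to `[n_min, n_max]`. An incomplete
#'   previous session falls back to `n_min` with a message.
#' @export
next_session_start <- function(prev, policy = adaptive_policy()) {
  stopifnot(inherits(prev, "efmt_session"))
  if (!isTRUE(prev$complete)) {
    message("previous session incomplete; restarting at N = ", policy$n_min)
    return(policy$n_min)
  }
  lv <- prev$blocks$n_level
  nxt <- switch(policy$carryover_rule,
    last = prev$end_n,
    modal = {
      tab <- table(lv)
      max(as.integer(names(tab)[tab == max(tab)]))
    },
    rounded_mean = as.integer(round(mean(lv)))
  )
  as.integer(min(max(nxt, policy$n_min), policy$n_max))
}
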