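#' Configuration of an in-silico randomized trial
#'
#' Bundles the design (sample size, 6 training weeks of 3 sessions each with
#' a baseline and six weekly assessment visits), the adherence model, and the
#' sub-module configurations.
#'
#' @param n_participants Number randomized (default 51).
#' @param n_weeks Training weeks (default 6).
#' @param sessions_per_week Scheduled sessions per week (default 3).
#' @param attendance_prob Per-session attendance probability.
#' @param block_size Randomization block size (default 6).
#' @param participant An [participant_config()].
#' @param trajectory An [trajectory_model()].
#' @param policy An [adaptive_policy()] for the simulated training task.
#' @param simulate_task Run the fast staircase simulator per participant to
#'   obtain achieved mean N levels (default TRUE).
#' @param simulate_items Allocate per-item Ham-D scores (default TRUE); set
#'   FALSE for Monte-Carlo runs that only need totals.
#' @return Object of class `efmt_trial_config`.
#' @export
trial_config <- function(n_participants = 51L, n_weeks = 6L,
                         sessions_per_week = 3L, attendance_prob = 0.87,
                         block_size = 6L,
                         participant = participant_config(),
                         trajectory = trajectory_model(),
                         policy = adaptive_policy(),
                         simulate_task = TRUE,
                         simulate_items = TRUE) {
  stopifnot(n_participants >= 1L, n_weeks == 6L, sessions_per_week >= 1L,
            attendance_prob >= 0, attendance_prob <= 1)
  structure(
    list(n_participants = as.integer(n_participants),
         n_weeks = as.integer(n_weeks),
         sessions_per_week = as.integer(sessions_per_week),
         attendance_prob = attendance_prob,
         block_size = as.integer(block_size),
         participant = participant, trajectory = trajectory,
         policy = policy, simulate_task = simulate_task,
         simulate_items = simulate_items),
    class = "efmt_trial_config"
  )
}

#' Run a complete simulated trial
#'
#' Enrolls and randomizes participants in permuted blocks, draws baseline
#' profiles, simulates weekly attendance with the protocol discontinuation
#' rule (fewer than two sessions in any week, or more than three cumulative
#' missed sessions), simulates clinical trajectories and training-task
#' performance, and assembles the analysis datasets.
#'
#' Membership flags: `itt` is TRUE for everyone randomized; `mitt` requires
#' at least one completed week of training and at least one post-baseline
#' Ham-D assessment (equivalently, discontinuation after week 1, if at all).
#'
#' @param config An [trial_config()].
#' @param seed Optional integer seed for full reproducibility.
#' @return Object of class `efmt_trial`: `long` (one row per participant per
#'   scheduled week up to and including any discontinuation week),
#'   `participants` (one row per participant), `allocation`, `config_digest`.
#' @export
run_trial <- function(config = trial_config(), seed = NULL) {
  stopifnot(inherits(config, "efmt_trial_config"))
  if (!is.null(seed)) set.seed(seed)
  alloc <- permuted_block_sequence(config$n_participants,
                                   block_size = config$block_size)
  n <- nrow(alloc)
  long <- vector("list", n)
  baseline_hamd <- baseline_bdi <- baseline_wais <- integer(n)
  episode <- capacity <- mean_n <- outcome_wais <- numeric(n)
  sessions_completed <- disc_week <- integer(n)
  discontinued <- mitt <- logical(n)
  for (i in seq_len(n)) {
    id <- alloc$participant_id[i]
    arm <- alloc$arm[i]
    prof <- sample_participant(arm, config$participant, config$trajectory,
                               participant_id = id)
    adh <- simulate_adherence(config$attendance_prob, config$n_weeks,
                              config$sessions_per_week)
    traj <- simulate_trajectory(prof, config$trajectory,
                                adh$sessions_by_week,
                                adh$discontinuation_week,
                                items = config$simulate_items)
    keep <- if (adh$discontinued) traj$week <= adh$discontinuation_week
            else rep(TRUE, nrow(traj))
    total_sessions <- sum(adh$sessions_by_week)
    perf <- if (config$simulate_task && total_sessions >= 1L) {
      simulate_regimen(responder_model(prof$capacity), total_sessions,
                       config$policy)
    } else list(mean_n = NA_real_, end_n = NA_integer_)
    long[[i]] <- traj[keep, , drop = FALSE]
    baseline_hamd[i] <- prof$baseline_hamd
    baseline_bdi[i] <- prof$baseline_bdi
    baseline_wais[i] <- prof$baseline_wais
    outcome_wais[i] <- prof$baseline_wais +
      stats::rnorm(1L, config$participant$wais_gain_mean,
                   config$participant$wais_gain_sd)
    episode[i] <- prof$episode_duration_months
    capacity[i] <- prof$capacity
    mean_n[i] <- perf$mean_n
    sessions_completed[i] <- total_sessions
    discontinued[i] <- adh$discontinued
    disc_week[i] <- adh$discontinuation_week
    mitt[i] <- !adh$discontinued || adh$discontinuation_week >= 2L
  }
  parts <- data.frame(
    participant_id = alloc$participant_id, arm = alloc$arm,
    block_index = alloc$block_index,
    baseline_hamd = baseline_hamd, baseline_bdi = baseline_bdi,
    baseline_wais = baseline_wais, outcome_wais = outcome_wais,
    episode_duration_months = episode, capacity = capacity,
    mean_n = mean_n, sessions_completed = sessions_completed,
    discontinued = discontinued, discontinuation_week = disc_week,
    itt = TRUE, mitt = mitt,
    stringsAsFactors = FALSE
  )
  structure(
    list(long = do.call(rbind, long),
         participants = parts,
         allocation = alloc,
         config = config),
    class = "efmt_trial"
  )
}

#' @export
print.efmt_trial <- function(x, ...) {
  p <- x$participants
  cat("Simulated randomized trial:", nrow(p), "participants (",
      sum(p$arm == "EFMT"), "EFMT /", sum(p$arm == "CT"), "CT )\n")
  cat("  m-ITT:", sum(p$mitt), "; discontinued:", sum(p$discontinued), "\n")
  cat("  visit rows:", nrow(x$long), "\n")
  invisible(x)
}

#' Last-observation-carried-forward imputation
#'
#' Expands every m-ITT participant to the full week 0..6 grid and fills each
#' missing Ham-D total (and item scores and BDI) with the participant's last
#' observed value. Imputed cells are flagged in `locf_imputed`. Applying the
#' operation twice equals applying it once.
#'
#' @param trial An `efmt_trial`.
#' @return The trial with `long` replaced by the imputed m-ITT grid (stored
#'   as `long_locf`; the observed-data `long` is retained unchanged).
#' @export
apply_locf <- function(trial) {
  stopifnot(inherits(trial, "efmt_trial"))
  ids <- trial$participants$participant_id[trial$participants$mitt]
  item_cols <- names(hamd_item_ranges())
  carry_cols <- c("hamd_total", item_cols, "bdi")
  rows <- lapply(ids, function(id) {
    obs <- trial$long[trial$long$participant_id == id, , drop = FALSE]
    obs <- obs[!is.na(obs$hamd_total), , drop = FALSE]
    if (!nrow(obs)) {
      message("participant ", id, " has no observed assessments; excluded ",
              "from the LOCF dataset")
      return(NULL)
    }
    grid <- obs[match(0:6, obs$week), , drop = FALSE]
    imputed <- is.na(grid$week)
    for (w in which(imputed)) {
      last <- max(obs$week[obs$week < (0:6)[w]])
      src <- obs[obs$week == last, , drop = FALSE]
      src$week <- (0:6)[w]
      src$sessions_this_week <- NA_integer_
      src$status <- "discontinued"
      grid[w, ] <- src
    }
    grid$week <- 0:6
    grid$locf_imputed <- imputed
    grid
  })
  trial$long_locf <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(trial$long_locf) <- NULL
  trial
}

#' Clinical responder flags
#'
#' A responder shows at least a 50 percent reduction in Ham-D total from
#' baseline to the outcome assessment (week 6, LOCF-imputed when the LOCF
#' dataset is present, otherwise the last observed value).
#'
#' @param trial An `efmt_trial`, ideally after [apply_locf()].
#' @return data.frame with `participant_id`, `arm`, `baseline`, `outcome`,
#'   `pct_change` (negative = improvement), `responder`.
#' @export
responder_flags <- function(trial) {
  stopifnot(inherits(trial, "efmt_trial"))
  src <- if (!is.null(trial$long_locf)) trial$long_locf else trial$long
  ids <- unique(src$participant_id)
  out <- lapply(ids, function(id) {
    d <- src[src$participant_id == id & !is.na(src$hamd_total), , drop = FALSE]
    base <- d$hamd_total[d$week == 0]
    if (!length(base)) return(NULL)
    if (base <= 0) stop("baseline Ham-D must be positive for participant ", id)
    outcome <- d$hamd_total[d$week == max(d$week)]
    data.frame(
      participant_id = id, arm = d$group[1],
      baseline = base, outcome = outcome,
      pct_change = 100 * (outcome - base) / base,
      responder = (base - outcome) / base >= 0.5,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Validate the internal consistency of a trial dataset
#'
#' Checks the schema invariants: every randomized participant has a baseline
#' row, no rows after a discontinuation week, cumulative sessions
#' non-decreasing, m-ITT a subset of ITT, and item scores re-summing to the
#' Ham-D total wherever observed.
#'
#' @param trial An `efmt_trial`.
#' @return TRUE invisibly; stops with an itemized message otherwise.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "efmt_trial"))
  p <- trial$participants; d <- trial$long
  errs <- character(0)
  if (!all(p$participant_id %in% d$participant_id[d$week == 0])) {
    errs <- c(errs, "participants missing baseline rows")
  }
  if (any(p$mitt & !p$itt)) errs <- c(errs, "m-ITT not a subset of ITT")
  for (i in seq_len(nrow(p))) {
    di <- d[d$participant_id == p$participant_id[i], , drop = FALSE]
    if (p$discontinued[i] && any(di$week > p$discontinuation_week[i])) {
      errs <- c(errs, paste0("rows after discontinuation for ",
                             p$participant_id[i]))
    }
    if (is.unsorted(di$sessions_cumulative)) {
      errs <- c(errs, paste0("cumulative sessions decrease for ",
                             p$participant_id[i]))
    }
  }
  obs <- d[!is.na(d$hamd_total), , drop = FALSE]
  item_sum <- rowSums(obs[, names(hamd_item_ranges())])
  if (any(!is.na(item_sum) & item_sum != obs$hamd_total)) {
    errs <- c(errs, "item scores do not re-sum to hamd_total")
  }
  if (length(errs)) stop("trial dataset invalid:\n  ",
                         paste(errs, collapse = "\n  "))
  invisible(TRUE)
}
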