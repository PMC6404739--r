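trial_long_columns <- function() {
  c("participant_id", "group", "week", "hamd_total",
    names(hamd_item_ranges()), "bdi", "sessions_this_week",
    "sessions_cumulative", "status")
}

trial_participant_columns <- function() {
  c("participant_id", "arm", "block_index", "baseline_hamd", "baseline_bdi",
    "baseline_wais", "outcome_wais", "episode_duration_months", "capacity",
    "mean_n", "sessions_completed", "discontinued", "discontinuation_week",
    "itt", "mitt")
}

#' Write a simulated trial to CSV files
#'
#' Writes `trial_long.csv`, `participants.csv` and `allocation.csv` (UTF-8,
#' comma separated, header row, empty fields for missing values) plus a JSON
#' run manifest recording the seed, configuration digest and file list.
#'
#' @param trial An `efmt_trial`.
#' @param dir Output directory (created if needed).
#' @param seed The seed the trial was generated with (recorded in the
#'   manifest; optional).
#' @return Invisibly, the paths written.
#' @export
write_trial_csv <- function(trial, dir, seed = NULL) {
  stopifnot(inherits(trial, "efmt_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trial_long.csv", "participants.csv",
                            "allocation.csv"))
  utils::write.csv(trial$long[, trial_long_columns()], paths[1],
                   row.names = FALSE, na = "")
  utils::write.csv(trial$participants[, trial_participant_columns()],
                   paths[2], row.names = FALSE, na = "")
  utils::write.csv(trial$allocation, paths[3], row.names = FALSE, na = "")
  manifest <- run_manifest(trial, seed = seed, files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

#' Read a simulated trial back from CSV files
#'
#' Validates the schema (an error names every missing column) and rebuilds
#' the `efmt_trial` object.
#'
#' @param dir Directory holding `trial_long.csv`, `participants.csv`,
#'   `allocation.csv`.
#' @return An `efmt_trial`.
#' @export
read_trial_csv <- function(dir) {
  long <- utils::read.csv(file.path(dir, "trial_long.csv"),
                          stringsAsFactors = FALSE)
  parts <- utils::read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  alloc <- utils::read.csv(file.path(dir, "allocation.csv"),
                           stringsAsFactors = FALSE)
  miss_long <- setdiff(trial_long_columns(), names(long))
  miss_p <- setdiff(trial_participant_columns(), names(parts))
  if (length(miss_long) || length(miss_p)) {
    stop("schema violation: missing columns: ",
         paste(c(miss_long, miss_p), collapse = ", "))
  }
  bad_week <- which(!(long$week %in% 0:6))
  if (length(bad_week)) {
    stop("schema violation: week outside 0..6 at rows ",
         paste(utils::head(bad_week, 10), collapse = ", "))
  }
  structure(
    list(long = long, participants = parts, allocation = alloc,
         config = NULL),
    class = "efmt_trial"
  )
}

#' Run manifest for reproducibility
#'
#' @param trial An `efmt_trial`.
#' @param seed Seed used (or NULL).
#' @param files Output file names.
#' @return A list suitable for JSON serialization: package version, seed,
#'   configuration digest, participant/row counts, timestamp.
#' @export
run_manifest <- function(trial, seed = NULL, files = character(0)) {
  cfg_digest <- if (!is.null(trial$config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(utils::capture.output(utils::str(trial$config)), tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  list(
    package = "efmt",
    version = as.character(utils::packageVersion("efmt")),
    seed = seed,
    config_digest = cfg_digest,
    n_participants = nrow(trial$participants),
    n_rows_long = nrow(trial$long),
    files = files,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Read a trial configuration from a YAML file
#'
#' Recognized top-level keys (all optional): `n_participants`,
#' `attendance_prob`, `block_size`, `simulate_task`, and nested `policy`
#' (`up_threshold`, `down_threshold`, `n_min`, `n_max`, `carryover_rule`),
#' `trajectory` (`dose_effect`, `dose_center`, `residual_sd`,
#' `residual_cor`), `participant` (any [participant_config()] argument).
#'
#' @param path YAML file path.
#' @return An [trial_config()].
#' @export
read_trial_config <- function(path) {
  y <- yaml::read_yaml(path)
  pol <- do.call(adaptive_policy, y$policy %||% list())
  traj_args <- y$trajectory %||% list()
  if (!is.null(traj_args$residual_sd) || !is.null(traj_args$residual_cor)) {
    s <- traj_args$residual_sd %||% 4.9
    r <- traj_args$residual_cor %||% 0.5
    traj_args$residual_cov <- s^2 * (r + (1 - r) * diag(7))
    traj_args$residual_sd <- NULL
    traj_args$residual_cor <- NULL
  }
  traj <- do.call(trajectory_model, traj_args)
  part <- do.call(participant_config, y$participant %||% list())
  trial_config(
    n_participants = y$n_participants %||% 51L,
    attendance_prob = y$attendance_prob %||% 0.87,
    block_size = y$block_size %||% 6L,
    participant = part, trajectory = traj, policy = pol,
    simulate_task = y$simulate_task %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a session log as JSON and per-item CSV
#'
#' @param session An `efmt_session` from [run_session()].
#' @param json_path Path for the JSON log (config echo, per-block and
#'   per-item records); NULL to skip.
#' @param csv_path Path for the flat one-row-per-item CSV; NULL to skip.
#' @param seed Seed recorded in the log.
#' @return Invisibly, the paths written.
#' @export
write_session_log <- function(session, json_path = NULL, csv_path = NULL,
                              seed = NULL) {
  stopifnot(inherits(session, "efmt_session"))
  written <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(session_index = session$session_index,
           modality = session$modality, seed = seed,
           start_n = session$start_n, end_n = session$end_n,
           mean_n = session$mean_n, complete = session$complete,
           blocks = session$blocks, items = session$items),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    )
    written <- c(written, json_path)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(session$items, csv_path, row.names = FALSE, na = "")
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' Run the full analysis suite on a trial and optionally write result files
#'
#' Runs the primary MMRM on the randomized (ITT) observed data, the LOCF
#' sensitivity model and item-level analysis on the m-ITT sample, responder
#' classification, the secondary between-arm t tests (sessions completed and
#' achieved mean N), and the dose-response correlations.
#'
#' @param trial An `efmt_trial` (LOCF applied internally if absent).
#' @param out_dir If non-NULL, writes `mmrm_contrasts.csv`,
#'   `secondary_tests.csv`, `item_level.csv` and `analysis_manifest.json`.
#' @return List with components `mmrm`, `sensitivity`, `items`,
#'   `responders`, `responder_table`, `secondary`, `dose_response`.
#' @export
analyze_trial <- function(trial, out_dir = NULL) {
  stopifnot(inherits(trial, "efmt_trial"))
  if (is.null(trial$long_locf)) trial <- apply_locf(trial)
  mm <- fit_mmrm(trial$long)
  sens <- locf_sensitivity_model(trial)
  items <- item_level_analysis(trial)
  resp <- responder_flags(trial)
  resp_tab <- table(resp$arm, resp$responder)

  p <- trial$participants[trial$participants$mitt, ]
  sum_stats <- function(v, arm) {
    v <- v[p$arm == arm]
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  se <- sum_stats(p$sessions_completed, "EFMT")
  sc <- sum_stats(p$sessions_completed, "CT")
  t_sessions <- pooled_t_from_summary(se["mean"], se["sd"], se["n"],
                                      sc["mean"], sc["sd"], sc["n"])
  ne <- sum_stats(p$mean_n, "EFMT")
  nc <- sum_stats(p$mean_n, "CT")
  t_mean_n <- if (ne["n"] >= 2 && nc["n"] >= 2) {
    pooled_t_from_summary(ne["mean"], ne["sd"], ne["n"],
                          nc["mean"], nc["sd"], nc["n"])
  } else NULL

  dr <- lapply(c(EFMT = "EFMT", CT = "CT"), function(a) {
    ids <- p$participant_id[p$arm == a]
    r <- resp[match(ids, resp$participant_id), ]
    s <- p$sessions_completed[p$arm == a]
    keep <- !is.na(r$pct_change)
    if (sum(keep) >= 3 && stats::sd(s[keep]) > 0 &&
        stats::sd(r$pct_change[keep]) > 0) {
      corr_with_p(s[keep], r$pct_change[keep])
    } else NULL
  })

  out <- list(mmrm = mm, sensitivity = sens, items = items,
              responders = resp, responder_table = resp_tab,
              secondary = list(sessions = t_sessions, mean_n = t_mean_n),
              dose_response = dr)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mm$contrasts,
                     file.path(out_dir, "mmrm_contrasts.csv"),
                     row.names = FALSE)
    sec <- data.frame(
      test = c("sessions_completed", "mean_n_achieved"),
      t = c(t_sessions$t, if (!is.null(t_mean_n)) t_mean_n$t else NA),
      df = c(t_sessions$df, if (!is.null(t_mean_n)) t_mean_n$df else NA),
      p = c(t_sessions$p, if (!is.null(t_mean_n)) t_mean_n$p else NA)
    )
    utils::write.csv(sec, file.path(out_dir, "secondary_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(items, file.path(out_dir, "item_level.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(package = "efmt",
           version = as.character(utils::packageVersion("efmt")),
           interaction = mm$interaction,
           sensitivity = sens[c("F", "df1", "df2", "p")],
           responders = as.data.frame(resp_tab),
           files = c("mmrm_contrasts.csv", "secondary_tests.csv",
                     "item_level.csv"),
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
      file.path(out_dir, "analysis_manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  out
}
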