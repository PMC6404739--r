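#' Score ranges of the 17 Hamilton Depression Rating Scale items
#'
#' Nine items are rated 0-4 (depressed mood, guilt, suicide, work and
#' activities, retardation, agitation, psychic anxiety, somatic anxiety,
#' hypochondriasis) and eight are rated 0-2 (the three insomnia items,
#' gastrointestinal and general somatic symptoms, genital symptoms, weight
#' loss, insight), for a maximum total of 52.
#'
#' @return Named integer vector of per-item maxima, length 17.
#' @export
hamd_item_ranges <- function() {
  mx <- c(4L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 4L, 2L, 2L)
  names(mx) <- paste0("item", seq_len(17L))
  mx
}

#' Weekly between-arm Ham-D differences used as the default effect profile
#'
#' Least-squares-mean differences (control minus active, Ham-D points) by
#' week 0..6 that the default trajectory model reproduces in expectation.
#' @return Numeric vector of length 7.
#' @export
default_weekly_differences <- function() {
  c(0.2283, -0.7493, 0.3586, 3.1462, 0.8958, 1.7720, 3.8681)
}

#' Clinical trajectory model for simulated participants
#'
#' Defines, per arm, the expected weekly Ham-D totals, the within-participant
#' residual covariance across the 7 visits (stored as a full unstructured
#' matrix), a mean-centered dose effect (Ham-D points per completed training
#' session, active arm only), the allocation profile over the 17 Ham-D items,
#' and the linear Ham-D-to-BDI-II map.
#'
#' Defaults: the active arm declines linearly from 19.25 at baseline to 10.60
#' at week 6; the control arm equals the active mean plus the weekly
#' difference profile ([default_weekly_differences()]), which pins the
#' week-6 expected contrast at 3.8681 Ham-D points. The residual covariance
#' is compound-symmetric with SD 4.9 and correlation 0.5 (stored dense so
#' nothing downstream may assume its structure).
#'
#' @param weekly_means Named list with numeric length-7 vectors `EFMT`, `CT`.
#' @param residual_cov 7x7 positive semi-definite matrix.
#' @param dose_effect Ham-D points per session relative to expected
#'   attendance (active arm only; negative = more sessions, larger
#'   improvement).
#' @param dose_center Expected sessions per week used to center the dose
#'   term so arm means are unchanged.
#' @param item_profile Positive weights, length 17, governing how a total is
#'   spread over items; default proportional to each item's maximum score.
#' @param bdi_anchors List of two-point anchors `(hamd, bdi)` per arm used to
#'   solve the linear Ham-D to BDI-II map.
#' @param bdi_noise_sd SD of the BDI-II residual around the linear map.
#' @return Object of class `efmt_trajectory_model`.
#' @export
trajectory_model <- function(weekly_means = NULL,
                             residual_cov = NULL,
                             dose_effect = -0.6,
                             dose_center = 2.61,
                             item_profile = NULL,
                             bdi_anchors = NULL,
                             bdi_noise_sd = 3) {
  if (is.null(weekly_means)) {
    efmt <- seq(19.25, 10.60, length.out = 7L)
    weekly_means <- list(EFMT = efmt, CT = efmt + default_weekly_differences())
  }
  stopifnot(is.list(weekly_means),
            all(c("EFMT", "CT") %in% names(weekly_means)),
            lengths(weekly_means[c("EFMT", "CT")] ) == 7L)
  if (is.null(residual_cov)) {
    residual_cov <- 4.9^2 * (0.5 + 0.5 * diag(7L))
  }
  residual_cov <- as.matrix(residual_cov)
  if (!isTRUE(all.equal(residual_cov, t(residual_cov))) ||
      min(eigen(residual_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8) {
    stop("residual_cov must be a symmetric positive semi-definite 7x7 matrix")
  }
  if (is.null(item_profile)) item_profile <- as.numeric(hamd_item_ranges())
  stopifnot(length(item_profile) == 17L, all(item_profile > 0))
  if (is.null(bdi_anchors)) {
    bdi_anchors <- list(
      EFMT = list(hamd = c(19.25, 10.60), bdi = c(31.28, 20.00)),
      CT   = list(hamd = c(19.48, 14.71), bdi = c(28.71, 25.29))
    )
  }
  bdi_map <- lapply(bdi_anchors, function(a) {
    beta <- diff(a$bdi) / diff(a$hamd)
    c(alpha = a$bdi[1] - beta * a$hamd[1], beta = beta)
  })
  structure(
    list(weekly_means = weekly_means, residual_cov = residual_cov,
         dose_effect = dose_effect, dose_center = dose_center,
         item_profile = item_profile / sum(item_profile),
         bdi_map = bdi_map, bdi_noise_sd = bdi_noise_sd),
    class = "efmt_trajectory_model"
  )
}

#' Configuration for drawing baseline clinical profiles
#'
#' @param hamd_mean,hamd_sd Per-arm mean/SD of the (pre-truncation) baseline
#'   Ham-D normal draw. Defaults 19.25 (2.55) active, 19.48 (2.64) control.
#' @param hamd_range Eligibility window; draws are rejected outside it
#'   (moderate severity required, very severe excluded).
#' @param wais_mean,wais_sd Baseline working-memory composite (mean scaled
#'   score of digit-span forward/backward and letter-number sequencing).
#' @param wais_gain_mean,wais_gain_sd Baseline-to-outcome composite change.
#' @param episode_meanlog,episode_sdlog Log-normal parameters of current
#'   episode duration (months).
#' @param capacity_mean,capacity_sd Per-arm N-back capacity distribution for
#'   the simulated responder.
#' @return Object of class `efmt_participant_config`.
#' @export
participant_config <- function(hamd_mean = c(EFMT = 19.25, CT = 19.48),
                               hamd_sd = c(EFMT = 2.55, CT = 2.64),
                               hamd_range = c(16L, 27L),
                               wais_mean = 10.9, wais_sd = 2.8,
                               wais_gain_mean = 0.8, wais_gain_sd = 1.5,
                               episode_meanlog = 2.5, episode_sdlog = 0.9,
                               capacity_mean = c(EFMT = 3.4, CT = 4.4),
                               capacity_sd = c(EFMT = 1.7, CT = 2.0)) {
  structure(
    list(hamd_mean = hamd_mean, hamd_sd = hamd_sd, hamd_range = hamd_range,
         wais_mean = wais_mean, wais_sd = wais_sd,
         wais_gain_mean = wais_gain_mean, wais_gain_sd = wais_gain_sd,
         episode_meanlog = episode_meanlog, episode_sdlog = episode_sdlog,
         capacity_mean = capacity_mean, capacity_sd = capacity_sd),
    class = "efmt_participant_config"
  )
}

#' Draw one participant's baseline clinical profile
#'
#' Baseline Ham-D is a rounded normal draw truncated by rejection to the
#' eligibility window (at least moderate severity, very severe excluded).
#' Note that the truncation raises the realized mean slightly above the
#' configured center, as screening does in practice.
#'
#' @param group `"EFMT"` or `"CT"`.
#' @param config An [participant_config()].
#' @param model An [trajectory_model()] (supplies the Ham-D to BDI map).
#' @param participant_id Identifier string.
#' @return Object of class `efmt_profile` with fields `participant_id`,
#'   `group`, `baseline_hamd`, `baseline_bdi`, `baseline_wais`,
#'   `episode_duration_months`, `capacity`.
#' @export
sample_participant <- function(group, config = participant_config(),
                               model = trajectory_model(),
                               participant_id = "P001") {
  stopifnot(group %in% c("EFMT", "CT"))
  m <- config$hamd_mean[[group]]
  s <- config$hamd_sd[[group]]
  lo <- config$hamd_range[1]; hi <- config$hamd_range[2]
  if (s == 0) {
    hamd <- min(max(round(m), lo), hi)
  } else {
    repeat {
      hamd <- round(stats::rnorm(1L, m, s))
      if (hamd >= lo && hamd <= hi) break
    }
  }
  bm <- model$bdi_map[[group]]
  bdi <- max(0L, round(bm[["alpha"]] + bm[["beta"]] * hamd +
                         stats::rnorm(1L, 0, model$bdi_noise_sd)))
  structure(
    list(participant_id = participant_id, group = group,
         baseline_hamd = as.integer(hamd),
         baseline_bdi = as.integer(bdi),
         baseline_wais = stats::rnorm(1L, config$wais_mean, config$wais_sd),
         episode_duration_months = stats::rlnorm(1L, config$episode_meanlog,
                                                 config$episode_sdlog),
         capacity = stats::rnorm(1L, config$capacity_mean[[group]],
                                 config$capacity_sd[[group]])),
    class = "efmt_profile"
  )
}

#' Simulate weekly attendance and the protocol discontinuation rule
#'
#' Sessions attended in each of the 6 training weeks are binomial draws
#' (3 scheduled sessions, per-session attendance probability). A participant
#' is discontinued in the first week in which fewer than two sessions were
#' completed, or in which the cumulative number of missed sessions exceeds
#' three; weeks after discontinuation have zero sessions.
#'
#' @param attendance_prob Per-session attendance probability.
#' @param n_weeks Number of training weeks (default 6).
#' @param sessions_per_week Scheduled sessions per week (default 3).
#' @return List with `sessions_by_week` (integer vector), `discontinued`
#'   (logical), `discontinuation_week` (integer or NA).
#' @export
simulate_adherence <- function(attendance_prob = 0.87, n_weeks = 6L,
                               sessions_per_week = 3L) {
  stopifnot(attendance_prob >= 0, attendance_prob <= 1)
  raw <- stats::rbinom(n_weeks, sessions_per_week, attendance_prob)
  disc_week <- discontinuation_week(raw, sessions_per_week)
  sessions <- raw
  if (!is.na(disc_week) && disc_week < n_weeks) {
    sessions[(disc_week + 1L):n_weeks] <- 0L
  }
  list(sessions_by_week = as.integer(sessions),
       discontinued = !is.na(disc_week),
       discontinuation_week = disc_week)
}

#' Apply the protocol discontinuation rule to an attendance vector
#'
#' @param sessions Integer vector of sessions attended per week.
#' @param sessions_per_week Scheduled sessions per week (default 3).
#' @return The first week violating the rule (fewer than two sessions that
#'   week, or cumulative missed sessions exceeding three), or NA if the
#'   regimen is completed.
#' @export
discontinuation_week <- function(sessions, sessions_per_week = 3L) {
  missed <- 0L
  for (w in seq_along(sessions)) {
    missed <- missed + (sessions_per_week - sessions[w])
    if (sessions[w] < 2L || missed > 3L) return(w)
  }
  NA_integer_
}

#' Split a Ham-D total into 17 item scores
#'
#' Allocates `total` points proportionally to `item_profile` with stochastic
#' rounding: each item receives the floor of its proportional share (capped
#' at the instrument maximum) and the leftover units are assigned one at a
#' time with probability proportional to the fractional remainders among
#' items still below their maximum. The items always re-sum to the total,
#' respect the per-item ranges, and have expected values proportional to the
#' profile whenever the caps are not binding.
#'
#' @param total Non-negative integer, at most 52.
#' @param item_profile Positive weights of length 17 (normalized internally).
#' @return Integer vector of length 17.
#' @export
decompose_hamd_items <- function(total,
                                 item_profile = as.numeric(hamd_item_ranges())) {
  total <- as.integer(total)
  mx <- as.integer(hamd_item_ranges())
  if (total < 0L) stop("total must be non-negative")
  if (total > sum(mx)) {
    stop("total exceeds the instrument maximum (", sum(mx), ")")
  }
  stopifnot(length(item_profile) == 17L, all(item_profile > 0))
  if (total == 0L) return(integer(17L))
  p <- item_profile / sum(item_profile)
  share <- total * p
  items <- pmin(as.integer(floor(share)), mx)
  frac <- pmin(share, mx) - items
  remaining <- total - sum(items)
  while (remaining > 0L) {
    open <- which(items < mx)
    w <- frac[open]
    if (sum(w) <= 0) w <- p[open]
    pick <- open[sample.int(length(open), 1L, prob = w)]
    items[pick] <- items[pick] + 1L
    frac[pick] <- 0
    remaining <- remaining - 1L
  }
  stopifnot(sum(items) == total, all(items <= mx))
  items
}

#' Simulate one participant's weekly clinical trajectory
#'
#' The expected Ham-D total at week w is the arm's weekly mean plus, in the
#' active arm, a mean-centered dose term (`dose_effect` times the deviation
#' of cumulative completed sessions from expected attendance). Residuals are
#' drawn from the model's 7x7 covariance; the week-0 residual is pinned to
#' the participant's screened baseline deviation and weeks 1..6 come from the
#' corresponding multivariate-normal conditional, so eligibility truncation
#' propagates into follow-up the way screening does. Totals are rounded and
#' clamped to the instrument range; items are allocated with
#' [decompose_hamd_items()]; BDI-II is the model's noisy linear transform of
#' the Ham-D total.
#'
#' @param profile An [sample_participant()] profile.
#' @param model An [trajectory_model()].
#' @param sessions_by_week Integer vector (length 6) of completed sessions,
#'   e.g. from [simulate_adherence()].
#' @param discontinuation_week Integer week of discontinuation or NA.
#' @param items Allocate item-level scores (default TRUE); set FALSE to skip
#'   the per-item decomposition when only totals are needed, e.g. in large
#'   Monte-Carlo runs.
#' @return data.frame with one row per week 0..6: `participant_id`, `group`,
#'   `week`, `hamd_total`, `item1..item17`, `bdi`, `sessions_this_week`,
#'   `sessions_cumulative`, `status` (`active`/`discontinued`/`completed`).
#'   Rows at and after a discontinuation week carry NA clinical scores (no
#'   assessment was performed).
#' @export
simulate_trajectory <- function(profile, model = trajectory_model(),
                                sessions_by_week = rep(3L, 6L),
                                discontinuation_week = NA_integer_,
                                items = TRUE) {
  stopifnot(inherits(profile, "efmt_profile"),
            inherits(model, "efmt_trajectory_model"),
            length(sessions_by_week) == 6L)
  g <- profile$group
  mu <- model$weekly_means[[g]]
  Sigma <- model$residual_cov
  cum <- c(0L, cumsum(sessions_by_week))
  dose <- if (g == "EFMT") {
    model$dose_effect * (cum - model$dose_center * 0:6)
  } else rep(0, 7L)

  if (all(Sigma == 0)) {
    eps <- rep(0, 7L)
  } else if (Sigma[1, 1] <= 0) {
    eps <- c(0, MASS::mvrnorm(1L, rep(0, 6L), Sigma[-1, -1]))
  } else {
    eps0 <- profile$baseline_hamd - mu[1]
    s21 <- Sigma[-1, 1]
    cond_mean <- s21 / Sigma[1, 1] * eps0
    cond_cov <- Sigma[-1, -1] - tcrossprod(s21) / Sigma[1, 1]
    eps <- c(eps0, MASS::mvrnorm(1L, cond_mean, cond_cov))
  }

  total <- pmin(pmax(round(mu + dose + eps), 0L), 52L)
  observed <- if (is.na(discontinuation_week)) rep(TRUE, 7L)
              else (0:6) < discontinuation_week
  item_mat <- t(vapply(seq_len(7L), function(i) {
    if (items && observed[i]) decompose_hamd_items(total[i], model$item_profile)
    else rep(NA_integer_, 17L)
  }, integer(17L)))
  colnames(item_mat) <- names(hamd_item_ranges())
  bm <- model$bdi_map[[g]]
  bdi <- ifelse(observed,
                pmax(0L, round(bm[["alpha"]] + bm[["beta"]] * total +
                                 stats::rnorm(7L, 0, model$bdi_noise_sd))),
                NA_integer_)
  status <- ifelse(!observed, "discontinued",
                   ifelse(0:6 == 6L, "completed", "active"))
  out <- data.frame(
    participant_id = profile$participant_id,
    group = g,
    week = 0:6,
    hamd_total = ifelse(observed, as.integer(total), NA_integer_),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(item_mat))
  out$bdi <- as.integer(bdi)
  out$sessions_this_week <- c(0L, as.integer(sessions_by_week))
  out$sessions_cumulative <- as.integer(cum)
  out$status <- status
  out
}

#' Working-memory composite score
#'
#' The mean scaled score of the Digit-Span Forward, Digit-Span Backward, and
#' Letter-Number Sequencing subtests.
#'
#' @param dsf,dsb,lns Scaled subtest scores.
#' @return Arithmetic mean.
#' @export
wais_composite <- function(dsf, dsb, lns) {
  (dsf + dsb + lns) / 3
}
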