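# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles, without calling the code paths they check.

# Re-scan an emitted item sequence and classify every scored item by direct
# label comparison at lags N and N +/- 1.
oracle_rescan <- function(items, n) {
  lab <- items$label
  total <- nrow(items)
  out <- data.frame(position = items$position, is_target = FALSE,
                    is_lure = FALSE)
  for (i in seq_len(total)) {
    p <- i - 1L
    if (p < n) next
    tgt <- lab[i] == lab[i - n]
    lure <- FALSE
    if (!tgt) {
      if (n >= 2L && lab[i] == lab[i - (n - 1L)]) lure <- TRUE
      if (p - (n + 1L) >= 0L && lab[i] == lab[i - (n + 1L)]) lure <- TRUE
    }
    out$is_target[i] <- tgt
    out$is_lure[i] <- lure
  }
  out
}

# Brute-force re-application of the protocol discontinuation rules on a raw
# weekly attendance vector: < 2 sessions in any week, or > 3 missed in total.
oracle_discontinuation <- function(raw, per_week = 3L) {
  cum_missed <- cumsum(per_week - raw)
  bad <- which(raw < 2L | cum_missed > 3L)
  if (length(bad)) bad[1] else NA_integer_
}

# Generic GLS estimator by direct matrix algebra on complete long data:
# estimate Sigma as the pooled within-arm residual cross-product (REML
# divisor N - 2), then beta = (X' V^-1 X)^-1 X' V^-1 y with V block-diagonal.
# Returns cell means and the covariance of the CT - EFMT weekly contrasts.
oracle_gls <- function(long) {
  d <- long[!is.na(long$hamd_total), ]
  d$weekf <- factor(d$week)
  d$group <- factor(d$group, levels = c("EFMT", "CT"))
  ids <- unique(d$participant_id)
  W <- nlevels(d$weekf)
  d <- d[order(match(d$participant_id, ids), d$week), ]
  X <- model.matrix(~ group * weekf, d)
  y <- d$hamd_total
  # stage 1: OLS residuals -> pooled Sigma
  b_ols <- qr.solve(X, y)
  r <- y - X %*% b_ols
  R <- matrix(r, ncol = W, byrow = TRUE)
  Sigma <- crossprod(R) / (length(ids) - 2L)
  # stage 2: GLS with block-diagonal V
  Vinv <- solve(Sigma)
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  for (k in seq_along(ids)) {
    idx <- ((k - 1L) * W + 1L):(k * W)
    Xi <- X[idx, , drop = FALSE]
    XtVX <- XtVX + t(Xi) %*% Vinv %*% Xi
    XtVy <- XtVy + t(Xi) %*% Vinv %*% y[idx]
  }
  Vb <- solve(XtVX)
  beta <- as.numeric(Vb %*% XtVy)
  grid <- expand.grid(group = factor(c("EFMT", "CT"),
                                     levels = c("EFMT", "CT")),
                      weekf = factor(levels(d$weekf),
                                     levels = levels(d$weekf)))
  Xg <- model.matrix(~ group * weekf, grid)
  mu <- as.numeric(Xg %*% beta)
  L <- t(vapply(seq_len(W), function(w) Xg[2L * w, ] - Xg[2L * w - 1L, ],
                numeric(ncol(X))))
  list(
    cell_means = matrix(mu, nrow = 2,
                        dimnames = list(c("EFMT", "CT"), levels(d$weekf))),
    diffs = as.numeric(L %*% beta),
    se = sqrt(rowSums((L %*% Vb) * L)),
    Sigma = Sigma
  )
}

# Small complete balanced trial generated straight from multivariate normals
# (not via the package's trajectory machinery).
make_complete_long <- function(n_per_arm, mu_efmt, mu_ct, Sigma,
                               integers = FALSE) {
  W <- length(mu_efmt)
  ids <- sprintf("S%03d", seq_len(2L * n_per_arm))
  grp <- rep(c("EFMT", "CT"), each = n_per_arm)
  Y <- rbind(MASS::mvrnorm(n_per_arm, mu_efmt, Sigma),
             MASS::mvrnorm(n_per_arm, mu_ct, Sigma))
  if (integers) Y <- round(Y)
  data.frame(
    participant_id = rep(ids, each = W),
    group = rep(grp, each = W),
    week = rep(seq_len(W) - 1L, times = 2L * n_per_arm),
    hamd_total = as.numeric(t(Y)),
    stringsAsFactors = FALSE
  )
}

# Default configs reused across simulation tests: full attendance, totals
# only, no dose term (with complete attendance the centered dose term is the
# only difference, so zeroing it keeps the configured means exact).
recovery_config <- function(n_participants) {
  trial_config(n_participants = n_participants, attendance_prob = 1,
               simulate_task = FALSE, simulate_items = FALSE,
               trajectory = trajectory_model(dose_effect = 0))
}

# Null-effect configuration: control arm set to the active arm's means.
null_config <- function(n_participants, attendance_prob = 1,
                        simulate_items = FALSE) {
  efmt_means <- seq(19.25, 10.60, length.out = 7)
  trial_config(
    n_participants = n_participants, attendance_prob = attendance_prob,
    simulate_task = FALSE, simulate_items = simulate_items,
    trajectory = trajectory_model(
      weekly_means = list(EFMT = efmt_means, CT = efmt_means),
      dose_effect = 0
    )
  )
}
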