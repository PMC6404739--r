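#' Fit the primary mixed-model repeated-measures analysis
#'
#' Models the weekly Ham-D total with treatment arm, visit (categorical),
#' and their interaction as fixed effects, and an unstructured 7x7
#' within-participant covariance — equivalently a multivariate normal model
#' for each participant's visit vector with arm-by-week cell means. Missing
#' visits are handled by likelihood (no imputation).
#'
#' Two engines produce identical estimates on complete data:
#' \describe{
#'   \item{`closed`}{the exact REML solution for complete data (cell means
#'     are arm-by-week sample means; the covariance is the pooled
#'     within-arm residual cross-product divided by N - 2). The overall
#'     group-by-time test on this path uses the exact Hotelling
#'     \eqn{T^2 \to F(q, \nu - q + 1)} mapping (\eqn{\nu = N - 2}), which is
#'     correctly calibrated at pilot-trial sizes where the large-sample Wald
#'     F is anticonservative.}
#'   \item{`gls`}{[nlme::gls()] with `corSymm` correlation and per-visit
#'     variance weights (REML), used whenever visits are missing. If the
#'     unstructured fit fails to converge it is restarted from a
#'     compound-symmetry fit's correlation estimate. The interaction test on
#'     this path is a Wald F with residual denominator df.}
#' }
#'
#' Per-week least-squares-mean contrasts are reported as control minus
#' active (positive favors the active arm) with residual-df t tests
#' (df = observations minus fixed-effect parameters), the convention named
#' in the output.
#'
#' @param data Long data.frame with columns `participant_id`, `group` (or
#'   `arm`), `week` (0..6) and the response.
#' @param response Response column name (default `"hamd_total"`).
#' @param engine `"auto"` (closed form when complete, else gls), `"closed"`,
#'   or `"gls"`.
#' @return Object of class `efmt_mmrm`: `contrasts` (week, difference, se,
#'   df, t, p), `interaction` (F, df1, df2, p, method), `cell_means`,
#'   `sigma` (7x7), `n_participants`, `n_obs`, `engine`, `converged`.
#' @export
fit_mmrm <- function(data, response = "hamd_total",
                     engine = c("auto", "closed", "gls")) {
  engine <- match.arg(engine)
  if (!"group" %in% names(data) && "arm" %in% names(data)) {
    data$group <- data$arm
  }
  stopifnot(all(c("participant_id", "group", "week", response) %in%
                  names(data)))
  d <- data[!is.na(data[[response]]),
            c("participant_id", "group", "week", response)]
  names(d)[4] <- "y"
  d$group <- factor(d$group, levels = c("EFMT", "CT"))
  if (any(is.na(d$group))) stop("group must be EFMT or CT")
  if (nlevels(droplevels(d$group)) < 2L) stop("need two arms")
  weeks <- sort(unique(d$week))
  if (length(weeks) < 2L) stop("need at least two observed visits")
  d$weekf <- factor(d$week, levels = weeks)

  tab <- table(d$participant_id)
  complete <- all(tab == length(weeks)) && !anyDuplicated(
    paste(d$participant_id, d$week))
  if (engine == "auto") engine <- if (complete) "closed" else "gls"
  if (engine == "closed" && !complete) {
    stop("closed-form engine requires complete data; use engine = 'gls'")
  }
  if (engine == "closed") {
    fit <- mmrm_closed(d, weeks)
  } else {
    fit <- mmrm_gls(d, weeks)
  }
  fit$response <- response
  fit
}

# exact REML for complete data: per-cell means + pooled covariance
mmrm_closed <- function(d, weeks) {
  W <- length(weeks)
  ids <- unique(d$participant_id)
  d <- d[order(match(d$participant_id, ids), d$week), ]
  Y <- matrix(d$y, ncol = W, byrow = TRUE,
              dimnames = list(ids, paste0("week", weeks)))
  grp <- d$group[match(ids, d$participant_id)]
  n1 <- sum(grp == "EFMT"); n2 <- sum(grp == "CT")
  mu <- rbind(EFMT = colMeans(Y[grp == "EFMT", , drop = FALSE]),
              CT   = colMeans(Y[grp == "CT", , drop = FALSE]))
  R <- Y - mu[as.character(grp), , drop = FALSE]
  nu <- n1 + n2 - 2L
  Sigma <- crossprod(R) / nu
  nobs <- nrow(d)
  df_resid <- nobs - 2L * W

  diffs <- mu["CT", ] - mu["EFMT", ]
  se <- sqrt(diag(Sigma) * (1 / n1 + 1 / n2))
  tt <- diffs / se
  contrasts <- data.frame(
    week = weeks, difference = as.numeric(diffs), se = as.numeric(se),
    df = df_resid, t = as.numeric(tt),
    p = 2 * stats::pt(-abs(tt), df_resid)
  )

  # group-by-time: differences-of-differences vs baseline week
  A <- cbind(-1, diag(W - 1L))
  dd <- as.numeric(A %*% diffs)
  Vdd <- (1 / n1 + 1 / n2) * A %*% Sigma %*% t(A)
  q <- W - 1L
  T2 <- as.numeric(crossprod(dd, solve(Vdd, dd)))
  Fh <- T2 * (nu - q + 1) / (nu * q)
  interaction <- list(
    F = Fh, df1 = q, df2 = nu - q + 1L,
    p = stats::pf(Fh, q, nu - q + 1L, lower.tail = FALSE),
    method = "Hotelling T2 (exact, complete data)"
  )
  structure(
    list(contrasts = contrasts, interaction = interaction,
         cell_means = mu, sigma = Sigma,
         n_participants = n1 + n2, n_obs = nobs,
         df_method = "residual (n_obs - n_fixed_params)",
         engine = "closed", converged = TRUE),
    class = "efmt_mmrm"
  )
}

mmrm_gls <- function(d, weeks) {
  d$visit <- match(d$week, weeks)
  ctrl <- nlme::glsControl(maxIter = 200, msMaxIter = 200, opt = "optim")
  form <- y ~ group * weekf
  fit <- tryCatch(
    nlme::gls(form, data = d,
              correlation = nlme::corSymm(form = ~ visit | participant_id),
              weights = nlme::varIdent(form = ~ 1 | weekf),
              method = "REML", control = ctrl),
    error = function(e) e
  )
  converged <- !inherits(fit, "error")
  if (!converged) {
    # restart from a compound-symmetry estimate
    cs <- nlme::gls(form, data = d,
                    correlation = nlme::corCompSymm(form = ~ visit | participant_id),
                    method = "REML", control = ctrl)
    rho <- stats::coef(cs$modelStruct$corStruct, unconstrained = FALSE)
    W <- length(weeks)
    init <- rep(rho, W * (W - 1) / 2)
    fit <- nlme::gls(form, data = d,
                     correlation = nlme::corSymm(value = init,
                                                 form = ~ visit | participant_id),
                     weights = nlme::varIdent(form = ~ 1 | weekf),
                     method = "REML", control = ctrl)
    converged <- TRUE
  }
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  W <- length(weeks)
  nobs <- nrow(d)
  p <- length(beta)
  df_resid <- nobs - p

  grid <- expand.grid(group = factor(c("EFMT", "CT"),
                                     levels = c("EFMT", "CT")),
                      weekf = factor(weeks, levels = weeks))
  X <- stats::model.matrix(~ group * weekf, grid)
  mu_hat <- as.numeric(X %*% beta)
  cell_means <- matrix(mu_hat, nrow = 2L,
                       dimnames = list(c("EFMT", "CT"),
                                       paste0("week", weeks)))
  # contrast rows: CT - EFMT at each week
  L <- t(vapply(seq_len(W), function(w) {
    X[2L * w, ] - X[2L * w - 1L, ]
  }, numeric(p)))
  diffs <- as.numeric(L %*% beta)
  se <- sqrt(rowSums((L %*% V) * L))
  tt <- diffs / se
  contrasts <- data.frame(
    week = weeks, difference = diffs, se = se, df = df_resid, t = tt,
    p = 2 * stats::pt(-abs(tt), df_resid)
  )
  A <- cbind(-1, diag(W - 1L))
  Ld <- A %*% L
  dd <- as.numeric(Ld %*% beta)
  Vdd <- Ld %*% V %*% t(Ld)
  q <- W - 1L
  Fw <- as.numeric(crossprod(dd, solve(Vdd, dd))) / q
  # marginal (unstructured) covariance implied by the fitted gls structure
  sig2 <- fit$sigma^2
  vw <- stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE,
                    allCoef = TRUE)
  vw <- vw[match(as.character(weeks), names(vw))]
  cms <- nlme::corMatrix(fit$modelStruct$corStruct)
  full <- which(vapply(cms, nrow, integer(1)) == W)
  Sigma <- if (length(full)) {
    S <- sig2 * outer(vw, vw) * cms[[full[1]]]
    dimnames(S) <- list(paste0("week", weeks), paste0("week", weeks))
    S
  } else NULL
  structure(
    list(contrasts = contrasts,
         interaction = list(F = Fw, df1 = q, df2 = df_resid,
                            p = stats::pf(Fw, q, df_resid,
                                          lower.tail = FALSE),
                            method = "Wald F, residual df"),
         cell_means = cell_means, sigma = Sigma,
         n_participants = length(unique(d$participant_id)), n_obs = nobs,
         df_method = "residual (n_obs - n_fixed_params)",
         engine = "gls", converged = converged, fit = fit),
    class = "efmt_mmrm"
  )
}

#' @export
print.efmt_mmrm <- function(x, ...) {
  cat("MMRM (unstructured covariance), engine:", x$engine, "\n")
  cat("  ", x$n_participants, "participants,", x$n_obs, "observations\n")
  cat(sprintf("  group x time: F(%d, %d) = %.2f, p = %.4g  [%s]\n",
              x$interaction$df1, x$interaction$df2, x$interaction$F,
              x$interaction$p, x$interaction$method))
  cat("  weekly LS-mean differences (CT - EFMT):\n")
  print(format(x$contrasts, digits = 4), row.names = FALSE)
  invisible(x)
}

#' t and p from a least-squares-mean contrast
#'
#' @param difference Contrast estimate (Ham-D points).
#' @param se Standard error (must be positive).
#' @param df Denominator degrees of freedom.
#' @return data.frame with `t = difference / se` and the two-sided p from
#'   the t distribution; vectorized over rows.
#' @export
contrast_t_p <- function(difference, se, df) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(df < 1)) stop("df must be >= 1")
  t <- difference / se
  data.frame(t = t, p = 2 * stats::pt(-abs(t), df))
}

#' Percent reduction from baseline
#'
#' @param baseline_mean Baseline mean (must be positive).
#' @param outcome_mean Outcome mean.
#' @return `100 * (baseline - outcome) / baseline`.
#' @export
percent_reduction <- function(baseline_mean, outcome_mean) {
  if (any(baseline_mean <= 0)) stop("baseline_mean must be positive")
  100 * (baseline_mean - outcome_mean) / baseline_mean
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return Object of class `efmt_summary_ttest`: `t`, `df = n1 + n2 - 2`,
#'   `p` (two-sided), plus the inputs. Two identical degenerate summaries
#'   (both SDs zero, equal means) give t = 0, p = 1 by convention.
#' @export
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- if (se == 0) {
    if (m1 == m2) 0 else stop("zero pooled SD with unequal means")
  } else (m1 - m2) / se
  structure(
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
         m1 = m1, sd1 = sd1, n1 = n1, m2 = m2, sd2 = sd2, n2 = n2),
    class = "efmt_summary_ttest"
  )
}

#' @export
print.efmt_summary_ttest <- function(x, ...) {
  cat(sprintf("two-sample pooled t: t(%d) = %.3f, p = %.3f\n",
              x$df, x$t, x$p))
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Object of class `efmt_correlation`: `r`, `n`,
#'   `t = r sqrt(n-2) / sqrt(1-r^2)`, `p` two-sided at df = n - 2.
#' @export
corr_with_p <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  corr_p_from_summary(stats::cor(x, y), length(x))
}

#' @rdname corr_with_p
#' @param r A correlation coefficient in [-1, 1].
#' @param n The sample size it was computed from.
#' @export
corr_p_from_summary <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  structure(
    list(r = r, n = n, t = t, p = 2 * stats::pt(-abs(t), n - 2)),
    class = "efmt_correlation"
  )
}

#' @export
print.efmt_correlation <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), t(%d) = %.3f, p = %.3f\n",
              x$r, x$n, x$n - 2L, x$t, x$p))
  invisible(x)
}

#' LOCF sensitivity analysis
#'
#' Group-by-time test of the baseline-to-outcome Ham-D change in the m-ITT
#' LOCF dataset, adjusting for baseline Ham-D and the number of training
#' sessions completed: a linear model of the change score on arm plus the
#' two covariates. The arm term's partial F has (1, n - 4) degrees of
#' freedom, the two-timepoint repeated-measures group-by-time test.
#'
#' @param trial An `efmt_trial` after [apply_locf()].
#' @return List with `F`, `df1`, `df2`, `p`, `estimate` (adjusted EFMT - CT
#'   change difference), and the fitted `model`.
#' @export
locf_sensitivity_model <- function(trial) {
  stopifnot(inherits(trial, "efmt_trial"))
  if (is.null(trial$long_locf)) stop("apply_locf() first")
  d <- trial$long_locf
  ids <- unique(d$participant_id)
  base <- d$hamd_total[d$week == 0][match(ids, d$participant_id[d$week == 0])]
  outc <- d$hamd_total[d$week == 6][match(ids, d$participant_id[d$week == 6])]
  p <- trial$participants
  idx <- match(ids, p$participant_id)
  dat <- data.frame(
    change = outc - base, baseline = base,
    sessions = p$sessions_completed[idx],
    arm = factor(p$arm[idx], levels = c("EFMT", "CT"))
  )
  full <- stats::lm(change ~ arm + baseline + sessions, data = dat)
  if (any(is.na(stats::coef(full)))) {
    warning("collinear covariates in the sensitivity model; ",
            "aliased terms dropped")
  }
  red <- stats::lm(change ~ baseline + sessions, data = dat)
  an <- stats::anova(red, full)
  list(F = an$F[2], df1 = an$Df[2], df2 = full$df.residual,
       p = an$`Pr(>F)`[2],
       estimate = -unname(stats::coef(full)["armCT"]),
       model = full)
}

#' Item-level group-by-time analysis of the 17 Ham-D symptoms
#'
#' For each item, tests the baseline-to-outcome change between arms in the
#' m-ITT (LOCF) sample: the two-timepoint group-by-time interaction,
#' computed as the arm F test in a linear model of the item change score,
#' with (1, n - 2) degrees of freedom. P values are deliberately
#' uncorrected for multiplicity (exploratory screen; the output carries an
#' explicit marker).
#'
#' @param trial An `efmt_trial` after [apply_locf()].
#' @param alpha Flagging threshold (default 0.05).
#' @return data.frame with 17 rows: `item`, `F`, `df1`, `df2`, `p`,
#'   `flagged`, `correction` (always `"none"`); items constant across the
#'   sample yield NA rows. The attribute `multiplicity_correction` is
#'   `"none"`.
#' @export
item_level_analysis <- function(trial, alpha = 0.05) {
  stopifnot(inherits(trial, "efmt_trial"))
  if (is.null(trial$long_locf)) stop("apply_locf() first")
  d <- trial$long_locf
  ids <- unique(d$participant_id)
  p <- trial$participants
  arm <- factor(p$arm[match(ids, p$participant_id)],
                levels = c("EFMT", "CT"))
  base <- d[d$week == 0, ][match(ids, d$participant_id[d$week == 0]), ]
  outc <- d[d$week == 6, ][match(ids, d$participant_id[d$week == 6]), ]
  items <- names(hamd_item_ranges())
  rows <- lapply(seq_along(items), function(i) {
    ch <- outc[[items[i]]] - base[[items[i]]]
    if (stats::var(ch) == 0) {
      message("item ", i, " constant; NA row")
      return(data.frame(item = i, F = NA_real_, df1 = NA_integer_,
                        df2 = NA_integer_, p = NA_real_, flagged = FALSE,
                        correction = "none"))
    }
    fit <- stats::lm(ch ~ arm)
    an <- stats::anova(fit)
    data.frame(item = i, F = an$`F value`[1], df1 = an$Df[1],
               df2 = an$Df[2], p = an$`Pr(>F)`[1],
               flagged = !is.na(an$`Pr(>F)`[1]) && an$`Pr(>F)`[1] < alpha,
               correction = "none")
  })
  out <- do.call(rbind, rows)
  attr(out, "multiplicity_correction") <- "none"
  out
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference `(m1 - m2) / s` where `s` is the pooled SD
#' (default) or the unweighted root-mean-square of the two SDs.
#'
#' @inheritParams pooled_t_from_summary
#' @param type `"pooled"` or `"unweighted"`.
#' @return Numeric d.
#' @export
cohens_d_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                                  type = c("pooled", "unweighted")) {
  type <- match.arg(type)
  s <- switch(type,
    pooled = sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)),
    unweighted = sqrt((sd1^2 + sd2^2) / 2)
  )
  if (s == 0) stop("zero pooled SD: d undefined")
  (m1 - m2) / s
}
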