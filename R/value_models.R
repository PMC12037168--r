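# Fitting the two-parameter forgetting Q-learning model to choice/reward
# series, |dQ| uncertainty splits, win-stay/lose-switch statistics,
# choice-history logistic regression, and vigor-by-value summaries.

#' Construct a choice series
#'
#' The per-trial input to all value-model analyses: completed choices and
#' their binary reward outcomes, with optional block, volume, and per-trial
#' kinematics columns. Omission and premature trials are excluded before
#' model fitting.
#'
#' @param choice Character vector of `"push"`/`"pull"`.
#' @param reward 0/1 vector of equal length.
#' @param block_id,volume_ul Optional per-trial annotations.
#' @param kinematics Optional data frame of per-trial kinematics
#'   (same length), e.g. from [session_vigor_analysis()].
#' @return Data frame of class `choice_series`.
#' @export
choice_series <- function(choice, reward, block_id = NULL, volume_ul = NULL,
                          kinematics = NULL) {
  n <- length(choice)
  if (length(reward) != n) stop("choice and reward must have equal lengths")
  if (!all(choice %in% c("push", "pull")))
    stop("choice_series holds completed choices only (push/pull)")
  if (!all(reward %in% c(0, 1))) stop("rewards must be 0/1")
  out <- data.frame(choice = choice, reward = as.numeric(reward))
  if (!is.null(block_id)) out$block_id <- block_id
  if (!is.null(volume_ul)) out$volume_ul <- volume_ul
  if (!is.null(kinematics)) {
    if (nrow(kinematics) != n) stop("kinematics must match series length")
    out <- cbind(out, kinematics)
  }
  class(out) <- c("choice_series", "data.frame")
  out
}

#' Extract the completed-choice series from a simulated session
#'
#' Drops omission and premature trials (kept in the session log) and carries
#' block id, volume and, when available, per-trial kinematics.
#'
#' @param session A `joy_session` from [run_bandit_session()].
#' @param kinematics Optional result of [session_vigor_analysis()]; its
#'   per-trial readouts are joined by trial index.
#' @return A [choice_series()].
#' @export
as_choice_series <- function(session, kinematics = NULL) {
  tr <- session$trials
  keep <- tr$outcome %in% c("rewarded", "unrewarded")
  tr <- tr[keep, ]
  kin <- NULL
  if (!is.null(kinematics)) {
    kt <- kinematics$trials
    kin_cols <- c("peak_displacement_mm", "n_bouts", "directional_consistency",
                  "decisive_mean_velocity_mm_s", "path_length_mm",
                  "choice_latency_ms")
    m <- match(tr$index, kt$index)
    kin <- kt[m, intersect(kin_cols, names(kt)), drop = FALSE]
    rownames(kin) <- NULL
  } else {
    kin <- data.frame(choice_latency_ms = tr$choice_latency_ms)
  }
  choice_series(tr$choice, as.numeric(tr$outcome == "rewarded"),
                block_id = tr$block_id, volume_ul = tr$volume_ul,
                kinematics = kin)
}

#' Negative log-likelihood and Q trajectories of the forgetting Q model
#'
#' Forward pass of the two-parameter forgetting Q-learning model over a
#' choice series, using the same update ([q_update()]) and choice rule
#' ([softmax_push_prob()]) as the generative agent. Values start at
#' `q_init`; the log-likelihood is accumulated on the log scale
#' (`log1p(exp())` form), so extreme `beta * dQ` never underflows.
#'
#' @param series A [choice_series()].
#' @param alpha Learning/forgetting rate in (0, 1].
#' @param beta Inverse temperature >= 0.
#' @param q_init Initial action value (default 0).
#' @return List with `nll` and per-trial `q_push`, `q_pull`, `delta_q`
#'   (values *before* each trial's update, i.e. the values the choice was
#'   made under).
#' @export
q_trajectory_nll <- function(series, alpha, beta, q_init = 0) {
  if (!(alpha > 0 && alpha <= 1) || beta < 0)
    stop("alpha must be in (0,1], beta >= 0")
  n <- nrow(series)
  if (n == 0) stop("empty choice series")
  is_push <- series$choice == "push"
  dq <- q_forward_deltas(is_push, series$reward, alpha, q_init)
  # -log P(choice): log(1 + exp(-beta * s * dQ)), s = +1 push, -1 pull
  z <- beta * ifelse(is_push, dq$delta_q, -dq$delta_q)
  nll <- sum(log1p(exp(-abs(z))) + pmax(-z, 0))
  list(nll = nll, q_push = dq$q_push, q_pull = dq$q_pull,
       delta_q = dq$delta_q)
}

# Forward pass of the value recursion only (independent of beta): returns
# pre-update Q values per trial.
q_forward_deltas <- function(is_push, reward, alpha, q_init = 0) {
  n <- length(is_push)
  qp <- numeric(n); qq <- numeric(n)
  cp <- q_init; cq <- q_init
  for (t in seq_len(n)) {
    qp[t] <- cp; qq[t] <- cq
    if (is_push[t]) {
      cp <- cp + alpha * (reward[t] - cp)
      cq <- (1 - alpha) * cq
    } else {
      cq <- cq + alpha * (reward[t] - cq)
      cp <- (1 - alpha) * cp
    }
  }
  list(q_push = qp, q_pull = qq, delta_q = qp - qq)
}

# nll for a vector of betas given precomputed delta_q: vectorized over
# trials and betas.
nll_given_deltas <- function(delta_q, is_push, betas) {
  s <- ifelse(is_push, 1, -1)
  z <- outer(s * delta_q, betas)                       # n x length(betas)
  colSums(log1p(exp(-abs(z))) + pmax(-z, 0))
}

#' Fit the forgetting Q-learning model by maximum likelihood
#'
#' Coarse grid search over `alpha` in \{0.025, 0.05, ..., 0.975\} and `beta`
#' in \{0, 0.25, ..., 20\} followed by Nelder-Mead refinement from the grid
#' optimum (bounded by reflecting the parameters into their domains). The
#' returned likelihood is never worse than the best grid point; the fit is
#' deterministic given the series. The grid is evaluated exactly but
#' factorized: Q trajectories depend only on `alpha`, so one forward pass
#' per `alpha` value serves every `beta`.
#'
#' @param series A [choice_series()].
#' @param q_init Initial action value.
#' @param alpha_grid,beta_grid Grid values (defaults as above).
#' @return List of class `q_fit` with `alpha_hat`, `beta_hat`,
#'   `neg_log_likelihood`, per-trial `q_push`, `q_pull`, `delta_q`, and the
#'   grid optimum.
#' @export
fit_q_model <- function(series, q_init = 0,
                        alpha_grid = seq(0.025, 0.975, by = 0.025),
                        beta_grid = seq(0, 20, by = 0.25)) {
  n <- nrow(series)
  if (n < 100)
    warning("fewer than 100 completed trials; Q-model fit may be unstable")
  if (length(unique(series$choice)) == 1)
    warning("degenerate series (all one choice); fit lies on the boundary")
  is_push <- series$choice == "push"
  reward <- series$reward

  best <- list(nll = Inf, alpha = NA, beta = NA)
  for (a in alpha_grid) {
    dq <- q_forward_deltas(is_push, reward, a, q_init)$delta_q
    nlls <- nll_given_deltas(dq, is_push, beta_grid)
    k <- which.min(nlls)
    if (nlls[k] < best$nll)
      best <- list(nll = nlls[k], alpha = a, beta = beta_grid[k])
  }

  # derivative-free refinement; reflect into (0,1] x [0, inf)
  obj <- function(par) {
    a <- par[1]; b <- par[2]
    if (a <= 1e-6 || a > 1 || b < 0) return(Inf)
    q_trajectory_nll(series, a, b, q_init)$nll
  }
  ref <- stats::optim(c(best$alpha, best$beta), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  if (ref$value <= best$nll) {
    alpha_hat <- ref$par[1]; beta_hat <- ref$par[2]; nll <- ref$value
  } else {
    alpha_hat <- best$alpha; beta_hat <- best$beta; nll <- best$nll
  }
  traj <- q_trajectory_nll(series, alpha_hat, beta_hat, q_init)
  structure(list(alpha_hat = alpha_hat, beta_hat = beta_hat,
                 neg_log_likelihood = nll,
                 q_push = traj$q_push, q_pull = traj$q_pull,
                 delta_q = traj$delta_q, n_trials = n,
                 grid_optimum = best),
            class = "q_fit")
}

#' @export
print.q_fit <- function(x, ...) {
  cat(sprintf("<q_fit> alpha = %.3f, beta = %.2f, nll = %.2f over %d trials\n",
              x$alpha_hat, x$beta_hat, x$neg_log_likelihood, x$n_trials))
  invisible(x)
}

#' Split trials by |dQ| uncertainty
#'
#' Trials with `|dQ|` below the given quantile of the fitted `|dQ|`
#' distribution form the high-uncertainty set (similar action values);
#' trials at/above it the low-uncertainty set. The split is invariant to the
#' sign of `dQ`.
#'
#' @param fit A `q_fit`.
#' @param quantile Split quantile (default 0.5, the median).
#' @return List of class `uncertainty_split` with logical masks
#'   `high_uncertainty`, `low_uncertainty`, the `threshold`, and `abs_dq`.
#' @export
uncertainty_split <- function(fit, quantile = 0.5) {
  adq <- abs(fit$delta_q)
  thr <- stats::quantile(adq, quantile, names = FALSE)
  if (max(adq) == min(adq)) {
    warning("constant |dQ|; all trials assigned to the low-uncertainty set")
    high <- rep(FALSE, length(adq))
  } else high <- adq < thr
  structure(list(high_uncertainty = high, low_uncertainty = !high,
                 threshold = thr, abs_dq = adq),
            class = "uncertainty_split")
}

#' Win-stay/lose-switch statistics
#'
#' `p_stay_given_win`: probability of repeating the previous choice given it
#' was rewarded; `p_switch_given_lose`: probability of switching given it
#' was not.
#'
#' @param series A [choice_series()].
#' @return List of class `wsls_stats` with the two probabilities and their
#'   conditioning-event counts (`NA` when a condition never occurs).
#' @export
wsls_stats <- function(series) {
  n <- nrow(series)
  if (n < 2) stop("wsls_stats needs at least 2 trials")
  stay <- series$choice[-1] == series$choice[-n]
  won <- series$reward[-n] == 1
  n_win <- sum(won); n_lose <- sum(!won)
  structure(list(
    p_stay_given_win = if (n_win > 0) mean(stay[won]) else NA_real_,
    p_switch_given_lose = if (n_lose > 0) mean(!stay[!won]) else NA_real_,
    n_win = n_win, n_lose = n_lose), class = "wsls_stats")
}

#' Choice-history logistic regression
#'
#' Predicts repetition of the previous choice (`repeat_t = [choice_t ==
#' choice_(t-1)]`) from indicator pairs of past rewarded and unrewarded
#' outcomes at lags `1..n_lags`. Positive rewarded weights and negative
#' unrewarded weights indicate win-stay/lose-switch-like evidence
#' integration. Because every included trial is either rewarded or
#' unrewarded, each lag's indicator pair sums to one: the model is fit
#' without an intercept (reported as 0), so each weight is directly the
#' log-odds of repeating given that outcome at that lag. Fitted by binomial
#' IRLS ([stats::glm]); on perfect separation, non-convergence, or rank
#' deficiency (pairs at lags beyond the first are mutually collinear) a
#' ridge-stabilized IRLS (penalty 1e-4) is used and flagged.
#'
#' @param series A [choice_series()].
#' @param n_lags Number of history lags (default 1).
#' @return List of class `lag_regression` with `intercept` (0 by
#'   construction), `rewarded_weights`, `unrewarded_weights` (length
#'   `n_lags`), `converged`, and `ridge_fallback`.
#' @export
repeat_choice_regression <- function(series, n_lags = 1) {
  n <- nrow(series)
  if (n_lags < 1) stop("n_lags must be >= 1")
  if (n <= 10 * (2 * n_lags + 1))
    stop("series too short for the requested number of lags")
  t_idx <- (n_lags + 1):n
  y <- as.numeric(series$choice[t_idx] == series$choice[t_idx - 1])
  X <- matrix(0, length(t_idx), 2 * n_lags)
  cn <- character(2 * n_lags)
  for (k in seq_len(n_lags)) {
    X[, 2 * k - 1] <- as.numeric(series$reward[t_idx - k] == 1)
    X[, 2 * k] <- as.numeric(series$reward[t_idx - k] == 0)
    cn[2 * k - 1] <- paste0("rewarded_lag", k)
    cn[2 * k] <- paste0("unrewarded_lag", k)
  }
  colnames(X) <- cn
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(stats::glm(y ~ . - 1, family = stats::binomial(),
                                     data = df))
  co <- stats::coef(fit)
  degenerate <- !fit$converged || anyNA(co) || any(abs(co) > 15)
  ridge <- FALSE
  if (degenerate) {
    rl <- ridge_logistic(X, y, lambda = 1e-4)
    coefs <- rl$beta
    converged <- rl$converged
    ridge <- TRUE
  } else {
    coefs <- co
    converged <- fit$converged
  }
  structure(list(intercept = 0,
                 rewarded_weights = unname(coefs[2 * seq_len(n_lags) - 1]),
                 unrewarded_weights = unname(coefs[2 * seq_len(n_lags)]),
                 converged = converged, ridge_fallback = ridge,
                 n_used = length(y)),
            class = "lag_regression")
}

# Ridge-penalized logistic IRLS; convergence by relative nll change < 1e-8,
# max 100 iterations.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(lambda, p)
  nll_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta <- solve(XtW %*% X + pen, XtW %*% z)
    eta <- drop(X %*% beta)
    nll <- -sum(y * eta - log1p(exp(pmin(eta, 700)))) +
      0.5 * lambda * sum(beta^2)
    if (is.finite(nll_old) && abs(nll_old - nll) < tol * (abs(nll_old) + 1)) {
      converged <- TRUE
      break
    }
    nll_old <- nll
  }
  list(beta = drop(beta), converged = converged)
}

# ---- rank-based trend / contrast machinery --------------------------------

# Jonckheere-style ordered-trend statistic: sum over ordered group pairs of
# the Mann-Whitney count #(x_i < y_j) + 0.5 #(x_i == y_j), groups ordered by
# their level. Larger than its permutation null mean => increasing trend.
jt_statistic <- function(values, groups) {
  lev <- sort(unique(groups))
  stat <- 0
  for (a in seq_along(lev)[-length(lev)]) {
    for (b in (a + 1):length(lev)) {
      x <- values[groups == lev[a]]
      y <- values[groups == lev[b]]
      cmp <- outer(x, y, "<")
      ties <- outer(x, y, "==")
      stat <- stat + sum(cmp) + 0.5 * sum(ties)
    }
  }
  stat
}

# Two-sided permutation p-value for a statistic under group-label shuffles.
perm_pvalue <- function(stat_fn, values, groups, reps) {
  obs <- stat_fn(values, groups)
  if (reps <= 0) return(list(statistic = obs, p = NA_real_, null_mean = NA_real_))
  null <- vapply(seq_len(reps), function(i)
    stat_fn(values, sample(groups)), 0)
  mu <- mean(null)
  p <- (1 + sum(abs(null - mu) >= abs(obs - mu))) / (reps + 1)
  list(statistic = obs, p = p, null_mean = mu)
}

# Rank-sum statistic (sum of ranks of group 2) for two-group contrasts.
ranksum_statistic <- function(values, groups) {
  g2 <- groups == sort(unique(groups))[2]
  sum(rank(values)[g2])
}

#' Vigor-by-value and uncertainty-contrast summaries
#'
#' Two analyses on a kinematics-annotated choice series:
#'
#' 1. **Volume trends** — per-volume medians of peak displacement and choice
#'    latency across the \{2, 4, 8\} ul blocks, with a Jonckheere-style
#'    ordered-trend statistic (explicit rank sums over ordered group pairs)
#'    and a permutation p-value. Vigor coupling predicts displacement
#'    increasing and latency decreasing with volume.
#' 2. **Uncertainty contrasts** — low- vs high-|dQ| rank-sum contrasts
#'    (permutation p-values) of the five per-trial readouts: peak
#'    displacement, decisive-bout mean velocity, bout count, directional
#'    consistency and path length.
#'
#' @param series A [choice_series()] carrying kinematics columns.
#' @param split An optional [uncertainty_split()] (from a fitted Q model) for
#'   the contrasts; skipped when `NULL`.
#' @param reps Permutation replicates (default 2000; 0 disables p-values).
#' @param min_group Groups with fewer trials are excluded with a flag.
#' @return List of class `vigor_summary` with `volume_medians`,
#'   `volume_trends`, `uncertainty_contrasts`, `excluded_groups`.
#' @export
vigor_by_value_summary <- function(series, split = NULL, reps = 2000,
                                   min_group = 3) {
  out <- list(volume_medians = NULL, volume_trends = NULL,
              uncertainty_contrasts = NULL, excluded_groups = character(0))

  if (!is.null(series$volume_ul)) {
    keep_lv <- names(which(table(series$volume_ul) >= min_group))
    dropped <- setdiff(unique(as.character(series$volume_ul)), keep_lv)
    if (length(dropped))
      out$excluded_groups <- paste0("volume_", dropped, "_ul")
    sub <- series[as.character(series$volume_ul) %in% keep_lv, ]
    med <- function(col) tapply(sub[[col]], sub$volume_ul, stats::median,
                                na.rm = TRUE)
    vars <- intersect(c("peak_displacement_mm", "choice_latency_ms"),
                      names(sub))
    out$volume_medians <- do.call(rbind, lapply(vars, function(v)
      data.frame(variable = v, volume_ul = as.numeric(names(med(v))),
                 median = as.numeric(med(v)))))
    if (length(keep_lv) >= 2) {
      out$volume_trends <- do.call(rbind, lapply(vars, function(v) {
        ok <- !is.na(sub[[v]])
        pr <- perm_pvalue(jt_statistic, sub[[v]][ok], sub$volume_ul[ok], reps)
        data.frame(variable = v, jt_statistic = pr$statistic,
                   null_mean = pr$null_mean,
                   direction = ifelse(is.na(pr$null_mean), NA,
                                      sign(pr$statistic - pr$null_mean)),
                   p_perm = pr$p)
      }))
    }
  }

  if (!is.null(split)) {
    vars <- intersect(c("peak_displacement_mm", "decisive_mean_velocity_mm_s",
                        "n_bouts", "directional_consistency",
                        "path_length_mm"), names(series))
    grp <- ifelse(split$high_uncertainty, "high_uncertainty", "low_uncertainty")
    out$uncertainty_contrasts <- do.call(rbind, lapply(vars, function(v) {
      ok <- !is.na(series[[v]])
      pr <- perm_pvalue(ranksum_statistic, series[[v]][ok], grp[ok], reps)
      data.frame(variable = v,
                 median_high = stats::median(series[[v]][ok][grp[ok] == "high_uncertainty"]),
                 median_low = stats::median(series[[v]][ok][grp[ok] == "low_uncertainty"]),
                 ranksum = pr$statistic, p_perm = pr$p)
    }))
  }
  class(out) <- c("vigor_summary", "list")
  out
}
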