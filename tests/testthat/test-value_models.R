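test_that("forward-pass likelihood matches a hand-computed oracle", {
  # beta = 0: uniform choice, nll = n log 2 exactly
  set.seed(2)
  cs <- choice_series(sample(c("push", "pull"), 40, TRUE), rbinom(40, 1, 0.5))
  expect_equal(q_trajectory_nll(cs, 0.5, 0)$nll, 40 * log(2))
  # single trial at symmetric start: -log 0.5
  one <- choice_series("push", 1)
  expect_equal(q_trajectory_nll(one, 0.3, 7)$nll, -log(0.5))
  # hand-computed 3-trial forward pass (alpha = 0.5, beta = 2)
  ser <- choice_series(c("push", "push", "pull"), c(1, 0, 1))
  # t1: Q=(0,0), P(push)=0.5; update -> (0.5, 0)
  # t2: P(push)=1/(1+exp(-2*0.5)); update -> (0.25, 0)
  # t3: P(pull)=1/(1+exp(-2*(0-0.25)))
  p2 <- 1 / (1 + exp(-1))
  p3 <- 1 / (1 + exp(0.5))
  manual <- -(log(0.5) + log(p2) + log(p3))
  res <- q_trajectory_nll(ser, 0.5, 2)
  expect_equal(res$nll, manual, tolerance = 1e-10)
  expect_equal(res$q_push, c(0, 0.5, 0.25))
  expect_equal(res$q_pull, c(0, 0, 0))
  expect_equal(res$delta_q, c(0, 0.5, 0.25))
  # relabeling invariance: swapping push/pull leaves the nll unchanged
  flip <- function(ch) ifelse(ch == "push", "pull", "push")
  ser2 <- choice_series(flip(ser$choice), ser$reward)
  expect_equal(q_trajectory_nll(ser2, 0.5, 2)$nll, res$nll)
  # extreme beta does not underflow
  expect_true(is.finite(q_trajectory_nll(ser, 0.9, 500)$nll))
})

test_that("the factorized grid equals the naive alpha x beta double loop", {
  set.seed(4)
  ser <- simulate_q_series(0.4, 4, 300)
  ag <- c(0.2, 0.5, 0.8); bg <- c(0, 1, 5)
  naive <- outer(ag, bg, Vectorize(function(a, b)
    q_trajectory_nll(ser, a, b)$nll))
  fit <- fit_q_model(ser, alpha_grid = ag, beta_grid = bg)
  k <- which(naive == min(naive), arr.ind = TRUE)
  expect_equal(fit$grid_optimum$nll, min(naive), tolerance = 1e-10)
  expect_equal(fit$grid_optimum$alpha, ag[k[1]])
  expect_equal(fit$grid_optimum$beta, bg[k[2]])
  expect_lte(fit$neg_log_likelihood, fit$grid_optimum$nll + 1e-9)
})

test_that("fit_q_model recovers generative parameters and is deterministic", {
  set.seed(9)
  ser <- simulate_q_series(0.5, 3, 5000)
  f1 <- fit_q_model(ser)
  f2 <- fit_q_model(ser)
  expect_identical(f1, f2)
  expect_lt(abs(f1$alpha_hat - 0.5), 0.1)
  expect_true(f1$beta_hat >= 2 && f1$beta_hat <= 4)
  # random agent: no value signal, beta ~ 0 (median over replicates; single
  # fits can drift up a shallow alpha->0 likelihood ridge)
  set.seed(10)
  betas <- replicate(5, {
    rand <- choice_series(sample(c("push", "pull"), 5000, TRUE),
                          rbinom(5000, 1, 0.5))
    fr <- fit_q_model(rand)
    # the spurious fit never explains the data meaningfully better than
    # a coin flip
    expect_lt(5000 * log(2) - fr$neg_log_likelihood, 10)
    fr$beta_hat
  })
  expect_lte(stats::median(betas), 0.5)
  # degenerate all-one-choice series warns
  ser1 <- choice_series(rep("push", 200), rbinom(200, 1, 0.8))
  expect_warning(fit_q_model(ser1), "degenerate")
})

test_that("uncertainty split partitions trials by |dQ| around the quantile", {
  fit <- structure(list(delta_q = c(0.1, -0.2, 0.3, -0.4)), class = "q_fit")
  sp <- uncertainty_split(fit)
  expect_equal(which(sp$high_uncertainty), c(1, 2))
  expect_equal(which(sp$low_uncertainty), c(3, 4))
  expect_equal(sp$threshold, 0.25)
  expect_true(all(xor(sp$high_uncertainty, sp$low_uncertainty)))
  # sign invariance
  fit2 <- structure(list(delta_q = -fit$delta_q), class = "q_fit")
  expect_equal(uncertainty_split(fit2)$high_uncertainty, sp$high_uncertainty)
  # constant |dQ| degenerates with a warning
  fit3 <- structure(list(delta_q = rep(0, 5)), class = "q_fit")
  expect_warning(sp3 <- uncertainty_split(fit3), "constant")
  expect_true(all(sp3$low_uncertainty))
})

test_that("win-stay/lose-switch statistics count conditioning events", {
  # 4-trial hand series: push/R, push/U, pull/U, push
  ser <- choice_series(c("push", "push", "pull", "push"), c(1, 0, 0, 1))
  st <- wsls_stats(ser)
  expect_equal(st$p_stay_given_win, 1)       # 1 of 1
  expect_equal(st$p_switch_given_lose, 1)    # 2 of 2 (push->pull, pull->push)
  expect_equal(st$n_win, 1)
  expect_equal(st$n_lose, 2)
  # random agent: both ~ 0.5
  set.seed(14)
  rnd <- choice_series(sample(c("push", "pull"), 10000, TRUE),
                       rbinom(10000, 1, 0.5))
  str <- wsls_stats(rnd)
  expect_equal(str$p_stay_given_win, 0.5, tolerance = 0.03)
  expect_equal(str$p_switch_given_lose, 0.5, tolerance = 0.03)
  # Q-agent: stays more after wins than after losses (Fig-3C-style)
  set.seed(15)
  for (pars in list(c(0.2, 1), c(0.5, 3), c(0.8, 10))) {
    ser <- simulate_q_series(pars[1], pars[2], 2000)
    s <- wsls_stats(ser)
    expect_gt(s$p_stay_given_win, 1 - s$p_switch_given_lose)
  }
})

test_that("choice-history regression recovers generative weights", {
  # WSLS data: strongly positive rewarded, strongly negative unrewarded
  set.seed(16)
  s <- run_bandit_session(agent_wsls(), 1000, seed = 41)
  reg <- repeat_choice_regression(as_choice_series(s))
  expect_gt(reg$rewarded_weights[1], 2)
  expect_lt(reg$unrewarded_weights[1], -2)
  # outcome-independent agent: both weights ~ 0
  set.seed(17)
  rnd <- choice_series(sample(c("push", "pull"), 10000, TRUE),
                       rbinom(10000, 1, 0.5))
  reg0 <- repeat_choice_regression(rnd)
  expect_lt(abs(reg0$rewarded_weights[1]), 0.1)
  expect_lt(abs(reg0$unrewarded_weights[1]), 0.1)
  # generative recovery: w_R = 1.5, w_U = -1.0, n = 20000
  set.seed(18)
  n <- 20000
  reward <- rbinom(n, 1, 0.5)
  choice <- character(n); choice[1] <- "push"
  for (t in 2:n) {
    p_rep <- stats::plogis(1.5 * reward[t - 1] - 1.0 * (1 - reward[t - 1]))
    stay <- stats::runif(1) < p_rep
    choice[t] <- if (stay) choice[t - 1] else
      if (choice[t - 1] == "push") "pull" else "push"
  }
  gen <- choice_series(choice, reward)
  regg <- repeat_choice_regression(gen)
  expect_lt(abs(regg$rewarded_weights[1] - 1.5), 0.15)
  expect_lt(abs(regg$unrewarded_weights[1] + 1.0), 0.15)
  expect_true(regg$converged)
  expect_error(repeat_choice_regression(gen[1:20, ], n_lags = 1), "too short")
})

test_that("vigor-by-value summaries detect volume trends and dQ contrasts", {
  set.seed(19)
  coupled <- agent_q(q_agent_params(0.6, 4, vigor_gain = 1.2,
                                    latency_gain = 500))
  s <- run_bandit_session(coupled, 400, phase = "volume", seed = 71,
                          traces = TRUE)
  va <- session_vigor_analysis(s)
  ser <- as_choice_series(s, kinematics = va)
  fit <- fit_q_model(ser)
  vs <- vigor_by_value_summary(ser, split = uncertainty_split(fit), reps = 500)
  expect_s3_class(vs$volume_medians, "data.frame")
  expect_true(all(c("peak_displacement_mm", "choice_latency_ms") %in%
                  vs$volume_trends$variable))
  # contrasts exist for the five readouts
  expect_equal(sort(vs$uncertainty_contrasts$variable),
               sort(c("peak_displacement_mm", "decisive_mean_velocity_mm_s",
                      "n_bouts", "directional_consistency", "path_length_mm")))
  expect_true(all(vs$uncertainty_contrasts$p_perm >= 0 &
                  vs$uncertainty_contrasts$p_perm <= 1))
  # reps = 0: statistics only, no p-values
  vs0 <- vigor_by_value_summary(ser, split = uncertainty_split(fit), reps = 0)
  expect_true(all(is.na(vs0$volume_trends$p_perm)))
})

test_that("vigor coupling produces the volume-trend directions; no coupling, no trend", {
  # displacement rises and latency falls with total value in blocks of
  # higher reward volume only through learned value, so test the mechanism
  # directly at the trace-policy level via the agent's vigor parameters
  set.seed(20)
  coupled <- agent_q(q_agent_params(0.6, 4, vigor_gain = 2, latency_gain = 600))
  s <- run_bandit_session(coupled, 500, phase = "volume", seed = 72,
                          traces = TRUE)
  va <- session_vigor_analysis(s)
  ser <- as_choice_series(s, kinematics = va)
  # proxy check: trials with higher total fitted value show larger peaks
  fit <- fit_q_model(ser)
  tot <- fit$q_push + fit$q_pull
  hi <- tot > stats::median(tot)
  expect_gt(stats::median(ser$peak_displacement_mm[hi]),
            stats::median(ser$peak_displacement_mm[!hi]))
  expect_lt(stats::median(ser$choice_latency_ms[hi]),
            stats::median(ser$choice_latency_ms[!hi]))
})
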