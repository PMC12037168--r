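# Virtual behaving agents and synthetic trajectory generators. These give
# every analysis module a controllable ground truth: the Q-learning agent and
# its update/choice rules are also the single source of truth reused by the
# model-fitting code in value_models.R.

#' Parameters of the forgetting Q-learning agent
#'
#' The two behavioral parameters of the forgetting Q-learning model:
#' `alpha`, the shared learning/forgetting rate, and `beta`, the softmax
#' inverse temperature. `vigor_gain` and `latency_gain` couple the agent's
#' total value (Q_push + Q_pull) to the peak displacement and choice latency
#' of its synthetic traces — a minimal generative mechanism for
#' value-modulated vigor, not a claim about mice.
#'
#' @param alpha Learning/forgetting rate in (0, 1].
#' @param beta Inverse temperature, >= 0.
#' @param q_init Initial action value (default 0).
#' @param vigor_gain mm of extra decisive-bout displacement per unit total
#'   value (default 0 = off).
#' @param latency_gain ms of latency reduction per unit total value
#'   (default 0 = off).
#' @return A list of class `q_agent_params`.
#' @export
q_agent_params <- function(alpha, beta, q_init = 0,
                           vigor_gain = 0, latency_gain = 0) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, q_init = q_init,
                 vigor_gain = vigor_gain, latency_gain = latency_gain),
            class = "q_agent_params")
}

#' Softmax probability of choosing push
#'
#' `P(push) = 1 / (1 + exp(-beta * (q_push - q_pull)))` — the standard
#' two-action softmax with no bias term (the model has exactly two free
#' parameters).
#'
#' @param q_push,q_pull Current action values.
#' @param beta Inverse temperature.
#' @return Probability of choosing push; vectorized over values.
#' @export
softmax_push_prob <- function(q_push, q_pull, beta) {
  stats::plogis(beta * (q_push - q_pull))
}

#' One forgetting Q-learning update
#'
#' Chosen action: `Q <- Q + alpha * (reward - Q)`. Unchosen action:
#' `Q <- (1 - alpha) * Q`, i.e. decay toward zero at the same rate
#' ("nondifferential" forgetting). With rewards in \{0, 1\} and initial
#' values in \[0, 1\], values stay in \[0, 1\].
#'
#' @param q_push,q_pull Current action values.
#' @param choice `"push"` or `"pull"`.
#' @param reward 0 or 1.
#' @param alpha Learning/forgetting rate.
#' @return List with updated `q_push`, `q_pull`.
#' @export
q_update <- function(q_push, q_pull, choice, reward, alpha) {
  if (choice == "push") {
    q_push <- q_push + alpha * (reward - q_push)
    q_pull <- (1 - alpha) * q_pull
  } else if (choice == "pull") {
    q_pull <- q_pull + alpha * (reward - q_pull)
    q_push <- (1 - alpha) * q_push
  } else stop("choice must be 'push' or 'pull'")
  list(q_push = q_push, q_pull = q_pull)
}

#' Win-stay/lose-switch policy
#'
#' Repeat the previous choice if it was rewarded, switch otherwise. On the
#' first trial (no history) the choice is random.
#'
#' @param prev_choice `"push"`, `"pull"` or `NA` (first trial).
#' @param prev_reward 0/1 or `NA`.
#' @return `"push"` or `"pull"`.
#' @export
wsls_policy <- function(prev_choice, prev_reward) {
  if (is.na(prev_choice) || is.na(prev_reward))
    return(sample(c("push", "pull"), 1))
  if (prev_reward == 1) prev_choice
  else if (prev_choice == "push") "pull" else "push"
}

# ---- agent constructors ----------------------------------------------------
# An agent is a list with:
#   choose(ctx) -> "push" / "pull" / "none"; ctx carries prev_choice,
#     prev_reward, high_side, trial index
#   update(choice, reward)  (optional learning step)
#   state()                 (optional; q-values for trace coupling)
#   reset()
#   label

#' Virtual agents for task simulations
#'
#' Constructors for the built-in agent types:
#' * `agent_q(params)` — forgetting Q-learning agent with softmax choice.
#' * `agent_wsls()` — win-stay/lose-switch.
#' * `agent_oracle()` — always chooses the current high-probability side
#'   (reads the un-cued contingency from the task context; a validation
#'   agent, not a model of behavior).
#' * `agent_random(p_push)` — chooses push with fixed probability.
#' * `agent_fixed(choice)` — always emits the same choice.
#' * `agent_silent()` — never responds (all trials are omissions).
#'
#' All randomness flows through R's RNG so a seeded session is
#' reproducible bit-for-bit.
#'
#' @param params A [q_agent_params()].
#' @return An agent object (list of closures) of class `joy_agent`.
#' @export
agent_q <- function(params) {
  q_push <- params$q_init; q_pull <- params$q_init
  structure(list(
    label = sprintf("q(alpha=%g,beta=%g)", params$alpha, params$beta),
    params = params,
    choose = function(ctx) {
      p <- softmax_push_prob(q_push, q_pull, params$beta)
      if (stats::runif(1) < p) "push" else "pull"
    },
    update = function(choice, reward) {
      q <- q_update(q_push, q_pull, choice, reward, params$alpha)
      q_push <<- q$q_push; q_pull <<- q$q_pull
      invisible(NULL)
    },
    state = function() list(q_push = q_push, q_pull = q_pull),
    reset = function() { q_push <<- params$q_init; q_pull <<- params$q_init }
  ), class = "joy_agent")
}

#' @rdname agent_q
#' @export
agent_wsls <- function() {
  structure(list(
    label = "wsls",
    choose = function(ctx) wsls_policy(ctx$prev_choice, ctx$prev_reward),
    update = function(choice, reward) invisible(NULL),
    state = function() NULL,
    reset = function() invisible(NULL)
  ), class = "joy_agent")
}

#' @rdname agent_q
#' @export
agent_oracle <- function() {
  structure(list(
    label = "oracle",
    choose = function(ctx) ctx$high_side,
    update = function(choice, reward) invisible(NULL),
    state = function() NULL,
    reset = function() invisible(NULL)
  ), class = "joy_agent")
}

#' @rdname agent_q
#' @param p_push Probability that the random agent pushes.
#' @export
agent_random <- function(p_push = 0.5) {
  structure(list(
    label = sprintf("random(p=%g)", p_push),
    choose = function(ctx) if (stats::runif(1) < p_push) "push" else "pull",
    update = function(choice, reward) invisible(NULL),
    state = function() NULL,
    reset = function() invisible(NULL)
  ), class = "joy_agent")
}

#' @rdname agent_q
#' @param choice Fixed choice for `agent_fixed`.
#' @export
agent_fixed <- function(choice = "push") {
  stopifnot(choice %in% c("push", "pull"))
  structure(list(
    label = paste0("fixed(", choice, ")"),
    choose = function(ctx) choice,
    update = function(choice, reward) invisible(NULL),
    state = function() NULL,
    reset = function() invisible(NULL)
  ), class = "joy_agent")
}

#' @rdname agent_q
#' @export
agent_silent <- function() {
  structure(list(
    label = "silent",
    choose = function(ctx) "none",
    update = function(choice, reward) invisible(NULL),
    state = function() NULL,
    reset = function() invisible(NULL)
  ), class = "joy_agent")
}

# ---- synthetic 2D trajectories --------------------------------------------

#' Style parameters for synthetic 2D joystick trajectories
#'
#' `stage` interpolates between naive (0) and expert (1) movement: lateral
#' jitter and meander shrink with stage while speed grows, so batches of
#' increasing stage reproduce the qualitative learning trends (falling
#' tortuosity, trajectory dispersion and explored area; rising velocity).
#' Pushes are biased downward-forward, pulls upward-backward.
#'
#' @param stage Learning stage in \[0, 1\].
#' @param jitter_mm Lateral noise scale at stage 0 (shrinks as `1 - stage`).
#' @param speed_mm_s Nominal outbound speed at stage 1; the realized speed is
#'   `speed_mm_s * (0.4 + 0.6 * stage)`.
#' @param target_displacement_mm Target excursion along the push/pull axis.
#' @param direction `"push"` or `"pull"`.
#' @param sample_rate_hz Simulated sampling rate (default 1000).
#' @return A list of class `trajectory_style`.
#' @export
trajectory_style <- function(stage = 1, jitter_mm = 1.2, speed_mm_s = 30,
                             target_displacement_mm = 4.5,
                             direction = c("push", "pull"),
                             sample_rate_hz = 1000) {
  direction <- match.arg(direction)
  if (stage < 0 || stage > 1) stop("stage must be in [0, 1]")
  structure(list(stage = stage, jitter_mm = jitter_mm, speed_mm_s = speed_mm_s,
                 target_displacement_mm = target_displacement_mm,
                 direction = direction, sample_rate_hz = sample_rate_hz),
            class = "trajectory_style")
}

#' Generate a synthetic 2D out-and-back joystick trajectory
#'
#' Builds an out-and-back path toward `target_displacement_mm` in the styled
#' direction. The main heading tilts downward for pushes and upward for
#' pulls; the return leg stops short of the origin (real reaches do not close
#' exactly), so first-to-last chord lengths stay well defined. Low-stage
#' trajectories acquire low-frequency meander and sample-level jitter, both
#' scaled by `1 - stage`.
#'
#' @param style A [trajectory_style()].
#' @return A [position_trace()].
#' @export
generate_trajectory_2d <- function(style) {
  tgt <- style$target_displacement_mm
  speed <- style$speed_mm_s * (0.4 + 0.6 * style$stage)
  dt <- 1000 / style$sample_rate_hz                     # ms per sample
  t_out <- tgt / speed * 1000                           # ms outbound
  t_total <- 1.6 * t_out                                # partial return
  n <- max(8L, ceiling(t_total / dt))
  tm <- seq(0, by = dt, length.out = n)
  sgn <- if (style$direction == "push") 1 else -1
  u <- c(1, -0.6) / sqrt(1.36) * sgn                    # heading, y-biased

  # longitudinal displacement: half-sine out to the target (peak at
  # ph = 0.625), then a linear 60%-of-the-way return leg
  ph <- tm / t_total
  s <- tgt * ifelse(ph <= 0.625, sin(pi * ph / 1.25),
                    1 - 0.6 * (ph - 0.625) / 0.375)
  # meander: smooth low-frequency lateral wander, strongest when naive
  amp <- (1 - style$stage) * 0.6 * tgt
  phase <- stats::runif(2, 0, 2 * pi)
  lat <- amp * (0.7 * sin(2 * pi * 1.7 * ph + phase[1]) +
                0.3 * sin(2 * pi * 3.3 * ph + phase[2]))
  # sample jitter: smoothed white noise
  jit_sd <- style$jitter_mm * (1 - style$stage)
  jx <- stats::rnorm(n, 0, jit_sd); jy <- stats::rnorm(n, 0, jit_sd)
  if (n >= 5) {
    k <- rep(1 / 5, 5)
    jx <- stats::filter(jx, k, sides = 2); jy <- stats::filter(jy, k, sides = 2)
    jx[is.na(jx)] <- 0; jy[is.na(jy)] <- 0
  }
  perp <- c(-u[2], u[1])
  x <- s * u[1] + lat * perp[1] + as.numeric(jx)
  y <- s * u[2] + lat * perp[2] + as.numeric(jy)
  position_trace(tm, x, y)
}

# ---- synthetic anteroposterior bout traces --------------------------------

#' Specification of one movement bout for trace synthesis
#'
#' A bout is a unidirectional movement episode with a smooth half-sine
#' velocity profile. `peak_speed_mm_s`, `duration_ms` and `displacement_mm`
#' are linked by the profile (`displacement = 2 * peak * duration / pi`);
#' give any two — when all three are supplied `displacement_mm` wins and the
#' peak speed is recomputed.
#'
#' @param onset_ms Bout onset time.
#' @param direction `"push"` or `"pull"`.
#' @param peak_speed_mm_s Peak speed (unsigned), mm/s.
#' @param duration_ms Bout duration, ms.
#' @param displacement_mm Net displacement magnitude, mm (optional).
#' @return A list of class `bout_spec`.
#' @export
bout_spec <- function(onset_ms, direction = c("push", "pull"),
                      peak_speed_mm_s = NULL, duration_ms = NULL,
                      displacement_mm = NULL) {
  direction <- match.arg(direction)
  if (is.null(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be given and positive")
  if (is.null(displacement_mm)) {
    if (is.null(peak_speed_mm_s)) stop("give peak_speed_mm_s or displacement_mm")
    displacement_mm <- 2 * peak_speed_mm_s * duration_ms / 1000 / pi
  } else {
    peak_speed_mm_s <- pi * displacement_mm / (2 * duration_ms / 1000)
  }
  if (peak_speed_mm_s <= 0 || displacement_mm <= 0)
    stop("peak speed and displacement must be positive")
  structure(list(onset_ms = onset_ms, direction = direction,
                 peak_speed_mm_s = peak_speed_mm_s, duration_ms = duration_ms,
                 displacement_mm = displacement_mm),
            class = "bout_spec")
}

#' Synthesize a 1D anteroposterior trace from bout specifications
#'
#' Produces baseline noise plus the programmed bouts, each with a half-sine
#' velocity profile matching its direction, peak speed, duration and
#' displacement. Positions accumulate across bouts (the joystick stays where
#' a bout leaves it). The closed-loop fixture for bout segmentation.
#'
#' @param bouts List of [bout_spec()]s, non-overlapping in time.
#' @param n_ms Total trace duration, ms.
#' @param noise_mm Baseline Gaussian noise SD, mm.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @return A [position_trace()] with `y_mm = 0`.
#' @export
generate_ap_trace <- function(bouts, n_ms, noise_mm = 0, sample_rate_hz = 1000) {
  dt <- 1000 / sample_rate_hz
  tm <- seq(0, n_ms, by = dt)
  n <- length(tm)
  if (length(bouts) > 1) {
    o <- order(vapply(bouts, `[[`, 0, "onset_ms"))
    bouts <- bouts[o]
    ends <- vapply(bouts, function(b) b$onset_ms + b$duration_ms, 0)
    starts <- vapply(bouts, `[[`, 0, "onset_ms")
    if (any(starts[-1] < ends[-length(ends)]))
      stop("bout specifications overlap in time")
  }
  v <- numeric(n)                                       # mm/s, signed
  for (b in bouts) {
    idx <- which(tm >= b$onset_ms & tm <= b$onset_ms + b$duration_ms)
    phase <- (tm[idx] - b$onset_ms) / b$duration_ms
    sgn <- if (b$direction == "push") 1 else -1
    v[idx] <- v[idx] + sgn * b$peak_speed_mm_s * sin(pi * phase)
  }
  x <- cumsum(v) * dt / 1000                            # integrate to mm
  if (noise_mm > 0) x <- x + stats::rnorm(n, 0, noise_mm)
  position_trace(tm, x)
}
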