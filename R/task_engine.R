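# Deterministic-given-seed state machines for the two behavioral paradigms:
# the auditory-motor 2AFC task and the two-armed bandit value task, plus the
# cue-tone synthesizer. Engines emit a `joy_session` (trial table + event
# log + optional per-trial traces).

#' Configuration of the auditory-motor discrimination task
#'
#' Defaults mirror the published task: a 2-5 s variable pretrial interval, a
#' 500 ms cue (12 kHz tone -> push, 5 kHz tone -> pull, each with five
#' overtones), a 5 s response window, 200 ms reward delay, 5 s white noise on
#' omission with an intertrial-interval reset, and sessions capped at 30 min
#' or 100 rewards of ~10 ul each.
#'
#' @param iti_range_s Pretrial interval range, seconds.
#' @param cue_ms Cue duration.
#' @param response_window_s Response window after cue onset.
#' @param reward_delay_ms Delay between correct response and reward.
#' @param noise_on_omission_s White-noise duration after an omission.
#' @param session_max_min,session_max_rewards Session caps.
#' @param reward_ul Water volume per reward, microliters.
#' @param high_tone_hz,low_tone_hz Cue fundamentals.
#' @param n_overtones Number of overtones accompanying each cue tone.
#' @param high_tone_action,low_tone_action Cue-action mapping.
#' @return List of class `auditory_config`.
#' @export
auditory_config <- function(iti_range_s = c(2, 5), cue_ms = 500,
                            response_window_s = 5, reward_delay_ms = 200,
                            noise_on_omission_s = 5, session_max_min = 30,
                            session_max_rewards = 100, reward_ul = 10,
                            high_tone_hz = 12000, low_tone_hz = 5000,
                            n_overtones = 5, high_tone_action = "push",
                            low_tone_action = "pull") {
  stopifnot(all(c(iti_range_s, cue_ms, response_window_s, reward_delay_ms,
                  noise_on_omission_s, session_max_min) > 0),
            high_tone_action != low_tone_action)
  structure(as.list(environment()), class = "auditory_config")
}

#' Configuration of the two-armed bandit value task
#'
#' Defaults mirror the published task: after joystick extension and a 100 ms
#' wait, a GO cue opens a 10 s response window; anteroposterior displacement
#' beyond 3 mm registers a choice. Reward probabilities are 80%:20% for the
#' high/low side; blocks last a minimum of 17 rewarded trials plus a
#' Geometric(p = 0.4) extension, after which the high side reverses un-cued.
#' Rewarded and unrewarded trials are followed by a 2.5-8 s intertrial
#' interval; omissions and premature responses by white noise and a 15 s
#' time-out. In the changing-volume phase reward volume is drawn per block
#' from \{2, 4, 8\} ul.
#'
#' @param pre_go_wait_ms Wait between joystick extension and GO cue.
#' @param response_window_s Response window after the GO cue.
#' @param iti_range_s Intertrial interval range, seconds.
#' @param timeout_s Time-out after omission/premature trials.
#' @param p_high,p_low Reward probabilities of the high/low side.
#' @param block_min_rewarded Minimum rewarded trials per block.
#' @param block_geom_p Success probability of the geometric block extension.
#' @param volumes_ul Reward volumes used in the changing-volume phase.
#' @param reversal_volume_ul Fixed volume in the plain reversal phase.
#' @param choice_threshold_mm Choice-registration threshold.
#' @return List of class `value_config`.
#' @export
value_config <- function(pre_go_wait_ms = 100, response_window_s = 10,
                         iti_range_s = c(2.5, 8), timeout_s = 15,
                         p_high = 0.8, p_low = 0.2,
                         block_min_rewarded = 17, block_geom_p = 0.4,
                         volumes_ul = c(2, 4, 8), reversal_volume_ul = 4,
                         choice_threshold_mm = 3) {
  stopifnot(p_low > 0, p_low < p_high, p_high <= 1,
            block_min_rewarded >= 1, block_geom_p > 0, block_geom_p < 1)
  structure(as.list(environment()), class = "value_config")
}

#' Draw the rewarded-trial length of a bandit block
#'
#' Block length in rewarded trials: `min_rewarded + G` with
#' `G ~ Geometric(p)` on support \{0, 1, 2, ...\}, so the printed minimum is
#' attainable.
#'
#' @param p Geometric success probability (default 0.4).
#' @param min_rewarded Minimum rewarded trials (default 17).
#' @param n Number of draws.
#' @return Integer vector of block lengths.
#' @export
draw_block_length <- function(p = 0.4, min_rewarded = 17, n = 1) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  min_rewarded + stats::rgeom(n, p)
}

#' Bernoulli reward assignment for a bandit choice
#'
#' Rewarded with probability `p_high` when the choice matches the current
#' high-probability side, `p_low` otherwise.
#'
#' @param choice `"push"` or `"pull"`.
#' @param high_side Current high-probability side.
#' @param cfg A [value_config()].
#' @return Logical: rewarded?
#' @export
assign_reward <- function(choice, high_side, cfg = value_config()) {
  if (!choice %in% c("push", "pull"))
    stop("assign_reward requires a completed choice (push/pull)")
  p <- if (choice == high_side) cfg$p_high else cfg$p_low
  stats::runif(1) < p
}

other_side <- function(side) if (side == "push") "pull" else "push"

new_session <- function(task, config, trials, events, traces = NULL,
                        seed = NA, agent_label = NA_character_) {
  structure(list(task = task, config = config, trials = trials,
                 events = events, traces = traces, seed = seed,
                 agent = agent_label),
            class = "joy_session")
}

#' @export
print.joy_session <- function(x, ...) {
  tab <- table(factor(x$trials$outcome,
                      c("rewarded", "unrewarded", "omission", "premature")))
  cat(sprintf("<joy_session> %s task, agent %s, %d trials (%s), seed %s\n",
              x$task, x$agent, nrow(x$trials),
              paste(names(tab), tab, sep = ":", collapse = " "),
              as.character(x$seed)))
  invisible(x)
}

# Build one synthetic anteroposterior trial trace: deliberation bout pairs
# (sub-threshold, count scaling with choice uncertainty) followed by a
# decisive bout whose displacement crosses the choice threshold and grows
# with total value when vigor coupling is on.
make_bandit_trace <- function(choice, total_value, uncertainty, cfg,
                              vigor_gain = 0, latency_gain = 0,
                              base_displacement_mm = 3.6,
                              base_idle_ms = 900, bout_rate = 2) {
  n_pairs <- stats::rpois(1, bout_rate * uncertainty)
  bouts <- list()
  t <- round(base_idle_ms * max(0.1, 1 - latency_gain * total_value / base_idle_ms) +
             stats::runif(1, 0, 300))
  first_dir <- sample(c("push", "pull"), 1)
  if (n_pairs > 0) {
    for (i in seq_len(n_pairs)) {
      d <- stats::runif(1, 0.8, 2.2)
      dur <- round(stats::runif(1, 80, 150))
      dir1 <- if (stats::runif(1) < 0.5) "push" else "pull"
      bouts[[length(bouts) + 1L]] <-
        bout_spec(t, dir1, duration_ms = dur, displacement_mm = d)
      t <- t + dur + round(stats::runif(1, 40, 160))
      bouts[[length(bouts) + 1L]] <-
        bout_spec(t, other_side(dir1), duration_ms = dur, displacement_mm = d)
      t <- t + dur + round(stats::runif(1, 40, 160))
    }
  }
  disp <- max(cfg$choice_threshold_mm + 0.3,
              base_displacement_mm + vigor_gain * total_value +
                stats::runif(1, -0.2, 0.4))
  # uncertain choices are executed faster (shorter decisive bout for the
  # same displacement), mirroring the velocity-under-uncertainty phenotype
  dur <- round(stats::runif(1, 120, 200) - 60 * uncertainty)
  bouts[[length(bouts) + 1L]] <- bout_spec(t, choice, duration_ms = dur,
                                           displacement_mm = disp)
  generate_ap_trace(bouts, n_ms = t + dur + 200, noise_mm = 0.03)
}

#' Simulate a two-armed bandit session
#'
#' Runs `n_trials` of the value task with a virtual agent. Reversals are
#' un-cued and triggered once the block's drawn rewarded-trial count is
#' reached; in the changing-volume phase the reward volume is re-drawn per
#' block from `cfg$volumes_ul`. Each trial is classified into exactly one of
#' rewarded / unrewarded / omission / premature. With `traces = TRUE` a
#' synthetic anteroposterior trace is generated for every completed-choice
#' trial and the choice and its latency are read back off the trace through
#' [detect_choice()], so the behavioral record and the kinematic record are
#' mutually consistent.
#'
#' @param agent A `joy_agent` (see [agent_q()]).
#' @param n_trials Number of trials.
#' @param cfg A [value_config()].
#' @param phase `"reversal"` (fixed volume) or `"volume"` (per-block volume).
#' @param seed Optional integer seed; same seed, config and agent give a
#'   bit-identical session.
#' @param traces Generate per-trial synthetic traces?
#' @param p_omission,p_premature Per-trial probabilities that the agent's
#'   response is pre-empted by an omission or a premature movement
#'   (default 0; raise to exercise all four outcome types).
#' @return A `joy_session` with `trials`, `events`, and (optionally)
#'   `traces`.
#' @export
run_bandit_session <- function(agent, n_trials, cfg = value_config(),
                               phase = c("reversal", "volume"), seed = NULL,
                               traces = FALSE, p_omission = 0, p_premature = 0) {
  phase <- match.arg(phase)
  if (!is.null(seed)) set.seed(seed)
  agent$reset()
  high_side <- sample(c("push", "pull"), 1)
  block_id <- 1L
  block_target <- draw_block_length(cfg$block_geom_p, cfg$block_min_rewarded)
  rewarded_in_block <- 0L
  volume <- if (phase == "volume") sample(cfg$volumes_ul, 1) else cfg$reversal_volume_ul

  ev_t <- numeric(0); ev_k <- character(0); ev_p <- character(0)
  emit <- function(t, kind, payload = "") {
    ev_t[length(ev_t) + 1L] <<- t
    ev_k[length(ev_k) + 1L] <<- kind
    ev_p[length(ev_p) + 1L] <<- payload
  }
  clock <- 0
  emit(clock, "session_start", sprintf("task=bandit;phase=%s", phase))

  trials <- vector("list", n_trials)
  trace_list <- if (traces) vector("list", n_trials) else NULL
  prev_choice <- NA_character_; prev_reward <- NA_real_

  for (i in seq_len(n_trials)) {
    emit(clock, "trial_start", sprintf("trial=%d;block=%d", i, block_id))
    emit(clock, "joystick_extend")
    t_go <- clock + cfg$pre_go_wait_ms
    premature <- stats::runif(1) < p_premature
    omitted <- !premature && stats::runif(1) < p_omission
    choice <- "none"; latency <- NA_real_; rewarded <- FALSE
    outcome <- NA_character_

    if (premature) {
      outcome <- "premature"
      t_resp <- clock + round(stats::runif(1, 10, cfg$pre_go_wait_ms - 1))
      emit(t_resp, "premature", sprintf("trial=%d", i))
      emit(t_resp, "white_noise_on")
      clock <- t_resp + cfg$timeout_s * 1000
    } else {
      emit(t_go, "go_cue")
      if (omitted) {
        outcome <- "omission"
        t_end <- t_go + cfg$response_window_s * 1000
        emit(t_end, "omission", sprintf("trial=%d", i))
        emit(t_end, "white_noise_on")
        clock <- t_end + cfg$timeout_s * 1000
      } else {
        ctx <- list(index = i, prev_choice = prev_choice,
                    prev_reward = prev_reward, high_side = high_side)
        choice <- agent$choose(ctx)
        if (choice == "none") {
          outcome <- "omission"
          t_end <- t_go + cfg$response_window_s * 1000
          emit(t_end, "omission", sprintf("trial=%d", i))
          emit(t_end, "white_noise_on")
          clock <- t_end + cfg$timeout_s * 1000
        } else {
          st <- agent$state()
          if (traces) {
            tv <- if (is.null(st)) 0.5 else st$q_push + st$q_pull
            un <- if (is.null(st)) 0.5 else 1 - min(1, abs(st$q_push - st$q_pull))
            pa <- if (!is.null(agent$params)) agent$params else
              list(vigor_gain = 0, latency_gain = 0)
            tr <- make_bandit_trace(choice, tv, un, cfg,
                                    vigor_gain = pa$vigor_gain,
                                    latency_gain = pa$latency_gain)
            det <- detect_choice(tr, cfg$choice_threshold_mm)
            latency <- det$t_cross_ms
            trace_list[[i]] <- tr
          } else {
            latency <- round(stats::runif(1, 250, 2500))
          }
          t_resp <- t_go + latency
          emit(t_resp, paste0("choice_", choice), sprintf("trial=%d", i))
          rewarded <- assign_reward(choice, high_side, cfg)
          if (rewarded) {
            emit(t_resp, "reward", sprintf("volume_ul=%g", volume))
            outcome <- "rewarded"
          } else outcome <- "unrewarded"
          iti <- round(stats::runif(1, cfg$iti_range_s[1] * 1000,
                                    cfg$iti_range_s[2] * 1000))
          emit(t_resp, "iti_start", sprintf("iti_ms=%d", iti))
          clock <- t_resp + iti
          agent$update(choice, as.numeric(rewarded))
          prev_choice <- choice; prev_reward <- as.numeric(rewarded)
        }
      }
    }

    trials[[i]] <- data.frame(
      index = i, block_id = block_id, high_side = high_side,
      volume_ul = volume, cue = "none", choice = choice, outcome = outcome,
      choice_latency_ms = latency,
      trace_ref = if (traces && !is.null(trace_list[[i]])) i else NA_integer_,
      stringsAsFactors = FALSE)

    if (rewarded) {
      rewarded_in_block <- rewarded_in_block + 1L
      if (rewarded_in_block >= block_target) {
        high_side <- other_side(high_side)
        block_id <- block_id + 1L
        emit(clock, "block_reversal",
             sprintf("block=%d;high_side=%s", block_id, high_side))
        block_target <- draw_block_length(cfg$block_geom_p,
                                          cfg$block_min_rewarded)
        rewarded_in_block <- 0L
        if (phase == "volume") volume <- sample(cfg$volumes_ul, 1)
      }
    }
  }
  emit(clock, "session_end")
  new_session("bandit", cfg, do.call(rbind, trials),
              event_log(ev_t, ev_k, ev_p), traces = trace_list,
              seed = if (is.null(seed)) NA else seed,
              agent_label = agent$label)
}

#' Agents for the auditory-motor task
#'
#' An auditory agent maps a cue (`"high"`/`"low"`) to a joystick action and
#' latency. `auditory_agent()` responds with probability `p_respond`,
#' correctly with probability `p_correct`, at a latency drawn uniformly from
#' `latency_range_ms`. `p_correct = 1, p_respond = 1` is the perfect expert.
#'
#' @param p_correct Probability a response matches the cue-action mapping.
#' @param p_respond Probability of responding at all within the window.
#' @param latency_range_ms Response latency range after cue onset.
#' @return List of class `auditory_agent`.
#' @export
auditory_agent <- function(p_correct = 1, p_respond = 1,
                           latency_range_ms = c(300, 1500)) {
  structure(list(
    label = sprintf("auditory(p_correct=%g,p_respond=%g)", p_correct, p_respond),
    respond = function(cue, cfg) {
      if (stats::runif(1) >= p_respond) return(NULL)
      correct_action <- if (cue == "high") cfg$high_tone_action else cfg$low_tone_action
      action <- if (stats::runif(1) < p_correct) correct_action
                else other_side(correct_action)
      list(action = action,
           latency_ms = round(stats::runif(1, latency_range_ms[1],
                                           latency_range_ms[2])))
    }
  ), class = "auditory_agent")
}

#' Simulate one auditory-motor session
#'
#' One single-association phase of the auditory task: a fixed cue each trial
#' (`"low"` -> pull or `"high"` -> push), 2-5 s pretrial interval, 500 ms
#' cue, 5 s response window. A correct displacement within the window
#' triggers reward after 200 ms; a wrong or missing displacement is an
#' omission followed by white noise and a reset intertrial interval. The
#' session halts at `session_max_rewards` rewards or `session_max_min`
#' minutes of simulated time, whichever comes first.
#'
#' @param agent An [auditory_agent()].
#' @param cue `"low"` or `"high"` (the phase's single association).
#' @param cfg An [auditory_config()].
#' @param seed Optional integer seed.
#' @return A `joy_session`; `sum` of reward volumes is in the
#'   `dispensed_ul` attribute of the trial table.
#' @export
run_auditory_session <- function(agent, cue = c("low", "high"),
                                 cfg = auditory_config(), seed = NULL) {
  cue <- match.arg(cue)
  if (!is.null(seed)) set.seed(seed)
  ev_t <- numeric(0); ev_k <- character(0); ev_p <- character(0)
  emit <- function(t, kind, payload = "") {
    ev_t[length(ev_t) + 1L] <<- t
    ev_k[length(ev_k) + 1L] <<- kind
    ev_p[length(ev_p) + 1L] <<- payload
  }
  clock <- 0
  limit_ms <- cfg$session_max_min * 60 * 1000
  emit(clock, "session_start", sprintf("task=auditory;cue=%s", cue))
  trials <- list()
  rewards <- 0L; dispensed <- 0
  i <- 0L
  while (rewards < cfg$session_max_rewards && clock < limit_ms) {
    i <- i + 1L
    iti <- round(stats::runif(1, cfg$iti_range_s[1] * 1000,
                              cfg$iti_range_s[2] * 1000))
    clock <- clock + iti
    emit(clock, "trial_start", sprintf("trial=%d", i))
    emit(clock, "cue_on", sprintf("cue=%s", cue))
    resp <- agent$respond(cue, cfg)
    correct_action <- if (cue == "high") cfg$high_tone_action else cfg$low_tone_action
    window_ms <- cfg$response_window_s * 1000
    if (!is.null(resp) && resp$latency_ms <= window_ms &&
        resp$action == correct_action) {
      t_resp <- clock + resp$latency_ms
      emit(t_resp, paste0("choice_", resp$action), sprintf("trial=%d", i))
      t_rew <- t_resp + cfg$reward_delay_ms
      emit(t_rew, "reward", sprintf("volume_ul=%g", cfg$reward_ul))
      rewards <- rewards + 1L
      dispensed <- dispensed + cfg$reward_ul
      trials[[i]] <- data.frame(index = i, block_id = 1L, high_side = NA,
                                volume_ul = cfg$reward_ul, cue = cue,
                                choice = resp$action, outcome = "rewarded",
                                choice_latency_ms = resp$latency_ms,
                                trace_ref = NA_integer_)
      clock <- t_rew
    } else {
      if (!is.null(resp) && resp$latency_ms <= window_ms) {
        t_resp <- clock + resp$latency_ms
        emit(t_resp, paste0("choice_", resp$action), sprintf("trial=%d", i))
        ch <- resp$action; lat <- resp$latency_ms
        clock <- t_resp
      } else {
        ch <- "none"; lat <- NA_real_
        clock <- clock + window_ms
      }
      emit(clock, "omission", sprintf("trial=%d", i))
      emit(clock, "white_noise_on")
      clock <- clock + cfg$noise_on_omission_s * 1000
      trials[[i]] <- data.frame(index = i, block_id = 1L, high_side = NA,
                                volume_ul = 0, cue = cue, choice = ch,
                                outcome = "omission",
                                choice_latency_ms = lat,
                                trace_ref = NA_integer_)
    }
  }
  emit(clock, "session_end", sprintf("rewards=%d;dispensed_ul=%g",
                                     rewards, dispensed))
  tr <- if (length(trials)) do.call(rbind, trials) else
    data.frame(index = integer(), block_id = integer(), high_side = logical(),
               volume_ul = numeric(), cue = character(), choice = character(),
               outcome = character(), choice_latency_ms = numeric(),
               trace_ref = integer())
  attr(tr, "dispensed_ul") <- dispensed
  new_session("auditory", cfg, tr, event_log(ev_t, ev_k, ev_p),
              seed = if (is.null(seed)) NA else seed,
              agent_label = agent$label)
}

#' Simulate a full auditory training day
#'
#' A daily run executes the two single-association phases (low tone -> pull,
#' high tone -> push) back to back, with the phase order alternating by day
#' parity. An expert animal completes both phases to the 100-reward cap, for
#' 200 correct trials and 2 ml of water.
#'
#' @param agent An [auditory_agent()].
#' @param day Day number (odd days start with the low-tone phase).
#' @param cfg An [auditory_config()].
#' @param seed Optional integer seed.
#' @return List with `sessions` (both phases) and `dispensed_ml`.
#' @export
run_auditory_day <- function(agent, day = 1, cfg = auditory_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  order <- if (day %% 2 == 1) c("low", "high") else c("high", "low")
  sessions <- lapply(order, function(cue)
    run_auditory_session(agent, cue = cue, cfg = cfg))
  names(sessions) <- order
  dispensed <- sum(vapply(sessions, function(s)
    attr(s$trials, "dispensed_ul"), 0))
  list(sessions = sessions, dispensed_ml = dispensed / 1000)
}

# ---- cue tones -------------------------------------------------------------

#' Synthesize a cue tone with overtones
#'
#' Sum of sinusoids at `k * fundamental_hz`, `k = 1 .. n_overtones + 1`, with
#' harmonic amplitudes `1/k`, peak-normalized to unit amplitude. Harmonics at
#' or above the Nyquist frequency are dropped with a warning.
#'
#' @param fundamental_hz Fundamental frequency (e.g. 5000 or 12000).
#' @param n_overtones Number of overtones above the fundamental (default 5).
#' @param dur_ms Duration (default 500 ms).
#' @param sample_rate_hz Sampling rate (default 96000).
#' @return List of class `joy_tone` with `samples` and `sample_rate_hz`.
#' @export
synthesize_tone <- function(fundamental_hz, n_overtones = 5, dur_ms = 500,
                            sample_rate_hz = 96000) {
  if (fundamental_hz <= 0) stop("fundamental frequency must be positive")
  k <- seq_len(n_overtones + 1)
  keep <- k * fundamental_hz < sample_rate_hz / 2
  if (!all(keep)) {
    warning(sprintf("%d harmonic(s) at/above Nyquist (%g Hz) dropped",
                    sum(!keep), sample_rate_hz / 2))
    k <- k[keep]
  }
  n <- round(dur_ms / 1000 * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  w <- rowSums(vapply(k, function(kk)
    sin(2 * pi * kk * fundamental_hz * t) / kk, numeric(n)))
  w <- w / max(abs(w))
  structure(list(samples = w, sample_rate_hz = sample_rate_hz,
                 fundamental_hz = fundamental_hz, harmonics = k),
            class = "joy_tone")
}

#' Frequency of the lowest spectral peak of a tone
#'
#' Magnitude spectrum via FFT; a peak is a local maximum exceeding 5% of the
#' spectral maximum. Returns the frequency (Hz) of the lowest-frequency peak.
#'
#' @param tone A `joy_tone` (or list with `samples` and `sample_rate_hz`).
#' @return Frequency in Hz.
#' @export
lowest_spectral_peak <- function(tone) {
  w <- tone$samples
  n <- length(w)
  mag <- Mod(stats::fft(w))[seq_len(floor(n / 2))]
  freq <- (seq_len(floor(n / 2)) - 1) * tone$sample_rate_hz / n
  thr <- 0.05 * max(mag)
  is_peak <- c(FALSE, mag[2:(length(mag) - 1)] > mag[1:(length(mag) - 2)] &
                 mag[2:(length(mag) - 1)] >= mag[3:length(mag)], FALSE) &
    mag > thr
  if (!any(is_peak)) stop("no spectral peak found")
  freq[which(is_peak)[1]]
}

#' Write a tone as a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/WAVE writer for exporting synthesized cue tones.
#'
#' @param tone A `joy_tone`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(tone, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, tone$samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  rate <- as.integer(tone$sample_rate_hz)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
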