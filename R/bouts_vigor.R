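# Movement-bout segmentation of anteroposterior traces and per-trial
# vigor/kinematic readouts.
#
# Bout criteria: (1) movement in one direction, (2) initiation speed
# > 7.5 mm/s, (3) speed maintained > 2.5 mm/s for > 50 ms, (4) the bout ends
# with a velocity sign change or joystick retraction.

#' Signed velocity of an anteroposterior trace
#'
#' Central finite difference of the anteroposterior (x) position, one-sided
#' at the endpoints, on the trace's own time base; mm/s. The trace should be
#' smoothed ([moving_average()], 20 ms) and re-baselined first so the
#' segmentation thresholds are meaningful.
#'
#' @param trace A [position_trace()].
#' @return Numeric vector of signed velocities (mm/s), same length as the
#'   trace.
#' @export
velocity_trace <- function(trace) {
  n <- nrow(trace)
  if (n < 3) stop("velocity_trace needs at least 3 samples")
  x <- trace$x_mm; t <- trace$t_ms
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  mid <- 2:(n - 1)
  v[mid] <- (x[mid + 1] - x[mid - 1]) / (t[mid + 1] - t[mid - 1])
  v * 1000
}

#' Segment a velocity sequence into movement bouts
#'
#' A bout opens at the first sample with `|v| > init_thresh` (its direction
#' is the velocity sign), stays open while `|v| > sustain_thresh` with
#' unchanged sign, and closes at a sign change, at `|v| <= sustain_thresh`,
#' or at joystick retraction. Candidate episodes that fail to sustain
#' `|v| > sustain_thresh` for more than `sustain_ms` are discarded. A sign
#' change that closes a bout immediately opens an opposite bout when the new
#' `|v|` already exceeds `init_thresh`. Thresholds are strict inequalities.
#'
#' @param v Signed velocity sequence, mm/s (from [velocity_trace()]).
#' @param t_ms Sample times matching `v`.
#' @param retract_t_ms Optional joystick-retraction time: segmentation stops
#'   there.
#' @param init_thresh Initiation speed threshold (default 7.5 mm/s).
#' @param sustain_thresh Sustain speed floor (default 2.5 mm/s).
#' @param sustain_ms Minimum time above the sustain floor (default 50 ms).
#' @param x_mm Optional position sequence; when given, each bout's
#'   displacement is `x[end] - x[start]`.
#' @return Data frame of class `bout_table`: `t_start_ms`, `t_end_ms`,
#'   `direction`, `peak_speed_mm_s`, `displacement_mm`. Zero rows when no
#'   bout qualifies.
#' @export
segment_bouts <- function(v, t_ms, retract_t_ms = NULL,
                          init_thresh = 7.5, sustain_thresh = 2.5,
                          sustain_ms = 50, x_mm = NULL) {
  stopifnot(length(v) == length(t_ms))
  if (!is.null(retract_t_ms)) {
    keep <- t_ms <= retract_t_ms
    v <- v[keep]; t_ms <- t_ms[keep]
    if (!is.null(x_mm)) x_mm <- x_mm[keep]
  }
  n <- length(v)
  res <- list()
  i <- 1L
  while (i <= n) {
    if (abs(v[i]) > init_thresh) {
      sgn <- sign(v[i])
      j <- i
      while (j < n && abs(v[j + 1]) > sustain_thresh && sign(v[j + 1]) == sgn)
        j <- j + 1L
      if (t_ms[j] - t_ms[i] > sustain_ms) {
        res[[length(res) + 1L]] <- data.frame(
          t_start_ms = t_ms[i], t_end_ms = t_ms[j],
          direction = if (sgn > 0) "push" else "pull",
          peak_speed_mm_s = max(abs(v[i:j])),
          displacement_mm = if (is.null(x_mm)) sum(v[i:j]) * mean(diff(t_ms)) / 1000
                            else x_mm[j] - x_mm[i])
      }
      # resume at the sample after the episode; a sign change with
      # supra-initiation |v| opens the next bout on its own at j + 1
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(t_start_ms = numeric(), t_end_ms = numeric(),
               direction = character(), peak_speed_mm_s = numeric(),
               displacement_mm = numeric())
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Segment a position trace into movement bouts
#'
#' Convenience wrapper: 20 ms moving average, re-baseline, central-difference
#' velocity, then [segment_bouts()].
#'
#' @param trace A raw [position_trace()].
#' @param smooth_ms Moving-average window (default 20 ms; 0 to skip).
#' @param rebaseline_ms Baseline window (default 50 ms; 0 to skip).
#' @inheritParams segment_bouts
#' @return A `bout_table`.
#' @export
segment_trace_bouts <- function(trace, smooth_ms = 20, rebaseline_ms = 50,
                                retract_t_ms = NULL, init_thresh = 7.5,
                                sustain_thresh = 2.5, sustain_ms = 50) {
  if (smooth_ms > 0) trace <- moving_average(trace, smooth_ms)
  if (rebaseline_ms > 0) trace <- rebaseline(trace, rebaseline_ms)
  segment_bouts(velocity_trace(trace), trace$t_ms, retract_t_ms = retract_t_ms,
                init_thresh = init_thresh, sustain_thresh = sustain_thresh,
                sustain_ms = sustain_ms, x_mm = trace$x_mm)
}

#' Directional consistency of a trial's bouts
#'
#' Proportion of bouts occurring in the trial's most frequent direction:
#' `n(bouts in most frequent direction) / n(all bouts)`. 1 means all bouts
#' share one direction; with at least one bout the value is always in
#' `[0.5, 1]`.
#'
#' @param bouts A `bout_table` (or data frame with a `direction` column).
#' @return Proportion in `[0.5, 1]`; `NA` with a warning for zero bouts.
#' @export
directional_consistency <- function(bouts) {
  n <- nrow(bouts)
  if (n == 0) {
    warning("directional consistency undefined with zero bouts")
    return(NA_real_)
  }
  max(table(bouts$direction)) / n
}

#' Per-trial vigor and kinematic readouts
#'
#' Computes the trial-level readouts from a (smoothed, re-baselined)
#' anteroposterior trace and its segmented bouts:
#' * `peak_displacement_mm` — maximum `|x|` away from baseline;
#' * `path_length_mm` — total distance travelled in any direction
#'   (`sum |dx|`);
#' * `n_bouts` and `directional_consistency`;
#' * `decisive_mean_velocity_mm_s` — mean `|v|` within the decisive bout,
#'   the bout whose span contains the choice-threshold crossing (when the
#'   crossing falls outside every bout, the nearest preceding bout is used
#'   and `decisive_fallback` is flagged);
#' * `choice_latency_ms` — `t_choice - t_go`.
#'
#' @param trace Smoothed, re-baselined [position_trace()].
#' @param bouts A `bout_table` from [segment_bouts()].
#' @param t_go GO-cue time on the trace's time base.
#' @param t_choice Threshold-crossing time (from [detect_choice()]).
#' @return One-row data frame of class `trial_kinematics`.
#' @export
trial_vigor_metrics <- function(trace, bouts, t_go, t_choice) {
  v <- velocity_trace(trace)
  peak <- max(abs(trace$x_mm))
  path <- sum(abs(diff(trace$x_mm)))
  nb <- nrow(bouts)
  dc <- if (nb > 0) directional_consistency(bouts) else NA_real_
  dec_vel <- NA_real_; fallback <- FALSE; dec_idx <- NA_integer_
  if (nb > 0 && !is.na(t_choice)) {
    inside <- which(bouts$t_start_ms <= t_choice & bouts$t_end_ms >= t_choice)
    if (length(inside) > 0) {
      dec_idx <- inside[1]
    } else {
      prior <- which(bouts$t_end_ms < t_choice)
      if (length(prior) > 0) {
        dec_idx <- prior[length(prior)]
        fallback <- TRUE
      }
    }
    if (!is.na(dec_idx)) {
      span <- trace$t_ms >= bouts$t_start_ms[dec_idx] &
        trace$t_ms <= bouts$t_end_ms[dec_idx]
      dec_vel <- mean(abs(v[span]))
    }
  }
  out <- data.frame(peak_displacement_mm = peak, n_bouts = nb,
                    directional_consistency = dc,
                    decisive_mean_velocity_mm_s = dec_vel,
                    path_length_mm = path,
                    choice_latency_ms = if (is.na(t_choice)) NA_real_
                                        else t_choice - t_go,
                    decisive_bout = dec_idx, decisive_fallback = fallback)
  class(out) <- c("trial_kinematics", "data.frame")
  out
}

#' Bout and vigor analysis of a whole bandit session
#'
#' Runs smoothing, re-baselining, choice detection, bout segmentation and
#' [trial_vigor_metrics()] on every traced trial of a session simulated with
#' `traces = TRUE`.
#'
#' @param session A `joy_session` from [run_bandit_session()].
#' @param smooth_ms,rebaseline_ms Preprocessing windows (0 to skip).
#' @return List with `trials` (per-trial kinematics joined to the trial
#'   table) and `bouts` (all bouts, with a `trial` column).
#' @export
session_vigor_analysis <- function(session, smooth_ms = 20, rebaseline_ms = 50) {
  idx <- which(!is.na(session$trials$trace_ref))
  if (length(idx) == 0) stop("session has no traces; simulate with traces = TRUE")
  per_trial <- list(); all_bouts <- list()
  for (i in idx) {
    tr <- session$traces[[session$trials$trace_ref[i]]]
    if (smooth_ms > 0) tr <- moving_average(tr, smooth_ms)
    if (rebaseline_ms > 0) tr <- rebaseline(tr, rebaseline_ms)
    det <- detect_choice(tr, session$config$choice_threshold_mm)
    bouts <- segment_bouts(velocity_trace(tr), tr$t_ms, x_mm = tr$x_mm)
    m <- trial_vigor_metrics(tr, bouts, t_go = tr$t_ms[1],
                             t_choice = det$t_cross_ms)
    m$index <- session$trials$index[i]
    per_trial[[length(per_trial) + 1L]] <- m
    if (nrow(bouts)) {
      bouts$trial <- session$trials$index[i]
      all_bouts[[length(all_bouts) + 1L]] <- bouts
    }
  }
  kin <- do.call(rbind, per_trial)
  # the trace-derived latency supersedes the engine's copy
  base <- session$trials[setdiff(names(session$trials), "choice_latency_ms")]
  trials <- merge(base, kin, by = "index", all.x = FALSE)
  list(trials = trials[order(trials$index), ],
       bouts = if (length(all_bouts)) do.call(rbind, all_bouts) else NULL)
}
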