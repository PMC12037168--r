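# Joystick signal I/O: ADC calibration, smoothing, re-baselining, threshold
# choice detection, and plain-text trace / event-log serialization.
#
# Coordinate convention used throughout the package:
#   +x = anterior (push), -x = posterior (pull), +y = upward.
# Times are integer-valued milliseconds unless stated otherwise.

#' Construct a joystick position trace
#'
#' A `position_trace` is the package-wide container for time-stamped joystick
#' samples: a data frame with columns `t_ms`, `x_mm`, `y_mm` and optional
#' baseline attributes. The x axis is anteroposterior (positive = anterior =
#' push), the y axis dorsoventral (positive = up).
#'
#' @param t_ms Strictly increasing sample times in milliseconds.
#' @param x_mm Anteroposterior position in millimeters.
#' @param y_mm Dorsoventral position in millimeters (defaults to zeros for
#'   traces constrained to the anteroposterior axis).
#' @param baseline_x,baseline_y Baseline position in mm (recorded by
#'   [rebaseline()]).
#' @return A data frame of class `position_trace`.
#' @export
position_trace <- function(t_ms, x_mm, y_mm = rep(0, length(t_ms)),
                           baseline_x = 0, baseline_y = 0) {
  t_ms <- as.numeric(t_ms)
  if (length(x_mm) != length(t_ms) || length(y_mm) != length(t_ms))
    stop("t_ms, x_mm and y_mm must have equal lengths")
  if (length(t_ms) > 1 && any(diff(t_ms) <= 0))
    stop("sample times must be strictly increasing")
  out <- data.frame(t_ms = t_ms, x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm))
  attr(out, "baseline_x") <- baseline_x
  attr(out, "baseline_y") <- baseline_y
  class(out) <- c("position_trace", "data.frame")
  out
}

#' @export
print.position_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<position_trace> %d samples, %.0f-%.0f ms, x range [%.2f, %.2f] mm\n",
              n, if (n) x$t_ms[1] else NA, if (n) x$t_ms[n] else NA,
              if (n) min(x$x_mm) else NA, if (n) max(x$x_mm) else NA))
  invisible(x)
}

#' Box calibration for the 10-bit joystick ADC
#'
#' The acquisition hardware digitizes each potentiometer axis with a 10-bit
#' ADC mapping 0-5 V onto integer codes 0-1023. Displacement in millimeters
#' is recovered per box by a linear calibration around the joystick's center
#' code (the resting position reads near the middle of the code range; the
#' midpoint 512 is the default and can be overridden per box).
#'
#' @param box_id Label of the behavior box the calibration belongs to.
#' @param slope_x,slope_y Millimeters per ADC count.
#' @param offset_x,offset_y Additive offset in mm after centering.
#' @param center_x,center_y ADC code of the joystick resting position.
#' @param adc_full_scale_volts Full-scale ADC voltage (default 5 V).
#' @param adc_max_code Largest ADC code (default 1023).
#' @return An object of class `joy_calibration`.
#' @export
calibration <- function(box_id = "box0", slope_x = 0.1, slope_y = 0.1,
                        offset_x = 0, offset_y = 0,
                        center_x = 512, center_y = 512,
                        adc_full_scale_volts = 5.0, adc_max_code = 1023L) {
  if (!is.finite(slope_x) || !is.finite(slope_y) || slope_x == 0 || slope_y == 0)
    stop("calibration slopes must be finite and nonzero")
  if (adc_max_code < 1) stop("adc_max_code must be >= 1")
  structure(list(box_id = box_id, slope_x = slope_x, slope_y = slope_y,
                 offset_x = offset_x, offset_y = offset_y,
                 center_x = center_x, center_y = center_y,
                 adc_full_scale_volts = adc_full_scale_volts,
                 adc_max_code = as.integer(adc_max_code)),
            class = "joy_calibration")
}

#' @export
print.joy_calibration <- function(x, ...) {
  cat(sprintf("<joy_calibration> box %s: slope (%.4g, %.4g) mm/count, center (%g, %g), %g V / %d codes\n",
              x$box_id, x$slope_x, x$slope_y, x$center_x, x$center_y,
              x$adc_full_scale_volts, x$adc_max_code))
  invisible(x)
}

#' Convert ADC codes to volts
#'
#' Linear code-to-voltage map, exact at the endpoints: code 0 reads 0 V and
#' code `adc_max_code` reads `adc_full_scale_volts`.
#'
#' @param code Integer ADC codes.
#' @param cal A [calibration()] object.
#' @return Voltages, same length as `code`.
#' @export
adc_to_volts <- function(code, cal = calibration()) {
  if (any(code < 0 | code > cal$adc_max_code))
    stop("ADC code outside [0, ", cal$adc_max_code, "]")
  cal$adc_full_scale_volts * code / cal$adc_max_code
}

#' Calibrate raw ADC samples to a millimeter position trace
#'
#' Applies the per-box linear calibration `x = slope_x * (x_code - center_x)
#' + offset_x` (and analogously for y) to a stream of raw joystick samples.
#'
#' @param samples Data frame with columns `t_ms`, `x_code`, `y_code`.
#' @param cal A [calibration()] object.
#' @return A [position_trace()] in millimeters; times preserved.
#' @export
adc_to_mm <- function(samples, cal = calibration()) {
  need <- c("t_ms", "x_code", "y_code")
  if (!all(need %in% names(samples)))
    stop("samples must have columns t_ms, x_code, y_code")
  bad <- samples$x_code < 0 | samples$x_code > cal$adc_max_code |
    samples$y_code < 0 | samples$y_code > cal$adc_max_code
  if (any(bad))
    stop(sprintf("ADC code outside [0, %d] at sample %d",
                 cal$adc_max_code, which(bad)[1]))
  position_trace(samples$t_ms,
                 cal$slope_x * (samples$x_code - cal$center_x) + cal$offset_x,
                 cal$slope_y * (samples$y_code - cal$center_y) + cal$offset_y)
}

#' Trailing moving average of a position trace
#'
#' Causal smoothing as performed in real time on the acquisition controller:
#' each output sample is the mean of all input samples within the trailing
#' `window_ms` window (samples with `t` in `(t_i - window_ms, t_i]`). The
#' time base is unchanged. The default 20 ms window suppresses single-sample
#' electrical glitches at 1 kHz sampling.
#'
#' @param trace A [position_trace()].
#' @param window_ms Window length in ms; must cover at least one sample
#'   interval.
#' @return Smoothed [position_trace()].
#' @export
moving_average <- function(trace, window_ms = 20) {
  n <- nrow(trace)
  if (n == 0) return(trace)
  if (n > 1 && window_ms < min(diff(trace$t_ms)))
    stop("window_ms shorter than the sampling interval")
  t <- trace$t_ms
  # for each i, first index j with t[j] > t[i] - window
  lo <- findInterval(t - window_ms, t) + 1L
  cx <- c(0, cumsum(trace$x_mm)); cy <- c(0, cumsum(trace$y_mm))
  idx <- seq_len(n)
  nwin <- idx - lo + 1L
  out <- position_trace(t, (cx[idx + 1L] - cx[lo]) / nwin,
                        (cy[idx + 1L] - cy[lo]) / nwin)
  attr(out, "baseline_x") <- attr(trace, "baseline_x")
  attr(out, "baseline_y") <- attr(trace, "baseline_y")
  out
}

#' Re-baseline a trace against its initial rest position
#'
#' When the joystick is (re-)extended at trial start a fresh baseline is
#' estimated to absorb slow drift: the mean position over the first
#' `baseline_window_ms` of the trace. Positions are returned as displacement
#' from that baseline, which is recorded in the `baseline_x`/`baseline_y`
#' attributes.
#'
#' @param trace A [position_trace()] beginning at/after joystick extension.
#' @param baseline_window_ms Baseline estimation window (default 50 ms).
#' @return Displacement [position_trace()].
#' @export
rebaseline <- function(trace, baseline_window_ms = 50) {
  if (nrow(trace) == 0) return(trace)
  t0 <- trace$t_ms[1]
  in_win <- trace$t_ms < t0 + baseline_window_ms
  if (all(in_win) && trace$t_ms[nrow(trace)] - t0 < baseline_window_ms)
    warning("trace shorter than baseline window; using all samples")
  bx <- mean(trace$x_mm[in_win]); by <- mean(trace$y_mm[in_win])
  position_trace(trace$t_ms, trace$x_mm - bx, trace$y_mm - by,
                 baseline_x = bx, baseline_y = by)
}

#' Detect a threshold-crossing choice on the anteroposterior axis
#'
#' Anteroposterior deviations strictly greater than `threshold_mm` from
#' baseline register as choices: the first sample with `x > +threshold` is a
#' push, the first with `x < -threshold` a pull, whichever comes first.
#' Samples after the first crossing are irrelevant.
#'
#' @param trace A re-baselined [position_trace()].
#' @param threshold_mm Choice threshold in mm (default 3, the value-task
#'   setting; the auditory task's threshold is rig-specific and must be
#'   supplied explicitly there).
#' @return List with `direction` (`"push"`, `"pull"` or `"none"`) and
#'   `t_cross_ms` (`NA` when never crossed).
#' @export
detect_choice <- function(trace, threshold_mm = 3) {
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  hit <- which(trace$x_mm > threshold_mm | trace$x_mm < -threshold_mm)
  if (length(hit) == 0)
    return(list(direction = "none", t_cross_ms = NA_real_))
  i <- hit[1]
  list(direction = if (trace$x_mm[i] > 0) "push" else "pull",
       t_cross_ms = trace$t_ms[i])
}

# ---- trace CSV -------------------------------------------------------------

#' Read / write a trace CSV
#'
#' Traces are exchanged as plain CSV with header `t_ms,x_mm,y_mm`
#' (calibrated) or `t_ms,x_code,y_code` (raw ADC). Raw files require a
#' calibration to convert to millimeters.
#'
#' @param path File path.
#' @param cal Optional [calibration()] applied when the file holds raw codes.
#' @return A [position_trace()].
#' @export
read_trace_csv <- function(path, cal = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("x_mm", "y_mm") %in% names(df)))
    return(position_trace(df$t_ms, df$x_mm, df$y_mm))
  if (all(c("x_code", "y_code") %in% names(df))) {
    if (is.null(cal)) stop("raw ADC trace file requires a calibration")
    return(adc_to_mm(df, cal))
  }
  stop("trace CSV must have columns t_ms,x_mm,y_mm or t_ms,x_code,y_code")
}

#' @rdname read_trace_csv
#' @param trace A [position_trace()] to write.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("t_ms", "x_mm", "y_mm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- event logs ------------------------------------------------------------

#' Closed vocabulary of task event kinds
#' @return Character vector of admissible `kind` values.
#' @export
event_kinds <- function() {
  c("session_start", "trial_start", "joystick_extend", "joystick_retract",
    "cue_on", "go_cue", "choice_push", "choice_pull", "reward", "omission",
    "premature", "white_noise_on", "lick", "iti_start", "block_reversal",
    "session_end")
}

#' Construct an event log
#'
#' Ordered timestamped task events with an optional `key=value;...` payload,
#' the in-memory form of the tab-separated session event file.
#'
#' @param t_ms Non-decreasing event times (ms).
#' @param kind Event kinds from [event_kinds()].
#' @param payload Character payloads, `"key=value;key=value"` or `""`.
#' @return Data frame of class `event_log`.
#' @export
event_log <- function(t_ms = numeric(), kind = character(),
                      payload = character(length(t_ms))) {
  if (length(kind) != length(t_ms) || length(payload) != length(t_ms))
    stop("t_ms, kind and payload must have equal lengths")
  bad <- !(kind %in% event_kinds())
  if (any(bad))
    stop("unknown event kind: ", kind[which(bad)[1]])
  if (length(t_ms) > 1 && any(diff(t_ms) < 0))
    stop("event times must be non-decreasing")
  out <- data.frame(t_ms = as.numeric(t_ms), kind = kind,
                    payload = as.character(payload),
                    stringsAsFactors = FALSE)
  class(out) <- c("event_log", "data.frame")
  out
}

#' Read / write a task event log
#'
#' Event logs are tab-separated text, one event per line:
#' `t_ms<TAB>kind<TAB>key=value;...` (the payload field may be empty but is
#' always present). Writing then reading reproduces the log exactly; the
#' serialization is canonical and byte-stable.
#'
#' @param path File path.
#' @return An [event_log()].
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(event_log())
  # sentinel keeps a trailing empty payload field from being dropped
  parts <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) { p[length(p)] <- sub("\x01$", "", p[length(p)]); p })
  nf <- lengths(parts)
  if (any(nf != 3))
    stop(sprintf("malformed event line %d: expected 3 tab-separated fields",
                 which(nf != 3)[1]))
  t_ms <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  if (anyNA(t_ms))
    stop(sprintf("malformed event line %d: non-numeric time", which(is.na(t_ms))[1]))
  kind <- vapply(parts, `[[`, "", 2)
  bad <- !(kind %in% event_kinds())
  if (any(bad))
    stop(sprintf("unknown event kind '%s' at line %d", kind[which(bad)[1]],
                 which(bad)[1]))
  if (any(diff(t_ms) < 0))
    stop(sprintf("non-monotone event time at line %d", which(diff(t_ms) < 0)[1] + 1))
  event_log(t_ms, kind, vapply(parts, `[[`, "", 3))
}

#' @rdname read_event_log
#' @param log An [event_log()] to write.
#' @export
write_event_log <- function(log, path) {
  fmt_t <- ifelse(log$t_ms == round(log$t_ms),
                  sprintf("%d", as.integer(round(log$t_ms))),
                  sprintf("%g", log$t_ms))
  writeLines(paste(fmt_t, log$kind, log$payload, sep = "\t"), path)
  invisible(path)
}

#' Read / write a box calibration file
#'
#' Calibrations are stored either as JSON or as flat `key=value` text with
#' one field per line.
#'
#' @param path File path (`.json` for JSON, anything else for key=value).
#' @return A [calibration()].
#' @export
read_calibration <- function(path) {
  if (grepl("\\.json$", path)) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    v <- stats::setNames(lapply(kv, function(p) {
      val <- trimws(p[2])
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }), trimws(vapply(kv, `[[`, "", 1)))
  }
  do.call(calibration, v[names(v) %in% names(formals(calibration))])
}

#' @rdname read_calibration
#' @param cal A [calibration()] to write.
#' @export
write_calibration <- function(cal, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  } else {
    writeLines(paste0(names(cal), "=", vapply(cal, as.character, "")), path)
  }
  invisible(path)
}
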