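# Orchestration: simulate -> analyze -> report workflows with explicit
# seeding and a reproducibility manifest.

#' Build a run configuration
#'
#' @param task `"bandit"` or `"auditory"`.
#' @param agent Agent specification: `"q"`, `"wsls"`, `"oracle"`, `"random"`
#'   (bandit) or `"perfect"`/`"noisy"` (auditory).
#' @param alpha,beta Q-agent parameters (when `agent = "q"`).
#' @param vigor_gain,latency_gain Q-agent vigor coupling.
#' @param n_trials Trials per bandit session.
#' @param n_sessions Number of sessions.
#' @param phase Bandit phase (`"reversal"`/`"volume"`).
#' @param traces Simulate per-trial traces (bandit only)?
#' @param seed Master seed; session `i` runs under `seed + i - 1`.
#' @param analyses Character subset of `c("kinematics", "bouts", "qfit",
#'   "value")` to run after simulation.
#' @return List of class `run_config`.
#' @export
run_config <- function(task = c("bandit", "auditory"), agent = "q",
                       alpha = 0.5, beta = 3, vigor_gain = 0,
                       latency_gain = 0, n_trials = 500, n_sessions = 1,
                       phase = "reversal", traces = TRUE, seed = 1,
                       analyses = c("bouts", "qfit", "value")) {
  task <- match.arg(task)
  structure(as.list(environment()), class = "run_config")
}

make_agent <- function(cfg) {
  switch(cfg$agent,
         q = agent_q(q_agent_params(cfg$alpha, cfg$beta,
                                    vigor_gain = cfg$vigor_gain,
                                    latency_gain = cfg$latency_gain)),
         wsls = agent_wsls(),
         oracle = agent_oracle(),
         random = agent_random(),
         stop("unknown bandit agent: ", cfg$agent))
}

#' Run a simulate-analyze-report experiment
#'
#' Simulates the configured sessions, runs the requested analyses, and
#' writes an artifact bundle under `out_dir`: session event logs (TSV),
#' trial tables (CSV), per-trial trace CSVs, bout/kinematics CSVs, Q-model
#' fits (JSON + per-trial Q CSV), and a `manifest.json` recording the
#' configuration, seeds and package version — every output is reproducible
#' from the manifest. On a partial failure the completed artifacts are kept
#' and the manifest marks the failed stage.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("joykin")),
                   seeds = cfg$seed + seq_len(cfg$n_sessions) - 1,
                   status = "running", failed_stage = NULL,
                   artifacts = character(0))
  add <- function(path) manifest$artifacts <<- c(manifest$artifacts, basename(path))
  stage <- "simulate"
  ok <- try({
    for (s in seq_len(cfg$n_sessions)) {
      seed_s <- cfg$seed + s - 1
      if (cfg$task == "bandit") {
        ses <- run_bandit_session(make_agent(cfg), n_trials = cfg$n_trials,
                                  phase = cfg$phase, seed = seed_s,
                                  traces = cfg$traces)
      } else {
        ses <- run_auditory_session(auditory_agent(), seed = seed_s)
      }
      tag <- sprintf("session%02d", s)
      write_event_log(ses$events, file.path(out_dir, paste0(tag, "_events.tsv")))
      add(paste0(tag, "_events.tsv"))
      utils::write.csv(ses$trials, file.path(out_dir, paste0(tag, "_trials.csv")),
                       row.names = FALSE)
      add(paste0(tag, "_trials.csv"))

      if (cfg$task == "bandit" && cfg$traces && "bouts" %in% cfg$analyses) {
        stage <- "bouts"
        va <- session_vigor_analysis(ses)
        utils::write.csv(va$trials,
                         file.path(out_dir, paste0(tag, "_trial_kinematics.csv")),
                         row.names = FALSE)
        add(paste0(tag, "_trial_kinematics.csv"))
        if (!is.null(va$bouts)) {
          utils::write.csv(va$bouts, file.path(out_dir, paste0(tag, "_bouts.csv")),
                           row.names = FALSE)
          add(paste0(tag, "_bouts.csv"))
        }
      } else va <- NULL

      if (cfg$task == "bandit" && "qfit" %in% cfg$analyses) {
        stage <- "qfit"
        series <- as_choice_series(ses, kinematics = va)
        fit <- fit_q_model(series)
        jsonlite::write_json(
          list(alpha_hat = fit$alpha_hat, beta_hat = fit$beta_hat,
               neg_log_likelihood = fit$neg_log_likelihood,
               n_trials = fit$n_trials),
          file.path(out_dir, paste0(tag, "_fit.json")),
          auto_unbox = TRUE, digits = NA)
        add(paste0(tag, "_fit.json"))
        utils::write.csv(data.frame(trial = seq_along(fit$q_push),
                                    q_push = fit$q_push, q_pull = fit$q_pull,
                                    delta_q = fit$delta_q),
                         file.path(out_dir, paste0(tag, "_qtraj.csv")),
                         row.names = FALSE)
        add(paste0(tag, "_qtraj.csv"))

        if (!is.null(va) && "value" %in% cfg$analyses) {
          stage <- "value"
          vs <- vigor_by_value_summary(series, split = uncertainty_split(fit),
                                       reps = 0)
          if (!is.null(vs$uncertainty_contrasts)) {
            utils::write.csv(vs$uncertainty_contrasts,
                             file.path(out_dir, paste0(tag, "_uncertainty.csv")),
                             row.names = FALSE)
            add(paste0(tag, "_uncertainty.csv"))
          }
        }
      }
    }
    TRUE
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- as.character(ok)
  } else manifest$status <- "complete"
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Summarize an experiment bundle
#'
#' Reads the artifacts written by [run_experiment()] and assembles summary
#' tables: per-session outcome counts, per-session kinematics medians, and
#' fitted Q parameters. Missing inputs are reported as named omissions, not
#' errors; re-running the report on the same bundle is idempotent.
#'
#' @param out_dir Bundle directory.
#' @return List of class `experiment_report` with `sessions`, `kinematics`,
#'   `fits`, and `omissions`.
#' @export
report_experiment <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  omissions <- character(0)
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  else {
    omissions <- c(omissions, "manifest.json")
    NULL
  }
  trial_files <- sort(list.files(out_dir, "_trials\\.csv$", full.names = TRUE))
  sessions <- if (length(trial_files)) do.call(rbind, lapply(trial_files, function(f) {
    tr <- utils::read.csv(f)
    data.frame(session = sub("_trials\\.csv$", "", basename(f)),
               n_trials = nrow(tr),
               rewarded = sum(tr$outcome == "rewarded"),
               unrewarded = sum(tr$outcome == "unrewarded"),
               omission = sum(tr$outcome == "omission"),
               premature = sum(tr$outcome == "premature"),
               n_blocks = length(unique(tr$block_id)))
  })) else {
    omissions <- c(omissions, "session trial tables")
    data.frame(session = character(0))
  }
  kin_files <- sort(list.files(out_dir, "_trial_kinematics\\.csv$", full.names = TRUE))
  kinematics <- if (length(kin_files)) do.call(rbind, lapply(kin_files, function(f) {
    k <- utils::read.csv(f)
    data.frame(session = sub("_trial_kinematics\\.csv$", "", basename(f)),
               median_peak_displacement_mm = stats::median(k$peak_displacement_mm, na.rm = TRUE),
               median_n_bouts = stats::median(k$n_bouts, na.rm = TRUE),
               median_path_length_mm = stats::median(k$path_length_mm, na.rm = TRUE),
               median_latency_ms = stats::median(k$choice_latency_ms, na.rm = TRUE))
  })) else {
    omissions <- c(omissions, "trial kinematics")
    NULL
  }
  fit_files <- sort(list.files(out_dir, "_fit\\.json$", full.names = TRUE))
  fits <- if (length(fit_files)) do.call(rbind, lapply(fit_files, function(f) {
    j <- jsonlite::read_json(f, simplifyVector = TRUE)
    data.frame(session = sub("_fit\\.json$", "", basename(f)),
               alpha_hat = j$alpha_hat, beta_hat = j$beta_hat,
               nll = j$neg_log_likelihood)
  })) else {
    omissions <- c(omissions, "Q-model fits")
    NULL
  }
  structure(list(manifest = manifest, sessions = sessions,
                 kinematics = kinematics, fits = fits, omissions = omissions),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (nrow(x$sessions) == 0) cat("  no data\n") else {
    cat("  sessions:\n")
    print(x$sessions, row.names = FALSE)
  }
  if (!is.null(x$fits)) { cat("  fits:\n"); print(x$fits, row.names = FALSE) }
  if (length(x$omissions))
    cat("  omitted inputs:", paste(x$omissions, collapse = ", "), "\n")
  invisible(x)
}

#' Occupancy heatmap of an explored-area grid
#'
#' Optional ggplot2 rendering of the visit-count grid from
#' [explored_area()].
#'
#' @param grid Visit-count matrix.
#' @param ws The [workspace()] the grid was computed over.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(grid, ws) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_occupancy requires ggplot2")
  df <- expand.grid(ix = seq_len(nrow(grid)), iy = seq_len(ncol(grid)))
  df$x <- ws$x_min + (df$ix - 0.5) * ws$bin_mm
  df$y <- ws$y_min + (df$iy - 0.5) * ws$bin_mm
  df$visits <- as.vector(grid)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = visits)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "anteroposterior (mm)", y = "dorsoventral (mm)",
                  fill = "visits")
}
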