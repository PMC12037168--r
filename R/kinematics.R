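# Trajectory kinematics: preprocessing, tortuosity, discrete Frechet
# distance, movement velocity, explored-area occupancy grids, and circular
# angular deviation.

#' Construct a labeled 2D trajectory
#'
#' @param t_ms Increasing sample times.
#' @param x_mm,y_mm Coordinates in mm.
#' @param label `"push"` or `"pull"` trial label (optional).
#' @param trial Trial index (optional).
#' @return Data frame of class `joy_trajectory`.
#' @export
trajectory <- function(t_ms, x_mm, y_mm, label = NA_character_, trial = NA) {
  if (length(x_mm) != length(t_ms) || length(y_mm) != length(t_ms))
    stop("coordinate and time vectors must have equal lengths")
  if (length(t_ms) > 1 && any(diff(t_ms) <= 0))
    stop("times must be strictly increasing")
  out <- data.frame(t_ms = as.numeric(t_ms), x_mm = as.numeric(x_mm),
                    y_mm = as.numeric(y_mm))
  attr(out, "label") <- label
  attr(out, "trial") <- trial
  class(out) <- c("joy_trajectory", "data.frame")
  out
}

#' Convert a position trace to a trajectory
#' @param trace A [position_trace()].
#' @inheritParams trajectory
#' @export
as_trajectory <- function(trace, label = NA_character_, trial = NA) {
  trajectory(trace$t_ms, trace$x_mm, trace$y_mm, label = label, trial = trial)
}

#' Preprocess a trajectory for kinematic analysis
#'
#' Removes consecutive repeated coordinate pairs (samples where the joystick
#' did not move) and centers the coordinates by subtracting the
#' per-trajectory median x and median y.
#'
#' @param traj A [trajectory()].
#' @return Preprocessed [trajectory()].
#' @export
preprocess_trajectory <- function(traj) {
  if (nrow(traj) < 2) stop("trajectory needs at least 2 raw points")
  keep <- c(TRUE, diff(traj$x_mm) != 0 | diff(traj$y_mm) != 0)
  if (sum(keep) < 2)
    stop("degenerate trajectory: all points identical")
  out <- traj[keep, , drop = FALSE]
  out$x_mm <- out$x_mm - stats::median(out$x_mm)
  out$y_mm <- out$y_mm - stats::median(out$y_mm)
  attr(out, "label") <- attr(traj, "label")
  attr(out, "trial") <- attr(traj, "trial")
  class(out) <- class(traj)
  rownames(out) <- NULL
  out
}

path_length_2d <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

#' Trajectory tortuosity
#'
#' Ratio of the total path length to the Euclidean distance between the
#' trajectory's first and last points; 1 for a straight monotone path. The
#' ratio is undefined for (nearly) closed paths: trajectories whose net
#' first-to-last displacement is below `epsilon_net` are excluded (`NA` with
#' an `"excluded"` attribute), never an error. `mode = "outbound"` restricts
#' the trajectory to the segment from the start to the point of maximum
#' displacement before computing the ratio.
#'
#' @param traj A [trajectory()].
#' @param mode `"full"` (first to last point) or `"outbound"`.
#' @param epsilon_net Minimum admissible net displacement, mm (default 0.5).
#' @return Tortuosity (>= 1), or `NA` with attribute `excluded = TRUE`.
#' @export
tortuosity <- function(traj, mode = c("full", "outbound"), epsilon_net = 0.5) {
  mode <- match.arg(mode)
  x <- traj$x_mm; y <- traj$y_mm
  if (mode == "outbound") {
    d0 <- sqrt((x - x[1])^2 + (y - y[1])^2)
    i_max <- which.max(d0)
    x <- x[seq_len(i_max)]; y <- y[seq_len(i_max)]
  }
  n <- length(x)
  chord <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (n < 2 || chord < epsilon_net) {
    out <- NA_real_
    attr(out, "excluded") <- TRUE
    attr(out, "reason") <- "net displacement below epsilon_net"
    return(out)
  }
  path_length_2d(x, y) / chord
}

#' Discrete Frechet distance between two trajectories
#'
#' Dynamic-programming evaluation of the discrete Frechet distance between
#' two point sequences:
#' `d[i,j] = max(||P_i - Q_j||, min(d[i-1,j], d[i,j-1], d[i-1,j-1]))`.
#' Symmetric, non-negative, zero exactly on identical sequences, and equal to
#' the naive recursion over all order-preserving couplings.
#'
#' @param p,q Trajectories ([trajectory()] or anything with `x_mm`, `y_mm`).
#' @return Distance in mm.
#' @export
frechet_distance <- function(p, q) {
  np <- nrow(p); nq <- nrow(q)
  if (np == 0 || nq == 0) stop("frechet_distance requires non-empty inputs")
  # pairwise point distances
  dmat <- sqrt(outer(p$x_mm, q$x_mm, "-")^2 + outer(p$y_mm, q$y_mm, "-")^2)
  ca <- matrix(0, np, nq)
  ca[1, 1] <- dmat[1, 1]
  for (i in 2:max(np, 2)) if (np >= 2)
    ca[i, 1] <- max(ca[i - 1, 1], dmat[i, 1])
  for (j in 2:max(nq, 2)) if (nq >= 2)
    ca[1, j] <- max(ca[1, j - 1], dmat[1, j])
  if (np >= 2 && nq >= 2) {
    for (i in 2:np) {
      for (j in 2:nq) {
        ca[i, j] <- max(dmat[i, j],
                        min(ca[i - 1, j], ca[i, j - 1], ca[i - 1, j - 1]))
      }
    }
  }
  ca[np, nq]
}

#' Resample a trajectory to a fixed number of points
#'
#' Arc-length-uniform resampling of the polyline; used to keep all-pairs
#' Frechet computations tractable for large sessions. Endpoints preserved.
#'
#' @param traj A [trajectory()].
#' @param n_points Number of points after resampling.
#' @return Resampled [trajectory()].
#' @export
resample_trajectory <- function(traj, n_points = 50) {
  n <- nrow(traj)
  if (n <= n_points) return(traj)
  seg <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
  s <- c(0, cumsum(seg))
  if (s[n] == 0) return(traj[c(1, n), , drop = FALSE])
  target <- seq(0, s[n], length.out = n_points)
  x <- stats::approx(s, traj$x_mm, xout = target, ties = "ordered")$y
  y <- stats::approx(s, traj$y_mm, xout = target, ties = "ordered")$y
  t <- stats::approx(s, traj$t_ms, xout = target, ties = "ordered")$y
  t <- cummax(t + seq_along(t) * 1e-9)   # keep strictly increasing
  trajectory(t, x, y, label = attr(traj, "label"), trial = attr(traj, "trial"))
}

#' Session-mean pairwise Frechet distance
#'
#' Mean of [frechet_distance()] over all unordered pairs of trajectories
#' (n(n-1)/2 pairs); the session-level trajectory-similarity readout. Lower
#' values mean more stereotyped movements.
#'
#' @param trajs List of trajectories.
#' @param resample_n Optional: resample each trajectory to this many points
#'   first (exact distances on the resampled polylines).
#' @return Mean distance in mm; `NA` with a warning when fewer than 2
#'   trajectories are supplied.
#' @export
session_frechet_mean <- function(trajs, resample_n = NULL) {
  n <- length(trajs)
  if (n < 2) {
    warning("session_frechet_mean undefined for fewer than 2 trajectories")
    return(NA_real_)
  }
  if (!is.null(resample_n))
    trajs <- lapply(trajs, resample_trajectory, n_points = resample_n)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + frechet_distance(trajs[[i]], trajs[[j]])
  tot / (n * (n - 1) / 2)
}

#' Movement velocity of a trajectory
#'
#' Euclidean distance between the first point and the point of maximum
#' displacement (the sample farthest from the first point), divided by the
#' corresponding time interval; mm/s.
#'
#' @param traj A [trajectory()].
#' @return Velocity in mm/s.
#' @export
movement_velocity <- function(traj) {
  d0 <- sqrt((traj$x_mm - traj$x_mm[1])^2 + (traj$y_mm - traj$y_mm[1])^2)
  i <- which.max(d0)
  dt <- traj$t_ms[i] - traj$t_ms[1]
  if (dt == 0) stop("maximum displacement at the first sample: zero interval")
  d0[i] / dt * 1000
}

#' Define a workspace from trajectories
#'
#' The global workspace spans the minimum and maximum x and y coordinates
#' across all supplied trajectories, partitioned into 1 mm x 1 mm bins
#' (half-open `[k, k+1)`, minima at bin edges; the top edge closes the last
#' bin).
#'
#' @param trajs List of trajectories.
#' @param bin_mm Bin side length (default 1).
#' @return List of class `joy_workspace`.
#' @export
workspace <- function(trajs, bin_mm = 1) {
  xs <- unlist(lapply(trajs, `[[`, "x_mm"))
  ys <- unlist(lapply(trajs, `[[`, "y_mm"))
  x_min <- min(xs); x_max <- max(xs); y_min <- min(ys); y_max <- max(ys)
  nx <- max(1L, ceiling((x_max - x_min) / bin_mm))
  ny <- max(1L, ceiling((y_max - y_min) / bin_mm))
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 bin_mm = bin_mm, nx = nx, ny = ny),
            class = "joy_workspace")
}

bin_index <- function(v, lo, bin, nbin) {
  i <- floor((v - lo) / bin) + 1L
  pmin(pmax(i, 1L), nbin)  # top edge closes the last bin
}

#' Explored area within a workspace
#'
#' Bins every trajectory point into the workspace's 1 mm^2 occupancy grid
#' and counts visited bins. Points outside the workspace are an error (the
#' workspace is defined from the global minima/maxima, so nothing should
#' fall outside it).
#'
#' @param trajs List of trajectories (or a single trajectory).
#' @param ws A [workspace()].
#' @return List with `area_mm2` (count of visited bins x bin area) and
#'   `grid` (visit-count matrix, rows = x bins, cols = y bins).
#' @export
explored_area <- function(trajs, ws) {
  if (inherits(trajs, "joy_trajectory")) trajs <- list(trajs)
  grid <- matrix(0L, ws$nx, ws$ny)
  for (tr in trajs) {
    out <- tr$x_mm < ws$x_min | tr$x_mm > ws$x_max |
      tr$y_mm < ws$y_min | tr$y_mm > ws$y_max
    if (any(out)) {
      k <- which(out)[1]
      stop(sprintf("point (%.3f, %.3f) outside workspace", tr$x_mm[k], tr$y_mm[k]))
    }
    ix <- bin_index(tr$x_mm, ws$x_min, ws$bin_mm, ws$nx)
    iy <- bin_index(tr$y_mm, ws$y_min, ws$bin_mm, ws$ny)
    for (k in seq_along(ix)) grid[ix[k], iy[k]] <- grid[ix[k], iy[k]] + 1L
  }
  list(area_mm2 = sum(grid > 0) * ws$bin_mm^2, grid = grid)
}

#' Angular deviation of a set of angles
#'
#' Circular spread statistic `s = sqrt(2 * (1 - Rbar))` where `Rbar` is the
#' mean resultant length of the angles; ranges from 0 (all angles identical)
#' to sqrt(2) (angles balanced around the circle).
#'
#' @param angles Angles in radians.
#' @return Value in `[0, sqrt(2)]`; `NA` for empty input.
#' @export
angular_deviation <- function(angles) {
  if (length(angles) == 0) return(NA_real_)
  rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  sqrt(2 * (1 - min(1, rbar)))
}

#' Session mean angular deviation over occupancy bins
#'
#' Inter-sample displacement directions (`atan2(dy, dx)` of successive
#' samples) are pooled by the occupancy bin of the segment's starting point;
#' the angular deviation is computed per bin (bins holding at least
#' `min_angles` angles) and averaged over those bins.
#'
#' @param trajs List of trajectories.
#' @param ws A [workspace()].
#' @param min_angles Minimum angles per evaluated bin (default 2).
#' @return Mean angular deviation in `[0, sqrt(2)]`; `NA` when no bin
#'   qualifies.
#' @export
mean_angular_deviation <- function(trajs, ws, min_angles = 2) {
  if (inherits(trajs, "joy_trajectory")) trajs <- list(trajs)
  bin_of <- integer(0); ang <- numeric(0)
  for (tr in trajs) {
    n <- nrow(tr)
    if (n < 2) next
    dx <- diff(tr$x_mm); dy <- diff(tr$y_mm)
    nonzero <- dx != 0 | dy != 0
    if (!any(nonzero)) next
    a <- atan2(dy[nonzero], dx[nonzero])
    ix <- bin_index(tr$x_mm[-n][nonzero], ws$x_min, ws$bin_mm, ws$nx)
    iy <- bin_index(tr$y_mm[-n][nonzero], ws$y_min, ws$bin_mm, ws$ny)
    bin_of <- c(bin_of, (iy - 1L) * ws$nx + ix)
    ang <- c(ang, a)
  }
  if (length(ang) == 0) return(NA_real_)
  per_bin <- tapply(ang, bin_of, function(a)
    if (length(a) >= min_angles) angular_deviation(a) else NA_real_)
  per_bin <- per_bin[!is.na(per_bin)]
  if (length(per_bin) == 0) return(NA_real_)
  mean(per_bin)
}

#' Session-level kinematics summary
#'
#' Applies the full suite to a batch of (preprocessed) trajectories: mean
#' tortuosity (with the exclusion count), mean movement velocity, session
#' Frechet mean, explored area and mean angular deviation.
#'
#' @param trajs List of trajectories.
#' @param ws A [workspace()]; computed from `trajs` when `NULL`.
#' @param preprocess Run [preprocess_trajectory()] first (default TRUE)?
#' @param frechet_resample_n Passed to [session_frechet_mean()].
#' @param tortuosity_mode Passed to [tortuosity()].
#' @return One-row data frame of session metrics.
#' @export
session_kinematics <- function(trajs, ws = NULL, preprocess = TRUE,
                               frechet_resample_n = 50,
                               tortuosity_mode = "full") {
  if (preprocess) trajs <- lapply(trajs, preprocess_trajectory)
  if (is.null(ws)) ws <- workspace(trajs)
  tort <- vapply(trajs, function(tr)
    as.numeric(tortuosity(tr, mode = tortuosity_mode)), 0)
  vel <- vapply(trajs, movement_velocity, 0)
  data.frame(
    n_trajectories = length(trajs),
    mean_tortuosity = mean(tort, na.rm = TRUE),
    n_tortuosity_excluded = sum(is.na(tort)),
    mean_velocity_mm_s = mean(vel),
    frechet_mean_mm = session_frechet_mean(trajs, resample_n = frechet_resample_n),
    explored_area_mm2 = explored_area(trajs, ws)$area_mm2,
    mean_angular_deviation = mean_angular_deviation(trajs, ws))
}
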