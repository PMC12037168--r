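# Shared fixture builders and independent oracles.

# Straight-line trajectory between two points.
line_traj <- function(p0, p1, n = 10, dt = 10) {
  trajectory(seq(0, by = dt, length.out = n),
             seq(p0[1], p1[1], length.out = n),
             seq(p0[2], p1[2], length.out = n))
}

# Memoized recursive discrete Frechet oracle (naive definition over all
# order-preserving couplings) — independent of the DP implementation.
frechet_oracle <- function(p, q) {
  np <- nrow(p); nq <- nrow(q)
  d <- function(i, j) sqrt((p$x_mm[i] - q$x_mm[j])^2 + (p$y_mm[i] - q$y_mm[j])^2)
  memo <- array(NA_real_, c(np, nq))
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == 1 && j == 1) d(1, 1)
    else if (i == 1) max(rec(1, j - 1), d(1, j))
    else if (j == 1) max(rec(i - 1, 1), d(i, 1))
    else max(min(rec(i - 1, j), rec(i, j - 1), rec(i - 1, j - 1)), d(i, j))
    memo[i, j] <<- val
    val
  }
  rec(np, nq)
}

# Random short trajectory for oracle-equivalence suites.
random_traj <- function(len, scale = 5) {
  trajectory(seq(0, by = 10, length.out = len),
             stats::runif(len, -scale, scale),
             stats::runif(len, -scale, scale))
}

# Simulate a static 80/20 bandit (no reversals) from a Q agent and return a
# choice_series; used for parameter recovery without engine overhead.
simulate_q_series <- function(alpha, beta, n, p_high = 0.8, p_low = 0.2,
                              high_side = "push") {
  qp <- 0; qq <- 0
  choice <- character(n); reward <- numeric(n)
  for (t in seq_len(n)) {
    p <- softmax_push_prob(qp, qq, beta)
    ch <- if (stats::runif(1) < p) "push" else "pull"
    pr <- if (ch == high_side) p_high else p_low
    r <- as.numeric(stats::runif(1) < pr)
    up <- q_update(qp, qq, ch, r, alpha)
    qp <- up$q_push; qq <- up$q_pull
    choice[t] <- ch; reward[t] <- r
  }
  choice_series(choice, reward)
}

# Bout-spec batch whose supra-sustain episode is guaranteed to exceed the
# 50 ms sustain requirement (peak and duration sampled accordingly).
random_bout_specs <- function(n_bouts, gap_ms = c(150, 400)) {
  t <- 100
  specs <- vector("list", n_bouts)
  for (i in seq_len(n_bouts)) {
    peak <- stats::runif(1, 12, 40)
    dur <- round(stats::runif(1, 100, 250))
    dirn <- sample(c("push", "pull"), 1)
    specs[[i]] <- bout_spec(t, dirn, peak_speed_mm_s = peak, duration_ms = dur)
    t <- t + dur + round(stats::runif(1, gap_ms[1], gap_ms[2]))
  }
  specs
}
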