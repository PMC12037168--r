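test_that("velocity_trace is an exact central difference", {
  # linear ramp 10 mm over 1 s: constant 10 mm/s on interior points
  tr <- position_trace(seq(0, 1000, by = 10), seq(0, 10, length.out = 101))
  v <- velocity_trace(tr)
  expect_equal(v, rep(10, 101), tolerance = 1e-9)
  # constant trace: zeros
  expect_equal(velocity_trace(position_trace(0:10, rep(2, 11))), rep(0, 11))
  # mirrored trace flips the sign
  tr2 <- position_trace(0:50, sin(seq(0, 2 * pi, length.out = 51)))
  mirrored <- position_trace(0:50, -tr2$x_mm)
  expect_equal(velocity_trace(mirrored), -velocity_trace(tr2))
  expect_error(velocity_trace(position_trace(0:1, c(0, 1))), "3 samples")
})

test_that("bout segmentation applies the four printed criteria", {
  # sub-initiation peak (5 < 7.5 mm/s): no bout
  slow <- generate_ap_trace(list(bout_spec(100, "push", peak_speed_mm_s = 5,
                                           duration_ms = 200)), 500)
  expect_equal(nrow(segment_bouts(velocity_trace(slow), slow$t_ms)), 0)
  # 30 ms supra-threshold blip at 10 mm/s: sustain unmet, no bout
  t <- 0:400
  v <- numeric(401); v[101:130] <- 10
  expect_equal(nrow(segment_bouts(v, t)), 0)
  # 100 ms at 10 mm/s: one push bout
  v2 <- numeric(401); v2[101:200] <- 10
  bt <- segment_bouts(v2, t)
  expect_equal(nrow(bt), 1)
  expect_equal(bt$direction, "push")
  # an immediate sign change above initiation opens the opposite bout
  v3 <- numeric(501); v3[101:200] <- 12; v3[201:300] <- -12
  bt3 <- segment_bouts(v3, 0:500)
  expect_equal(bt3$direction, c("push", "pull"))
  # retraction truncates segmentation
  v4 <- numeric(501); v4[101:400] <- 10
  bt4 <- segment_bouts(v4, 0:500, retract_t_ms = 150)
  expect_equal(nrow(bt4), 0)  # only 50 ms left before retraction
})

test_that("segmentation recovers programmed bouts over randomized fixtures", {
  set.seed(101)
  for (rep in 1:100) {
    n_bouts <- sample(1:4, 1)
    specs <- random_bout_specs(n_bouts)
    total <- specs[[n_bouts]]$onset_ms + specs[[n_bouts]]$duration_ms + 200
    ap <- generate_ap_trace(specs, total)
    bt <- segment_bouts(velocity_trace(ap), ap$t_ms, x_mm = ap$x_mm)
    expect_equal(nrow(bt), n_bouts)
    expect_equal(bt$direction, vapply(specs, `[[`, "", "direction"))
    # boundaries sit at the analytic initiation-threshold crossing (+/- 2 ms)
    for (k in seq_len(n_bouts)) {
      b <- specs[[k]]
      t_open <- b$onset_ms + b$duration_ms / pi * asin(7.5 / b$peak_speed_mm_s)
      expect_lt(abs(bt$t_start_ms[k] - t_open), 2.5)
      expect_equal(bt$peak_speed_mm_s[k], b$peak_speed_mm_s, tolerance = 0.05)
    }
  }
})

test_that("directional consistency follows the bout-count formula", {
  mk <- function(dirs) data.frame(direction = dirs)
  expect_equal(directional_consistency(mk(rep("push", 4))), 1.0)
  expect_equal(directional_consistency(mk(c("push", "push", "push", "pull"))), 0.75)
  expect_equal(directional_consistency(mk(c("push", "push", "pull", "pull"))), 0.5)
  expect_warning(res <- directional_consistency(mk(character(0))), "undefined")
  expect_true(is.na(res))
  # always in [0.5, 1] when bouts exist
  set.seed(3)
  for (i in 1:30) {
    dirs <- sample(c("push", "pull"), sample(1:9, 1), replace = TRUE)
    dc <- directional_consistency(mk(dirs))
    expect_true(dc >= 0.5 && dc <= 1)
  }
})

test_that("trial vigor metrics compute the five trial readouts", {
  # single monotone 4 mm bout crossing 3 mm
  spec <- bout_spec(200, "push", duration_ms = 200, displacement_mm = 4)
  tr <- generate_ap_trace(list(spec), 700)
  det <- detect_choice(tr, 3)
  bt <- segment_bouts(velocity_trace(tr), tr$t_ms, x_mm = tr$x_mm)
  m <- trial_vigor_metrics(tr, bt, t_go = 0, t_choice = det$t_cross_ms)
  expect_equal(m$peak_displacement_mm, 4, tolerance = 0.01)
  expect_equal(m$path_length_mm, 4, tolerance = 0.01)
  expect_equal(m$n_bouts, 1)
  expect_equal(m$directional_consistency, 1)
  expect_false(m$decisive_fallback)
  expect_equal(m$choice_latency_ms, det$t_cross_ms)
  expect_gt(m$decisive_mean_velocity_mm_s, 0)
  # back-and-forth +/-2 mm twice then +4 mm: path 12, peak 4
  x <- c(seq(0, 2, by = 0.1), seq(2, 0, by = -0.1), seq(0, 2, by = 0.1),
         seq(2, 0, by = -0.1), seq(0, 4, by = 0.1))
  tr2 <- position_trace(seq_along(x) - 1, x)
  bt2 <- segment_bouts(velocity_trace(tr2), tr2$t_ms, x_mm = tr2$x_mm)
  m2 <- trial_vigor_metrics(tr2, bt2, t_go = 0, t_choice = 110)
  expect_equal(m2$path_length_mm, 12, tolerance = 0.01)
  expect_equal(m2$peak_displacement_mm, 4)
  # t_go == t_choice: zero latency
  m3 <- trial_vigor_metrics(tr, bt, t_go = det$t_cross_ms,
                            t_choice = det$t_cross_ms)
  expect_equal(m3$choice_latency_ms, 0)
  # path length >= peak displacement (property over random traces)
  set.seed(8)
  for (i in 1:25) {
    specs <- random_bout_specs(sample(1:3, 1))
    last <- specs[[length(specs)]]
    ap <- generate_ap_trace(specs, last$onset_ms + last$duration_ms + 100,
                            noise_mm = 0.02)
    b <- segment_bouts(velocity_trace(ap), ap$t_ms, x_mm = ap$x_mm)
    mm <- trial_vigor_metrics(ap, b, 0, ap$t_ms[which.max(abs(ap$x_mm))])
    expect_gte(mm$path_length_mm, mm$peak_displacement_mm - 1e-9)
  }
})

test_that("uncertainty shapes session kinematics in the expected directions", {
  # high- vs low-uncertainty trajectory policies: more bouts, mixed
  # directions, longer paths, faster decisive movement under uncertainty
  set.seed(55)
  low_u <- run_bandit_session(agent_q(q_agent_params(0.7, 8)), 150,
                              seed = 301, traces = TRUE)
  high_u <- run_bandit_session(agent_q(q_agent_params(0.05, 0.5)), 150,
                               seed = 302, traces = TRUE)
  klo <- session_vigor_analysis(low_u)$trials
  khi <- session_vigor_analysis(high_u)$trials
  expect_gt(mean(khi$n_bouts), mean(klo$n_bouts))
  expect_lt(mean(khi$directional_consistency, na.rm = TRUE),
            mean(klo$directional_consistency, na.rm = TRUE))
  expect_gt(mean(khi$path_length_mm), mean(klo$path_length_mm))
  expect_gt(mean(khi$decisive_mean_velocity_mm_s, na.rm = TRUE),
            mean(klo$decisive_mean_velocity_mm_s, na.rm = TRUE))
})
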