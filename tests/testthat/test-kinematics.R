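test_that("preprocessing drops repeated pairs and centers on the median", {
  tr <- trajectory(c(0, 10, 20), c(1, 1, 2), c(1, 1, 2))
  pp <- preprocess_trajectory(tr)
  expect_equal(nrow(pp), 2)
  expect_equal(pp$x_mm, c(1, 2) - 1.5)
  # symmetric path about the origin is unchanged by centering
  sym <- trajectory(0:4, c(-2, -1, 0, 1, 2), c(2, 1, 0, -1, -2))
  expect_equal(preprocess_trajectory(sym)$x_mm, sym$x_mm)
  # median (3, -1) shifts every point by (-3, +1)
  off <- trajectory(0:2, c(2, 3, 4), c(-2, -1, 0))
  pp2 <- preprocess_trajectory(off)
  expect_equal(pp2$x_mm, c(-1, 0, 1))
  expect_equal(pp2$y_mm, c(-1, 0, 1))
  expect_error(preprocess_trajectory(trajectory(0:2, rep(1, 3), rep(1, 3))),
               "degenerate")
})

test_that("tortuosity is path length over chord with an exclusion guard", {
  expect_equal(as.numeric(tortuosity(line_traj(c(0, 0), c(5, 0)))), 1)
  # right-angle path: (0,0)->(3,0)->(3,4): path 7 over chord 5
  ra <- trajectory(c(0, 10, 20), c(0, 3, 3), c(0, 0, 4))
  expect_equal(as.numeric(tortuosity(ra)), 1.4)
  # closed loop: excluded, not an error
  loop <- trajectory(c(0, 10, 20, 30), c(0, 2, 2, 0), c(0, 0, 2, 0.1))
  res <- tortuosity(loop)
  expect_true(is.na(res))
  expect_true(attr(res, "excluded"))
  # tortuosity >= 1 over random admissible trajectories (triangle inequality)
  set.seed(31)
  for (i in 1:50) {
    tr <- random_traj(sample(5:15, 1))
    v <- tortuosity(tr)
    if (!is.na(v)) expect_gte(as.numeric(v), 1)
  }
})

test_that("discrete Frechet DP matches the recursive oracle and its properties", {
  p <- trajectory(c(0, 10), c(0, 1), c(0, 0))
  q <- trajectory(c(0, 10), c(0, 1), c(1, 1))
  expect_equal(frechet_distance(p, q), 1)
  expect_equal(frechet_distance(p, p), 0)
  # oracle equivalence on >= 200 random short pairs, plus symmetry and the
  # endpoint lower bound
  set.seed(12)
  for (i in 1:200) {
    a <- random_traj(sample(2:6, 1))
    b <- random_traj(sample(2:6, 1))
    d <- frechet_distance(a, b)
    expect_equal(d, frechet_oracle(a, b), tolerance = 1e-12)
    expect_equal(d, frechet_distance(b, a))
    lb <- max(sqrt((a$x_mm[1] - b$x_mm[1])^2 + (a$y_mm[1] - b$y_mm[1])^2),
              sqrt((tail(a$x_mm, 1) - tail(b$x_mm, 1))^2 +
                   (tail(a$y_mm, 1) - tail(b$y_mm, 1))^2))
    expect_gte(d + 1e-12, lb)
  }
})

test_that("session Frechet mean averages all unordered pairs", {
  t0 <- line_traj(c(0, 0), c(4, 0))
  expect_equal(session_frechet_mean(list(t0, t0, t0)), 0)
  # three parallel lines at y = 0, 1, 3: pairwise distances 1, 3, 2 -> mean 2
  trs <- lapply(c(0, 1, 3), function(y) line_traj(c(0, y), c(4, y)))
  expect_equal(session_frechet_mean(trs), 2)
  expect_warning(res <- session_frechet_mean(list(t0)), "fewer than 2")
  expect_true(is.na(res))
  # tight cluster vs dispersed batch from the generator
  set.seed(44)
  tight <- lapply(1:12, function(i)
    as_trajectory(generate_trajectory_2d(trajectory_style(stage = 1, jitter_mm = 0.3))))
  loose <- lapply(1:12, function(i)
    as_trajectory(generate_trajectory_2d(trajectory_style(stage = 0))))
  expect_lt(session_frechet_mean(tight, resample_n = 40),
            session_frechet_mean(loose, resample_n = 40))
})

test_that("movement velocity uses the point of maximum displacement", {
  tr <- trajectory(c(0, 100, 200), c(0, 2, 4), c(0, 0, 0))
  expect_equal(movement_velocity(tr), 20)
  # doubling the timestamps halves the velocity
  tr2 <- trajectory(c(0, 200, 400), c(0, 2, 4), c(0, 0, 0))
  expect_equal(movement_velocity(tr2), 10)
  # out-and-back: the turning point, not the endpoint, defines the velocity
  oab <- trajectory(c(0, 100, 300), c(0, 4, 1), c(0, 0, 0))
  expect_equal(movement_velocity(oab), 40)
  expect_error(movement_velocity(trajectory(c(0, 10), c(0, -1), c(0, 0))),
               NA)
})

test_that("explored area counts half-open 1 mm bins inside the workspace", {
  still <- trajectory(c(0, 10), c(0.5, 0.5), c(0.5, 0.5))
  ws1 <- workspace(list(still))
  expect_equal(explored_area(still, ws1)$area_mm2, 1)
  # straight 5.5 mm horizontal path starting at a bin edge spans 6 bins
  path <- trajectory(seq(0, 550, by = 10), seq(0, 5.5, length.out = 56),
                     rep(0.2, 56))
  ws <- structure(list(x_min = 0, x_max = 6, y_min = 0, y_max = 1,
                       bin_mm = 1, nx = 6L, ny = 1L), class = "joy_workspace")
  res <- explored_area(path, ws)
  expect_equal(res$area_mm2, 6)
  expect_equal(sum(res$grid), 56)
  # union property: area(A u B) <= area(A) + area(B)
  a <- trajectory(0:1, c(0.1, 0.9), c(0.1, 0.1))
  b <- trajectory(0:1, c(3.1, 3.9), c(0.1, 0.1))
  wsu <- workspace(list(a, b))
  expect_lte(explored_area(list(a, b), wsu)$area_mm2,
             explored_area(a, wsu)$area_mm2 + explored_area(b, wsu)$area_mm2)
  # disjoint bins: equality
  expect_equal(explored_area(list(a, b), wsu)$area_mm2,
               explored_area(a, wsu)$area_mm2 + explored_area(b, wsu)$area_mm2)
  # outside point is an error naming the point
  expect_error(explored_area(trajectory(0:1, c(0, 99), c(0, 0)), wsu),
               "outside workspace")
})

test_that("angular deviation spans [0, sqrt(2)] with the circular-statistics form", {
  expect_equal(angular_deviation(rep(1.1, 25)), 0)
  expect_equal(angular_deviation(seq(0, 2 * pi, length.out = 361)[-361]),
               sqrt(2), tolerance = 1e-10)
  expect_equal(angular_deviation(c(0, pi)), sqrt(2))
  expect_true(is.na(angular_deviation(numeric(0))))
  # rotation invariance (property)
  set.seed(6)
  for (i in 1:20) {
    a <- runif(sample(3:30, 1), 0, 2 * pi)
    rot <- runif(1, 0, 2 * pi)
    expect_equal(angular_deviation(a), angular_deviation(a + rot),
                 tolerance = 1e-9)
    expect_true(angular_deviation(a) >= 0 && angular_deviation(a) <= sqrt(2) + 1e-12)
  }
})

test_that("session mean angular deviation pools displacement angles by bin", {
  # straight lines everywhere: zero deviation in every bin
  trs <- lapply(0:3, function(y) line_traj(c(0, y + 0.5), c(5, y + 0.5), n = 30))
  ws <- workspace(trs)
  expect_equal(mean_angular_deviation(trs, ws), 0, tolerance = 1e-9)
  # balanced opposite directions within a single bin: sqrt(2) exactly
  fwd <- line_traj(c(0.2, 0.5), c(0.8, 0.5), n = 15)
  bwd <- line_traj(c(0.8, 0.5), c(0.2, 0.5), n = 15)
  ws2 <- workspace(list(fwd, bwd))
  expect_equal(mean_angular_deviation(list(fwd, bwd), ws2), sqrt(2),
               tolerance = 1e-9)
  # opposite directions through many bins: near-maximal deviation
  fwd2 <- line_traj(c(0.2, 0.5), c(4.8, 0.5), n = 30)
  bwd2 <- line_traj(c(4.8, 0.5), c(0.2, 0.5), n = 30)
  ws3 <- workspace(list(fwd2, bwd2))
  expect_gt(mean_angular_deviation(list(fwd2, bwd2), ws3), 1.25)
})

test_that("staged batches reproduce the learning-trend orderings", {
  set.seed(77)
  stages <- c(0, 0.5, 1)
  batches <- lapply(stages, function(st)
    lapply(1:30, function(i) as_trajectory(
      generate_trajectory_2d(trajectory_style(stage = st)))))
  ws <- workspace(lapply(batches, function(b)
    lapply(b, preprocess_trajectory))[[1]])
  all_pp <- lapply(batches, function(b) lapply(b, preprocess_trajectory))
  ws <- workspace(do.call(c, all_pp))
  summ <- lapply(all_pp, function(b)
    session_kinematics(b, ws = ws, preprocess = FALSE, frechet_resample_n = 40))
  tort <- vapply(summ, `[[`, 0, "mean_tortuosity")
  frech <- vapply(summ, `[[`, 0, "frechet_mean_mm")
  area <- vapply(summ, `[[`, 0, "explored_area_mm2")
  vel <- vapply(summ, `[[`, 0, "mean_velocity_mm_s")
  expect_true(all(diff(tort) <= 0))
  expect_true(all(diff(frech) <= 0))
  expect_true(all(diff(area) <= 0))
  expect_true(all(diff(vel) >= 0))
  # angular deviation stays within its admissible range at every stage
  mad <- vapply(summ, `[[`, 0, "mean_angular_deviation")
  expect_true(all(mad >= 0 & mad <= sqrt(2)))
})
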