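test_that("a zero-jitter recumbent-only scenario freezes positions and velocity", {
  pen <- pen_config(n_animals = 5, frame_interval_s = 1, sampling_interval_s = 60)
  sc <- behavior_scenario(data.frame(start_s = 0, state = "all_recumbent"),
                          jitter_speed_mean = 0, jitter_speed_sd = 0,
                          false_detection_rate = 0.3, seed = 4)
  sim <- simulate_trajectories(pen, sc, duration_s = 300)
  pos <- split(sim$frames[c("x_m", "y_m")], sim$frames$animal_id)
  for (p in pos) {
    expect_equal(length(unique(p$x_m)), 1L)
    expect_equal(length(unique(p$y_m)), 1L)
  }
  pv <- quiet(compute_group_velocity(sim$frames))
  expect_true(all(pv$v_mps == 0))
  expect_true(all(summarize_windows(pv, 60)$v_mps == 0, na.rm = TRUE))
})

test_that("frame count, pen bounds and ethogram follow the schedule", {
  pen <- pen_config(n_animals = 3, frame_interval_s = 1, sampling_interval_s = 1200)
  sched <- data.frame(start_s = 1800 * (0:3),
                      state = rep(c("all_recumbent", "some_active"), 2))
  sc <- behavior_scenario(sched, seed = 9)
  sim <- simulate_trajectories(pen, sc, duration_s = 7200)
  expect_equal(length(unique(sim$frames$t_s)), 7200L)
  expect_equal(nrow(sim$frames), 7200L * 3L)
  expect_true(all(sim$frames$x_m >= 0 & sim$frames$x_m <= pen$width_m))
  expect_true(all(sim$frames$y_m >= 0 & sim$frames$y_m <= pen$height_m))
  expect_equal(sim$ethogram$t_s, seq(0, 6000, by = 1200))
  expect_equal(sim$ethogram$code, c(0L, 0L, 1L, 0L, 0L, 1L))
})

test_that("window velocities form two clusters recovering the configured speeds", {
  pen <- pen_config()  # 18 animals in a 2.55 x 3.20 m pen
  n_episodes <- 20
  sched <- data.frame(start_s = 600 * (0:(n_episodes - 1)),
                      state = rep(c("all_recumbent", "some_active"), n_episodes / 2))
  fdr <- 0.05
  sc <- behavior_scenario(sched, n_active = 1,
                          active_speed_mean = 0.05, active_speed_sd = 0.01,
                          jitter_speed_mean = 5e-4, jitter_speed_sd = 2e-4,
                          false_detection_rate = fdr, seed = 42)
  sim <- simulate_trajectories(pen, sc, duration_s = 600 * n_episodes)
  w <- summarize_windows(quiet(compute_group_velocity(sim$frames)), window_s = 300)
  state <- rep(rep(c(0, 1), each = 2), n_episodes / 2)[seq_len(nrow(w))]
  act <- w$v_mps[state == 1]
  rec <- w$v_mps[state == 0]

  # Direct averaging of the configured distributions: the group velocity
  # sums the speeds of flagged animals, so the expected window mean is
  # (number flagged) x (truncated mean speed) for each population.
  e_act <- 1 * truncated_speed_mean(0.05, 0.01) +
    fdr * (pen$n_animals - 1) * truncated_speed_mean(5e-4, 2e-4)
  e_rec <- fdr * pen$n_animals * truncated_speed_mean(5e-4, 2e-4)
  expect_lt(abs(mean(act) - e_act), 3 * sd(act) / sqrt(length(act)))
  expect_lt(abs(mean(rec) - e_rec), 3 * sd(rec) / sqrt(length(rec)))
  expect_gt(min(act), max(rec))  # two separated clusters
})

test_that("trajectory generation is reproducible for a fixed seed", {
  pen <- pen_config(n_animals = 4, sampling_interval_s = 120)
  sched <- data.frame(start_s = c(0, 300), state = c("all_recumbent", "some_active"))
  a <- simulate_trajectories(pen, behavior_scenario(sched, seed = 5), 600)
  b <- simulate_trajectories(pen, behavior_scenario(sched, seed = 5), 600)
  d <- simulate_trajectories(pen, behavior_scenario(sched, seed = 6), 600)
  expect_identical(a$frames, b$frames)
  expect_identical(a$ethogram, b$ethogram)
  expect_false(identical(a$frames, d$frames))
})

test_that("invalid scenarios and schedules are rejected", {
  pen <- pen_config(n_animals = 2)
  expect_error(behavior_scenario(data.frame(start_s = 100, state = "some_active")),
               "start at time 0")
  expect_error(behavior_scenario(data.frame(start_s = c(0, 0),
                                            state = c("all_recumbent", "some_active"))),
               "strictly increasing")
  expect_error(behavior_scenario(data.frame(start_s = 0, state = "all_recumbent"),
                                 active_speed_mean = 1e-5, jitter_speed_mean = 1e-4),
               "must exceed")
  sc <- behavior_scenario(data.frame(start_s = 0, state = "some_active"), n_active = 5)
  expect_error(simulate_trajectories(pen, sc, 60), "group size")
})
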