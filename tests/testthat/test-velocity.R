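frame_at <- function(t, x, y, standing, pen = "p1") {
  data.frame(pen_id = pen, t_s = t, animal_id = seq_along(x),
             x_m = x, y_m = y, detected_standing = standing)
}

test_that("pair velocity follows the standing-displacement formula", {
  f0 <- frame_at(0, c(0, 1), c(0, 1), c(1, 0))
  expect_equal(pair_velocity(f0, transform(f0, t_s = 5)), 0)  # identical frames

  f1 <- frame_at(1, c(0.3, 1), c(0.4, 1), c(1, 0))
  expect_equal(pair_velocity(f0, f1), 0.5)  # 3-4-5 displacement over 1 s

  # five animals, two flagged standing, dt = 2: hand-summed oracle
  withr::with_seed(31, {
    p0 <- frame_at(0, runif(5, 0, 2), runif(5, 0, 3), rep(0L, 5))
    p1 <- frame_at(2, runif(5, 0, 2), runif(5, 0, 3), c(1L, 0L, 1L, 0L, 0L))
  })
  by_hand <- (sqrt(sum((p1[1, c("x_m", "y_m")] - p0[1, c("x_m", "y_m")])^2)) +
                sqrt(sum((p1[3, c("x_m", "y_m")] - p0[3, c("x_m", "y_m")])^2))) / 2
  expect_equal(pair_velocity(p0, p1), as.numeric(by_hand))
})

test_that("degenerate frame pairs are rejected and absences contribute zero", {
  f0 <- frame_at(0, 1, 1, 1)
  expect_error(pair_velocity(f0, frame_at(0, 1, 1, 1)), "positive")
  expect_error(pair_velocity(f0, frame_at(-1, 1, 1, 1)), "positive")
  expect_error(pair_velocity(f0[0, ], frame_at(1, 1, 1, 1)), "empty")
  curr <- frame_at(1, c(1, 2), c(1, 2), c(1, 1))
  curr$animal_id <- c(1L, 9L)  # animal 9 absent from the previous frame
  expect_message(v <- pair_velocity(f0, curr), "missing from previous frame")
  expect_equal(v, 0)
})

test_that("stream velocities agree with frame-by-frame pair computation", {
  pen <- pen_config(n_animals = 4, frame_interval_s = 2, sampling_interval_s = 60)
  sc <- behavior_scenario(data.frame(start_s = 0, state = "some_active"),
                          n_active = 2, seed = 14)
  frames <- simulate_trajectories(pen, sc, duration_s = 120)$frames
  pv <- quiet(compute_group_velocity(frames))
  by_frame <- split(as.data.frame(frames), frames$t_s)
  for (i in seq_along(by_frame)[-1]) {
    expect_equal(pv$v_mps[i - 1], pair_velocity(by_frame[[i - 1]], by_frame[[i]]))
  }
})

test_that("pair velocity is invariant to rigid motions and scales linearly", {
  withr::with_seed(8, {
    f0 <- frame_at(0, runif(6), runif(6), rbinom(6, 1, 0.5))
    f1 <- frame_at(1.5, runif(6), runif(6), rbinom(6, 1, 0.5))
  })
  v <- pair_velocity(f0, f1)
  rot <- function(f, a, dx, dy) transform(f,
    x_m = cos(a) * x_m - sin(a) * y_m + dx,
    y_m = sin(a) * x_m + cos(a) * y_m + dy)
  expect_equal(pair_velocity(rot(f0, 0.7, 2, -1), rot(f1, 0.7, 2, -1)), v)
  scale_xy <- function(f, k) transform(f, x_m = k * x_m, y_m = k * y_m)
  expect_equal(pair_velocity(scale_xy(f0, 3), scale_xy(f1, 3)), 3 * v)
  f1_down <- transform(f1, detected_standing = 0L)
  expect_equal(pair_velocity(f0, f1_down), 0)
})

test_that("window summaries average pair velocities over half-open windows", {
  pv <- tibble::tibble(pen_id = "p1", t_s = 1:300, v_mps = 0.2)
  w <- summarize_windows(pv, window_s = 300, origin = c(p1 = 0))
  expect_equal(w$v_mps[1], 0.2)

  pv2 <- tibble::tibble(pen_id = "p1", t_s = c(10, 200), v_mps = c(0.1, 0.3))
  expect_equal(summarize_windows(pv2, 300, origin = c(p1 = 0))$v_mps, 0.2)

  withr::with_seed(2, {
    pv3 <- tibble::tibble(pen_id = "p1", t_s = 1:300, v_mps = runif(300))
  })
  w3 <- summarize_windows(pv3, window_s = 300, origin = c(p1 = 0))
  # independent mean computation: split-by-index second code path
  expected <- unname(sapply(split(pv3$v_mps, floor(pv3$t_s / 300)), mean))
  expect_equal(w3$v_mps, expected)
  expect_equal(w3$n_frame_pairs, c(299L, 1L))
})

test_that("empty windows are kept with zero pairs and missing velocity", {
  pv <- tibble::tibble(pen_id = "p1", t_s = c(5, 10, 650), v_mps = c(1, 2, 3))
  w <- summarize_windows(pv, window_s = 300, origin = c(p1 = 0))
  expect_equal(w$n_frame_pairs, c(2L, 0L, 1L))
  expect_true(is.na(w$v_mps[2]))
  expect_equal(w$window_start_s, c(0, 300, 600))
})

test_that("window summaries are invariant to a constant timestamp shift", {
  withr::with_seed(6, {
    pv <- tibble::tibble(pen_id = "p1", t_s = sort(runif(100, 0, 1000)),
                         v_mps = runif(100))
  })
  w1 <- summarize_windows(pv, 300, origin = c(p1 = 0))
  pv_shift <- transform(pv, t_s = t_s + 12345)
  w2 <- summarize_windows(pv_shift, 300, origin = c(p1 = 12345))
  expect_equal(w1$v_mps, w2$v_mps)
  expect_equal(w1$n_frame_pairs, w2$n_frame_pairs)
})

test_that("linking matches images to covering windows and drops the rest", {
  rec <- tibble::tibble(pen_id = "p1",
                        window_start_s = c(0, 300, 600),
                        window_end_s = c(300, 600, 900),
                        v_mps = c(0.1, NA, 0.3),
                        n_frame_pairs = c(10L, 0L, 10L))
  labels <- tibble::tibble(pen_id = "p1", t_s = c(610, 450, 2000), code = c(1L, 0L, 1L))
  expect_message(out <- link_samples(rec, labels), "dropped 2")
  expect_equal(nrow(out), 1L)
  expect_equal(out$v_mps, 0.3)  # image at 610 s sits in [600, 900)
  expect_equal(attr(out, "n_dropped"), 2L)

  dup <- labels[c(1, 1), ]
  expect_error(link_samples(rec, dup), "duplicate")
})

test_that("a large synthetic link is verified sample-by-sample", {
  pen <- pen_config(n_animals = 3, frame_interval_s = 5, sampling_interval_s = 120)
  sched <- data.frame(start_s = c(0, 1800), state = c("all_recumbent", "some_active"))
  sim <- simulate_trajectories(pen, behavior_scenario(sched, seed = 19), 3600)
  w <- summarize_windows(quiet(compute_group_velocity(sim$frames)), 300)
  linked <- quiet(link_samples(w, sim$ethogram))
  expect_gt(nrow(linked), 0)
  for (i in seq_len(nrow(linked))) {   # brute-force containment scan
    hit <- w[w$pen_id == linked$pen_id[i] &
               w$window_start_s <= linked$t_s[i] &
               linked$t_s[i] < w$window_end_s, ]
    expect_equal(linked$v_mps[i], hit$v_mps)
  }
})
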