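#' Pen configuration
#'
#' Describes one rearing pen as seen by the overhead tracking camera:
#' its floor dimensions, group size, the frame rate of the position
#' stream and the interval at which single frames are sampled for
#' behaviour coding.
#'
#' @param pen_id Pen label.
#' @param width_m,height_m Pen floor dimensions in metres. Defaults match
#'   a commercial rearing pen of 2.55 m x 3.20 m.
#' @param n_animals Number of pigs housed in the pen (default 18).
#' @param frame_interval_s Time between consecutive tracked frames, in
#'   seconds.
#' @param sampling_interval_s Interval at which still images are sampled
#'   for coding, in seconds (default 1200 s = 20 min).
#'
#' @return A `pen_config` list.
#' @export
#' @examples
#' pen_config("pen1")
pen_config <- function(pen_id = "pen1", width_m = 2.55, height_m = 3.20,
                       n_animals = 18, frame_interval_s = 1,
                       sampling_interval_s = 1200) {
  stop_if_not(is.character(pen_id) && length(pen_id) == 1L, "pen_id must be a single label")
  stop_if_not(is_scalar_number(width_m) && width_m > 0, "width_m must be > 0")
  stop_if_not(is_scalar_number(height_m) && height_m > 0, "height_m must be > 0")
  stop_if_not(is_count(n_animals) && n_animals >= 1, "n_animals must be a count >= 1")
  stop_if_not(is_scalar_number(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be > 0")
  stop_if_not(is_scalar_number(sampling_interval_s) && sampling_interval_s > 0,
              "sampling_interval_s must be > 0")
  structure(list(pen_id = pen_id, width_m = width_m, height_m = height_m,
                 n_animals = as.integer(n_animals),
                 frame_interval_s = frame_interval_s,
                 sampling_interval_s = sampling_interval_s),
            class = "pen_config")
}

#' Group behaviour scenario
#'
#' Defines the alternating group states driving the trajectory generator:
#' a schedule of `all_recumbent` / `some_active` episodes, the speed
#' distribution of actively moving pigs, and the small positional jitter
#' that the tracker reports even for lying animals (detection noise).
#'
#' The tracker abstraction also covers mis-detections: during any state a
#' recumbent animal is falsely flagged as standing with probability
#' `false_detection_rate` per frame, which is what makes the measured
#' group velocity of a fully recumbent pen small-but-nonzero rather than
#' exactly zero.
#'
#' @param state_schedule Data frame with columns `start_s` (strictly
#'   increasing, first value 0) and `state` (`"all_recumbent"` or
#'   `"some_active"`).
#' @param n_active Number of pigs moving during a `some_active` episode.
#' @param active_speed_mean,active_speed_sd Per-frame speed distribution
#'   (normal, truncated at 0) of an actively moving pig, in m/s.
#' @param jitter_speed_mean,jitter_speed_sd Per-frame apparent speed of a
#'   recumbent pig due to detection noise, in m/s.
#' @param false_detection_rate Probability per frame that a recumbent pig
#'   is falsely flagged as standing by the tracker.
#' @param seed Integer seed for reproducible generation.
#'
#' @return A `behavior_scenario` list.
#' @export
behavior_scenario <- function(state_schedule,
                              n_active = 1L,
                              active_speed_mean = 0.02,
                              active_speed_sd = 0.003,
                              jitter_speed_mean = 5e-4,
                              jitter_speed_sd = 2e-4,
                              false_detection_rate = 0.05,
                              seed = 123L) {
  state_schedule <- as.data.frame(state_schedule)
  stop_if_not(all(c("start_s", "state") %in% names(state_schedule)),
              "state_schedule needs columns start_s and state")
  stop_if_not(nrow(state_schedule) >= 1L && state_schedule$start_s[1] == 0,
              "state_schedule must start at time 0")
  stop_if_not(all(diff(state_schedule$start_s) > 0),
              "state_schedule start times must be strictly increasing")
  stop_if_not(all(state_schedule$state %in% c("all_recumbent", "some_active")),
              "unknown group state in schedule")
  stop_if_not(is_count(n_active) && n_active >= 1, "n_active must be >= 1")
  stop_if_not(active_speed_mean > jitter_speed_mean,
              "active speed mean must exceed recumbent jitter mean")
  stop_if_not(active_speed_sd >= 0 && jitter_speed_sd >= 0, "speed sds must be >= 0")
  stop_if_not(false_detection_rate >= 0 && false_detection_rate <= 1,
              "false_detection_rate must lie in [0, 1]")
  structure(list(state_schedule = state_schedule,
                 n_active = as.integer(n_active),
                 active_speed_mean = active_speed_mean,
                 active_speed_sd = active_speed_sd,
                 jitter_speed_mean = jitter_speed_mean,
                 jitter_speed_sd = jitter_speed_sd,
                 false_detection_rate = false_detection_rate,
                 seed = as.integer(seed)),
            class = "behavior_scenario")
}

# State label at each queried time, from a step-function schedule.
schedule_state_at <- function(schedule, t_s) {
  idx <- findInterval(t_s, schedule$start_s)
  stop_if_not(all(idx >= 1L), "time before schedule start")
  schedule$state[idx]
}

# Advance one frame: each animal takes a step of its drawn length in a
# uniformly random heading, redrawing the heading while the step would
# leave the pen (animals turn away from walls). This preserves the step
# length -- and hence the configured speed distribution -- exactly, which
# hard clipping or reflective folding would not. After 50 redraws the
# position is clamped to the pen (pathological step lengths only).
advance_positions <- function(px, py, step, width, height) {
  theta <- runif(length(px), 0, 2 * pi)
  nx <- px + step * cos(theta)
  ny <- py + step * sin(theta)
  bad <- which(nx < 0 | nx > width | ny < 0 | ny > height)
  tries <- 0L
  while (length(bad) > 0 && tries < 50L) {
    th <- runif(length(bad), 0, 2 * pi)
    nx[bad] <- px[bad] + step[bad] * cos(th)
    ny[bad] <- py[bad] + step[bad] * sin(th)
    bad <- bad[nx[bad] < 0 | nx[bad] > width | ny[bad] < 0 | ny[bad] > height]
    tries <- tries + 1L
  }
  list(x = nx, y = ny, n_clamped = length(bad))
}

#' Simulate tracked positions and a ground-truth ethogram for one pen
#'
#' Emulates the output of a camera-based pig tracker: per-frame positions
#' of every animal in pen coordinates (metres, origin at one pen corner)
#' plus a detected-standing flag, driven by a group-level behaviour
#' schedule. During `all_recumbent` episodes every animal moves only by
#' detection jitter; during `some_active` episodes exactly
#' `scenario$n_active` animals (re-drawn at each episode start) move with
#' speeds from the active distribution and are flagged standing.
#' Trajectories reflect off the pen walls so the configured speed
#' distribution is preserved; any residual out-of-bound position is
#' clamped to the pen and counted in a message.
#'
#' The ground-truth ethogram codes the group state at every image
#' sampling instant: 0 when all pigs are recumbent, 1 when at least one
#' pig is standing or moving.
#'
#' @param pen A [pen_config()].
#' @param scenario A [behavior_scenario()].
#' @param duration_s Total simulated duration in seconds; the schedule
#'   must cover it.
#'
#' @return A list with elements `frames` (tibble: `pen_id`, `t_s`,
#'   `animal_id`, `x_m`, `y_m`, `detected_standing`) and `ethogram`
#'   (tibble: `pen_id`, `t_s`, `code`).
#' @export
#' @examples
#' pen <- pen_config(n_animals = 4, sampling_interval_s = 60)
#' sc <- behavior_scenario(data.frame(start_s = c(0, 120),
#'                                    state = c("all_recumbent", "some_active")))
#' sim <- simulate_trajectories(pen, sc, duration_s = 240)
#' head(sim$frames)
#' sim$ethogram
simulate_trajectories <- function(pen, scenario, duration_s) {
  stop_if_not(inherits(pen, "pen_config"), "pen must be a pen_config")
  stop_if_not(inherits(scenario, "behavior_scenario"), "scenario must be a behavior_scenario")
  stop_if_not(is_scalar_number(duration_s) && duration_s > 0, "duration_s must be > 0")
  sched <- scenario$state_schedule
  stop_if_not(sched$start_s[1] <= 0, "schedule does not cover the requested duration")

  n_frames <- floor(duration_s / pen$frame_interval_s)
  stop_if_not(n_frames >= 1, "duration shorter than one frame interval")
  t_s <- pen$frame_interval_s * (seq_len(n_frames) - 1)
  n <- pen$n_animals
  state <- schedule_state_at(sched, t_s)
  active_state <- state == "some_active"
  stop_if_not(scenario$n_active <= n, "n_active exceeds the group size")

  sim <- with_seed(scenario$seed, {
    # Active-animal set is fixed within an episode, re-drawn at each start.
    episode <- cumsum(c(TRUE, state[-1] != state[-n_frames]))
    active_mask <- matrix(FALSE, n_frames, n)
    for (ep in unique(episode[active_state])) {
      rows <- episode == ep
      ids <- sample.int(n, scenario$n_active)
      active_mask[rows, ids] <- TRUE
    }

    speed <- matrix(rnorm(n_frames * n, scenario$jitter_speed_mean,
                          scenario$jitter_speed_sd), n_frames, n)
    if (any(active_mask)) {
      speed[active_mask] <- rnorm(sum(active_mask), scenario$active_speed_mean,
                                  scenario$active_speed_sd)
    }
    speed[speed < 0] <- 0
    step <- speed * pen$frame_interval_s

    x <- matrix(0, n_frames, n)
    y <- matrix(0, n_frames, n)
    x[1, ] <- runif(n, 0, pen$width_m)
    y[1, ] <- runif(n, 0, pen$height_m)
    n_clamped <- 0L
    if (n_frames > 1L) {
      for (k in 2:n_frames) {
        # Frame k's position results from the step taken during (t[k-1], t[k]].
        adv <- advance_positions(x[k - 1L, ], y[k - 1L, ], step[k, ],
                                 pen$width_m, pen$height_m)
        x[k, ] <- adv$x
        y[k, ] <- adv$y
        n_clamped <- n_clamped + adv$n_clamped
      }
    }
    if (n_clamped > 0) log_msg("clamped %d out-of-pen positions", n_clamped)
    x <- pmin(pmax(x, 0), pen$width_m)
    y <- pmin(pmax(y, 0), pen$height_m)

    standing <- active_mask
    false_det <- matrix(rbinom(n_frames * n, 1L, scenario$false_detection_rate) == 1L,
                        n_frames, n)
    standing[!active_mask] <- false_det[!active_mask]
    list(x = x, y = y, standing = standing)
  })

  frames <- tibble::tibble(
    pen_id = pen$pen_id,
    t_s = rep(t_s, times = n),
    animal_id = rep(seq_len(n), each = n_frames),
    x_m = as.vector(sim$x),
    y_m = as.vector(sim$y),
    detected_standing = as.integer(as.vector(sim$standing))
  )
  frames <- dplyr::arrange(frames, .data$t_s, .data$animal_id)

  t_sample <- seq(0, duration_s - pen$frame_interval_s, by = pen$sampling_interval_s)
  ethogram <- tibble::tibble(
    pen_id = pen$pen_id,
    t_s = t_sample,
    code = as.integer(schedule_state_at(sched, t_sample) == "some_active")
  )

  structure(list(frames = frames, ethogram = ethogram, pen = pen,
                 scenario = scenario, duration_s = duration_s),
            class = "recumbency_sim")
}
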