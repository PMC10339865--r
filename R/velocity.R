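#' Cumulative group velocity of one frame pair
#'
#' The activity signal of a pen between two consecutive tracked frames:
#' the Euclidean displacements of all animals flagged as standing are
#' summed and divided by the time interval, giving a group velocity in
#' m/s. The standing flag is taken from the later frame of the pair (a
#' fixed convention). Animals present in only one of the two frames
#' contribute zero displacement and are counted in a message.
#'
#' @param prev,curr Data frames for the earlier and later frame, with
#'   columns `animal_id`, `x_m`, `y_m`, `detected_standing` and
#'   (optionally) `pen_id` and `t_s`. Each must describe a single frame.
#' @param dt_s Time interval in seconds; taken from the frames' `t_s`
#'   columns when omitted.
#'
#' @return Group velocity in m/s (a single nonnegative number).
#' @export
#' @examples
#' f0 <- data.frame(animal_id = 1:2, x_m = c(0, 1), y_m = c(0, 1),
#'                  detected_standing = c(1, 0), t_s = 0)
#' f1 <- data.frame(animal_id = 1:2, x_m = c(0.3, 1), y_m = c(0.4, 1),
#'                  detected_standing = c(1, 0), t_s = 1)
#' pair_velocity(f0, f1)  # 0.5 m/s: a 3-4-5 displacement over 1 s
pair_velocity <- function(prev, curr, dt_s = NULL) {
  stop_if_not(nrow(prev) > 0 && nrow(curr) > 0, "empty frames are not allowed")
  if ("pen_id" %in% names(prev) && "pen_id" %in% names(curr)) {
    stop_if_not(identical(unique(prev$pen_id), unique(curr$pen_id)),
                "frames belong to different pens")
  }
  if (is.null(dt_s)) {
    stop_if_not(all(c("t_s") %in% names(prev)) && "t_s" %in% names(curr),
                "dt_s missing and frames carry no t_s column")
    dt_s <- unique(curr$t_s) - unique(prev$t_s)
  }
  stop_if_not(is_scalar_number(dt_s) && dt_s > 0, "time interval must be positive")
  stop_if_not(!anyDuplicated(prev$animal_id) && !anyDuplicated(curr$animal_id),
              "animal ids must be unique within a frame")
  standing <- curr[curr$detected_standing == 1, , drop = FALSE]
  m <- match(standing$animal_id, prev$animal_id)
  if (anyNA(m)) log_msg("%d standing animals missing from previous frame contribute 0",
                        sum(is.na(m)))
  ok <- !is.na(m)
  disp <- sqrt((standing$x_m[ok] - prev$x_m[m[ok]])^2 +
                 (standing$y_m[ok] - prev$y_m[m[ok]])^2)
  sum(disp) / dt_s
}

#' Per-pair group velocities of a whole tracked stream
#'
#' Vectorised application of [pair_velocity()] over a multi-pen position
#' stream: within each pen, every consecutive frame pair yields one group
#' velocity, timestamped at the later frame. An animal contributes to a
#' pair only if it was observed at the pen's immediately preceding frame
#' time; others contribute zero (counted in a message).
#'
#' @param frames Tibble with columns `pen_id`, `t_s`, `animal_id`, `x_m`,
#'   `y_m`, `detected_standing` (as produced by
#'   [simulate_trajectories()]).
#'
#' @return Tibble with columns `pen_id`, `t_s` (later frame of the pair)
#'   and `v_mps`, carrying each pen's first frame time in the
#'   `stream_start` attribute (a named vector used for window alignment).
#' @export
compute_group_velocity <- function(frames) {
  needed <- c("pen_id", "t_s", "animal_id", "x_m", "y_m", "detected_standing")
  stop_if_not(all(needed %in% names(frames)), "frames missing required columns")
  stop_if_not(nrow(frames) > 0, "empty frames are not allowed")

  frame_times <- frames |>
    dplyr::distinct(.data$pen_id, .data$t_s) |>
    dplyr::arrange(.data$pen_id, .data$t_s) |>
    dplyr::group_by(.data$pen_id) |>
    dplyr::mutate(t_prev = dplyr::lag(.data$t_s)) |>
    dplyr::ungroup()
  stop_if_not(all(frame_times$t_prev < frame_times$t_s, na.rm = TRUE),
              "t_s must be strictly increasing within a pen")

  d <- frames |>
    dplyr::arrange(.data$pen_id, .data$animal_id, .data$t_s) |>
    dplyr::group_by(.data$pen_id, .data$animal_id) |>
    dplyr::mutate(x_prev = dplyr::lag(.data$x_m),
                  y_prev = dplyr::lag(.data$y_m),
                  t_obs_prev = dplyr::lag(.data$t_s)) |>
    dplyr::ungroup() |>
    dplyr::left_join(frame_times, by = c("pen_id", "t_s")) |>
    dplyr::filter(!is.na(.data$t_prev))  # first frame of each pen has no pair

  # Valid displacement only when the animal was seen at the previous frame.
  gap <- !is.na(d$t_obs_prev) & d$t_obs_prev < d$t_prev
  missing_prev <- is.na(d$t_obs_prev) | gap
  n_gap <- sum(missing_prev & d$detected_standing == 1)
  if (n_gap > 0) log_msg("%d standing animal-frames lack a previous observation; contribute 0",
                         n_gap)
  disp <- ifelse(d$detected_standing == 1 & !missing_prev,
                 sqrt((d$x_m - d$x_prev)^2 + (d$y_m - d$y_prev)^2), 0)

  out <- tibble::tibble(pen_id = d$pen_id, t_s = d$t_s,
                        dt = d$t_s - d$t_prev, disp = disp) |>
    dplyr::group_by(.data$pen_id, .data$t_s, .data$dt) |>
    dplyr::summarise(disp = sum(.data$disp), .groups = "drop") |>
    dplyr::mutate(v_mps = .data$disp / .data$dt) |>
    dplyr::select("pen_id", "t_s", "v_mps") |>
    dplyr::arrange(.data$pen_id, .data$t_s)

  starts <- tapply(frames$t_s, frames$pen_id, min)
  attr(out, "stream_start") <- stats::setNames(as.numeric(starts), names(starts))
  out
}

#' Summarise pair velocities over fixed windows
#'
#' Aggregates per-pair group velocities into half-open windows
#' `[start, start + window_s)` aligned to each pen's stream start; the
#' window summary is the arithmetic mean of the pair velocities it
#' contains (the 5-minute average velocity, with the default
#' `window_s = 300`). Windows without any frame pair are retained with
#' `n_frame_pairs = 0` and a missing `v_mps`.
#'
#' @param velocities Output of [compute_group_velocity()], or any tibble
#'   with `pen_id`, `t_s`, `v_mps`.
#' @param window_s Window length in seconds (default 300 = 5 min).
#' @param origin Optional named vector of per-pen window origins;
#'   defaults to the `stream_start` attribute, falling back to each pen's
#'   first pair timestamp.
#'
#' @return Tibble of velocity records: `pen_id`, `window_start_s`,
#'   `window_end_s`, `v_mps`, `n_frame_pairs`.
#' @export
summarize_windows <- function(velocities, window_s = 300, origin = NULL) {
  stop_if_not(all(c("pen_id", "t_s", "v_mps") %in% names(velocities)),
              "velocities missing required columns")
  stop_if_not(is_scalar_number(window_s) && window_s > 0, "window_s must be > 0")
  origin <- origin %||% attr(velocities, "stream_start")

  per_pen <- function(d) {
    pen <- d$pen_id[1]
    o <- if (!is.null(origin) && pen %in% names(origin)) origin[[pen]] else min(d$t_s)
    idx <- floor((d$t_s - o) / window_s)
    stop_if_not(all(idx >= 0), "timestamps precede the window origin")
    all_idx <- 0:max(idx)
    v <- tapply(d$v_mps, factor(idx, levels = all_idx), mean)
    n <- tapply(d$v_mps, factor(idx, levels = all_idx), length)
    tibble::tibble(pen_id = pen,
                   window_start_s = o + all_idx * window_s,
                   window_end_s = o + (all_idx + 1) * window_s,
                   v_mps = as.numeric(v),
                   n_frame_pairs = as.integer(ifelse(is.na(n), 0L, n)))
  }
  velocities |>
    dplyr::group_by(.data$pen_id) |>
    dplyr::group_split() |>
    lapply(per_pen) |>
    dplyr::bind_rows()
}

#' Link labelled images to their velocity windows
#'
#' Joins each consensus-coded image to the velocity window containing its
#' timestamp, by pen and time, producing the classification dataset: one
#' row per usable image with its window's group velocity. Images falling
#' in empty windows (no frame pairs) or outside all windows are dropped
#' and counted in a message.
#'
#' @param records Velocity records from [summarize_windows()].
#' @param labels Tibble with `pen_id`, `t_s`, `code` and optionally
#'   `blur_score`; `(pen_id, t_s)` must be unique.
#'
#' @return Tibble of linked samples: `pen_id`, `t_s`, `v_mps`, `code` and
#'   `blur_score` (NA when labels carry none), with the number of dropped
#'   labels in the `n_dropped` attribute.
#' @export
link_samples <- function(records, labels) {
  stop_if_not(all(c("pen_id", "window_start_s", "window_end_s", "v_mps",
                    "n_frame_pairs") %in% names(records)),
              "records missing required columns")
  stop_if_not(all(c("pen_id", "t_s", "code") %in% names(labels)),
              "labels missing required columns")
  stop_if_not(!anyDuplicated(labels[c("pen_id", "t_s")]),
              "duplicate (pen_id, t_s) labels")
  if (!"blur_score" %in% names(labels)) labels$blur_score <- NA_real_

  empty <- cbind(labels[0, c("pen_id", "t_s", "code", "blur_score")],
                 v_mps = numeric(0))
  out <- lapply(split(labels, labels$pen_id), function(lab) {
    rec <- records[records$pen_id == lab$pen_id[1], , drop = FALSE]
    rec <- rec[order(rec$window_start_s), , drop = FALSE]
    if (nrow(rec) == 0) {
      return(cbind(lab[0, c("pen_id", "t_s", "code", "blur_score")],
                   v_mps = numeric(0)))
    }
    i <- findInterval(lab$t_s, rec$window_start_s)
    ok <- i >= 1 & lab$t_s < rec$window_end_s[pmax(i, 1L)] &
      rec$n_frame_pairs[pmax(i, 1L)] > 0
    cbind(lab[ok, c("pen_id", "t_s", "code", "blur_score")],
          v_mps = rec$v_mps[i[ok]])
  })
  out <- tibble::as_tibble(do.call(rbind, c(list(empty), out)))
  n_dropped <- nrow(labels) - nrow(out)
  if (n_dropped > 0) log_msg("link: dropped %d labels without a covering window", n_dropped)
  out <- out[c("pen_id", "t_s", "v_mps", "code", "blur_score")]
  attr(out, "n_dropped") <- n_dropped
  out
}
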