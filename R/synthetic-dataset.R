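#' Generate a complete labelled synthetic dataset
#'
#' Runs the trajectory generator for a set of pens, renders one synthetic
#' image per ethogram sampling instant across a ladder of blur widths,
#' and produces two coder label tables: coder A equals the ground truth,
#' coder B differs on a seeded random subset, emulating independent
#' binary coding by two observers.
#'
#' Disagreements can be seeded in two ways: `disagreement_rate` flips
#' each of coder B's codes independently with that probability
#' (binomially distributed disagreement count), while `n_disagreements`
#' flips an exact number of randomly chosen codes (useful to reproduce a
#' stated discrepancy count).
#'
#' @param pens List of [pen_config()]s.
#' @param scenarios List of [behavior_scenario()]s, one per pen.
#' @param duration_s Simulated duration in seconds.
#' @param image_spec Optional [synthetic_image_spec()] template for the
#'   sampled images; `NULL` skips image generation.
#' @param blur_sigmas Blur widths recycled over the sampled images.
#' @param disagreement_rate Per-label flip probability for coder B.
#' @param n_disagreements Exact number of coder-B flips; overrides
#'   `disagreement_rate`.
#' @param seed Integer seed for the coder-B flips and per-image seeds.
#'
#' @return List with `frames`, `ethogram` (ground truth), `images` (list
#'   of [image_record()]s or `NULL`), `coder_a`, `coder_b` (tibbles:
#'   `pen_id`, `t_s`, `coder_id`, `code`) and `summary` (label count,
#'   class balance, seeded disagreements).
#' @export
#' @examples
#' pen <- pen_config(n_animals = 3, sampling_interval_s = 120)
#' sc <- behavior_scenario(data.frame(start_s = c(0, 300),
#'                                    state = c("all_recumbent", "some_active")))
#' ds <- simulate_labeled_dataset(list(pen), list(sc), duration_s = 600,
#'                                disagreement_rate = 0)
#' ds$summary
simulate_labeled_dataset <- function(pens, scenarios, duration_s,
                                     image_spec = NULL,
                                     blur_sigmas = c(0, 0.5, 1, 2, 4),
                                     disagreement_rate = 0,
                                     n_disagreements = NULL,
                                     seed = 123L) {
  stop_if_not(length(pens) == length(scenarios), "one scenario per pen is required")
  stop_if_not(disagreement_rate >= 0 && disagreement_rate <= 1,
              "disagreement_rate must lie in [0, 1]")
  sims <- Map(simulate_trajectories, pens, scenarios, MoreArgs = list(duration_s = duration_s))
  frames <- dplyr::bind_rows(lapply(sims, `[[`, "frames"))
  ethogram <- dplyr::bind_rows(lapply(sims, `[[`, "ethogram"))
  starts <- unlist(lapply(sims, function(s) {
    stats::setNames(min(s$frames$t_s), s$pen$pen_id)
  }))

  images <- NULL
  if (!is.null(image_spec)) {
    sig <- rep_len(blur_sigmas, nrow(ethogram))
    images <- lapply(seq_len(nrow(ethogram)), function(i) {
      sp <- image_spec
      sp$blur_sigma <- sig[i]
      sp$seed <- image_spec$seed + i
      simulate_image(sp, pen_id = ethogram$pen_id[i], t_s = ethogram$t_s[i])
    })
  }

  n <- nrow(ethogram)
  coder_a <- tibble::tibble(pen_id = ethogram$pen_id, t_s = ethogram$t_s,
                            coder_id = "A", code = ethogram$code)
  flip <- with_seed(seed, {
    if (!is.null(n_disagreements)) {
      stop_if_not(is_count(n_disagreements) && n_disagreements <= n,
                  "n_disagreements must be a count <= number of labels")
      idx <- sample.int(n, n_disagreements)
      seq_len(n) %in% idx
    } else {
      rbinom(n, 1L, disagreement_rate) == 1L
    }
  })
  coder_b <- coder_a
  coder_b$coder_id <- "B"
  coder_b$code <- ifelse(flip, 1L - coder_a$code, coder_a$code)

  summary <- list(n_labels = n,
                  n_code1 = sum(ethogram$code == 1),
                  n_code0 = sum(ethogram$code == 0),
                  n_disagreements = sum(flip),
                  n_frames = nrow(frames))
  list(frames = frames, ethogram = ethogram, images = images,
       coder_a = coder_a, coder_b = coder_b,
       stream_start = starts, summary = summary)
}
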