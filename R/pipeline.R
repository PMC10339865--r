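#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run: the synthetic-herd
#' layout, the behaviour schedule, window length, blur cutoff, fitting
#' method and cross-validation settings. The configuration round-trips
#' through YAML via [read_run_config()].
#'
#' @param out_dir Directory for all stage artifacts (created if needed).
#' @param n_pens Number of pens to simulate.
#' @param duration_s Simulated duration per pen, seconds.
#' @param state_period_s Length of each alternating behaviour episode,
#'   seconds (episodes alternate all-recumbent / some-active).
#' @param frame_interval_s,sampling_interval_s,n_animals Passed to
#'   [pen_config()].
#' @param window_s Velocity summarisation window, seconds.
#' @param blur_cutoff Laplacian-variance keep threshold.
#' @param blur_sigmas Blur ladder recycled over sampled images.
#' @param image_size_px Synthetic image size, `c(rows, cols)`.
#' @param disagreement_rate Coder-B flip probability.
#' @param method Threshold fitting method, see [fit_threshold()].
#' @param k Cross-validation folds.
#' @param seed Master seed; every stochastic stage derives from it.
#'
#' @return A `run_config` list.
#' @export
pipeline_config <- function(out_dir,
                            n_pens = 4L,
                            duration_s = 6 * 3600,
                            state_period_s = 1800,
                            frame_interval_s = 1,
                            sampling_interval_s = 1200,
                            n_animals = 18L,
                            window_s = 300,
                            blur_cutoff = 1000,
                            blur_sigmas = c(0, 0.5, 1, 2, 4),
                            image_size_px = c(64L, 64L),
                            disagreement_rate = 0.025,
                            method = "exhaustive",
                            k = 10L,
                            seed = 123L) {
  structure(list(out_dir = out_dir, n_pens = as.integer(n_pens),
                 duration_s = duration_s, state_period_s = state_period_s,
                 frame_interval_s = frame_interval_s,
                 sampling_interval_s = sampling_interval_s,
                 n_animals = as.integer(n_animals),
                 window_s = window_s, blur_cutoff = blur_cutoff,
                 blur_sigmas = blur_sigmas,
                 image_size_px = as.integer(image_size_px),
                 disagreement_rate = disagreement_rate,
                 method = method, k = as.integer(k), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; missing keys take the defaults.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  stop_if_not(!is.null(y$out_dir), "config must provide out_dir")
  do.call(pipeline_config, y)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full recumbency-detection pipeline
#'
#' Executes the stage chain simulate -> blur QC -> consensus coding ->
#' velocity aggregation -> linking -> threshold fit -> cross-validated
#' evaluation, writing every stage's artifact (CSV/PNG/JSON) under
#' `config$out_dir` plus a `manifest.json` with input hashes, stage
#' counts and the final average metrics. Identical configuration and
#' seed produce byte-identical reports. A stage failure aborts with the
#' stage named; artifacts of completed stages are retained.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @param write_images Write sampled frames as PNGs (default TRUE);
#'   scoring always runs on the in-memory pixel grids.
#'
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, write_images = TRUE) {
  stop_if_not(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(config$out_dir, "images")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)
  path <- function(...) file.path(config$out_dir, ...)

  # -- simulate ---------------------------------------------------------
  ds <- run_stage("simulate", {
    pens <- lapply(seq_len(config$n_pens), function(i) {
      pen_config(pen_id = sprintf("pen%02d", i),
                 n_animals = config$n_animals,
                 frame_interval_s = config$frame_interval_s,
                 sampling_interval_s = config$sampling_interval_s)
    })
    n_states <- ceiling(config$duration_s / config$state_period_s)
    schedule <- data.frame(
      start_s = config$state_period_s * (seq_len(n_states) - 1),
      state = rep_len(c("all_recumbent", "some_active"), n_states))
    scenarios <- lapply(seq_len(config$n_pens), function(i) {
      behavior_scenario(schedule, seed = config$seed + i)
    })
    spec <- synthetic_image_spec(size_px = config$image_size_px,
                                 seed = config$seed)
    simulate_labeled_dataset(pens, scenarios, config$duration_s,
                             image_spec = spec,
                             blur_sigmas = config$blur_sigmas,
                             disagreement_rate = config$disagreement_rate,
                             seed = config$seed)
  })
  write_table_csv(ds$frames, path("trajectories.csv"))
  write_table_csv(ds$ethogram, path("ethogram.csv"))
  write_table_csv(ds$coder_a, path("coder_a.csv"))
  write_table_csv(ds$coder_b, path("coder_b.csv"))

  # -- blur QC ----------------------------------------------------------
  blur_manifest <- run_stage("blur_qc", {
    images <- score_images(ds$images)
    if (write_images) {
      for (img in images) {
        write_image_png(img, file.path(img_dir,
                                       sprintf("%s_%s.png", img$pen_id, img$t_s)))
      }
    }
    tibble::tibble(
      filename = vapply(images, function(i) sprintf("%s_%s.png", i$pen_id, i$t_s), ""),
      pen_id = vapply(images, `[[`, "", "pen_id"),
      t_s = vapply(images, `[[`, numeric(1), "t_s"),
      blur_score = vapply(images, `[[`, numeric(1), "blur_score"),
      kept = as.integer(vapply(images, `[[`, numeric(1), "blur_score") >=
                          config$blur_cutoff))
  })
  write_table_csv(blur_manifest, path("blur_manifest.csv"))

  # -- consensus coding -------------------------------------------------
  consensus <- run_stage("coding", {
    agreement <- intercoder_agreement(ds$coder_a, ds$coder_b)
    cons <- build_consensus(ds$coder_a, ds$coder_b, resolution = ds$ethogram)
    attr(cons, "agreement_pct") <- agreement
    cons
  })
  write_table_csv(consensus, path("consensus.csv"))

  # -- velocity ---------------------------------------------------------
  records <- run_stage("velocity", {
    pv <- compute_group_velocity(ds$frames)
    summarize_windows(pv, window_s = config$window_s, origin = ds$stream_start)
  })
  write_table_csv(records, path("velocity.csv"))

  # -- link -------------------------------------------------------------
  linked <- run_stage("link", {
    kept <- blur_manifest[blur_manifest$kept == 1, c("pen_id", "t_s", "blur_score")]
    labels <- dplyr::inner_join(consensus[c("pen_id", "t_s", "code")], kept,
                                by = c("pen_id", "t_s"))
    link_samples(records, labels)
  })
  write_table_csv(linked, path("linked.csv"))

  # -- fit --------------------------------------------------------------
  model <- run_stage("fit", fit_threshold(linked, method = config$method))
  write_model_json(model, path("model.json"))

  # -- evaluate ---------------------------------------------------------
  report <- run_stage("evaluate", {
    cv <- cross_validate(linked, k = config$k, seed = config$seed,
                         method = config$method)
    tt <- velocity_ttest(linked)
    list(cv = cv, ttest = tt)
  })
  jsonlite::write_json(
    list(seed = config$seed, k = config$k, method = config$method,
         n_samples = nrow(linked),
         per_fold = report$cv$per_fold,
         averages = as.list(report$cv$averages),
         ttest = report$ttest[c("t", "df", "p_value", "mean_active",
                                "mean_recumbent", "significant")]),
    path("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest ---------------------------------------------------------
  artifact_files <- c("trajectories.csv", "ethogram.csv", "coder_a.csv",
                      "coder_b.csv", "blur_manifest.csv", "consensus.csv",
                      "velocity.csv", "linked.csv", "model.json", "report.json")
  hashes <- as.list(tools::md5sum(vapply(artifact_files, path, "")))
  names(hashes) <- artifact_files
  n_labels <- nrow(consensus)
  n_dropped_qc <- n_labels - sum(blur_manifest$kept)
  n_dropped_unmatched <- attr(linked, "n_dropped") %||% 0L
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    intercoder_agreement_pct = attr(consensus, "agreement_pct"),
    counts = list(labels_in = n_labels,
                  images_kept = sum(blur_manifest$kept),
                  dropped_by_qc = n_dropped_qc,
                  dropped_unmatched = n_dropped_unmatched,
                  linked = nrow(linked)),
    threshold_mps = model$threshold_mps,
    average_metrics = as.list(report$cv$averages),
    files = hashes)
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
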