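# Plain-text artifact I/O: CSV tables, 8-bit grayscale PNG images,
# JSON models/reports. Column layouts are the package's stable external
# interfaces.

#' Write and read pipeline CSV artifacts
#'
#' Thin wrappers around `write.csv`/`read.csv` pinning the column layouts
#' of the pipeline's tabular artifacts: trajectories (`pen_id`, `t_s`,
#' `animal_id`, `x_m`, `y_m`, `detected_standing`), ethogram/label tables
#' (`pen_id`, `t_s`, `code`, ...), velocity records and linked samples.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_table_csv` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an image record as an 8-bit grayscale PNG
#'
#' Pixels on the 0-255 scale are clamped and quantised to 8 bits. The
#' conventional filename is `<pen>_<t_s>.png`.
#'
#' @param img An [image_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  stop_if_not(inherits(img, "image_record"), "img must be an image_record")
  px <- pmin(pmax(img$pixels, 0), 255)
  png::writePNG(round(px) / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG into an image record
#'
#' @param path PNG path.
#' @param pen_id,t_s Metadata; parsed from a `<pen>_<t_s>.png` filename
#'   when omitted.
#' @return An [image_record()] with pixels on the 0-255 scale.
#' @export
read_image_png <- function(path, pen_id = NULL, t_s = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  base <- sub("\\.png$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(pen_id)) pen_id <- paste(utils::head(parts, -1), collapse = "_")
  if (is.null(t_s)) t_s <- suppressWarnings(as.numeric(parts[length(parts)]))
  image_record(pen_id, t_s, px * 255)
}

#' Write a threshold model to JSON
#'
#' @param model A [threshold_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stop_if_not(inherits(model, "threshold_model"), "model must be a threshold_model")
  jsonlite::write_json(list(threshold_mps = model$threshold_mps,
                            rule = model$rule,
                            method = model$method,
                            fitted_on_n = model$fitted_on_n),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a threshold model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return A [threshold_model()].
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_model(x$threshold_mps, x$method, fitted_on_n = x$fitted_on_n)
}
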