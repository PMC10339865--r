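#' Laplacian-variance blur score
#'
#' Scores image sharpness as the population variance of the discrete
#' Laplacian response. The image is convolved with the 3x3 Laplacian
#' kernel (centre -4, 4-neighbours +1, corners 0) and the variance of the
#' response over valid interior pixels is returned; no border padding is
#' used, so the score depends only on fully supported responses. Sharp
#' images with many edges score high, blurred images low.
#'
#' Intensities are treated as floating point before convolution (the -4
#' centre tap would saturate 8-bit arithmetic). Colour input (a 3-slice
#' array) is converted to grayscale with luma weights 0.299/0.587/0.114
#' and a message is emitted.
#'
#' @param image An [image_record()], a numeric matrix of grayscale
#'   intensities, or a rows x cols x 3 colour array. Must be at least
#'   3 x 3.
#'
#' @return A single nonnegative score.
#' @export
#' @examples
#' laplacian_variance(matrix(5, 10, 10))      # constant image scores 0
laplacian_variance <- function(image) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  if (is.array(px) && length(dim(px)) == 3L) {
    stop_if_not(dim(px)[3] %in% c(3L, 4L), "colour input must have 3 (or 4) channels")
    log_msg("converting colour input to grayscale (luma 0.299/0.587/0.114)")
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  stop_if_not(is.matrix(px) && is.numeric(px), "image must be a numeric matrix")
  nr <- nrow(px); nc <- ncol(px)
  stop_if_not(nr >= 3 && nc >= 3, "image smaller than the 3x3 Laplacian kernel")
  px <- matrix(as.numeric(px), nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  lap <- px[i - 1, j] + px[i + 1, j] + px[i, j - 1] + px[i, j + 1] - 4 * px[i, j]
  mean((lap - mean(lap))^2)  # population variance over interior responses
}

#' Score a batch of image records
#'
#' @param images List of [image_record()]s.
#' @return The same list with `blur_score` filled in.
#' @export
score_images <- function(images) {
  lapply(images, function(img) {
    stop_if_not(inherits(img, "image_record"), "images must be image_records")
    img$blur_score <- laplacian_variance(img)
    img
  })
}

#' Partition images into sharp and blurred
#'
#' Applies the blur-QC rule: an image is kept if and only if its
#' Laplacian-variance score is at least `cutoff`; images scoring strictly
#' lower are considered blurred and excluded from analysis.
#'
#' The default cutoff of 1000 is tied to the scoring configuration
#' (kernel, border convention, 8-bit intensity scale) and should be
#' treated as a tunable, not a portable constant.
#'
#' @param records Either a list of scored [image_record()]s or a data
#'   frame with a `blur_score` column.
#' @param cutoff Minimum score to keep (default 1000).
#'
#' @return A list with elements `kept` and `excluded`, each the same type
#'   as `records`; counts are reported in a message.
#' @export
filter_blurred <- function(records, cutoff = 1000) {
  stop_if_not(is_scalar_number(cutoff), "cutoff must be a number")
  scores <- if (is.data.frame(records)) {
    stop_if_not("blur_score" %in% names(records), "records need a blur_score column")
    records$blur_score
  } else {
    vapply(records, function(r) {
      stop_if_not(inherits(r, "image_record"), "records must be image_records")
      r$blur_score
    }, numeric(1))
  }
  stop_if_not(!anyNA(scores), "all records must be scored before filtering")
  keep <- scores >= cutoff
  log_msg("blur QC: kept %d of %d images (cutoff %g)", sum(keep), length(keep), cutoff)
  if (is.data.frame(records)) {
    list(kept = records[keep, , drop = FALSE],
         excluded = records[!keep, , drop = FALSE])
  } else {
    list(kept = records[keep], excluded = records[!keep])
  }
}
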