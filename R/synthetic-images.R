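#' Synthetic image specification
#'
#' Parameters for a procedurally generated grayscale test scene: a flat
#' background carrying `shape_count` random rectangles (sharp edges, the
#' signal the Laplacian blur score responds to), optionally smoothed by a
#' Gaussian blur of width `blur_sigma` to emulate a soiled camera lens.
#'
#' @param shape_count Number of random rectangles drawn on the
#'   background; 0 yields a constant image.
#' @param intensity_range Two-element numeric range of pixel intensities
#'   (8-bit scale, default `c(0, 255)`).
#' @param blur_sigma Nonnegative Gaussian blur standard deviation in
#'   pixels; 0 means no blur.
#' @param size_px Image size as `c(rows, cols)`, each at least 8.
#' @param seed Integer seed; the unblurred base scene is fully determined
#'   by `seed`, `size_px`, `shape_count` and `intensity_range`, so the
#'   same seed with different `blur_sigma` blurs the same scene.
#'
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(shape_count = 40L,
                                 intensity_range = c(0, 255),
                                 blur_sigma = 0,
                                 size_px = c(64L, 64L),
                                 seed = 123L) {
  stop_if_not(is_count(shape_count), "shape_count must be a nonnegative count")
  stop_if_not(is.numeric(intensity_range) && length(intensity_range) == 2L &&
                intensity_range[1] <= intensity_range[2],
              "intensity_range must be an increasing pair")
  stop_if_not(is_scalar_number(blur_sigma) && blur_sigma >= 0, "blur_sigma must be >= 0")
  stop_if_not(length(size_px) == 2L && all(size_px >= 8), "size_px must be >= (8, 8)")
  structure(list(shape_count = as.integer(shape_count),
                 intensity_range = as.numeric(intensity_range),
                 blur_sigma = blur_sigma,
                 size_px = as.integer(size_px),
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Separable Gaussian blur with replicated edges; kernel radius 3*sigma.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (off in (-r):r) {
      idx <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[off + r + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

#' Construct an image record
#'
#' Container for one sampled camera frame: pen, timestamp, pixel grid and
#' (once scored) its Laplacian-variance blur score.
#'
#' @param pen_id Pen label.
#' @param t_s Timestamp in seconds.
#' @param pixels Numeric matrix of grayscale intensities.
#' @param blur_score Laplacian variance, `NA` until scored.
#'
#' @return An `image_record` list.
#' @export
image_record <- function(pen_id, t_s, pixels, blur_score = NA_real_) {
  stop_if_not(is.matrix(pixels), "pixels must be a matrix")
  structure(list(pen_id = pen_id, t_s = t_s, pixels = pixels,
                 blur_score = blur_score),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> pen %s, t = %g s, %d x %d px, blur score %s\n",
              x$pen_id, x$t_s, nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$blur_score), "unscored", format(x$blur_score))))
  invisible(x)
}

#' Generate a synthetic grayscale image
#'
#' Renders the scene described by a [synthetic_image_spec()]:
#' deterministic for a fixed seed, and applying a larger `blur_sigma` to
#' the same base scene never increases its expected Laplacian variance.
#' Pixels are kept as floating point on the 8-bit intensity scale;
#' quantisation happens only when writing PNG files.
#'
#' @param spec A [synthetic_image_spec()].
#' @param pen_id,t_s Metadata attached to the record.
#'
#' @return An [image_record()] (blur score unset).
#' @export
#' @examples
#' img <- simulate_image(synthetic_image_spec(seed = 1))
#' laplacian_variance(img)
simulate_image <- function(spec, pen_id = "pen1", t_s = 0) {
  stop_if_not(inherits(spec, "synthetic_image_spec"), "spec must be a synthetic_image_spec")
  nr <- spec$size_px[1]; nc <- spec$size_px[2]
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  base <- with_seed(spec$seed, {
    m <- matrix(mean(c(lo, hi)), nr, nc)
    for (i in seq_len(spec$shape_count)) {
      r0 <- sample.int(nr, 1L); c0 <- sample.int(nc, 1L)
      h <- sample.int(max(2L, nr %/% 4L), 1L)
      w <- sample.int(max(2L, nc %/% 4L), 1L)
      val <- runif(1, lo, hi)
      m[r0:min(nr, r0 + h), c0:min(nc, c0 + w)] <- val
    }
    m
  })
  image_record(pen_id, t_s, gaussian_blur(base, spec$blur_sigma))
}

#' Generate a blur ladder
#'
#' The same base scene rendered at a sequence of Gaussian blur widths,
#' used to exercise the monotonicity of the blur score.
#'
#' @param spec A [synthetic_image_spec()]; its `blur_sigma` is ignored.
#' @param sigmas Numeric vector of blur widths.
#' @inheritParams simulate_image
#'
#' @return A list of [image_record()]s, one per sigma.
#' @export
simulate_blur_ladder <- function(spec, sigmas, pen_id = "pen1", t_s = 0) {
  lapply(sigmas, function(s) {
    sp <- spec
    sp$blur_sigma <- s
    simulate_image(sp, pen_id = pen_id, t_s = t_s)
  })
}
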