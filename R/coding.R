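#' Intercoder agreement of two binary coders
#'
#' Percentage of observation units (images keyed by pen and timestamp)
#' assigned identical codes by two independent observers. Both tables
#' must cover exactly the same keys; a mismatch is rejected with the
#' differing keys listed.
#'
#' @param codes_a,codes_b Tibbles with columns `pen_id`, `t_s`, `code`
#'   (codes in {0, 1}).
#'
#' @return Percent agreement in `[0, 100]` (full precision; round at
#'   report time). Symmetric in the two coders.
#' @export
#' @examples
#' a <- data.frame(pen_id = "p1", t_s = 1:4, code = c(0, 1, 1, 0))
#' b <- a; b$code[2] <- 0
#' intercoder_agreement(a, b)  # 75
intercoder_agreement <- function(codes_a, codes_b) {
  check_code_table(codes_a); check_code_table(codes_b)
  key <- function(d) paste(d$pen_id, d$t_s, sep = "\r")
  ka <- key(codes_a); kb <- key(codes_b)
  stop_if_not(!anyDuplicated(ka) && !anyDuplicated(kb), "duplicate (pen_id, t_s) keys")
  extra <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(extra) > 0) {
    stop(sprintf("coder tables cover different keys; %d unmatched, e.g. %s",
                 length(extra), paste(utils::head(gsub("\r", "/", extra), 5),
                                      collapse = ", ")), call. = FALSE)
  }
  m <- match(ka, kb)
  100 * mean(codes_a$code == codes_b$code[m])
}

check_code_table <- function(d) {
  stop_if_not(all(c("pen_id", "t_s", "code") %in% names(d)),
              "code table needs columns pen_id, t_s, code")
  stop_if_not(all(d$code %in% c(0L, 1L)), "codes must be 0 or 1")
  invisible(d)
}

#' Build consensus labels from two coders plus adjudication
#'
#' Keys on which the coders agree pass through unchanged; discrepant keys
#' take the code from an explicit adjudication table (mirroring the joint
#' review in which disagreements are discussed and resolved) and are
#' flagged. An unresolved discrepancy is an error.
#'
#' @param codes_a,codes_b Coder tables as in [intercoder_agreement()].
#' @param resolution Tibble with `pen_id`, `t_s`, `code` supplying the
#'   adjudicated code for every discrepant key; may be `NULL` when the
#'   coders fully agree.
#'
#' @return Tibble of consensus labels: `pen_id`, `t_s`, `code`,
#'   `was_discrepant`.
#' @export
build_consensus <- function(codes_a, codes_b, resolution = NULL) {
  check_code_table(codes_a); check_code_table(codes_b)
  key <- function(d) paste(d$pen_id, d$t_s, sep = "\r")
  ka <- key(codes_a)
  m <- match(ka, key(codes_b))
  stop_if_not(!anyNA(m) && length(ka) == nrow(codes_b),
              "coder tables cover different keys")
  disagree <- codes_a$code != codes_b$code[m]
  code <- codes_a$code
  if (any(disagree)) {
    stop_if_not(!is.null(resolution), "unresolved discrepancies: no resolution table")
    check_code_table(resolution)
    r <- match(ka[disagree], key(resolution))
    stop_if_not(!anyNA(r), "resolution table missing adjudications for some discrepant keys")
    code[disagree] <- resolution$code[r]
  }
  tibble::tibble(pen_id = codes_a$pen_id, t_s = codes_a$t_s,
                 code = as.integer(code), was_discrepant = disagree)
}

#' Class composition of a labelled image set
#'
#' Per-pen and total counts of images coded 1 (at least one pig standing
#' or sitting) and 0 (all pigs recumbent), with the standing percentage.
#'
#' @param labels Tibble with `pen_id` and `code`.
#'
#' @return Tibble with one row per pen plus a `"total"` row: `pen_id`,
#'   `n_standing`, `n_recumbent`, `n_total`, `pct_standing`.
#' @export
class_composition <- function(labels) {
  stop_if_not(nrow(labels) > 0, "labels must be nonempty")
  stop_if_not(all(c("pen_id", "code") %in% names(labels)), "labels need pen_id and code")
  stop_if_not(all(labels$code %in% c(0L, 1L)), "codes must be 0 or 1")
  per_pen <- labels |>
    dplyr::group_by(pen_id = as.character(.data$pen_id)) |>
    dplyr::summarise(n_standing = sum(.data$code == 1),
                     n_recumbent = sum(.data$code == 0), .groups = "drop")
  total <- tibble::tibble(pen_id = "total",
                          n_standing = sum(per_pen$n_standing),
                          n_recumbent = sum(per_pen$n_recumbent))
  out <- dplyr::bind_rows(per_pen, total)
  out$n_total <- out$n_standing + out$n_recumbent
  out$pct_standing <- 100 * out$n_standing / out$n_total
  out
}
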