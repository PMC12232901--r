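#' Cumulative residence-time histogram (CRTH)
#'
#' Summarise a set of single-molecule dwell times as a survival-style curve:
#' at each unique observed duration `t`, the number of events whose duration
#' is at least `t`. This is the representation the exponential-mixture model
#' is fitted to, with one point per unique observed duration (duplicate
#' durations contribute their multiplicity to the counts, not extra points).
#'
#' @param durations numeric vector of event durations in seconds, all > 0.
#' @param normalized logical; if `TRUE` counts are divided by the number of
#'   events so the curve starts at 1.
#' @return An object of class `"crth"`: a data frame with columns `t`
#'   (unique durations, ascending) and `count` (cumulative counts),
#'   and attributes `n_events` and `normalized`.
#' @examples
#' h <- build_crth(c(1, 2, 2, 3))
#' h$count  # 4 3 1
#' @export
build_crth <- function(durations, normalized = FALSE) {
  if (length(durations) == 0L) stop("no durations supplied")
  if (anyNA(durations) || any(!is.finite(durations))) {
    stop("durations must be finite and non-missing")
  }
  if (any(durations <= 0)) stop("durations must be positive")
  n <- length(durations)
  t_unique <- sort(unique(durations))
  # count of events with duration >= t, at each unique t
  cnt <- n - findInterval(t_unique, sort(durations), left.open = TRUE)
  if (normalized) cnt <- cnt / n
  out <- data.frame(t = t_unique, count = cnt)
  attr(out, "n_events") <- n
  attr(out, "normalized") <- normalized
  class(out) <- c("crth", "data.frame")
  out
}

#' @export
print.crth <- function(x, ...) {
  cat(sprintf(
    "Cumulative residence-time histogram: %d events, %d unique durations, t in [%.3g, %.3g] s%s\n",
    attr(x, "n_events"), nrow(x), min(x$t), max(x$t),
    if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""
  ))
  invisible(x)
}

#' @export
plot.crth <- function(x, ..., log = "y") {
  graphics::plot(x$t, x$count, log = log, xlab = "duration (s)",
                 ylab = if (isTRUE(attr(x, "normalized"))) "cumulative frequency"
                        else "cumulative count",
                 pch = 1, ...)
  invisible(x)
}

#' Write a CRTH to CSV
#'
#' Two columns, `t_s` and `cumulative_frequency`, suitable for plotting.
#'
#' @param hist a `crth` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_crth_csv <- function(hist, path) {
  stopifnot(inherits(hist, "crth"))
  utils::write.csv(
    data.frame(t_s = hist$t, cumulative_frequency = hist$count),
    path, row.names = FALSE
  )
  invisible(path)
}
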