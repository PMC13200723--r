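#' Centred rolling median
#'
#' Smooths a numeric series with a centred rolling median. Near the edges the
#' window either shrinks symmetrically (`edge = "shrink"`, default) or keeps
#' its full width anchored inside the series (`edge = "clamp"`), which avoids
#' under-smoothed values at the ends. A window of 1 returns the input
#' unchanged.
#'
#' @param x numeric vector.
#' @param window odd integer window width (cycles).
#' @param edge edge handling, `"shrink"` or `"clamp"`.
#' @return numeric vector, same length as `x`.
#' @keywords internal
rolling_median <- function(x, window = 3L, edge = c("shrink", "clamp")) {
  window <- as.integer(window)
  edge <- match.arg(edge)
  if (window <= 1L || length(x) < 3L) return(x)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  half <- window %/% 2L
  n <- length(x)
  if (edge == "shrink") {
    vapply(seq_len(n), function(i) {
      h <- min(half, i - 1L, n - i)
      stats::median(x[(i - h):(i + h)])
    }, numeric(1))
  } else {
    w <- min(window, n)
    h <- w %/% 2L
    vapply(seq_len(n), function(i) {
      lo <- min(max(i - h, 1L), n - w + 1L)
      stats::median(x[lo:(lo + w - 1L)])
    }, numeric(1))
  }
}

#' Percent change between two group means
#'
#' Relative difference of a treatment mean from a reference mean, in percent.
#' Negative values indicate a reduction relative to the reference.
#'
#' @param reference reference group mean.
#' @param treatment treatment group mean.
#' @return `100 * (treatment - reference) / reference`.
#' @examples
#' percent_change(21.47, 16.78)  # ~ -21.8
#' @export
percent_change <- function(reference, treatment) {
  stopifnot(is.finite(reference), reference != 0)
  100 * (treatment - reference) / reference
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
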