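#' Quality-control settings for per-cycle oxygen regressions
#'
#' @param min_r2 minimum coefficient of determination of the O2-vs-time
#'   regression for a cycle to pass QC. Default 0.9, a common respirometry
#'   screening threshold.
#' @param max_positive_slope largest tolerated positive O2 slope
#'   (µmol l-1 h-1); oxygen should fall while an animal respires, so any
#'   increase beyond this flags the cycle. Default 0.
#' @param min_points minimum number of samples in a measure cycle. Default 5.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(min_r2 = 0.9, max_positive_slope = 0, min_points = 5L) {
  stopifnot(min_r2 >= 0, min_r2 <= 1, min_points >= 2)
  structure(list(min_r2 = min_r2,
                 max_positive_slope = max_positive_slope,
                 min_points = as.integer(min_points)),
            class = "qc_config")
}

# Ordinary least-squares slope of y on x with r-squared, without lm() overhead.
# A cycle whose residual s.d. is below `flat_tol` is a perfect (possibly flat)
# fit: its r-squared is reported as 1 even when total variance is zero.
ols_slope <- function(x, y, flat_tol = 1e-9) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  b <- sum(xc * yc) / sxx
  fitted <- b * xc
  rss <- sum((yc - fitted)^2)
  tss <- sum(yc^2)
  resid_sd <- sqrt(rss / max(n - 2L, 1L))
  r2 <- if (resid_sd < flat_tol) 1 else if (tss <= 0) 0 else 1 - rss / tss
  list(slope = b, r_squared = r2, n = n, resid_sd = resid_sd)
}

#' Per-cycle oxygen consumption rates from an intermittent-flow trace
#'
#' For every sealed measure cycle, fits an ordinary least-squares regression of
#' oxygen concentration against time and converts the decline slope into a
#' mass-specific oxygen consumption rate,
#' \deqn{\dot{M}_{O_2} = -b \, V_{eff} / M}
#' where `b` is the slope (µmol l-1 h-1), `V_eff` the effective respirometer
#' volume (chamber minus fish volume, in litres) and `M` the body mass (g), so
#' rates come out in µmol O2 g-1 h-1. Cycles fail QC when the fit is poor
#' (`r_squared < min_r2`), when oxygen rises (`slope > max_positive_slope`), or
#' when too few samples are present. A perfectly flat cycle (zero slope, zero
#' residual) passes QC with a rate of 0.
#'
#' @param trace a [resp_trace()].
#' @param qc a [qc_config()].
#' @return An object of class `mo2_series`: a tibble with one row per measure
#'   cycle (`cycle_index`, `midpoint_time`, `mo2`, `r_squared`, `n_points`,
#'   `qc_pass`, `qc_reason`), carrying the trace metadata as attributes.
#' @examples
#' tr <- resp_trace(
#'   tibble::tibble(time = seq(0, 10 / 60, length.out = 11),
#'                  o2 = seq(250, 240, length.out = 11),
#'                  phase = "measure", cycle_index = 1L),
#'   animal_id = "f1", mass = 0.4, chamber_volume = 40)
#' compute_mo2(tr)  # 60 umol/l/h decline in 39.6 ml -> 5.94 umol g-1 h-1
#' @export
compute_mo2 <- function(trace, qc = qc_config()) {
  if (!inherits(trace, "resp_trace")) {
    stop("`trace` must be a resp_trace", call. = FALSE)
  }
  measure <- trace[trace$phase == "measure", , drop = FALSE]
  if (nrow(measure) == 0) stop("empty trace: no measure cycles", call. = FALSE)
  v_eff_l <- (attr(trace, "chamber_volume") - attr(trace, "fish_volume")) / 1000
  mass <- attr(trace, "mass")

  idx <- split(seq_len(nrow(measure)), measure$cycle_index)
  rows <- lapply(idx, function(i) {
    tt <- measure$time[i]
    oo <- measure$o2[i]
    mid <- (tt[1] + tt[length(tt)]) / 2
    if (length(i) < 2L) {
      return(list(midpoint_time = mid, mo2 = NA_real_, r_squared = 0,
                  n_points = length(i), qc_pass = FALSE,
                  qc_reason = "too few points"))
    }
    fit <- ols_slope(tt, oo)
    mo2 <- -fit$slope * v_eff_l / mass
    reason <- ""
    if (fit$n < qc$min_points) {
      reason <- "too few points"
    } else if (fit$slope > qc$max_positive_slope) {
      reason <- "positive slope"
    } else if (fit$r_squared < qc$min_r2) {
      reason <- "low r2"
    }
    list(midpoint_time = mid, mo2 = mo2, r_squared = fit$r_squared,
         n_points = fit$n, qc_pass = identical(reason, ""), qc_reason = reason)
  })
  out <- tibble::tibble(
    cycle_index = as.integer(names(idx)),
    midpoint_time = unname(vapply(rows, `[[`, numeric(1), "midpoint_time")),
    mo2 = unname(vapply(rows, `[[`, numeric(1), "mo2")),
    r_squared = pmin(pmax(unname(vapply(rows, `[[`, numeric(1), "r_squared")), 0), 1),
    n_points = vapply(rows, function(r) as.integer(r$n_points), integer(1),
                      USE.NAMES = FALSE),
    qc_pass = unname(vapply(rows, `[[`, logical(1), "qc_pass")),
    qc_reason = unname(vapply(rows, `[[`, character(1), "qc_reason"))
  )
  out <- out[order(out$midpoint_time), , drop = FALSE]
  structure(out,
            class = c("mo2_series", class(tibble::tibble())),
            animal_id = attr(trace, "animal_id"),
            genotype = attr(trace, "genotype"),
            mass = mass)
}
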