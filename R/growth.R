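#' Specific growth rate
#'
#' Instantaneous growth rate from two masses,
#' \deqn{g = (\ln M_2 - \ln M_1)/\Delta t, \qquad G = 100 g}
#' with `G` the specific growth rate in percent per day.
#'
#' @param m1 initial mass (g), positive.
#' @param m2 final mass (g), positive.
#' @param dt elapsed days, positive (weekly weighing defaults to 7).
#' @return list with `g` (instantaneous rate, day-1) and `G` (% day-1).
#' @examples
#' sgr(0.0865, 0.3234, dt = 56)$G  # 2.355 % day-1
#' @export
sgr <- function(m1, m2, dt = 7) {
  if (any(!is.finite(m1)) || any(m1 <= 0) || any(!is.finite(m2)) || any(m2 <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  if (any(!is.finite(dt)) || any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  g <- (log(m2) - log(m1)) / dt
  list(g = g, G = 100 * g)
}

#' Feed conversion ratio
#'
#' Feed intake divided by mass gain over the same interval. A non-positive
#' gain makes the ratio undefined; rather than erroring, the result is `NaN`
#' (or `-Inf`-free) with a `"no growth"` flag so trial tables keep their rows.
#'
#' @param feed_mg feed intake (mg), non-negative.
#' @param gain_mg mass gain (mg).
#' @return numeric vector of FCR values with attribute `flag` (character;
#'   `"no growth"` where gain was non-positive, `""` otherwise).
#' @export
fcr <- function(feed_mg, gain_mg) {
  if (any(feed_mg < 0)) stop("`feed_mg` must be non-negative", call. = FALSE)
  out <- ifelse(gain_mg > 0, feed_mg / gain_mg, NaN)
  attr(out, "flag") <- ifelse(gain_mg > 0, "", "no growth")
  out
}

#' Fulton's condition factor
#'
#' \deqn{K = 100 \, M_b / L^3} with body mass in g and length in cm.
#'
#' @param mass body mass (g), positive.
#' @param length total length (cm), positive.
#' @return K (unitless).
#' @examples
#' condition_factor(1, 10)  # 0.1
#' @export
condition_factor <- function(mass, length) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("`mass` must be positive", call. = FALSE)
  if (any(!is.finite(length)) || any(length <= 0)) stop("`length` must be positive", call. = FALSE)
  100 * mass / length^3
}

#' Daily ration from body mass
#'
#' @param mass body mass (g), positive.
#' @param ration_fraction ration as a fraction of body mass, in (0, 1);
#'   e.g. 0.03 for a 3% daily ration.
#' @return feed mass (g).
#' @export
ration_mass <- function(mass, ration_fraction) {
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("`mass` must be positive", call. = FALSE)
  if (any(!is.finite(ration_fraction)) || any(ration_fraction <= 0) ||
      any(ration_fraction >= 1)) {
    stop("`ration_fraction` must lie in (0, 1)", call. = FALSE)
  }
  mass * ration_fraction
}

#' Per-week growth metrics for a trial table
#'
#' Derives specific growth rate, feed conversion ratio and (when lengths are
#' available) Fulton's K for every animal-week of a growth trial.
#'
#' @param records data frame with columns `animal_id`, `genotype`, `week`
#'   (integer, the week being summarised), `period` (e.g. control /
#'   omeprazole / recovery), `mass_start` and `mass_end` (g), `feed_mg`
#'   (feed intake over the interval, mg), optional `length_cm` and `days`
#'   (interval length, default 7).
#' @return tibble with the input identifiers plus `g`, `G` (% day-1), `fcr`,
#'   `fcr_flag` and `K` (NA without lengths).
#' @export
growth_table <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("animal_id", "genotype", "week", "period", "mass_start",
              "mass_end", "feed_mg")
  if (!all(needed %in% names(records))) {
    stop("growth records need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  days <- if ("days" %in% names(records)) records$days else 7
  rates <- sgr(records$mass_start, records$mass_end, days)
  gain_mg <- (records$mass_end - records$mass_start) * 1000
  ratio <- fcr(records$feed_mg, gain_mg)
  k <- if ("length_cm" %in% names(records)) {
    condition_factor(records$mass_end, records$length_cm)
  } else {
    NA_real_
  }
  tibble::tibble(
    animal_id = records$animal_id, genotype = records$genotype,
    week = records$week, period = records$period,
    mass_start = records$mass_start, mass_end = records$mass_end,
    feed_mg = records$feed_mg,
    g = rates$g, G = rates$G,
    fcr = as.numeric(ratio), fcr_flag = attr(ratio, "flag"),
    K = k
  )
}
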