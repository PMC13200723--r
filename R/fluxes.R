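#' Net flux of a water-borne analyte from a static flux chamber
#'
#' Mass-specific net flux over one sampling interval,
#' \deqn{J_X = ([X]_f - [X]_i) \, V / (M \, t)}
#' with initial and final per-litre amounts, chamber water volume `V` (l),
#' body mass `M` (kg) and interval duration `t` (h). Positive values mean
#' excretion into the water (the analyte accumulates); negative values mean
#' uptake by the animal.
#'
#' @param conc_initial initial concentration (µmol l-1 for total ammonia,
#'   µEq l-1 for titratable alkalinity).
#' @param conc_final final concentration, same units.
#' @param volume chamber water volume (l).
#' @param mass body mass (kg).
#' @param duration flux period (h), positive.
#' @return flux in µmol kg-1 h-1 (or µEq kg-1 h-1).
#' @examples
#' net_flux(0, 50, volume = 0.05, mass = 0.0004, duration = 3)  # 2083.33
#' @export
net_flux <- function(conc_initial, conc_final, volume, mass, duration) {
  stop_if_not_positive(volume, "volume")
  stop_if_not_positive(mass, "mass")
  if (any(!is.finite(duration)) || any(duration <= 0)) {
    stop("`duration` must be positive", call. = FALSE)
  }
  (conc_final - conc_initial) * volume / (mass * duration)
}

#' Titratable alkalinity from an acid titration
#'
#' Converts the acid volume needed to bring a water sample to the pH 4.0
#' endpoint into titratable alkalinity. A two-stage titration (autotitrator to
#' pH 4.3, manual to pH 4.0) is handled by passing the summed titrant volume or
#' a vector of per-stage volumes, which are summed.
#'
#' @param titrant_volume acid volume(s) to the endpoint (l). Vectors are summed
#'   (per-stage volumes of a two-stage titration).
#' @param titrant_normality acid normality (Eq l-1), e.g. 0.01 for
#'   0.01 mol l-1 HCl.
#' @param sample_volume titrated water sample volume (l), e.g. 0.010 for 10 ml.
#' @return titratable alkalinity (µEq l-1).
#' @examples
#' titratable_alkalinity(0.250e-3, 0.01, 0.010)  # 250 uEq l-1
#' @export
titratable_alkalinity <- function(titrant_volume, titrant_normality,
                                  sample_volume) {
  if (any(titrant_volume < 0)) stop("negative titrant volume", call. = FALSE)
  stop_if_not_positive(titrant_normality, "titrant_normality")
  stop_if_not_positive(sample_volume, "sample_volume")
  sum(titrant_volume) * titrant_normality / sample_volume * 1e6
}

#' Net acid-base flux
#'
#' Difference between the titratable-alkalinity and total-ammonia fluxes over
#' one interval. Negative values indicate a net base uptake (i.e. acid
#' excretion) and positive values indicate net base excretion.
#'
#' @param j_talk titratable alkalinity flux (µEq kg-1 h-1).
#' @param j_tamm total ammonia flux (µmol kg-1 h-1).
#' @return net acid-base flux (µEq kg-1 h-1).
#' @export
net_acid_base <- function(j_talk, j_tamm) {
  j_talk - j_tamm
}

#' Cumulative ammonia excreted above baseline
#'
#' Integrates the above-baseline part of a sequence of contiguous ammonia flux
#' intervals back to an absolute amount:
#' \deqn{\sum_k \max(J_k - J_{baseline}, 0) \times M \times t_k}
#' Sub-baseline intervals contribute zero (the clamp), so the result is the
#' post-prandial excess load, in µmol.
#'
#' @param flux per-interval ammonia fluxes (µmol kg-1 h-1).
#' @param start interval start times (h); must be contiguous with `end`.
#' @param end interval end times (h).
#' @param baseline baseline flux subtracted before accumulation
#'   (µmol kg-1 h-1), e.g. the pre-feed or unfed-control mean.
#' @param mass body mass (kg).
#' @return cumulative excess ammonia excreted (µmol).
#' @export
cumulative_tan <- function(flux, start, end, baseline, mass) {
  stopifnot(length(flux) == length(start), length(start) == length(end))
  stop_if_not_positive(mass, "mass")
  if (any(end <= start)) stop("intervals must have positive duration", call. = FALSE)
  if (length(start) > 1) {
    gaps <- start[-1] - end[-length(end)]
    if (any(gaps < -1e-9)) stop("overlapping intervals", call. = FALSE)
  }
  sum(pmax(flux - baseline, 0) * mass * (end - start))
}

#' Excess ammonia excretion as a percentage of meal ammonia
#'
#' Expresses the cumulative above-baseline ammonia excreted as a percentage of
#' the ammonia ingested with the meal. Values above 100% indicate that amino
#' acid catabolism, not direct absorption of meal ammonia, dominates the
#' excretion; such results carry a `catabolic` flag.
#'
#' @param excreted_over_baseline cumulative excess ammonia excreted (µmol).
#' @param meal_tan total ammonia content of the ingested meal (µmol), positive.
#' @return percentage (numeric scalar) with attribute `catabolic` (logical,
#'   `TRUE` when the percentage exceeds 100).
#' @export
meal_tan_fraction <- function(excreted_over_baseline, meal_tan) {
  if (!is.finite(meal_tan) || meal_tan <= 0) {
    stop("`meal_tan` must be positive", call. = FALSE)
  }
  pct <- 100 * excreted_over_baseline / meal_tan
  attr(pct, "catabolic") <- pct > 100
  pct
}

#' Ammonia speciation parameters
#'
#' The apparent dissociation constant of the NH4+/NH3 pair and the NH3
#' solubility coefficient are temperature- and ionic-strength-dependent; no
#' universal values are hard-coded. The defaults are freshwater values at 23°C
#' and an assumed ionic strength of 125 mmol l-1 (pK' ~9.46; alpha ~
#' 0.00566 mmol l-1 torr-1, i.e. 5.66 µmol l-1 torr-1 — supply your own values
#' for other conditions).
#'
#' @param pk_prime apparent NH4+/NH3 pK (must lie in (7, 11)).
#' @param alpha_nh3 NH3 solubility (µmol l-1 torr-1), positive.
#' @param ionic_strength documentation field, mmol l-1 (default 125).
#' @return list of class `speciation_params`.
#' @export
speciation_params <- function(pk_prime = 9.46, alpha_nh3 = 5.66,
                              ionic_strength = 125) {
  if (pk_prime <= 7 || pk_prime >= 11) {
    stop("`pk_prime` must lie in (7, 11)", call. = FALSE)
  }
  stop_if_not_positive(alpha_nh3, "alpha_nh3")
  structure(list(pk_prime = pk_prime, alpha_nh3 = alpha_nh3,
                 ionic_strength = ionic_strength),
            class = "speciation_params")
}

#' Un-ionized ammonia concentration and partial pressure
#'
#' Henderson–Hasselbalch speciation of total ammonia:
#' \deqn{[NH_3] = TAN / (1 + 10^{pK' - pH}), \quad P_{NH_3} = [NH_3]/\alpha_{NH_3}}
#'
#' @param tan total ammonia (µmol l-1), non-negative.
#' @param ph sample pH.
#' @param params a [speciation_params()].
#' @return list with `nh3` (µmol l-1) and `p_nh3` (torr).
#' @examples
#' nh3_speciation(1000, ph = 7.0, speciation_params(pk_prime = 9.5))
#' @export
nh3_speciation <- function(tan, ph, params = speciation_params()) {
  if (any(tan < 0)) stop("`tan` must be non-negative", call. = FALSE)
  nh3 <- tan / (1 + 10^(params$pk_prime - ph))
  list(nh3 = nh3, p_nh3 = nh3 / params$alpha_nh3)
}

#' Oxygen cost of gastric acid secretion
#'
#' Estimates the direct metabolic cost of neutralizing/acidifying a meal
#' through the gastric proton pump. The acid load is either supplied directly
#' or computed from the pH shift the meal undergoes, the meal buffer capacity
#' and the ration:
#' \deqn{load = \beta \times \Delta pH \times ration \times 1000}
#' (µmol H+ per g body mass, with buffer capacity in
#' µmol H+ (g meal)-1 pH-1 and ration in g meal (g body)-1). With a pump
#' stoichiometry of `h_o2_ratio` mol H+ transported per mol O2 consumed,
#' the oxygen cost is `load / h_o2_ratio`, and its share of the
#' post-prandial response is `100 * cost / sda_magnitude`.
#'
#' @param h_o2_ratio H+ : O2 stoichiometry (mol H+ per mol O2), positive.
#'   Published pump estimates span 5.0 (ideal) down to 2.3 (allowing proton
#'   back-leak).
#' @param acid_load acid load (µmol H+ g-1 body). Either supply this directly
#'   or all three of `delta_ph`, `buffer_capacity`, `ration`.
#' @param delta_ph pH units neutralized.
#' @param buffer_capacity meal buffer capacity (µmol H+ (g meal)-1 pH-1).
#' @param ration meal size (g meal per g body mass).
#' @param sda_magnitude SDA magnitude (µmol O2 g-1), positive; used for the
#'   share calculation when supplied.
#' @return list of class `acid_cost` with `acid_load`, `h_o2_ratio`,
#'   `o2_cost` (µmol O2 g-1 body) and `sda_share` (%; `NA` when no magnitude
#'   given).
#' @examples
#' acid_cost(h_o2_ratio = 5.0, acid_load = 2.82, sda_magnitude = 21.47)
#' @export
acid_cost <- function(h_o2_ratio, acid_load = NULL, delta_ph = NULL,
                      buffer_capacity = NULL, ration = NULL,
                      sda_magnitude = NULL) {
  if (!is.finite(h_o2_ratio) || h_o2_ratio <= 0) {
    stop("`h_o2_ratio` must be positive", call. = FALSE)
  }
  if (is.null(acid_load)) {
    if (is.null(delta_ph) || is.null(buffer_capacity) || is.null(ration)) {
      stop("supply `acid_load` or all of `delta_ph`, `buffer_capacity`, `ration`",
           call. = FALSE)
    }
    acid_load <- buffer_capacity * delta_ph * ration * 1000
  }
  if (acid_load < 0) stop("`acid_load` must be non-negative", call. = FALSE)
  o2_cost <- acid_load / h_o2_ratio
  share <- NA_real_
  if (!is.null(sda_magnitude)) {
    if (!is.finite(sda_magnitude) || sda_magnitude <= 0) {
      stop("`sda_magnitude` must be positive", call. = FALSE)
    }
    share <- 100 * o2_cost / sda_magnitude
  }
  structure(list(acid_load = acid_load, h_o2_ratio = h_o2_ratio,
                 o2_cost = o2_cost, sda_share = share),
            class = "acid_cost")
}

#' @export
print.acid_cost <- function(x, ...) {
  cat(sprintf("<acid_cost> load %.3f umol H+ g-1, H+:O2 = %.1f\n",
              x$acid_load, x$h_o2_ratio))
  cat(sprintf("  O2 cost  %.3f umol O2 g-1\n", x$o2_cost))
  if (is.finite(x$sda_share)) {
    cat(sprintf("  share    %.1f%% of SDA magnitude\n", x$sda_share))
  }
  invisible(x)
}

#' Per-interval flux table from a water-sample series
#'
#' Turns a series of chamber water samples (times and concentrations) into a
#' tidy per-interval net-flux table for one animal.
#'
#' @param time sample times (h), strictly increasing; the first sample opens
#'   the first interval.
#' @param conc analyte concentrations at `time` (µmol l-1 or µEq l-1).
#' @param volume chamber water volume (l).
#' @param mass body mass (kg).
#' @param analyte label (e.g. `"TAN"` or `"TAlk"`).
#' @param animal_id animal label.
#' @return tibble with one row per interval: `animal_id`, `analyte`, `start`,
#'   `end`, `duration`, `conc_initial`, `conc_final`, `flux` (positive =
#'   excretion into the water).
#' @export
flux_table <- function(time, conc, volume, mass, analyte = "TAN",
                       animal_id = NA_character_) {
  stopifnot(length(time) == length(conc), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("sample times must increase", call. = FALSE)
  n <- length(time)
  i0 <- seq_len(n - 1)
  tibble::tibble(
    animal_id = as.character(animal_id),
    analyte = analyte,
    start = time[i0],
    end = time[i0 + 1],
    duration = time[i0 + 1] - time[i0],
    conc_initial = conc[i0],
    conc_final = conc[i0 + 1],
    flux = net_flux(conc[i0], conc[i0 + 1], volume, mass,
                    time[i0 + 1] - time[i0])
  )
}
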