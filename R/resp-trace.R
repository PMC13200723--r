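#' Construct a respirometry trace
#'
#' Bundles a raw intermittent-flow oxygen time series with the chamber geometry
#' and animal metadata needed to convert oxygen declines into mass-specific
#' oxygen consumption rates. Measure phases are the sealed periods during which
#' chamber oxygen falls; flush phases renew the water and are ignored by the
#' rate regression.
#'
#' @param samples data frame with columns `time` (h since chamber entry,
#'   strictly increasing), `o2` (µmol O2 l-1, non-negative), `phase`
#'   (`"measure"`, `"flush"` or `"wait"`), and `cycle_index` (integer; required
#'   on every measure sample).
#' @param animal_id animal label.
#' @param mass wet body mass (g), positive.
#' @param chamber_volume respirometer volume (ml).
#' @param fish_volume fish volume (ml); defaults to `mass` assuming a tissue
#'   density of 1 g ml-1. Must satisfy `chamber_volume > fish_volume >= 0`.
#' @param genotype optional genotype/group label.
#' @return An object of class `resp_trace`: the sample tibble with metadata
#'   attributes (`animal_id`, `genotype`, `mass`, `chamber_volume`,
#'   `fish_volume`).
#' @export
resp_trace <- function(samples, animal_id, mass, chamber_volume,
                       fish_volume = mass, genotype = NA_character_) {
  samples <- tibble::as_tibble(samples)
  required <- c("time", "o2", "phase", "cycle_index")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("trace samples lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stop_if_not_positive(mass, "mass")
  stop_if_not_positive(chamber_volume, "chamber_volume")
  if (!is.numeric(fish_volume) || fish_volume < 0) {
    stop("`fish_volume` must be >= 0", call. = FALSE)
  }
  if (chamber_volume <= fish_volume) {
    stop("`chamber_volume` must exceed `fish_volume`", call. = FALSE)
  }
  if (any(diff(samples$time) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (any(samples$o2 < 0, na.rm = TRUE)) {
    stop("oxygen concentrations must be non-negative", call. = FALSE)
  }
  is_measure <- samples$phase == "measure"
  if (any(is_measure & is.na(samples$cycle_index))) {
    stop("every measure sample needs a `cycle_index`", call. = FALSE)
  }
  structure(samples,
            class = c("resp_trace", class(samples)),
            animal_id = as.character(animal_id),
            genotype = as.character(genotype),
            mass = mass,
            chamber_volume = chamber_volume,
            fish_volume = fish_volume)
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> animal %s (%s), %.3f g, chamber %.1f ml (fish %.1f ml)\n",
              attr(x, "animal_id"), attr(x, "genotype"), attr(x, "mass"),
              attr(x, "chamber_volume"), attr(x, "fish_volume")))
  n_cycles <- length(unique(x$cycle_index[x$phase == "measure"]))
  cat(sprintf("  %d samples over %.1f h, %d measure cycles\n",
              nrow(x), diff(range(x$time)), n_cycles))
  invisible(x)
}

#' Read respirometry traces from long-format CSV files
#'
#' Reads an oxygen trace table (`animal_id, time_h, o2_umol_l, phase, cycle`)
#' and a metadata table (`animal_id, genotype, mass_g, chamber_ml`, optional
#' `fish_ml`) and returns one [resp_trace()] per animal.
#'
#' @param trace_file path to the long-format trace CSV.
#' @param meta_file path to the per-animal metadata CSV.
#' @return named list of `resp_trace` objects, one per animal.
#' @export
read_resp_trace <- function(trace_file, meta_file) {
  traces <- utils::read.csv(trace_file, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  needed_t <- c("animal_id", "time_h", "o2_umol_l", "phase", "cycle")
  needed_m <- c("animal_id", "genotype", "mass_g", "chamber_ml")
  if (!all(needed_t %in% names(traces))) {
    stop("trace CSV needs columns: ", paste(needed_t, collapse = ", "), call. = FALSE)
  }
  if (!all(needed_m %in% names(meta))) {
    stop("metadata CSV needs columns: ", paste(needed_m, collapse = ", "), call. = FALSE)
  }
  out <- lapply(meta$animal_id, function(id) {
    rows <- traces[traces$animal_id == id, , drop = FALSE]
    if (nrow(rows) == 0) stop("no trace rows for animal ", id, call. = FALSE)
    m <- meta[meta$animal_id == id, , drop = FALSE]
    fish_ml <- if ("fish_ml" %in% names(m)) m$fish_ml else m$mass_g
    resp_trace(
      tibble::tibble(time = rows$time_h, o2 = rows$o2_umol_l,
                     phase = rows$phase, cycle_index = rows$cycle),
      animal_id = id, genotype = m$genotype, mass = m$mass_g,
      chamber_volume = m$chamber_ml, fish_volume = fish_ml
    )
  })
  names(out) <- meta$animal_id
  out
}
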