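#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the seeded generators that emulate the pipeline's
#' inputs: a two-group (wild-type vs knockout) cohort with a baseline metabolic
#' rate plus a transient post-prandial bump, static-chamber analyte
#' accumulation, exponential growth with a drug-depression window, and
#' log-scale gene expression with multiple reference genes. Defaults encode
#' the study conditions the package is designed around: group SMR means
#' 5.42/5.10 µmol O2 g-1 h-1, wild-type peak 3.03 µmol O2 g-1 h-1 and duration
#' 15.25 h, a -21.8% knockout effect on SDA magnitude and -11% on duration
#' (the knockout peak is derived from these two effects), cycle noise
#' s.d. 0.25 µmol O2 g-1 h-1, chamber samples at 0/3/6/9/24 h, a growth trial
#' of 3 control + 2 omeprazole + 3 recovery weeks with a 45.2% growth-rate
#' depression, and a -1 log2 knockout effect on the intestinal satiation gene.
#'
#' @param seed integer seed; every generator is bit-reproducible under it.
#' @param n_per_group animals per genotype group.
#' @param smr_mean,smr_sd named group means (`wt`, `ko`) and common s.d. of
#'   SMR (µmol O2 g-1 h-1).
#' @param sda_peak_mean,sda_peak_sd wild-type net-peak mean and common s.d.
#'   (µmol O2 g-1 h-1); the knockout mean is
#'   `sda_peak_mean * (1 + magnitude_effect) / (1 + duration_effect)`.
#' @param sda_duration_mean,sda_duration_sd wild-type duration mean and
#'   common s.d. (h); knockout mean is scaled by `1 + duration_effect`.
#' @param magnitude_effect,duration_effect relative knockout effects on SDA
#'   magnitude and duration (negative = reduction).
#' @param peak_time_fraction position of the bump apex as a fraction of the
#'   duration (default 0.45; post-prandial curves peak well before half-way
#'   through recovery).
#' @param cycle_noise_sd per-cycle noise on the oxygen-consumption rate
#'   (µmol O2 g-1 h-1).
#' @param o2_noise_sd within-cycle sample noise on oxygen concentration
#'   (µmol l-1; default 0 so all stochasticity is at the cycle level).
#' @param activity_spike_rate expected activity excursions per hour; spiked
#'   cycles get an elevated rate and a noisy, qc-failing oxygen regression.
#' @param regurgitation_prob probability an animal truncates its response to
#'   ~3 h (meal regurgitation).
#' @param mass_mean,mass_sd named group body-mass means (g) and s.d.
#' @param chamber_ml respirometer volume (ml).
#' @param record_h,measure_min,flush_min,samples_per_measure trace geometry:
#'   record length (h), sealed and flush phase lengths (min), samples per
#'   measure phase.
#' @param o2_sat flush oxygen concentration (µmol l-1).
#' @param flux_sample_times chamber water sampling times (h).
#' @param baseline_jtamm baseline ammonia flux (µmol kg-1 h-1).
#' @param jtamm_mult named post-feed multipliers of the baseline ammonia flux
#'   at the first interval (decaying thereafter). Defaults give a 3.65-fold
#'   wild-type:knockout post-feed flux ratio and a 5-fold excess ratio.
#' @param jtamm_halflife decay half-life of the post-feed excess (h).
#' @param baseline_jtalk titratable alkalinity flux (µEq kg-1 h-1), common to
#'   both groups.
#' @param flux_chamber_l flux chamber water volume (l).
#' @param tan_noise_sd,talk_noise_sd concentration measurement noise
#'   (µmol l-1 / µEq l-1).
#' @param base_g baseline specific growth rate (% day-1).
#' @param growth_sd weekly noise on the growth rate (% day-1).
#' @param drug_depression_fraction fractional growth-rate reduction during the
#'   depressed weeks (default 0.452).
#' @param depressed_weeks trial weeks with depressed growth (default 5:7 —
#'   the second treatment week and the first two recovery weeks).
#' @param mass0_mean,mass0_sd named initial-mass means (g) and common s.d.
#' @param ration_fraction daily ration as a fraction of body mass.
#' @param qpcr_effects named log2 knockout effects per target gene.
#' @param ct_sd technical Ct noise (cycles).
#' @param sample_offset_sd between-sample Ct offset s.d. (RNA input
#'   variation; cancelled by normalization).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_per_group = 12L,
                       smr_mean = c(wt = 5.42, ko = 5.10), smr_sd = 0.4,
                       sda_peak_mean = 3.03, sda_peak_sd = 0.35,
                       sda_duration_mean = 15.25, sda_duration_sd = 1.0,
                       magnitude_effect = -0.218, duration_effect = -0.11,
                       peak_time_fraction = 0.45,
                       cycle_noise_sd = 0.25, o2_noise_sd = 0,
                       activity_spike_rate = 0.2, regurgitation_prob = 0,
                       mass_mean = c(wt = 0.40, ko = 0.35), mass_sd = 0.04,
                       chamber_ml = 40, record_h = 24,
                       measure_min = 10, flush_min = 5,
                       samples_per_measure = 10L, o2_sat = 260,
                       flux_sample_times = c(0, 3, 6, 9, 24),
                       baseline_jtamm = 200,
                       jtamm_mult = c(wt = 10.8, ko = 2.96),
                       jtamm_halflife = 9,
                       baseline_jtalk = 100,
                       flux_chamber_l = 0.05,
                       tan_noise_sd = 2, talk_noise_sd = 5,
                       base_g = 2.8, growth_sd = 0.15,
                       drug_depression_fraction = 0.452,
                       depressed_weeks = 5:7,
                       mass0_mean = c(wt = 0.0865, ko = 0.1155),
                       mass0_sd = 0.03,
                       ration_fraction = 0.03,
                       qpcr_effects = c(cck = -1.0),
                       ct_sd = 0.15, sample_offset_sd = 0.3) {
  stopifnot(smr_sd >= 0, sda_peak_sd >= 0, sda_duration_sd >= 0,
            cycle_noise_sd >= 0, o2_noise_sd >= 0,
            regurgitation_prob >= 0, regurgitation_prob <= 1,
            peak_time_fraction > 0, peak_time_fraction < 1,
            tan_noise_sd >= 0, talk_noise_sd >= 0, growth_sd >= 0,
            drug_depression_fraction >= 0, drug_depression_fraction <= 1,
            ct_sd >= 0, sample_offset_sd >= 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_per_group <- as.integer(n_per_group)
  structure(cfg, class = "sim_config")
}

# Post-prandial excess-rate profile with compact support on [0, duration]:
# a smoothstep rise from zero to the apex (height `peak` at
# `ptf * duration`), then a square-root fall back to exactly zero at the
# duration — the recovery accelerates terminally, as post-prandial curves do.
# Zero outside the window.
sda_bump <- function(t, peak, duration, ptf = 0.45) {
  tp <- ptf * duration
  val <- numeric(length(t))
  rise <- t >= 0 & t <= tp
  u <- t[rise] / tp
  val[rise] <- peak * (3 * u^2 - 2 * u^3)
  fall <- t > tp & t <= duration
  v <- (t[fall] - tp) / (duration - tp)
  val[fall] <- peak * sqrt(1 - v)
  val
}

# Closed-form time integral of sda_bump over [0, duration] (µmol O2 g-1):
# smoothstep integrates to 1/2, sqrt(1 - v) to 2/3.
sda_bump_area <- function(peak, duration, ptf = 0.45) {
  tp <- ptf * duration
  peak * (tp / 2 + 2 * (duration - tp) / 3)
}

gen_one_trace <- function(cfg, animal_id, group) {
  mass <- max(rnorm(1, cfg$mass_mean[[group]], cfg$mass_sd), 0.05)
  smr <- max(rnorm(1, cfg$smr_mean[[group]], cfg$smr_sd), 1)
  peak_mean <- if (group == "wt") cfg$sda_peak_mean else {
    cfg$sda_peak_mean * (1 + cfg$magnitude_effect) / (1 + cfg$duration_effect)
  }
  dur_mean <- if (group == "wt") cfg$sda_duration_mean else {
    cfg$sda_duration_mean * (1 + cfg$duration_effect)
  }
  peak <- max(rnorm(1, peak_mean, cfg$sda_peak_sd), 0.5)
  duration <- max(rnorm(1, dur_mean, cfg$sda_duration_sd), 6)
  regurgitated <- runif(1) < cfg$regurgitation_prob
  if (regurgitated) duration <- runif(1, 2.5, 3.5)

  measure_h <- cfg$measure_min / 60
  flush_h <- cfg$flush_min / 60
  cycle_h <- measure_h + flush_h
  n_cycles <- floor(cfg$record_h / cycle_h)
  starts <- (seq_len(n_cycles) - 1) * cycle_h
  mids <- starts + measure_h / 2

  excess <- sda_bump(mids, peak, duration, cfg$peak_time_fraction)
  mo2_cycle <- pmax(smr + excess + rnorm(n_cycles, 0, cfg$cycle_noise_sd), 0.1)

  n_spikes <- stats::rpois(1, cfg$activity_spike_rate * cfg$record_h)
  spike_cycles <- integer(0)
  if (n_spikes > 0) {
    spike_cycles <- sample.int(n_cycles, min(n_spikes, n_cycles))
    mo2_cycle[spike_cycles] <- mo2_cycle[spike_cycles] +
      stats::rexp(length(spike_cycles), rate = 0.5)
  }

  v_eff_l <- (cfg$chamber_ml - mass) / 1000
  slope <- mo2_cycle * mass / v_eff_l  # µmol l-1 h-1 decline within the seal
  npt <- cfg$samples_per_measure
  offs <- seq(0, measure_h, length.out = npt)

  t_meas <- rep(starts, each = npt) + rep(offs, times = n_cycles)
  o2_meas <- cfg$o2_sat - rep(slope, each = npt) * rep(offs, times = n_cycles)
  if (cfg$o2_noise_sd > 0) {
    o2_meas <- o2_meas + rnorm(length(o2_meas), 0, cfg$o2_noise_sd)
  }
  if (length(spike_cycles) > 0) {
    # activity ruins the within-cycle linearity: noise on the scale of the
    # whole decline drives r-squared below any sane QC threshold
    for (ci in spike_cycles) {
      rows <- ((ci - 1) * npt + 1):(ci * npt)
      o2_meas[rows] <- o2_meas[rows] +
        rnorm(npt, 0, max(slope[ci] * measure_h, 1))
    }
  }
  o2_meas <- pmax(o2_meas, 0)

  # two flush samples per cycle, rising back toward saturation
  t_fl <- rep(starts + measure_h, each = 2) + rep(flush_h * c(1 / 3, 2 / 3), n_cycles)
  o2_end <- cfg$o2_sat - slope * measure_h
  o2_fl <- as.vector(rbind(o2_end + (cfg$o2_sat - o2_end) * 0.7,
                           o2_end + (cfg$o2_sat - o2_end) * 0.95))

  samples <- tibble::tibble(
    time = c(t_meas, t_fl),
    o2 = c(o2_meas, o2_fl),
    phase = rep(c("measure", "flush"), c(length(t_meas), length(t_fl))),
    cycle_index = c(rep(seq_len(n_cycles), each = npt),
                    rep(NA_integer_, length(t_fl)))
  )
  samples <- samples[order(samples$time), , drop = FALSE]

  trace <- resp_trace(samples, animal_id = animal_id, mass = mass,
                      chamber_volume = cfg$chamber_ml, fish_volume = mass,
                      genotype = group)
  truth <- tibble::tibble(
    animal_id = animal_id, genotype = group, mass = mass,
    smr = smr, peak = peak, duration = duration,
    magnitude = sda_bump_area(peak, duration, cfg$peak_time_fraction),
    regurgitated = regurgitated,
    n_spike_cycles = length(spike_cycles)
  )
  list(trace = trace, truth = truth)
}

#' Simulate one intermittent-flow respirometry trace
#'
#' Generates 24 h of measure/flush cycles for one animal. The oxygen samples
#' are back-computed from the cycle's true oxygen consumption rate through the
#' chamber mass balance, so [compute_mo2()] inverts the generator exactly in
#' the noise-free limit. Activity spikes inject qc-failing cycles;
#' regurgitating animals truncate their response to ~3 h.
#'
#' @param cfg a [sim_config()].
#' @param animal_id animal label.
#' @param group `"wt"` or `"ko"`.
#' @param seed seed for this trace (defaults to `cfg$seed`).
#' @return list with `trace` (a [resp_trace()]) and `truth` (one-row tibble of
#'   generator parameters: `smr`, `peak`, `duration`, `magnitude`,
#'   `regurgitated`, `n_spike_cycles`).
#' @export
simulate_resp_trace <- function(cfg = sim_config(), animal_id = "a1",
                                group = c("wt", "ko"), seed = cfg$seed) {
  group <- match.arg(group)
  set.seed(seed)
  gen_one_trace(cfg, animal_id, group)
}

#' Simulate a full two-group respirometry cohort
#'
#' @param cfg a [sim_config()]; `n_per_group` animals are drawn per genotype.
#' @param seed cohort seed (defaults to `cfg$seed`).
#' @return list with `traces` (named list of [resp_trace()]) and `truth`
#'   (tibble, one row per animal).
#' @export
simulate_respirometry_study <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  ids <- c(sprintf("wt%02d", seq_len(cfg$n_per_group)),
           sprintf("ko%02d", seq_len(cfg$n_per_group)))
  groups <- rep(c("wt", "ko"), each = cfg$n_per_group)
  out <- Map(function(id, g) gen_one_trace(cfg, id, g), ids, groups)
  list(traces = lapply(out, `[[`, "trace"),
       truth = dplyr::bind_rows(lapply(out, `[[`, "truth")))
}

gen_one_flux <- function(cfg, animal_id, group) {
  mass_kg <- max(rnorm(1, cfg$mass_mean[[group]], cfg$mass_sd), 0.05) / 1000
  times <- cfg$flux_sample_times
  n_int <- length(times) - 1
  starts <- times[-length(times)]
  ends <- times[-1]
  mult <- cfg$jtamm_mult[[group]]
  j_tamm <- cfg$baseline_jtamm *
    (1 + (mult - 1) * 2^(-starts / cfg$jtamm_halflife))
  j_talk <- rep(cfg$baseline_jtalk, n_int)

  v <- cfg$flux_chamber_l
  tan0 <- 5     # near-ambient total ammonia in fresh chamber water
  talk0 <- 500  # background alkalinity of the artificial fresh water
  tan <- tan0 + c(0, cumsum(j_tamm * mass_kg * (ends - starts) / v))
  talk <- talk0 + c(0, cumsum(j_talk * mass_kg * (ends - starts) / v))
  if (cfg$tan_noise_sd > 0) tan <- pmax(tan + rnorm(length(tan), 0, cfg$tan_noise_sd), 0)
  if (cfg$talk_noise_sd > 0) talk <- pmax(talk + rnorm(length(talk), 0, cfg$talk_noise_sd), 0)

  titrant_n <- 0.01
  sample_l <- 0.010
  samples <- tibble::tibble(
    animal_id = animal_id, genotype = group, time_h = times,
    tan_umol_l = tan, talk_ueq_l = talk,
    titrant_ml = talk * 1e-6 * sample_l / titrant_n * 1000,
    titrant_n = titrant_n, sample_ml = sample_l * 1000,
    volume_l = v, mass_kg = mass_kg
  )
  truth <- tibble::tibble(
    animal_id = animal_id, genotype = group, mass_kg = mass_kg,
    start = starts, end = ends, j_tamm = j_tamm, j_talk = j_talk,
    baseline_jtamm = cfg$baseline_jtamm
  )
  list(samples = samples, truth = truth)
}

#' Simulate static-chamber water-sample series
#'
#' Piecewise-constant true ammonia and titratable-alkalinity fluxes (post-feed
#' excess decaying with a half-life) are integrated into chamber
#' concentrations at the sampling times, plus optional measurement noise.
#' Alkalinity is also expressed as the titrant volume that would reach the
#' pH 4.0 endpoint, so the titration arithmetic can be exercised end to end.
#'
#' @inheritParams simulate_resp_trace
#' @return list with `samples` (tibble of water samples across both groups)
#'   and `truth` (tibble of per-interval true fluxes).
#' @export
simulate_flux_study <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  ids <- c(sprintf("wt%02d", seq_len(cfg$n_per_group)),
           sprintf("ko%02d", seq_len(cfg$n_per_group)))
  groups <- rep(c("wt", "ko"), each = cfg$n_per_group)
  out <- Map(function(id, g) gen_one_flux(cfg, id, g), ids, groups)
  list(samples = dplyr::bind_rows(lapply(out, `[[`, "samples")),
       truth = dplyr::bind_rows(lapply(out, `[[`, "truth")))
}

#' @rdname simulate_flux_study
#' @param animal_id animal label.
#' @param group `"wt"` or `"ko"`.
#' @export
simulate_flux_series <- function(cfg = sim_config(), animal_id = "a1",
                                 group = c("wt", "ko"), seed = cfg$seed) {
  group <- match.arg(group)
  set.seed(seed)
  gen_one_flux(cfg, animal_id, group)
}

#' Simulate a growth trial
#'
#' Exponential mass trajectories over an 8-week trial structured as 3 control,
#' 2 drug-treatment and 3 recovery weeks. The instantaneous growth rate is
#' multiplied by `1 - drug_depression_fraction` during the depressed weeks
#' (by default the second treatment week through the second recovery week).
#' Feed follows the daily ration re-set from each week's starting mass.
#'
#' @inheritParams simulate_resp_trace
#' @return list with `records` (tibble consumable by [growth_table()]) and
#'   `truth` (per animal-week true growth rates, % day-1).
#' @export
simulate_growth <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  periods <- c(rep("control", 3), rep("omeprazole", 2), rep("recovery", 3))
  n_weeks <- length(periods)
  rows <- list()
  truths <- list()
  k <- 0
  for (group in c("wt", "ko")) {
    for (i in seq_len(cfg$n_per_group)) {
      id <- sprintf("%s%02d", group, i)
      mass <- max(rnorm(1, cfg$mass0_mean[[group]], cfg$mass0_sd), 0.02)
      for (w in seq_len(n_weeks)) {
        dep <- w %in% cfg$depressed_weeks
        g_true <- cfg$base_g * (1 - if (dep) cfg$drug_depression_fraction else 0)
        g_week <- g_true + rnorm(1, 0, cfg$growth_sd)
        mass_end <- mass * exp(g_week / 100 * 7)
        feed_mg <- ration_mass(mass, cfg$ration_fraction) * 7 * 1000
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          animal_id = id, genotype = group, week = w, period = periods[w],
          mass_start = mass, mass_end = mass_end, feed_mg = feed_mg)
        truths[[k]] <- tibble::tibble(
          animal_id = id, genotype = group, week = w,
          g_true = g_true, g_realized = g_week, depressed = dep)
        mass <- mass_end
      }
    }
  }
  list(records = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truths))
}

#' Simulate a qPCR Ct table
#'
#' Reference genes are constant in expectation across groups; target genes are
#' shifted by per-gene log2 effects in the knockout group. A shared per-sample
#' Ct offset emulates RNA-input variation and is removed by multi-reference
#' normalization.
#'
#' @inheritParams simulate_resp_trace
#' @return list with `table` (Ct tibble consumable by [ddct()]) and `truth`
#'   (named log2 knockout effects).
#' @export
simulate_ct_table <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  ref_genes <- c("ef1a", "r18s", "gapdh")
  base_ct <- c(ef1a = 18, r18s = 12, gapdh = 16)
  targets <- names(cfg$qpcr_effects)
  target_base <- setNames(rep(25, length(targets)), targets)
  eff_pct <- setNames(rep(100, length(ref_genes) + length(targets)),
                      c(ref_genes, targets))
  if ("cck" %in% targets) eff_pct["cck"] <- 95.3

  rows <- list()
  k <- 0
  for (group in c("wt", "ko")) {
    for (i in seq_len(cfg$n_per_group)) {
      id <- sprintf("%s%02d", group, i)
      offset <- rnorm(1, 0, cfg$sample_offset_sd)
      for (gene in c(ref_genes, targets)) {
        shift <- 0
        if (gene %in% targets && group == "ko") {
          shift <- -cfg$qpcr_effects[[gene]]  # lower expression = later Ct
        }
        base <- if (gene %in% ref_genes) base_ct[[gene]] else target_base[[gene]]
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          sample_id = id, group = group, gene = gene,
          ct = base + offset + shift + rnorm(1, 0, cfg$ct_sd),
          efficiency_pct = eff_pct[[gene]],
          is_reference = gene %in% ref_genes)
      }
    }
  }
  list(table = dplyr::bind_rows(rows), truth = cfg$qpcr_effects)
}
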