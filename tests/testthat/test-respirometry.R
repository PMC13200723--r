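test_that("oxygen decline slope converts to a mass-specific rate", {
  # 10 umol/l fall over 10 min in a 40 ml chamber holding a 0.4 g fish:
  # slope -60 umol/l/h, effective volume 39.6 ml -> 60 * 0.0396 / 0.4 = 5.94
  tr <- resp_trace(measure_cycle(0, 250, slope_per_h = 60),
                   animal_id = "f1", mass = 0.4, chamber_volume = 40)
  ser <- compute_mo2(tr)
  expect_equal(ser$mo2, 5.94, tolerance = 1e-12)
  expect_equal(ser$r_squared, 1)
  expect_true(ser$qc_pass)
  expect_equal(ser$midpoint_time, 10 / 60 / 2)
})

test_that("cycle QC flags flat, rising, short and noisy regressions", {
  flat <- measure_cycle(0, 250, 0, cycle = 1L)
  rising <- measure_cycle(0.25, 250, -30, cycle = 2L)     # O2 increasing
  short <- measure_cycle(0.5, 250, 60, n = 3, cycle = 3L)
  noisy <- measure_cycle(0.75, 250, 60, cycle = 4L)
  # a balanced zigzag keeps the decline negative but wrecks the fit
  noisy$o2 <- noisy$o2 + rep_len(c(4, -4), 11)
  tr <- resp_trace(dplyr::bind_rows(flat, rising, short, noisy),
                   animal_id = "f1", mass = 0.4, chamber_volume = 40)
  ser <- compute_mo2(tr)
  expect_equal(ser$mo2[1], 0)
  expect_true(ser$qc_pass[1])         # flat but perfectly fit cycle passes
  expect_false(ser$qc_pass[2])
  expect_equal(ser$qc_reason[2], "positive slope")
  expect_false(ser$qc_pass[3])
  expect_equal(ser$qc_reason[3], "too few points")
  expect_false(ser$qc_pass[4])
  expect_equal(ser$qc_reason[4], "low r2")
})

test_that("degenerate traces are rejected", {
  flushes <- tibble::tibble(time = 1:3 / 10, o2 = 250, phase = "flush",
                            cycle_index = NA_integer_)
  tr <- resp_trace(flushes, animal_id = "f1", mass = 0.4, chamber_volume = 40)
  expect_error(compute_mo2(tr), "empty trace")
  bad <- measure_cycle(0, 250, 60)
  bad$time[5] <- bad$time[3]
  expect_error(resp_trace(bad, "f1", 0.4, 40), "strictly increasing")
  expect_error(resp_trace(measure_cycle(0, 250, 60), "f1", 0.4,
                          chamber_volume = 0.3), "exceed")
})

test_that("SMR is the mean of the lowest quantile of window cycles", {
  cfg <- sda_config(smr_window_fraction = 1, smr_quantile = 0.2,
                    smooth_cycles = 1, smr_smooth_cycles = 1)
  expect_equal(estimate_smr(make_series(1:5, rep(5, 5)), cfg), 5)
  # lowest 20% of {4..13} is {4, 5}
  expect_equal(estimate_smr(make_series(1:10, 4:13), cfg), 4.5)
  expect_error(
    estimate_smr(make_series(1:2, c(5, 6)),
                 sda_config(min_cycles_for_smr = 3, smr_window_fraction = 1)),
    "insufficient data")
})

test_that("SMR window defaults to the final quarter of the record", {
  # elevated early rates must not contaminate the late-window estimate
  cfg <- sda_config(smr_smooth_cycles = 1, smr_quantile = 1)
  mo2 <- c(rep(9, 15), rep(5, 5))
  expect_equal(estimate_smr(make_series(seq(0, 19), mo2), cfg), 5)
})

test_that("a response that never leaves SMR has zero duration and magnitude", {
  ser <- make_series(seq(0, 20, by = 0.5), rep(5, 41))
  res <- extract_sda(ser, smr = 5, sda_config(smooth_cycles = 1))
  expect_equal(res$duration, 0)
  expect_equal(res$net_peak, 0)
  expect_equal(res$magnitude, 0)
})

test_that("a triangular response is integrated exactly on its grid", {
  tt <- seq(0, 20, by = 0.5)
  ser <- make_series(tt, 5 + tent(tt, 3, 7.5))
  res <- extract_sda(ser, smr = 5,
                     sda_config(smooth_cycles = 1, end_tolerance = 0))
  expect_equal(res$net_peak, 3, tolerance = 1e-12)
  expect_equal(res$sda_end, 15)
  expect_equal(res$duration, 15)
  # trapezoid of a piecewise-linear tent with knots on the grid is exact
  expect_equal(res$magnitude, 0.5 * 3 * 15, tolerance = 1e-12)
  expect_false(res$excluded)
})

test_that("short responses are flagged as regurgitation", {
  tt <- seq(0, 20, by = 0.5)
  ser <- make_series(tt, 5 + tent(tt, 3, 1.5))  # back at SMR by 3 h
  res <- extract_sda(ser, smr = 5,
                     sda_config(smooth_cycles = 1, end_tolerance = 0))
  expect_true(res$excluded)
  expect_equal(res$exclusion_reason, "regurgitation")
  expect_lt(res$duration, 4)
})

test_that("animals with mostly failing cycles are excluded for activity", {
  tt <- seq(0, 20, by = 0.5)
  ser <- make_series(tt, 5 + tent(tt, 3, 7.5),
                     qc_pass = rep(c(TRUE, FALSE), length.out = length(tt)))
  res <- extract_sda(ser, smr = 5, sda_config(smooth_cycles = 1))
  expect_true(res$excluded)
  expect_equal(res$exclusion_reason, "activity")
  expect_error(extract_sda(ser, smr = -1), "positive")
})

test_that("magnitude equals an independent trapezoid on the same grid", {
  set.seed(7)
  for (i in 1:20) {
    tt <- sort(runif(60, 0, 24))
    smr <- runif(1, 3, 8)
    mo2 <- smr + runif(1, 0.5, 4) + abs(sin(tt)) * runif(1, 0.5, 2)
    ser <- make_series(tt, mo2)
    res <- extract_sda(ser, smr,
                       sda_config(smooth_cycles = 1, min_duration = 0))
    excess <- pmax(mo2 - smr, 0)
    oracle <- sum(diff(tt) * (excess[-length(tt)] + excess[-1]) / 2)
    expect_equal(res$magnitude, oracle, tolerance = 1e-9)
    expect_equal(res$sda_end, max(tt))  # never recovers: clipped to record end
  }
})

test_that("magnitude is shift-invariant and scales with bump amplitude", {
  tt <- seq(0, 20, by = 0.5)
  base <- tent(tt, 1, 7.5)
  cfg <- sda_config(smooth_cycles = 1, end_tolerance = 0)
  m1 <- extract_sda(make_series(tt, 5 + 2 * base), 5, cfg)$magnitude
  m2 <- extract_sda(make_series(tt + 13.7, 5 + 2 * base), 5, cfg)$magnitude
  m3 <- extract_sda(make_series(tt, 5 + 6 * base), 5, cfg)$magnitude
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(m3, 3 * m1, tolerance = 1e-12)
})

test_that("long-format CSVs round-trip into traces", {
  sim <- simulate_resp_trace(sim_config(), "fish_a", "wt", seed = 33)
  tr <- sim$trace
  trace_csv <- tempfile(fileext = ".csv")
  meta_csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(animal_id = "fish_a", time_h = tr$time,
                              o2_umol_l = tr$o2, phase = tr$phase,
                              cycle = tr$cycle_index),
                   trace_csv, row.names = FALSE)
  utils::write.csv(data.frame(animal_id = "fish_a", genotype = "wt",
                              mass_g = attr(tr, "mass"), chamber_ml = 40,
                              fish_ml = attr(tr, "fish_volume")),
                   meta_csv, row.names = FALSE)
  loaded <- read_resp_trace(trace_csv, meta_csv)
  expect_named(loaded, "fish_a")
  a <- analyze_sda(loaded$fish_a)
  b <- analyze_sda(tr)
  expect_equal(a$magnitude, b$magnitude, tolerance = 1e-9)
  expect_equal(a$smr, b$smr, tolerance = 1e-9)
})

test_that("noise-free synthetic declines regress back perfectly", {
  sim <- simulate_resp_trace(
    sim_config(cycle_noise_sd = 0, activity_spike_rate = 0),
    "a1", "wt", seed = 21)
  ser <- compute_mo2(sim$trace)
  expect_true(all(ser$r_squared == 1))
  expect_true(all(ser$qc_pass))
  truth <- sim$truth
  expected <- truth$smr + sdaflux:::sda_bump(ser$midpoint_time, truth$peak,
                                             truth$duration, 0.45)
  expect_equal(ser$mo2, expected, tolerance = 1e-9)
})
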