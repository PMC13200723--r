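test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_per_group = 2)
  a <- simulate_resp_trace(cfg, "a1", "wt", seed = 5)
  b <- simulate_resp_trace(cfg, "a1", "wt", seed = 5)
  expect_identical(as.data.frame(a$trace), as.data.frame(b$trace))
  expect_identical(a$truth, b$truth)
  expect_false(identical(as.data.frame(a$trace),
                         as.data.frame(simulate_resp_trace(cfg, "a1", "wt",
                                                           seed = 6)$trace)))
  expect_identical(simulate_flux_study(cfg, seed = 5),
                   simulate_flux_study(cfg, seed = 5))
  expect_identical(simulate_growth(cfg, seed = 5),
                   simulate_growth(cfg, seed = 5))
  expect_identical(simulate_ct_table(cfg, seed = 5),
                   simulate_ct_table(cfg, seed = 5))
})

test_that("noise-free respirometry simulation inverts through the analyzer", {
  cfg <- sim_config(cycle_noise_sd = 0, activity_spike_rate = 0)
  sim <- simulate_resp_trace(cfg, "a1", "ko", seed = 8)
  ser <- compute_mo2(sim$trace)
  truth <- sim$truth
  # the regression recovers the generator rate exactly at cycle midpoints
  expect_equal(ser$mo2,
               truth$smr + sdaflux:::sda_bump(ser$midpoint_time, truth$peak,
                                              truth$duration, 0.45),
               tolerance = 1e-9)
  res <- extract_sda(ser, estimate_smr(ser), sda_config())
  expect_equal(res$smr, truth$smr, tolerance = 1e-9)
  expect_equal(res$net_peak, truth$peak, tolerance = 0.01)
  expect_equal(res$duration, truth$duration, tolerance = 0.05)
  expect_equal(res$magnitude, truth$magnitude, tolerance = 0.05)
})

test_that("forced regurgitation excludes every animal", {
  cfg <- sim_config(regurgitation_prob = 1, cycle_noise_sd = 0,
                    activity_spike_rate = 0, n_per_group = 3)
  study <- simulate_respirometry_study(cfg, seed = 12)
  res <- sda_table(lapply(study$traces, analyze_sda))
  expect_true(all(res$excluded))
  expect_true(all(res$exclusion_reason == "regurgitation"))
})

test_that("noise-free flux series round-trip through net_flux exactly", {
  cfg <- sim_config(tan_noise_sd = 0, talk_noise_sd = 0, n_per_group = 2)
  sim <- simulate_flux_series(cfg, "a1", "wt", seed = 13)
  s <- sim$samples
  tam <- flux_table(s$time_h, s$tan_umol_l, s$volume_l[1], s$mass_kg[1])
  alk <- flux_table(s$time_h, s$talk_ueq_l, s$volume_l[1], s$mass_kg[1],
                    analyte = "TAlk")
  expect_equal(tam$flux, sim$truth$j_tamm, tolerance = 1e-9)
  expect_equal(alk$flux, sim$truth$j_talk, tolerance = 1e-9)
  # titration volumes reproduce the alkalinity they encode
  expect_equal(titratable_alkalinity(s$titrant_ml / 1000, s$titrant_n[1],
                                     s$sample_ml[1] / 1000),
               sum(s$talk_ueq_l), tolerance = 1e-9)
})

test_that("cumulative excess ammonia matches a fine-grid integral of truth", {
  cfg <- sim_config(tan_noise_sd = 0, talk_noise_sd = 0, n_per_group = 1)
  sim <- simulate_flux_series(cfg, "a1", "wt", seed = 14)
  tr <- sim$truth
  got <- cumulative_tan(tr$j_tamm, tr$start, tr$end, tr$baseline_jtamm[1],
                        tr$mass_kg[1])
  # brute-force Riemann sum on a 0.001 h grid over the piecewise-constant truth
  grid <- seq(min(tr$start), max(tr$end), by = 0.001)
  grid <- grid[-length(grid)] + 0.0005
  j_at <- tr$j_tamm[findInterval(grid, tr$start)]
  oracle <- sum(pmax(j_at - tr$baseline_jtamm[1], 0) * tr$mass_kg[1] * 0.001)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("post-feed ammonia excretion is elevated and group-contrasted", {
  cfg <- sim_config(tan_noise_sd = 0, talk_noise_sd = 0, n_per_group = 1)
  wt <- simulate_flux_series(cfg, "w", "wt", seed = 15)$truth
  ko <- simulate_flux_series(cfg, "k", "ko", seed = 15)$truth
  expect_equal(wt$j_tamm[1] / ko$j_tamm[1], 3.65, tolerance = 0.01)
  excess_ratio <- (wt$j_tamm[1] - wt$baseline_jtamm[1]) /
    (ko$j_tamm[1] - ko$baseline_jtamm[1])
  expect_equal(excess_ratio, 5, tolerance = 0.01)
  expect_true(all(diff(wt$j_tamm) < 0))  # post-feed excess decays
})

test_that("zero-noise growth recovers the generator rates exactly", {
  cfg <- sim_config(growth_sd = 0, n_per_group = 2)
  sim <- simulate_growth(cfg, seed = 16)
  gt <- growth_table(sim$records)
  expect_equal(gt$G, sim$truth$g_true, tolerance = 1e-9)
  dep <- gt$week %in% cfg$depressed_weeks
  expect_equal(mean(gt$G[dep]) / mean(gt$G[!dep]), 1 - 0.452,
               tolerance = 1e-9)
  # no drug depression: flat growth across all periods
  flat <- simulate_growth(sim_config(growth_sd = 0, n_per_group = 1,
                                     drug_depression_fraction = 0), seed = 17)
  expect_equal(diff(range(growth_table(flat$records)$G)), 0, tolerance = 1e-9)
})

test_that("expression effects propagate through ddct at cohort scale", {
  null_cfg <- sim_config(n_per_group = 10, ct_sd = 0,
                         qpcr_effects = c(cck = 0))
  nf <- ddct(simulate_ct_table(null_cfg, seed = 18)$table, "cck", "wt")
  expect_equal(nf$fold, rep(1, 20), tolerance = 1e-9)
  big <- sim_config(n_per_group = 50, qpcr_effects = c(cck = -1))
  f <- ddct(simulate_ct_table(big, seed = 19)$table, "cck", "wt")
  ko_mean <- mean(f$fold[f$group == "ko"])
  expect_equal(ko_mean, 0.5, tolerance = 0.05)
})
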