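# Build a minimal mo2_series by hand (bypassing the trace regression) so SMR
# and SDA logic can be exercised on exactly known cycle values.
make_series <- function(time, mo2, qc_pass = TRUE, animal_id = "t1") {
  structure(
    tibble::tibble(cycle_index = seq_along(time), midpoint_time = time,
                   mo2 = mo2, r_squared = 1, n_points = 10L,
                   qc_pass = rep_len(qc_pass, length(time)),
                   qc_reason = ifelse(rep_len(qc_pass, length(time)), "", "low r2")),
    class = c("mo2_series", class(tibble::tibble())),
    animal_id = animal_id, genotype = "wt", mass = 0.4)
}

# Symmetric triangular excess profile: 0 at t = 0, apex `height` at t = half,
# back to 0 at t = 2 * half, 0 afterwards.
tent <- function(t, height, half) {
  pmax(height * (1 - abs(t - half) / half), 0)
}

# Linear-decline measure cycle samples for building traces by hand.
measure_cycle <- function(start_h, o2_start, slope_per_h, n = 11,
                          length_h = 10 / 60, cycle = 1L) {
  tt <- start_h + seq(0, length_h, length.out = n)
  tibble::tibble(time = tt, o2 = o2_start - slope_per_h * (tt - start_h),
                 phase = "measure", cycle_index = as.integer(cycle))
}
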