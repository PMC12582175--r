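test_that("subthreshold sweeps yield no spikes", {
  np <- neuron_params()
  sim <- simulate_current_clamp(np, steps_pA = c(-20, 0, 50))
  for (sw in 1:3)
    expect_identical(nrow(detect_spikes(sim$sweepset, sw)), 0L)
})

test_that("piecewise-linear spike gives closed-form threshold and width", {
  fix <- ramp_spike_sweep(v_base = -55, v_peak = 20, rise_slope = 20,
                          fall_slope = -15)
  sp <- detect_spikes(fix$ss, 1)
  expect_identical(nrow(sp), 1L)
  # ramp rises at 20 mV/ms > 10 mV/ms criterion from its first sample:
  # the detected threshold lies within one sample of the ramp foot
  expect_equal(sp$threshold_mV, fix$threshold_mV, tolerance = 0.15)
  expect_equal(sp$peak_mV, fix$peak_mV)
  expect_equal(sp$amplitude_mV, fix$amplitude_mV, tolerance = 0.15)
  expect_equal(sp$half_width_ms, fix$half_width_ms, tolerance = 0.02)
  expect_equal(sp$max_rise_slope_mV_per_ms, 20, tolerance = 1)
  expect_equal(sp$max_decay_slope_mV_per_ms, -15, tolerance = 1)
})

test_that("peaks below -10 mV are not counted as spikes", {
  fix <- ramp_spike_sweep(v_base = -60, v_peak = -15, rise_slope = 20,
                          fall_slope = -15)
  expect_identical(nrow(detect_spikes(fix$ss, 1)), 0L)
  # identical construction peaking at -5 mV is counted
  fix2 <- ramp_spike_sweep(v_base = -60, v_peak = -5, rise_slope = 20,
                           fall_slope = -15)
  expect_identical(nrow(detect_spikes(fix2$ss, 1)), 1L)
})

test_that("spike features are invariant to a uniform time shift", {
  a <- ramp_spike_sweep(t_start_s = 0.15)
  b <- ramp_spike_sweep(t_start_s = 0.25)
  sa <- detect_spikes(a$ss, 1, epoch = c(0.1, 0.2))
  sb <- detect_spikes(b$ss, 1, epoch = c(0.2, 0.2))
  expect_equal(sb$peak_time_s - sa$peak_time_s, 0.1, tolerance = 1e-9)
  for (col in c("peak_mV", "threshold_mV", "amplitude_mV", "half_width_ms",
                "max_rise_slope_mV_per_ms", "max_decay_slope_mV_per_ms"))
    expect_equal(sb[[col]], sa[[col]], tolerance = 1e-9)
})

test_that("exactly linear F-I families recover the construction slope", {
  # 1 extra spike per 50 pA: slope 0.02 spikes/pA
  steps <- seq(0, 400, 50)
  fam <- constructed_fi_family(counts = 0:8, step_pA = steps)
  fi <- fi_analysis(fam)
  expect_identical(fi$spike_counts$n_spikes, as.numeric(0:8))
  expect_equal(fi$fi_gain_spikes_per_pA, 0.02, tolerance = 1e-12)
  expect_equal(fi$rheobase_pA, 50)
  expect_equal(fi$total_spike_output, sum(0:8))
})

test_that("F-I range ends at the lowest-current maximum-count step", {
  counts <- c(0, 0, 2, 4, 6, 6, 5)
  steps <- seq(0, 300, 50)
  fam <- constructed_fi_family(counts, steps)
  fi <- fi_analysis(fam)
  # prefix [0, 200] pA: counts 0,0,2,4,6 — hand-computed OLS slope
  x <- steps[1:5]; y <- counts[1:5]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fi$fi_gain_spikes_per_pA, slope, tolerance = 1e-12)
  expect_equal(fi$max_firing_sweep_pA, 200)
  expect_equal(fi$total_spike_output, 12)
  expect_equal(fi$rheobase_pA, 100)
})

test_that("spikeless families report absent rheobase and zero gain", {
  fam <- constructed_fi_family(rep(0, 5), seq(0, 200, 50))
  fi <- fi_analysis(fam)
  expect_true(is.na(fi$rheobase_pA))
  expect_equal(fi$fi_gain_spikes_per_pA, 0)
  expect_equal(fi$total_spike_output, 0)
})

test_that("adaptation index follows the half-count arithmetic", {
  steps <- c(0, 50, 100)
  # regular even train -> 0
  fam <- constructed_fi_family(c(0, 4, 8), steps)
  expect_equal(adaptation_index(fam, rheobase_pA = 50), 0)
  # 7 spikes: 5 in the first half, 2 in the second -> 3/7
  n <- round(1.4 * 20000)
  v <- rep(-65, n)
  times <- c(0.25 + (0:4) * 0.05, 0.75, 0.95)
  for (tm in times) {
    j <- round(tm * 20000) + 1
    v[(j - 10):j] <- seq(-55, 20, length.out = 11)
    v[j:(j + 20)] <- seq(20, -65, length.out = 21)
  }
  ss <- sweepset(list(v), 20000, "current_clamp",
                 stimulus = data.frame(onset = 0.2, duration = 1,
                                       amplitude = 100))
  expect_equal(adaptation_index(ss, rheobase_pA = 50), 3 / 7,
               tolerance = 1e-12)
  # all spikes in the first half -> +1
  fam3 <- constructed_fi_family(c(0, 0, 3), steps)
  ss3 <- fam3
  # compress spike times into the first half
  v3 <- rep(-65, length(fam3$sweeps[[3]]))
  for (tm in c(0.25, 0.35, 0.45)) {
    j <- round(tm * 20000) + 1
    v3[(j - 10):j] <- seq(-55, 20, length.out = 11)
    v3[j:(j + 20)] <- seq(20, -65, length.out = 21)
  }
  ss3$sweeps[[3]] <- v3
  expect_equal(adaptation_index(ss3, rheobase_pA = 50), 1)
})

test_that("adaptation index stays within [-1, 1] over random patterns", {
  set.seed(14)
  for (i in 1:10) {
    k <- sample(1:10, 1)
    fam <- constructed_fi_family(c(0, k), c(0, 100))
    ai <- adaptation_index(fam, rheobase_pA = 50)
    expect_gte(ai, -1)
    expect_lte(ai, 1)
  }
})

test_that("passive properties recover the analytic RC membrane", {
  ss <- rc_step_trace(R_MOhm = 150, tau_ms = 15, I_pA = -20)
  p <- passive_properties(ss)
  expect_lt(abs(p$rin_MOhm - 150) / 150, 0.02)
  expect_lt(abs(p$tc_ms - 15) / 15, 0.05)
  expect_equal(p$cin_pF, 1000 * p$tc_ms / p$rin_MOhm)   # exact identity
  expect_equal(p$sag_ratio, 1, tolerance = 0.01)
  expect_equal(p$rmp_mV, -65, tolerance = 1e-9)
})

test_that("sag ratio is the peak-to-steady deflection ratio", {
  # constructed trace: peak deflection -10 mV, steady last-50 ms mean -8 mV
  fs <- 20000
  tt <- (seq_len(fs) - 1) / fs
  v <- rep(-65, fs)
  on <- tt >= 0.2 & tt < 0.8
  te <- (tt[on] - 0.2) * 1000
  v[on] <- -65 - 10 * (1 - exp(-te / 10)) + 2 * (1 - exp(-te / 60))
  ss <- sweepset(list(v), fs, "current_clamp",
                 stimulus = data.frame(onset = 0.2, duration = 0.6,
                                       amplitude = -20))
  p <- passive_properties(ss)
  expect_equal(p$sag_ratio, abs(min(v[on]) + 65) /
                 abs(mean(v[tt >= 0.75 & tt < 0.8]) + 65),
               tolerance = 1e-9)
  expect_gt(p$sag_ratio, 1.05)
})

test_that("sag ratio grows with the simulator's sag conductance", {
  sags <- c(0, 2, 4)
  ratios <- vapply(sags, function(g) {
    sim <- simulate_current_clamp(neuron_params(sag_nS = g),
                                  steps_pA = -60, duration_s = 1,
                                  sweep_s = 1.4)
    passive_properties(sim$sweepset)$sag_ratio
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], 1, tolerance = 0.01)
  expect_gt(ratios[3], 1.05)
})

test_that("intrinsic_profile wires the component analyses together", {
  np <- neuron_params(R_MOhm = 150, C_pF = 100, b_pA = 60)
  sim <- simulate_current_clamp(np, steps_pA = c(-20, seq(0, 400, 50)))
  prof <- intrinsic_profile(sim$sweepset)
  expect_equal(prof$rheobase_pA %% 50, 0)
  expect_equal(prof$cin_pF, 1000 * prof$tc_ms / prof$rin_MOhm)
  truth <- vapply(sim$ground_truth$spike_times, length, numeric(1))
  expect_identical(prof$spike_counts$n_spikes[order(prof$spike_counts$current_pA)],
                   truth[order(sim$ground_truth$steps_pA)])
  expect_true(prof$adaptation_index >= -1 && prof$adaptation_index <= 1)
})
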