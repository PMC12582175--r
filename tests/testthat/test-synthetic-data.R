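test_that("passive limit of the membrane simulator matches the RC circuit", {
  np <- neuron_params(R_MOhm = 150, C_pF = 100, sag_nS = 0)
  sim <- simulate_current_clamp(np, steps_pA = -20, onset_s = 0.2,
                                duration_s = 0.6, sweep_s = 1)
  v <- sim$sweepset$sweeps[[1]]
  fs <- sim$sweepset$sampling_rate
  # Ohm's law: steady-state deflection -3 mV
  ss_dev <- mean(v[round(0.75 * fs):round(0.8 * fs)]) - (-65)
  expect_equal(ss_dev, -3, tolerance = 0.01)
  # mono-exponential relaxation with tau = R*C = 15 ms: compare the whole
  # step segment against the closed form
  ref <- rc_step_trace(150, 15, -20)$sweeps[[1]]
  on <- (round(0.2 * fs) + 1):round(0.8 * fs)
  expect_lt(max(abs(v[on] - ref[on])), 0.02)
  # sag-free: sag ratio 1 within 1%
  p <- passive_properties(sim$sweepset)
  expect_equal(p$sag_ratio, 1, tolerance = 0.01)
})

test_that("integrator converges to the dense-step reference", {
  np <- neuron_params(R_MOhm = 120, C_pF = 90, sag_nS = 2, b_pA = 50)
  coarse <- simulate_current_clamp(np, steps_pA = c(-20, 200),
                                   duration_s = 1)
  fine <- simulate_current_clamp(np, steps_pA = c(-20, 200),
                                 duration_s = 1, dt_divisor = 10L)
  # same spike counts, spike times within 1 ms
  for (sw in 1:2) {
    st_c <- coarse$ground_truth$spike_times[[sw]]
    st_f <- fine$ground_truth$spike_times[[sw]]
    expect_length(st_c, length(st_f))
    if (length(st_c))
      expect_lt(max(abs(st_c - st_f)), 0.001)
  }
  # subthreshold sweep nearly identical between integrations
  expect_lt(max(abs(coarse$sweepset$sweeps[[1]] -
                      fine$sweepset$sweeps[[1]])), 0.05)
})

test_that("spike-triggered adaptation produces non-decreasing ISIs", {
  np <- neuron_params(b_pA = 60, tau_w_ms = 200, sag_nS = 0)
  sim <- simulate_current_clamp(np, steps_pA = 250, duration_s = 1)
  st <- sim$ground_truth$spike_times[[1]]
  expect_gt(length(st), 3)
  isi <- diff(st)
  expect_true(all(diff(isi) > -1e-6))
})

test_that("event generator realizes the configured Poisson process", {
  gp <- event_gen_params(rate_Hz = 2)
  vc <- simulate_voltage_clamp(gp, n_sweeps = 10, sweep_s = 30, seed = 5)
  n_ev <- nrow(vc$ground_truth$events)
  expect_lt(abs(n_ev - 600), 3 * sqrt(600))
  expect_true(all(vc$ground_truth$events$time_s >= 0 &
                    vc$ground_truth$events$time_s <= 30))
  # rate 0: truth empty, trace is pulse + noise only
  vc0 <- simulate_voltage_clamp(event_gen_params(rate_Hz = 0,
                                                 noise_sd_pA = 0),
                                n_sweeps = 1, sweep_s = 2, seed = 5)
  expect_identical(nrow(vc0$ground_truth$events), 0L)
  post <- vc0$sweepset$sweeps[[1]][(1 * 20000):(2 * 20000 - 1)]
  expect_lt(max(abs(post)), 0.5)
})

test_that("kernel is peak-normalized so amplitudes are trace amplitudes", {
  k <- psc_kernel(0.5, 8, 20000)
  expect_equal(max(k), 1)
  # noise-free single 20 pA event: post-pulse trace minimum exactly -20
  ss <- planted_event_sweep(5, 20, sweep_s = 8)
  expect_equal(min(ss$sweeps[[1]]), -20, tolerance = 1e-9)
})

test_that("evoked-train generator follows the plasticity recurrence", {
  p <- stp_params(A1_pA = 100, U = 0.2, tau_rec_s = 0.5, noise_sd_pA = 0)
  expect_equal(tm_amplitudes(p),
               tm_oracle(100, 0.2, 0.5, 0, 10, 10), tolerance = 1e-12)
  # facilitation path against the oracle
  pf <- stp_params(A1_pA = 80, U = 0.15, tau_rec_s = 0.3, tau_facil_s = 0.5,
                   noise_sd_pA = 0)
  expect_equal(tm_amplitudes(pf),
               tm_oracle(80, 0.15, 0.3, 0.5, 10, 10), tolerance = 1e-12)
  # U = 1, no facilitation: pulses 2..n all equal the recovery factor
  pd <- stp_params(A1_pA = 100, U = 1, tau_rec_s = 0.5, noise_sd_pA = 0)
  amps <- tm_amplitudes(pd)
  rec <- 1 - exp(-0.1 / 0.5)
  expect_equal(amps[-1] / amps[1], rep(rec, 9), tolerance = 1e-12)
  # single pulse
  p1 <- stp_params(n_pulses = 1, noise_sd_pA = 0)
  tr <- simulate_evoked_train(p1)
  expect_equal(train_metrics(tr$sweepset)$normalized_amplitudes, 1)
})

test_that("generators are bit-reproducible given a seed", {
  a <- simulate_voltage_clamp(event_gen_params(rate_Hz = 1), n_sweeps = 2,
                              sweep_s = 5, seed = 11)
  b <- simulate_voltage_clamp(event_gen_params(rate_Hz = 1), n_sweeps = 2,
                              sweep_s = 5, seed = 11)
  expect_identical(a$sweepset$sweeps, b$sweepset$sweeps)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  t1 <- simulate_evoked_train(stp_params(), seed = 4)
  t2 <- simulate_evoked_train(stp_params(), seed = 4)
  expect_identical(t1$sweepset$sweeps, t2$sweepset$sweeps)
  c1 <- simulate_current_clamp(neuron_params(), steps_pA = c(-20, 200),
                               noise_sd_mV = 0.2, seed = 9)
  c2 <- simulate_current_clamp(neuron_params(), steps_pA = c(-20, 200),
                               noise_sd_mV = 0.2, seed = 9)
  expect_identical(c1$sweepset$sweeps, c2$sweepset$sweeps)
})

test_that("cell-table generator reproduces the configured design", {
  design <- data.frame(
    region = c("RSP", "ACA", "RSP"),
    cluster_label = c("133_L2 IT RSPv-POST-PRE", "245_L5 IT CTX", "VLMC"),
    mean = c(0.1, 5.0, 0),
    dispersion = c(2, 2, 2),
    n_cells = c(2000, 2000, 50))
  tab <- generate_cell_table(design, seed = 21)
  expect_identical(nrow(tab), 4050L)
  # cluster labels verbatim
  expect_setequal(unique(tab$cluster_label), design$cluster_label)
  # zero-mean group all zero
  expect_true(all(tab$target_gene_count[tab$cluster_label == "VLMC"] == 0))
  # CLT: sample means within 10% of truth for the large groups
  m1 <- mean(tab$target_gene_count[tab$cluster_label ==
                                     "133_L2 IT RSPv-POST-PRE"])
  m2 <- mean(tab$target_gene_count[tab$cluster_label == "245_L5 IT CTX"])
  expect_lt(abs(m1 - 0.1) / 0.1, 0.10)
  expect_lt(abs(m2 - 5.0) / 5.0, 0.10)
  # reproducible
  expect_identical(tab, generate_cell_table(design, seed = 21))
})
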