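test_that("sweepset enforces its structural invariants", {
  expect_error(sweepset(list(1:10, 1:9), 1000, "current_clamp"),
               "unequal lengths")
  expect_error(sweepset(list(rnorm(10)), -1, "current_clamp"), "positive")
  expect_error(
    sweepset(list(rnorm(100)), 1000, "current_clamp",
             stimulus = data.frame(onset = 0.05, duration = 0.2,
                                   amplitude = 10)),
    "outside the sweep")
})

test_that("csv+json dialect round-trips sweepsets bit-exactly", {
  for (seed in 1:4) {
    ss <- random_sweepset(seed, mode = if (seed %% 2) "voltage_clamp"
                          else "current_clamp")
    path <- file.path(tempdir(), sprintf("rt_%d.csv", seed))
    save_sweepset(ss, path)
    back <- load_sweepset(path)
    expect_identical(back$sweeps, ss$sweeps)
    expect_identical(back$sampling_rate, ss$sampling_rate)
    expect_identical(back$clamp_mode, ss$clamp_mode)
    expect_equal(back$stimulus[[1]], ss$stimulus[[1]])
    expect_identical(back$annotations, ss$annotations)
  }
})

test_that("loading rejects missing sidecars and ragged CSVs", {
  path <- file.path(tempdir(), "orphan.csv")
  writeLines("sweep,time_s,value\n1,0,0.5", path)
  expect_error(load_sweepset(path), "sidecar missing")
  # ragged sweeps written by hand
  ss <- random_sweepset(1)
  ok_path <- file.path(tempdir(), "ragged.csv")
  save_sweepset(ss, ok_path)
  dt <- data.table::fread(ok_path)
  data.table::fwrite(dt[-2, ], ok_path)
  expect_error(load_sweepset(ok_path), "unequal lengths")
  expect_error(load_sweepset(file.path(tempdir(), "nothere.csv")),
               "not found")
})

test_that("test-pulse decomposition recovers Rs and Rin of an RC circuit", {
  # analytic two-resistor RC response: Rs = 10, Rm = 150, dV = -5 mV
  fs <- 20000
  vc <- simulate_voltage_clamp(event_gen_params(rate_Hz = 0,
                                                noise_sd_pA = 0),
                               n_sweeps = 1, sweep_s = 2, fs = fs,
                               rc = list(Rs_MOhm = 10, Rm_MOhm = 150,
                                         Cm_pF = 100))
  tp <- test_pulse_metrics(vc$sweepset, 1)
  expect_lt(abs(tp$series_resistance_MOhm - 10) / 10, 0.10)
  expect_lt(abs(tp$input_resistance_MOhm - 150) / 150, 0.05)

  # pure resistor limit: no transient, I_peak = I_ss, Rs + Rin = dV/I_ss
  n <- 2 * fs
  sig <- numeric(n)
  on <- (round(0.1 * fs) + 1):round(0.35 * fs)
  sig[on] <- 1000 * (-5) / 160                     # dV/(Rs+Rm), pA
  ss <- sweepset(list(sig), fs, "voltage_clamp",
                 stimulus = data.frame(onset = 0.1, duration = 0.25,
                                       amplitude = -5))
  tp2 <- test_pulse_metrics(ss, 1)
  expect_equal(tp2$series_resistance_MOhm + tp2$input_resistance_MOhm, 160,
               tolerance = 1e-10)

  # invariance to a constant holding-current offset
  ss_off <- ss
  ss_off$sweeps[[1]] <- sig - 37.5
  tp3 <- test_pulse_metrics(ss_off, 1)
  expect_equal(tp3$series_resistance_MOhm, tp2$series_resistance_MOhm,
               tolerance = 1e-10)
  expect_equal(tp3$input_resistance_MOhm, tp2$input_resistance_MOhm,
               tolerance = 1e-10)

  # degenerate inputs
  expect_error(test_pulse_metrics(ss, 1, pulse = c(0.1, 0.25), delta_mV = 0),
               "zero-amplitude")
  flat <- sweepset(list(numeric(n)), fs, "voltage_clamp",
                   stimulus = data.frame(onset = 0.1, duration = 0.25,
                                         amplitude = -5))
  expect_error(test_pulse_metrics(flat, 1), "degenerate")
})

test_that("QC applies every exclusion rule with the AD-thalamus exception", {
  good <- list(rmp_mV = -62, rs_MOhm = 20, rs_change_frac = 0.05,
               rin_change_frac = 0.02)
  expect_true(evaluate_qc(good, "cortical")$pass)

  shallow <- good; shallow$rmp_mV <- -50
  r <- evaluate_qc(shallow, "cortical")
  expect_false(r$pass)
  expect_identical(r$reasons, "rmp")
  expect_true(evaluate_qc(shallow, "ad_thalamus")$pass)

  bad <- list(rmp_mV = -62, rs_MOhm = 40, rs_change_frac = 0.30,
              rin_change_frac = 0.30)
  r3 <- evaluate_qc(bad, "cortical")
  expect_false(r3$pass)
  expect_setequal(r3$reasons, c("rs", "rs_change", "rin_change"))
  expect_length(r3$reasons, 3)
})

test_that("QC is monotone: worsening a measurement never rescues a failure", {
  base <- list(rmp_mV = -50, rs_MOhm = 40, rs_change_frac = 0.30,
               rin_change_frac = -0.30)
  stopifnot(!evaluate_qc(base)$pass)
  worse <- list(
    list(rmp_mV = -45, rs_MOhm = 40, rs_change_frac = 0.30,
         rin_change_frac = -0.30),
    list(rmp_mV = -50, rs_MOhm = 60, rs_change_frac = 0.30,
         rin_change_frac = -0.30),
    list(rmp_mV = -50, rs_MOhm = 40, rs_change_frac = 0.50,
         rin_change_frac = -0.30),
    list(rmp_mV = -50, rs_MOhm = 40, rs_change_frac = 0.30,
         rin_change_frac = -0.50))
  for (w in worse) {
    r <- evaluate_qc(w)
    expect_false(r$pass)
    expect_gte(length(r$reasons), length(evaluate_qc(base)$reasons))
  }
  expect_error(evaluate_qc(list(rmp_mV = NA, rs_MOhm = 1,
                                rs_change_frac = 0, rin_change_frac = 0)),
               "finite")
})

test_that("pass is true exactly when no rule is violated", {
  set.seed(99)
  for (i in 1:25) {
    m <- list(rmp_mV = runif(1, -80, -40), rs_MOhm = runif(1, 5, 50),
              rs_change_frac = runif(1, -0.5, 0.5),
              rin_change_frac = runif(1, -0.5, 0.5))
    r <- evaluate_qc(m, sample(c("cortical", "ad_thalamus"), 1))
    expect_identical(r$pass, length(r$reasons) == 0L)
  }
})
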