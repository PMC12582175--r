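# Shared fixtures and independent oracles used across the suite.

# Random small sweepset for round-trip tests.
random_sweepset <- function(seed, n_sweeps = 2, n = 200, fs = 1000,
                            mode = "voltage_clamp") {
  set.seed(seed)
  sweepset(lapply(seq_len(n_sweeps), function(i) rnorm(n)),
           sampling_rate = fs, clamp_mode = mode,
           stimulus = data.frame(onset = 0.01, duration = 0.05,
                                 amplitude = -5),
           holding = -70,
           annotations = list(cell = paste0("c", seed), region = "RSG"))
}

# Analytic voltage response of a passive RC membrane to a current step:
# V(t) = V0 + I*R*(1 - exp(-t/tau)) during the step.
rc_step_trace <- function(R_MOhm, tau_ms, I_pA, fs = 20000, onset_s = 0.2,
                          dur_s = 0.6, sweep_s = 1, V0 = -65) {
  tt <- (seq_len(round(sweep_s * fs)) - 1) / fs
  dv <- I_pA * R_MOhm / 1000                  # mV steady-state deflection
  v <- rep(V0, length(tt))
  on <- tt >= onset_s & tt < onset_s + dur_s
  te <- (tt[on] - onset_s) * 1000
  v[on] <- V0 + dv * (1 - exp(-te / tau_ms))
  off <- tt >= onset_s + dur_s
  v_end <- V0 + dv * (1 - exp(-dur_s * 1000 / tau_ms))
  to <- (tt[off] - onset_s - dur_s) * 1000
  v[off] <- V0 + (v_end - V0) * exp(-to / tau_ms)
  sweepset(list(v), fs, "current_clamp",
           stimulus = data.frame(onset = onset_s, duration = dur_s,
                                 amplitude = I_pA))
}

# Piecewise-linear spike riding on a flat baseline: rises at `rise_slope`
# mV/ms from `v_base` to `v_peak`, falls at `fall_slope` back to base.
# Returns the sweepset plus the construction's closed-form threshold,
# amplitude and half-width.
ramp_spike_sweep <- function(v_base = -55, v_peak = 20, rise_slope = 20,
                             fall_slope = -15, fs = 20000, sweep_s = 0.4,
                             t_start_s = 0.2) {
  dt_ms <- 1000 / fs
  n_up <- round((v_peak - v_base) / (rise_slope * dt_ms))
  n_dn <- round((v_peak - v_base) / (-fall_slope * dt_ms))
  v <- rep(v_base, round(sweep_s * fs))
  i0 <- round(t_start_s * fs) + 1
  up <- v_base + rise_slope * dt_ms * seq_len(n_up)
  dn <- v_peak + fall_slope * dt_ms * seq_len(n_dn)
  v[i0:(i0 + n_up - 1)] <- up
  v[(i0 + n_up):(i0 + n_up + n_dn - 1)] <- pmax(dn, v_base)
  amp <- v_peak - v_base
  half <- v_base + amp / 2
  hw_ms <- (v_peak - half) / rise_slope + (v_peak - half) / (-fall_slope)
  list(ss = sweepset(list(v), fs, "current_clamp",
                     stimulus = data.frame(onset = 0.1, duration = 0.25,
                                           amplitude = 100)),
       threshold_mV = v_base, amplitude_mV = amp, half_width_ms = hw_ms,
       peak_time_s = (i0 + n_up - 1 - 1) / fs, peak_mV = v_peak)
}

# Independent Tsodyks-Markram recurrence oracle (kept separate from the
# package's tm_amplitudes): textbook update evaluated step by step.
tm_oracle <- function(A1, U, tau_rec, tau_facil, n_pulses, rate) {
  dt <- 1 / rate
  amps <- numeric(n_pulses)
  u_prev <- 0; x_prev <- 1
  for (k in seq_len(n_pulses)) {
    u <- if (k == 1) U else {
      if (tau_facil > 0) U + u_prev * (1 - U) * exp(-dt / tau_facil) else U
    }
    x <- if (k == 1) 1 else 1 - (1 - x_prev * (1 - u_prev)) * exp(-dt / tau_rec)
    amps[k] <- u * x
    u_prev <- u; x_prev <- x
  }
  A1 * amps / amps[1]
}

# Build a current-clamp family with hand-placed idealized spikes so that the
# spike count per step is exactly `counts[i]`; spikes are sharp triangular
# deflections peaking at +20 mV.
constructed_fi_family <- function(counts, step_pA, fs = 20000,
                                  onset_s = 0.2, dur_s = 1) {
  n <- round((onset_s + dur_s + 0.2) * fs)
  sweeps <- lapply(seq_along(counts), function(i) {
    v <- rep(-65, n)
    k <- counts[i]
    if (k > 0) {
      times <- onset_s + dur_s * (seq_len(k) - 0.5) / k
      for (tm in times) {
        j <- round(tm * fs) + 1
        n_up <- round(0.0005 * fs); n_dn <- round(0.001 * fs)
        v[(j - n_up):j] <- seq(-55, 20, length.out = n_up + 1)
        v[j:(j + n_dn)] <- seq(20, -65, length.out = n_dn + 1)
      }
    }
    v
  })
  stim <- lapply(step_pA, function(a)
    data.frame(onset = onset_s, duration = dur_s, amplitude = a))
  sweepset(sweeps, fs, "current_clamp", stimulus = stim)
}

# Quiet voltage-clamp sweepset with hand-placed kernel events.
planted_event_sweep <- function(times_s, amps_pA, sweep_s = 10, fs = 20000,
                                rise = 0.5, decay = 8, noise_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(sweep_s * fs)
  sig <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  kern <- psc_kernel(rise, decay, fs, length_ms = 10 * decay)
  for (e in seq_along(times_s)) {
    i0 <- round(times_s[e] * fs) + 1
    span <- i0:min(n, i0 + length(kern) - 1)
    sig[span] <- sig[span] - amps_pA[e] * kern[seq_along(span)]
  }
  sweepset(list(sig), fs, "voltage_clamp")
}
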