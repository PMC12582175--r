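#' Ground-truth neuron parameters for the current-clamp simulator
#'
#' Parameters of an adaptive exponential integrate-and-fire (AdEx) membrane
#' with an additive slow sag conductance. The passive side is characterised
#' by `R_MOhm` and `C_pF` (membrane time constant `R*C`); the spiking side by
#' the exponential threshold (`V_T_mV`, slope factor `delta_T_mV`), reset,
#' refractory period, and the adaptation variable (subthreshold coupling
#' `a_nS`, spike increment `b_pA`, time constant `tau_w_ms`). The sag current
#' is a hyperpolarization-activated conductance (`sag_nS`, gate time constant
#' `sag_tau_ms`, reversal `sag_E_mV`) producing the characteristic
#' depolarizing rebound during negative steps; `sag_nS = 0` gives a pure RC
#' membrane below threshold.
#'
#' @param R_MOhm input resistance, MOhm.
#' @param C_pF input capacitance, pF.
#' @param E_L_mV leak reversal (resting potential), mV.
#' @param sag_nS sag conductance strength, nS (0 disables sag).
#' @param sag_tau_ms sag gate time constant, ms.
#' @param sag_E_mV sag current reversal, mV.
#' @param sag_Vhalf_mV,sag_k_mV sag gate half-activation and slope, mV.
#' @param V_T_mV,delta_T_mV AdEx exponential threshold and slope factor, mV.
#' @param V_reset_mV post-spike reset potential, mV.
#' @param a_nS,b_pA,tau_w_ms adaptation parameters.
#' @param refractory_ms absolute refractory period, ms.
#' @param V_peak_mV stereotyped spike peak voltage, mV.
#' @return list of class `neuron_params`.
#' @export
neuron_params <- function(R_MOhm = 150, C_pF = 100, E_L_mV = -65,
                          sag_nS = 0, sag_tau_ms = 40, sag_E_mV = -45,
                          sag_Vhalf_mV = -80, sag_k_mV = 6,
                          V_T_mV = -45, delta_T_mV = 2, V_reset_mV = -55,
                          a_nS = 0, b_pA = 40, tau_w_ms = 150,
                          refractory_ms = 2, V_peak_mV = 30) {
  stopifnot(R_MOhm > 0, C_pF > 0, sag_nS >= 0, sag_tau_ms > 0,
            delta_T_mV > 0, tau_w_ms > 0, refractory_ms >= 0)
  structure(as.list(environment()), class = "neuron_params")
}

#' Simulate a current-clamp step family
#'
#' Integrates the AdEx-with-sag membrane of [neuron_params()] over a family
#' of square current steps, one sweep per step, using exponential-Euler
#' updates at the trace sampling interval. At each sweep start the membrane
#' is biased to `bias_mV` by a constant holding current `(bias_mV - E_L)/R`.
#' When the voltage crosses the AdEx spike cut (`V_T + 5*delta_T`) a
#' stereotyped spike waveform (0.3 ms rise to `V_peak_mV`, 0.6 ms fall to
#' reset) is written into the trace, the adaptation current is incremented by
#' `b_pA`, and the true spike peak time is recorded as ground truth.
#'
#' @param params a [neuron_params()] object.
#' @param steps_pA step amplitudes, pA; one sweep each.
#' @param onset_s,duration_s step onset and duration, s.
#' @param sweep_s total sweep duration, s.
#' @param bias_mV membrane potential commanded at sweep start, mV.
#' @param fs sampling rate, samples/s.
#' @param noise_sd_mV SD of white voltage noise added to the trace, mV.
#' @param seed RNG seed (only used when `noise_sd_mV > 0`).
#' @param dt_divisor integration substeps per sample (1 = native sampling;
#'   larger values give a finer reference integration).
#' @return list with `sweepset` (current-clamp [sweepset()]) and
#'   `ground_truth` (per-sweep list of true spike peak times, the parameter
#'   object, and the step amplitudes).
#' @export
simulate_current_clamp <- function(params, steps_pA = c(-20, seq(0, 400, 50)),
                                   onset_s = 0.2, duration_s = 1,
                                   sweep_s = onset_s + duration_s + 0.2,
                                   bias_mV = -65, fs = 20000,
                                   noise_sd_mV = 0, seed = NULL,
                                   dt_divisor = 1L) {
  stopifnot(inherits(params, "neuron_params"))
  if (onset_s < 0 || onset_s + duration_s > sweep_s)
    stop("step epoch outside sweep", call. = FALSE)
  p <- params
  dt_ms <- 1000 / fs / dt_divisor
  tau_m <- p$R_MOhm * p$C_pF / 1000          # ms
  n <- round(sweep_s * fs)
  i_on <- round(onset_s * fs) + 1L
  i_off <- round((onset_s + duration_s) * fs)
  i_bias <- (bias_mV - p$E_L_mV) / p$R_MOhm * 1000   # pA
  v_cut <- p$V_T_mV + 5 * p$delta_T_mV
  n_ref <- max(1L, round(p$refractory_ms / 1000 * fs))
  # stereotyped spike shape, relative indices after the cut crossing
  n_rise <- max(1L, round(0.0003 * fs))
  n_fall <- max(1L, round(0.0006 * fs))

  if (!is.null(seed)) set.seed(seed)
  sweeps <- vector("list", length(steps_pA))
  spikes <- vector("list", length(steps_pA))
  for (sw in seq_along(steps_pA)) {
    v <- numeric(n)
    V <- bias_mV; w <- p$a_nS * (bias_mV - p$E_L_mV); s <- sag_inf(bias_mV, p)
    st <- numeric(0)
    k <- 1L
    while (k <= n) {
      I_inj <- i_bias + if (k >= i_on && k <= i_off) steps_pA[sw] else 0
      for (sub in seq_len(dt_divisor)) {
        # leak conductance g_L = 1000/R_MOhm nS; I_exp_pA = g_L*dT*exp(.)
        I_exp <- if (V > p$V_T_mV - 10 * p$delta_T_mV)
          (1000 / p$R_MOhm) * p$delta_T_mV *
            exp(min((V - p$V_T_mV) / p$delta_T_mV, 20))
        else 0
        I_sag <- p$sag_nS * s * (p$sag_E_mV - V)
        V_inf <- p$E_L_mV + p$R_MOhm / 1000 * (I_inj + I_exp + I_sag - w)
        V <- V_inf + (V - V_inf) * exp(-dt_ms / tau_m)
        w_inf <- p$a_nS * (V - p$E_L_mV)
        w <- w_inf + (w - w_inf) * exp(-dt_ms / p$tau_w_ms)
        si <- sag_inf(V, p)
        s <- si + (s - si) * exp(-dt_ms / p$sag_tau_ms)
        if (!is.finite(V) || !is.finite(w))
          stop("simulation error: non-finite state", call. = FALSE)
        if (V >= v_cut) break
      }
      if (V >= v_cut) {
        # paste stereotyped spike; ground-truth peak at the end of the rise
        i_pk <- min(n, k + n_rise)
        rise_idx <- k:i_pk
        v[rise_idx] <- seq(v_cut, p$V_peak_mV, length.out = length(rise_idx))
        i_end <- min(n, i_pk + n_fall)
        if (i_end > i_pk)
          v[(i_pk + 1L):i_end] <- seq(p$V_peak_mV, p$V_reset_mV,
                                      length.out = i_end - i_pk + 1L)[-1L]
        # ground truth counts spikes whose peak falls within the step
        if (i_pk <= i_off) st <- c(st, (i_pk - 1L) / fs)
        w <- w + p$b_pA
        V <- p$V_reset_mV
        k_next <- i_end + n_ref
        if (k_next > i_end && i_end < n)
          v[(i_end + 1L):min(n, k_next)] <- p$V_reset_mV
        k <- k_next + 1L
      } else {
        v[k] <- V
        k <- k + 1L
      }
    }
    if (noise_sd_mV > 0) v <- v + stats::rnorm(n, 0, noise_sd_mV)
    sweeps[[sw]] <- v
    spikes[[sw]] <- st
  }
  stim <- lapply(steps_pA, function(a)
    data.frame(onset = onset_s, duration = duration_s, amplitude = a))
  ss <- sweepset(sweeps, fs, "current_clamp", stimulus = stim,
                 holding = bias_mV,
                 annotations = list(source = "simulate_current_clamp"))
  list(sweepset = ss,
       ground_truth = list(params = params, steps_pA = steps_pA,
                           spike_times = spikes))
}

sag_inf <- function(V, p) 1 / (1 + exp((V - p$sag_Vhalf_mV) / p$sag_k_mV))

#' Ground-truth parameters for the spontaneous-event generator
#'
#' @param rate_Hz homogeneous Poisson event rate, Hz.
#' @param amp_meanlog,amp_sdlog lognormal amplitude parameters (log pA).
#' @param rise_tau_ms,decay_tau_ms biexponential kernel time constants, ms
#'   (`decay > rise > 0`). The kernel is normalized to unit peak so the drawn
#'   amplitude is the trace amplitude.
#' @param noise_sd_pA SD of white current noise, pA.
#' @param drift_amp_pA,drift_period_s optional sinusoidal baseline drift
#'   (peak amplitude and period); `drift_amp_pA = 0` disables it.
#' @return list of class `event_gen_params`.
#' @export
event_gen_params <- function(rate_Hz = 1, amp_meanlog = log(15),
                             amp_sdlog = 0.3, rise_tau_ms = 0.5,
                             decay_tau_ms = 8, noise_sd_pA = 2,
                             drift_amp_pA = 0, drift_period_s = 5) {
  stopifnot(rate_Hz >= 0, is.finite(rate_Hz), amp_sdlog >= 0,
            rise_tau_ms > 0, decay_tau_ms > rise_tau_ms,
            noise_sd_pA >= 0, drift_period_s > 0)
  structure(as.list(environment()), class = "event_gen_params")
}

#' Biexponential synaptic kernel with unit peak
#'
#' `k(t) = (exp(-t/tau_d) - exp(-t/tau_r)) / k(t_peak)`, evaluated on the
#' sample grid out to `length_ms`.
#' @param rise_tau_ms,decay_tau_ms kernel time constants, ms.
#' @param fs sampling rate, samples/s.
#' @param length_ms kernel support, ms.
#' @return numeric vector, `max(kernel) == 1`.
#' @export
psc_kernel <- function(rise_tau_ms, decay_tau_ms, fs, length_ms = 60) {
  t_ms <- seq(0, length_ms, by = 1000 / fs)
  k <- exp(-t_ms / decay_tau_ms) - exp(-t_ms / rise_tau_ms)
  k / max(k)
}

#' Simulate voltage-clamp sweeps with spontaneous synaptic events
#'
#' Generates `n_sweeps` sweeps of membrane current at a -70 mV holding
#' potential: a test-pulse response from a fixed two-resistor RC model
#' (series resistance `rc$Rs_MOhm`, membrane `rc$Rm_MOhm`, capacitance
#' `rc$Cm_pF`), homogeneous-Poisson event times, each adding a negative-going
#' unit-peak biexponential kernel scaled by a lognormal amplitude, plus white
#' noise and (optionally) a slow sinusoidal drift. Events superpose linearly.
#'
#' @param params an [event_gen_params()] object.
#' @param n_sweeps number of sweeps.
#' @param sweep_s sweep duration, s (default 30).
#' @param fs sampling rate, samples/s.
#' @param pulse_onset_s,pulse_dur_s,pulse_mV test-pulse epoch (-5 mV /
#'   250 ms starting 0.1 s into each sweep).
#' @param hold_mV holding potential, mV (annotation only).
#' @param rc list with `Rs_MOhm`, `Rm_MOhm`, `Cm_pF` for the test-pulse
#'   response.
#' @param seed RNG seed.
#' @return list with `sweepset` and `ground_truth` (`events`: data frame of
#'   sweep, time_s, amplitude_pA; plus the parameter object and `rc`).
#' @export
simulate_voltage_clamp <- function(params = event_gen_params(), n_sweeps = 10,
                                   sweep_s = 30, fs = 20000,
                                   pulse_onset_s = 0.1, pulse_dur_s = 0.25,
                                   pulse_mV = -5, hold_mV = -70,
                                   rc = list(Rs_MOhm = 15, Rm_MOhm = 150,
                                             Cm_pF = 100),
                                   seed = NULL) {
  stopifnot(inherits(params, "event_gen_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- round(sweep_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  kern <- psc_kernel(params$rise_tau_ms, params$decay_tau_ms, fs,
                     length_ms = 10 * params$decay_tau_ms)
  pulse <- test_pulse_response(tt, pulse_onset_s, pulse_dur_s, pulse_mV, rc)

  sweeps <- vector("list", n_sweeps)
  ev_all <- vector("list", n_sweeps)
  for (sw in seq_len(n_sweeps)) {
    n_ev <- stats::rpois(1L, params$rate_Hz * sweep_s)
    t_ev <- sort(stats::runif(n_ev, 0, sweep_s))
    a_ev <- stats::rlnorm(n_ev, params$amp_meanlog, params$amp_sdlog)
    sig <- pulse
    if (n_ev > 0) {
      idx <- round(t_ev * fs) + 1L
      keep <- idx <= n
      idx <- idx[keep]; t_ev <- t_ev[keep]; a_ev <- a_ev[keep]
      for (e in seq_along(idx)) {
        span <- idx[e]:min(n, idx[e] + length(kern) - 1L)
        sig[span] <- sig[span] - a_ev[e] * kern[seq_along(span)]
      }
    }
    if (params$drift_amp_pA > 0)
      sig <- sig + params$drift_amp_pA *
        sin(2 * pi * tt / params$drift_period_s)
    if (params$noise_sd_pA > 0)
      sig <- sig + stats::rnorm(n, 0, params$noise_sd_pA)
    sweeps[[sw]] <- sig
    ev_all[[sw]] <- data.frame(sweep = rep(sw, length(t_ev)),
                               time_s = t_ev, amplitude_pA = a_ev)
  }
  stim <- data.frame(onset = pulse_onset_s, duration = pulse_dur_s,
                     amplitude = pulse_mV)
  ss <- sweepset(sweeps, fs, "voltage_clamp", stimulus = stim,
                 holding = hold_mV,
                 annotations = list(source = "simulate_voltage_clamp"))
  list(sweepset = ss,
       ground_truth = list(params = params, rc = rc,
                           events = do.call(rbind, ev_all)))
}

# Analytic current response of the Rs-Rm-Cm voltage-clamp circuit to a
# square command step: on-transient peak dV/Rs decaying to dV/(Rs+Rm) with
# tau' = Cm * Rs*Rm/(Rs+Rm); mirror-image off-transient.
test_pulse_response <- function(tt, onset_s, dur_s, dV_mV, rc) {
  Rp <- rc$Rs_MOhm * rc$Rm_MOhm / (rc$Rs_MOhm + rc$Rm_MOhm)
  tau_s <- rc$Cm_pF * Rp * 1e-6                 # pF * MOhm = us
  i_peak <- 1000 * dV_mV / rc$Rs_MOhm           # pA
  i_ss <- 1000 * dV_mV / (rc$Rs_MOhm + rc$Rm_MOhm)
  out <- numeric(length(tt))
  on <- tt >= onset_s & tt < onset_s + dur_s
  te <- tt[on] - onset_s
  out[on] <- i_ss + (i_peak - i_ss) * exp(-te / tau_s)
  off <- tt >= onset_s + dur_s
  to <- tt[off] - (onset_s + dur_s)
  out[off] <- -(i_peak - i_ss) * exp(-to / tau_s)
  out
}

#' Ground-truth parameters for evoked 10 Hz trains
#'
#' Short-term plasticity follows the Tsodyks-Markram resource-utilization
#' recurrence: at each pulse the utilization `u` facilitates toward 1 with
#' time constant `tau_facil_s` and the resource fraction `x` depletes by
#' `u*x` and recovers with `tau_rec_s`. `tau_facil_s = 0` gives constant
#' `u = U` (pure depression).
#'
#' @param A1_pA first-pulse amplitude, pA.
#' @param U release fraction in (0, 1].
#' @param tau_rec_s,tau_facil_s recovery and facilitation time constants, s.
#' @param n_pulses pulses per train.
#' @param rate_Hz pulse rate, Hz.
#' @param rise_tau_ms,decay_tau_ms synaptic kernel time constants, ms.
#' @param noise_sd_pA white noise SD per trial, pA.
#' @param n_trials number of trials.
#' @return list of class `stp_params`.
#' @export
stp_params <- function(A1_pA = 100, U = 0.5, tau_rec_s = 0.5,
                       tau_facil_s = 0, n_pulses = 10, rate_Hz = 10,
                       rise_tau_ms = 0.5, decay_tau_ms = 8,
                       noise_sd_pA = 2, n_trials = 5) {
  stopifnot(U > 0, U <= 1, tau_rec_s > 0, tau_facil_s >= 0,
            n_pulses >= 1, rate_Hz > 0, noise_sd_pA >= 0, n_trials >= 1)
  structure(as.list(environment()), class = "stp_params")
}

#' Tsodyks-Markram per-pulse amplitudes
#'
#' Evaluates the depression/facilitation recurrence at a regular pulse train
#' and returns the true per-pulse amplitudes, scaled so pulse 1 equals
#' `A1_pA`.
#' @param params an [stp_params()] object.
#' @return numeric vector of length `n_pulses`.
#' @export
tm_amplitudes <- function(params) {
  p <- params
  dt <- 1 / p$rate_Hz
  u <- p$U; x <- 1
  amps <- numeric(p$n_pulses)
  for (i in seq_len(p$n_pulses)) {
    if (i > 1L) {
      u <- if (p$tau_facil_s > 0)
        p$U + u * (1 - p$U) * exp(-dt / p$tau_facil_s)
      else p$U
      x <- 1 - (1 - x_after) * exp(-dt / p$tau_rec_s)
    }
    amps[i] <- u * x
    x_after <- x * (1 - u)
  }
  p$A1_pA * amps / amps[1L]
}

#' Simulate an optogenetically evoked pulse train
#'
#' Places the unit-peak biexponential kernel at each pulse time, scaled by
#' the Tsodyks-Markram amplitude of [tm_amplitudes()]; overlapping kernels
#' superpose linearly. One sweep per trial, with independent white noise.
#'
#' @param params an [stp_params()] object.
#' @param sweep_s sweep duration, s.
#' @param first_pulse_s time of the first pulse, s.
#' @param fs sampling rate, samples/s.
#' @param seed RNG seed.
#' @return list with `sweepset` (one voltage-clamp sweep per trial, pulse
#'   epochs in `stimulus`) and `ground_truth` (`amplitudes_pA`,
#'   `pulse_times_s`, the parameter object).
#' @export
simulate_evoked_train <- function(params = stp_params(), sweep_s = 2,
                                  first_pulse_s = 0.5, fs = 20000,
                                  seed = NULL) {
  stopifnot(inherits(params, "stp_params"))
  if (!is.null(seed)) set.seed(seed)
  amps <- tm_amplitudes(params)
  t_pulse <- first_pulse_s + (seq_len(params$n_pulses) - 1L) / params$rate_Hz
  n <- round(sweep_s * fs)
  kern <- psc_kernel(params$rise_tau_ms, params$decay_tau_ms, fs,
                     length_ms = 10 * params$decay_tau_ms)
  clean <- numeric(n)
  idx <- round(t_pulse * fs) + 1L
  for (i in seq_along(idx)) {
    span <- idx[i]:min(n, idx[i] + length(kern) - 1L)
    clean[span] <- clean[span] - amps[i] * kern[seq_along(span)]
  }
  sweeps <- lapply(seq_len(params$n_trials), function(tr) {
    if (params$noise_sd_pA > 0)
      clean + stats::rnorm(n, 0, params$noise_sd_pA)
    else clean
  })
  stim <- data.frame(onset = t_pulse, duration = 0.001, amplitude = NA_real_)
  ss <- sweepset(sweeps, fs, "voltage_clamp", stimulus = stim,
                 holding = -70,
                 annotations = list(source = "simulate_evoked_train"))
  list(sweepset = ss,
       ground_truth = list(params = params, amplitudes_pA = amps,
                           pulse_times_s = t_pulse))
}

#' Generate an annotated cell-by-gene count table
#'
#' Draws negative-binomial per-cell counts of a single target gene for each
#' configured group and attaches region and cluster annotations, emulating
#' an annotated single-cell expression table.
#'
#' @param design data frame with one row per group: columns `region`,
#'   `cluster_label`, `mean` (NB mean, >= 0), `dispersion` (NB size
#'   parameter), `n_cells`.
#' @param seed RNG seed.
#' @return data frame with columns `cell_id`, `region_label`,
#'   `cluster_label`, `class`, `target_gene_count`.
#' @export
generate_cell_table <- function(design, seed = NULL) {
  design <- as.data.frame(design)
  need <- c("region", "cluster_label", "mean", "dispersion", "n_cells")
  stopifnot(all(need %in% names(design)), all(design$mean >= 0),
            all(design$n_cells >= 1))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(g) {
    n <- design$n_cells[g]
    mu <- design$mean[g]
    counts <- if (mu == 0) integer(n)
    else stats::rnbinom(n, size = design$dispersion[g], mu = mu)
    data.frame(region_label = design$region[g],
               cluster_label = design$cluster_label[g],
               class = "glutamatergic",
               target_gene_count = counts)
  })
  out <- do.call(rbind, rows)
  out$cell_id <- sprintf("cell_%06d", seq_len(nrow(out)))
  out[, c("cell_id", "region_label", "cluster_label", "class",
          "target_gene_count")]
}
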