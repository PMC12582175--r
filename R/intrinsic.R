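#' Detect action potentials in a current-clamp sweep
#'
#' Finds spike peaks as local voltage maxima reaching at least `peak_min_mV`
#' (-10 mV by default; smaller events are not counted) within the stimulus
#' epoch, then extracts per-spike waveform features. The threshold of each
#' spike is the last point before the peak where the voltage slope
#' (`dV/dt`, central differences in mV/ms) rises through
#' `threshold_slope_mV_per_ms` (10 mV/ms), located by backward search from
#' the peak with linear interpolation between samples. Amplitude is peak
#' minus threshold voltage; half-width is the interpolated width at
#' threshold + amplitude/2; maximum rise and decay slopes are taken between
#' the threshold and the post-peak trough.
#'
#' @param x a current-clamp [sweepset()].
#' @param sweep sweep index.
#' @param epoch numeric `c(onset, duration)` in seconds; defaults to the
#'   sweep's first stimulus epoch.
#' @param peak_min_mV minimum peak voltage for a counted spike, mV.
#' @param threshold_slope_mV_per_ms slope criterion defining threshold.
#' @param min_isi_ms minimum separation between accepted peaks, ms.
#' @return data frame (one row per spike): `peak_time_s`, `peak_mV`,
#'   `threshold_time_s`, `threshold_mV`, `amplitude_mV`, `half_width_ms`,
#'   `max_rise_slope_mV_per_ms`, `max_decay_slope_mV_per_ms`.
#' @export
detect_spikes <- function(x, sweep = 1L, epoch = NULL, peak_min_mV = -10,
                          threshold_slope_mV_per_ms = 10, min_isi_ms = 1) {
  stopifnot(inherits(x, "sweepset"))
  if (x$clamp_mode != "current_clamp")
    stop("detect_spikes requires a current-clamp sweepset", call. = FALSE)
  v <- x$sweeps[[sweep]]
  fs <- x$sampling_rate
  if (is.null(epoch)) {
    ep <- x$stimulus[[sweep]]
    if (is.null(ep) || nrow(ep) == 0L)
      stop("no stimulus epoch available", call. = FALSE)
    epoch <- c(ep$onset[1L], ep$duration[1L])
  }
  i_on <- round(epoch[1L] * fs) + 1L
  i_off <- round((epoch[1L] + epoch[2L]) * fs)
  if (i_on < 1L || i_off > length(v))
    stop("epoch outside sweep", call. = FALSE)

  empty <- data.frame(peak_time_s = numeric(0), peak_mV = numeric(0),
                      threshold_time_s = numeric(0), threshold_mV = numeric(0),
                      amplitude_mV = numeric(0), half_width_ms = numeric(0),
                      max_rise_slope_mV_per_ms = numeric(0),
                      max_decay_slope_mV_per_ms = numeric(0))
  n <- length(v)
  # local maxima >= peak_min within the epoch
  core <- 2:(n - 1L)
  is_pk <- v[core] >= v[core - 1L] & v[core] > v[core + 1L] &
    v[core] >= peak_min_mV
  pk <- core[is_pk]
  pk <- pk[pk >= i_on & pk <= i_off]
  if (length(pk) == 0L) return(empty)
  # enforce minimum inter-peak spacing, keeping the taller peak
  if (length(pk) > 1L) {
    ord <- order(v[pk], decreasing = TRUE)
    keep <- logical(length(pk))
    taken <- integer(0)
    min_gap <- round(min_isi_ms / 1000 * fs)
    for (j in ord) {
      if (!length(taken) || all(abs(pk[j] - taken) >= min_gap)) {
        keep[j] <- TRUE
        taken <- c(taken, pk[j])
      }
    }
    pk <- sort(pk[keep])
  }

  dvdt <- c(NA_real_, (v[3:n] - v[1:(n - 2L)]) * fs / 2000, NA_real_) # mV/ms
  thr_slope <- threshold_slope_mV_per_ms
  rows <- lapply(seq_along(pk), function(j) {
    p <- pk[j]
    lo <- if (j > 1L) pk[j - 1L] else max(i_on - round(0.01 * fs), 2L)
    # backward search for the last upward crossing of the slope criterion
    i <- p
    thr_i <- NA_integer_
    while (i > lo + 1L) {
      if (!is.na(dvdt[i]) && !is.na(dvdt[i - 1L]) &&
          dvdt[i] >= thr_slope && dvdt[i - 1L] < thr_slope) {
        thr_i <- i
        break
      }
      i <- i - 1L
    }
    if (is.na(thr_i)) return(NULL)
    # interpolate the crossing between samples thr_i-1 and thr_i
    f <- (thr_slope - dvdt[thr_i - 1L]) / (dvdt[thr_i] - dvdt[thr_i - 1L])
    thr_t <- (thr_i - 2L + f) / fs
    thr_v <- v[thr_i - 1L] + f * (v[thr_i] - v[thr_i - 1L])
    amp <- v[p] - thr_v
    if (amp <= 0) return(NULL)
    # post-peak trough: minimum before the next peak (or epoch end)
    hi <- if (j < length(pk)) pk[j + 1L] else min(i_off, n - 1L)
    tr_i <- p + which.min(v[(p + 1L):hi])
    half <- thr_v + amp / 2
    hw <- half_width_interp(v, fs, p, half, lo_bound = thr_i - 1L,
                            hi_bound = tr_i)
    seg <- dvdt[(thr_i - 1L):tr_i]
    data.frame(peak_time_s = (p - 1L) / fs, peak_mV = v[p],
               threshold_time_s = thr_t, threshold_mV = thr_v,
               amplitude_mV = amp, half_width_ms = hw,
               max_rise_slope_mV_per_ms = max(seg, na.rm = TRUE),
               max_decay_slope_mV_per_ms = min(seg, na.rm = TRUE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# interpolated width (ms) at voltage `level` around peak index p
half_width_interp <- function(v, fs, p, level, lo_bound, hi_bound) {
  i <- p
  while (i > lo_bound && v[i - 1L] > level) i <- i - 1L
  if (i == lo_bound && v[i] > level) return(NA_real_)
  f1 <- (level - v[i - 1L]) / (v[i] - v[i - 1L])
  t1 <- (i - 2L + f1) / fs
  j <- p
  while (j < hi_bound && v[j + 1L] > level) j <- j + 1L
  if (j == hi_bound && v[j] > level) return(NA_real_)
  f2 <- (v[j] - level) / (v[j] - v[j + 1L])
  t2 <- (j - 1L + f2) / fs
  (t2 - t1) * 1000
}

#' F-I (frequency-current) analysis of a step family
#'
#' Counts spikes per step and derives: rheobase (smallest step current
#' eliciting at least one spike), F-I gain (ordinary least-squares slope of
#' spike count against injected current from 0 pA up to the step attaining
#' the maximum count or `max_current_pA`, whichever comes first; ties for the
#' maximum broken toward the lowest current) and total spike output (sum of
#' counts over that same range).
#'
#' @param x a current-clamp [sweepset()] whose stimulus amplitudes are the
#'   step currents (strictly increasing, including 0 pA).
#' @param max_current_pA upper cap of the regression range, pA.
#' @param ... passed to [detect_spikes()].
#' @return list: `rheobase_pA` (NA when no sweep spikes),
#'   `fi_gain_spikes_per_pA`, `total_spike_output`, `max_firing_sweep_pA`,
#'   and `spike_counts` (data frame current_pA, n_spikes).
#' @export
fi_analysis <- function(x, max_current_pA = 400, ...) {
  stopifnot(inherits(x, "sweepset"))
  cur <- vapply(x$stimulus, function(ep) ep$amplitude[1L], numeric(1))
  counts <- vapply(seq_along(x$sweeps),
                   function(i) nrow(detect_spikes(x, i, ...)), numeric(1))
  ord <- order(cur)
  cur <- cur[ord]; counts <- counts[ord]

  rheo <- if (any(counts > 0)) min(cur[counts > 0]) else NA_real_
  in_range <- cur >= 0 & cur <= max_current_pA
  cur_r <- cur[in_range]; cnt_r <- counts[in_range]
  i_max <- which(cnt_r == max(cnt_r))[1L]           # lowest current on ties
  # no spikes anywhere: regression over the full range (slope 0)
  sel <- if (max(cnt_r) == 0) seq_along(cnt_r) else seq_len(i_max)
  gain <- if (length(sel) >= 2L)
    unname(stats::coef(stats::lm(cnt_r[sel] ~ cur_r[sel]))[2L])
  else NA_real_
  list(rheobase_pA = rheo,
       fi_gain_spikes_per_pA = gain,
       total_spike_output = sum(cnt_r[sel]),
       max_firing_sweep_pA = cur_r[i_max],
       spike_counts = data.frame(current_pA = cur, n_spikes = counts))
}

#' Spike-frequency adaptation index
#'
#' Computed on the sweep whose step current is closest to twice the rheobase
#' (ties broken toward the lower current) among sweeps with a step of
#' `target_duration_s`: `(N_first_half - N_second_half) / N_total`, with
#' spikes assigned to halves by peak time relative to the epoch midpoint.
#' Positive values indicate adaptation (more spikes early).
#'
#' @param x a current-clamp [sweepset()].
#' @param rheobase_pA rheobase, pA (from [fi_analysis()]).
#' @param target_duration_s step duration required for the index, s.
#' @param duration_tol_s tolerance when matching the duration, s.
#' @param ... passed to [detect_spikes()].
#' @return scalar in [-1, 1], or NA when the selected sweep has no spikes.
#' @export
adaptation_index <- function(x, rheobase_pA, target_duration_s = 1,
                             duration_tol_s = 0.05, ...) {
  stopifnot(inherits(x, "sweepset"))
  if (!is.finite(rheobase_pA)) return(NA_real_)
  cur <- vapply(x$stimulus, function(ep) ep$amplitude[1L], numeric(1))
  dur <- vapply(x$stimulus, function(ep) ep$duration[1L], numeric(1))
  cand <- which(abs(dur - target_duration_s) <= duration_tol_s)
  if (!length(cand)) cand <- seq_along(cur)
  d <- abs(cur[cand] - 2 * rheobase_pA)
  best <- cand[order(d, cur[cand])][1L]
  ep <- x$stimulus[[best]]
  sp <- detect_spikes(x, best, ...)
  if (nrow(sp) == 0L) return(NA_real_)
  mid <- ep$onset[1L] + ep$duration[1L] / 2
  n1 <- sum(sp$peak_time_s < mid)
  n2 <- nrow(sp) - n1
  (n1 - n2) / nrow(sp)
}

#' Passive membrane properties from small hyperpolarizing steps
#'
#' For each hyperpolarizing sweep: baseline is the mean of the 100 ms
#' preceding the step; the maximum response is the extremal deflection from
#' baseline during the step. `Rin = |dV_max / I|`; the membrane time
#' constant is a single-exponential least-squares fit of the voltage from
#' step onset to the time of the maximum response; `Cin = TC / Rin`; the sag
#' ratio is `|dV_max|` divided by the magnitude of the mean deflection over
#' the last 50 ms of the step. Values from multiple qualifying sweeps are
#' averaged.
#'
#' @param x a current-clamp [sweepset()].
#' @param sweeps indices to use; defaults to all sweeps with negative step
#'   amplitude.
#' @return list: `rin_MOhm`, `tc_ms`, `cin_pF`, `sag_ratio`, `rmp_mV`
#'   (mean pre-step baseline), and `per_sweep` data frame.
#' @export
passive_properties <- function(x, sweeps = NULL) {
  stopifnot(inherits(x, "sweepset"))
  if (x$clamp_mode != "current_clamp")
    stop("passive_properties requires current clamp", call. = FALSE)
  amps <- vapply(x$stimulus, function(ep) ep$amplitude[1L], numeric(1))
  if (is.null(sweeps)) sweeps <- which(amps < 0)
  if (!length(sweeps))
    stop("no hyperpolarizing sweeps available", call. = FALSE)
  fs <- x$sampling_rate

  per <- lapply(sweeps, function(sw) {
    v <- x$sweeps[[sw]]
    ep <- x$stimulus[[sw]]
    i_on <- round(ep$onset[1L] * fs) + 1L
    i_off <- round((ep$onset[1L] + ep$duration[1L]) * fs)
    n_base <- round(0.1 * fs)
    if (i_on - n_base < 1L)
      stop("need >= 100 ms pre-stimulus baseline", call. = FALSE)
    base <- mean(v[(i_on - n_base):(i_on - 1L)])
    dev <- v[i_on:i_off] - base
    i_pk <- which.max(abs(dev))
    dv_max <- dev[i_pk]
    rin <- abs(1000 * dv_max / ep$amplitude[1L])           # MOhm
    n50 <- round(0.05 * fs)
    ss <- mean(dev[(length(dev) - n50 + 1L):length(dev)])
    sag <- abs(dv_max) / abs(ss)
    tc <- fit_decay_tau(seq(0, by = 1000 / fs, length.out = i_pk),
                        dev[seq_len(i_pk)])
    data.frame(sweep = sw, current_pA = ep$amplitude[1L], rin_MOhm = rin,
               tc_ms = tc, sag_ratio = sag, rmp_mV = base)
  })
  per <- do.call(rbind, per)
  rin <- mean(per$rin_MOhm)
  tc <- mean(per$tc_ms, na.rm = TRUE)
  list(rin_MOhm = rin, tc_ms = tc,
       cin_pF = 1000 * tc / rin,
       sag_ratio = mean(per$sag_ratio),
       rmp_mV = mean(per$rmp_mV),
       per_sweep = per)
}

# Single-exponential fit y(t) = y_inf + (y0 - y_inf) exp(-t/tau); t in ms.
# Initial tau from the 1 - 1/e crossing of the normalized trajectory.
fit_decay_tau <- function(t_ms, y) {
  if (length(y) < 4L) return(NA_real_)
  y0 <- y[1L]; y_inf <- y[length(y)]
  if (abs(y_inf - y0) < 1e-12) return(NA_real_)
  frac <- (y - y0) / (y_inf - y0)
  i63 <- which(frac >= 1 - exp(-1))[1L]
  tau0 <- if (is.na(i63)) t_ms[length(t_ms)] / 3 else max(t_ms[i63], 1e-3)
  resid_fn <- function(p) y - (p[1] + (p[2] - p[1]) * exp(-t_ms / p[3]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(y_inf, y0, tau0), fn = resid_fn,
                       lower = c(-Inf, -Inf, 1e-4),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) return(NA_real_)
  unname(fit$par[3])
}

#' Full intrinsic profile of one cell
#'
#' Convenience wrapper combining [fi_analysis()], [adaptation_index()] and
#' [passive_properties()] on one current-clamp family.
#'
#' @param x a current-clamp [sweepset()] containing both the hyperpolarizing
#'   passive step(s) and the 50 pA depolarizing ladder.
#' @param ... passed to [detect_spikes()] via the component analyses.
#' @return list of class `intrinsic_profile` with `rheobase_pA`,
#'   `fi_gain_spikes_per_pA`, `total_spike_output`, `max_firing_sweep_pA`,
#'   `adaptation_index`, `rin_MOhm`, `tc_ms`, `cin_pF`, `sag_ratio`,
#'   `rmp_mV`, and the per-step `spike_counts`.
#' @export
intrinsic_profile <- function(x, ...) {
  fi <- fi_analysis(x, ...)
  pas <- passive_properties(x)
  ai <- adaptation_index(x, fi$rheobase_pA, ...)
  structure(list(rheobase_pA = fi$rheobase_pA,
                 fi_gain_spikes_per_pA = fi$fi_gain_spikes_per_pA,
                 total_spike_output = fi$total_spike_output,
                 max_firing_sweep_pA = fi$max_firing_sweep_pA,
                 adaptation_index = ai,
                 rin_MOhm = pas$rin_MOhm, tc_ms = pas$tc_ms,
                 cin_pF = pas$cin_pF, sag_ratio = pas$sag_ratio,
                 rmp_mV = pas$rmp_mV,
                 spike_counts = fi$spike_counts),
            class = "intrinsic_profile")
}

#' @export
print.intrinsic_profile <- function(x, ...) {
  cat("<intrinsic_profile>\n")
  cat(sprintf("  rheobase %.0f pA | F-I gain %.4f spikes/pA | total output %d\n",
              x$rheobase_pA, x$fi_gain_spikes_per_pA, x$total_spike_output))
  cat(sprintf("  Rin %.1f MOhm | TC %.2f ms | Cin %.1f pF | sag %.3f | RMP %.1f mV\n",
              x$rin_MOhm, x$tc_ms, x$cin_pF, x$sag_ratio, x$rmp_mV))
  invisible(x)
}
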