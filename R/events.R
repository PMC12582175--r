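#' Detection parameters for spontaneous synaptic events
#'
#' Defaults mirror a standard threshold-based EPSC detector configuration:
#' negative peak direction, 5 ms local-maximum period, 30 ms decay search
#' period, 8 pA amplitude threshold, 10 ms search period, 1 ms averaged
#' baseline, and a curved (drift-following) baseline. The curved baseline is
#' realised as a rolling median with window `curved_window_s`. Rise-time
#' bounds give a deterministic automated surrogate for manual rejection of
#' noise events.
#'
#' @param amplitude_threshold_pA detection threshold on baseline-subtracted
#'   amplitude, pA.
#' @param local_max_period_ms candidates whose peaks fall within this period
#'   of a larger candidate are merged into it, ms.
#' @param decay_search_ms post-peak window used for the averaged-event decay
#'   fit, ms.
#' @param search_period_ms window after a threshold crossing searched for
#'   the event peak, ms.
#' @param baseline_avg_ms local-baseline averaging window immediately before
#'   the event onset, ms.
#' @param curved_window_s rolling-median window for the curved baseline, s.
#' @param min_rise_ms,max_rise_ms accepted onset-to-peak rise times, ms.
#' @param direction only `"negative"` (inward currents) is supported.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(amplitude_threshold_pA = 8,
                             local_max_period_ms = 5,
                             decay_search_ms = 30,
                             search_period_ms = 10,
                             baseline_avg_ms = 1,
                             curved_window_s = 0.5,
                             min_rise_ms = 0.1, max_rise_ms = 5,
                             direction = "negative") {
  stopifnot(amplitude_threshold_pA > 0, local_max_period_ms > 0,
            decay_search_ms > 0, search_period_ms > 0, baseline_avg_ms > 0,
            curved_window_s > 0, min_rise_ms >= 0,
            max_rise_ms > min_rise_ms, identical(direction, "negative"))
  structure(as.list(environment()), class = "detection_params")
}

# Event onset: walk back from the (smoothed-trace) peak until the trace
# either recovers to 10% of the peak depth (rise start on a quiet baseline)
# or falls `tol` below the running maximum (the turn point of an event
# riding on a previous event's decay).
event_onset <- function(ys, pk_i, lo, tol) {
  depth10 <- 0.1 * ys[pk_i]
  j <- pk_i; best <- pk_i
  while (j > lo) {
    j <- j - 1L
    if (ys[j] >= depth10) return(j)
    if (ys[j] > ys[best]) best <- j
    else if (ys[best] - ys[j] > tol) return(best)
  }
  best
}

# Curved baseline: rolling median computed on a ~1 kHz decimated copy of the
# trace and linearly interpolated back to the full grid. Robust to events
# (median) while following slow drift.
curved_baseline <- function(sig, fs, window_s) {
  dec <- max(1L, floor(fs / 1000))
  idx <- seq(1L, length(sig), by = dec)
  sub <- sig[idx]
  k <- round(window_s * fs / dec)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(sub) %% 2L == 0L) length(sub) - 1L else length(sub))
  if (k < 3L) return(rep(stats::median(sig), length(sig)))
  med <- stats::runmed(sub, k, endrule = "median")
  stats::approx(idx, med, xout = seq_along(sig), rule = 2)$y
}

#' Detect spontaneous synaptic events in a voltage-clamp sweep
#'
#' Threshold-based detection of negative-going events: (1) a curved baseline
#' (rolling median over `curved_window_s`) is subtracted; (2) candidate
#' onsets are downward crossings of `-amplitude_threshold_pA`; (3) the event
#' peak is the most negative point within `search_period_ms` of the
#' crossing, and candidates whose peaks fall within `local_max_period_ms` of
#' a larger candidate are merged into it; (4) the local baseline is the mean
#' of the raw signal over `baseline_avg_ms` immediately before onset, and
#' amplitude = local baseline - peak; (5) events with onset-to-peak rise
#' times outside `[min_rise_ms, max_rise_ms]`, amplitude below threshold, or
#' peaks inside an exclusion epoch are rejected.
#'
#' @param x a voltage-clamp [sweepset()].
#' @param sweep sweep index.
#' @param params a [detection_params()] object.
#' @param exclusions data frame with columns `onset`, `duration` (s) whose
#'   windows are excluded (test pulse, optogenetic artifacts). Defaults to
#'   the sweep's stimulus epochs.
#' @return data frame of class `event_table`: `onset_time_s`, `peak_time_s`,
#'   `amplitude_pA` (positive magnitude), `rise_time_ms`,
#'   `local_baseline_pA`.
#' @export
detect_events <- function(x, sweep = 1L, params = detection_params(),
                          exclusions = NULL) {
  stopifnot(inherits(x, "sweepset"), inherits(params, "detection_params"))
  if (x$clamp_mode != "voltage_clamp")
    stop("detect_events requires a voltage-clamp sweepset", call. = FALSE)
  sig <- x$sweeps[[sweep]]
  fs <- x$sampling_rate
  dur <- length(sig) / fs
  if (is.null(exclusions)) {
    ep <- if (!is.null(x$stimulus)) x$stimulus[[sweep]] else NULL
    exclusions <- if (is.null(ep)) data.frame(onset = numeric(0),
                                              duration = numeric(0))
    else ep[, c("onset", "duration")]
  }
  if (nrow(exclusions) &&
      sum(pmin(exclusions$onset + exclusions$duration, dur) -
            pmax(exclusions$onset, 0)) >= dur - 1e-9)
    stop("empty analysis: exclusion epochs cover the entire sweep",
         call. = FALSE)

  y <- sig - curved_baseline(sig, fs, params$curved_window_s)
  thr <- -params$amplitude_threshold_pA
  n <- length(y)
  below <- y <= thr
  crossings <- which(below & !c(FALSE, below[-n]))
  empty <- data.frame(onset_time_s = numeric(0), peak_time_s = numeric(0),
                      amplitude_pA = numeric(0), rise_time_ms = numeric(0),
                      local_baseline_pA = numeric(0))
  n_search <- round(params$search_period_ms / 1000 * fs)
  peak_idx <- vapply(crossings, function(cr) {
    win <- cr:min(n, cr + n_search)
    win[which.min(y[win])]
  }, integer(1))
  # one candidate per distinct peak (two crossings can find the same peak)
  keep1 <- !duplicated(peak_idx)
  crossings <- crossings[keep1]; peak_idx <- peak_idx[keep1]

  # Secondary candidates: events arriving while the trace is still below
  # threshold from an earlier event produce no fresh crossing. Find local
  # minima of a lightly smoothed trace below threshold and require the
  # relative drop from the preceding turn to reach the amplitude threshold.
  ks <- max(3L, round(0.00025 * fs))
  ys <- as.numeric(stats::filter(y, rep(1 / ks, ks), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  core <- 2:(n - 1L)
  lm_i <- core[ys[core] <= ys[core - 1L] & ys[core] < ys[core + 1L] &
                 ys[core] < thr]
  if (length(lm_i) && length(peak_idx)) {
    min_gap0 <- round(params$local_max_period_ms / 1000 * fs)
    near <- vapply(lm_i, function(i)
      any(abs(i - peak_idx) < min_gap0), logical(1))
    lm_i <- lm_i[!near]
  }
  tol <- params$amplitude_threshold_pA / 2
  if (length(lm_i)) {
    sec <- vapply(lm_i, function(i) {
      on_i <- event_onset(ys, i, max(2L, i - n_search), tol)
      if (ys[on_i] - ys[i] < params$amplitude_threshold_pA) return(NA_integer_)
      win <- max(1L, i - ks):min(n, i + ks)      # refine on the raw trace
      win[which.min(y[win])]
    }, integer(1))
    peak_idx <- c(peak_idx, sec[!is.na(sec)])
  }
  if (!length(peak_idx)) return(structure(empty, class = c("event_table",
                                                           "data.frame")))
  peak_idx <- peak_idx[!duplicated(peak_idx)]
  # merge candidates within the local-maximum period, keeping the largest
  min_gap <- round(params$local_max_period_ms / 1000 * fs)
  ord <- order(y[peak_idx])                       # most negative first
  keep <- logical(length(peak_idx))
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(peak_idx[j] - taken) >= min_gap)) {
      keep[j] <- TRUE
      taken <- c(taken, peak_idx[j])
    }
  }
  peak_idx <- sort(peak_idx[keep])

  n_base <- max(1L, round(params$baseline_avg_ms / 1000 * fs))
  rows <- lapply(seq_along(peak_idx), function(j) {
    pk_i <- peak_idx[j]
    on_i <- event_onset(ys, pk_i, max(2L, pk_i - n_search), tol)
    b_lo <- max(1L, on_i - n_base)
    local_base <- mean(sig[b_lo:(on_i - 1L + (b_lo == on_i))])
    # peak depth read from the lightly smoothed trace: suppresses the
    # noise-extreme bias of the raw minimum near the threshold
    pk_s <- ys[pk_i] + (sig[pk_i] - y[pk_i])   # smoothed, on the raw offset
    amp <- local_base - pk_s
    rise <- (pk_i - on_i) / fs * 1000
    data.frame(onset_time_s = (on_i - 1L) / fs,
               peak_time_s = (pk_i - 1L) / fs,
               amplitude_pA = amp, rise_time_ms = rise,
               local_baseline_pA = local_base)
  })
  out <- do.call(rbind, rows)
  ok <- out$amplitude_pA >= params$amplitude_threshold_pA &
    out$rise_time_ms >= params$min_rise_ms &
    out$rise_time_ms <= params$max_rise_ms
  if (nrow(exclusions))
    for (e in seq_len(nrow(exclusions)))
      ok <- ok & !(out$peak_time_s >= exclusions$onset[e] &
                     out$peak_time_s <= exclusions$onset[e] +
                       exclusions$duration[e])
  out <- out[ok, , drop = FALSE]
  out <- out[order(out$peak_time_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("event_table", "data.frame"))
}

#' Per-sweep summaries of detected events
#'
#' Frequency is the event count divided by the analysis window: sweep
#' duration minus the discarded first second containing the test pulse
#' (minus 2 s when optogenetic stimulation is present), i.e. 29 s or 28 s
#' for 30 s sweeps. Events with peaks inside the discarded lead-in are not
#' counted. Mean amplitude averages all events in the sweep. Event kinetics
#' (half-width, decay time constant) come from the averaged event: all
#' events are aligned on their peaks over a window of 5 ms before to
#' `decay_search_ms` after the peak, locally baseline-subtracted, and
#' averaged; the half-width is the interpolated width at half the averaged
#' peak and the decay constant a single-exponential fit to the averaged
#' decay.
#'
#' @param x the voltage-clamp [sweepset()] the events came from.
#' @param tables list of [detect_events()] results, one per sweep.
#' @param opto_present logical; discard 2 s instead of 1 s.
#' @param params the [detection_params()] used (for the decay window).
#' @return data frame (one row per sweep): `sweep`, `n_events`,
#'   `analysis_window_s`, `frequency_Hz`, `mean_amplitude_pA`,
#'   `half_width_ms`, `decay_tau_ms`.
#' @export
summarize_events <- function(x, tables, opto_present = FALSE,
                             params = detection_params()) {
  stopifnot(inherits(x, "sweepset"), length(tables) == n_sweeps(x))
  fs <- x$sampling_rate
  dur <- sweep_duration(x)
  discard <- if (opto_present) 2 else 1
  window <- dur - discard
  if (window <= 0) stop("analysis window is empty", call. = FALSE)

  n_pre <- round(0.005 * fs)
  n_post <- round(params$decay_search_ms / 1000 * fs)
  rows <- lapply(seq_along(tables), function(sw) {
    ev <- tables[[sw]]
    ev <- ev[ev$peak_time_s >= discard, , drop = FALSE]
    ne <- nrow(ev)
    if (ne == 0L)
      return(data.frame(sweep = sw, n_events = 0L,
                        analysis_window_s = window, frequency_Hz = 0,
                        mean_amplitude_pA = NA_real_,
                        half_width_ms = NA_real_, decay_tau_ms = NA_real_))
    sig <- x$sweeps[[sw]]
    segs <- vapply(seq_len(ne), function(e) {
      pk <- round(ev$peak_time_s[e] * fs) + 1L
      lo <- pk - n_pre; hi <- pk + n_post
      if (lo < 1L || hi > length(sig)) return(rep(NA_real_, n_pre + n_post + 1L))
      sig[lo:hi] - ev$local_baseline_pA[e]
    }, numeric(n_pre + n_post + 1L))
    avg <- rowMeans(segs, na.rm = TRUE)
    kin <- averaged_event_kinetics(avg, fs, n_pre)
    data.frame(sweep = sw, n_events = ne, analysis_window_s = window,
               frequency_Hz = ne / window,
               mean_amplitude_pA = mean(ev$amplitude_pA),
               half_width_ms = kin$half_width_ms,
               decay_tau_ms = kin$decay_tau_ms)
  })
  do.call(rbind, rows)
}

# Kinetics of the averaged (negative-going, baseline-subtracted) event.
averaged_event_kinetics <- function(avg, fs, i_peak0) {
  i_pk <- i_peak0 + 1L
  pk <- avg[i_pk]
  if (!is.finite(pk) || pk >= 0)
    return(list(half_width_ms = NA_real_, decay_tau_ms = NA_real_))
  half <- pk / 2
  # width at half amplitude, linear interpolation on both flanks
  i <- i_pk
  while (i > 1L && avg[i - 1L] < half) i <- i - 1L
  t1 <- if (i == 1L) NA_real_ else
    (i - 2L + (half - avg[i - 1L]) / (avg[i] - avg[i - 1L])) / fs
  j <- i_pk
  while (j < length(avg) && avg[j + 1L] < half) j <- j + 1L
  t2 <- if (j == length(avg)) NA_real_ else
    (j - 1L + (avg[j] - half) / (avg[j] - avg[j + 1L])) / fs
  hw <- (t2 - t1) * 1000
  t_ms <- (seq_along(avg) - i_pk) / fs * 1000
  dec <- t_ms >= 0
  tau <- fit_decay_tau(t_ms[dec], avg[dec])
  list(half_width_ms = hw, decay_tau_ms = tau)
}

#' Acute-pharmacology time course
#'
#' For the acute drug-application protocol (`n_baseline` sweeps in control
#' solution immediately followed by `n_drug` sweeps in drug), expresses each
#' sweep's event frequency as a percentage of the mean baseline frequency
#' and reports the paired per-cell baseline/drug means.
#'
#' @param summaries a [summarize_events()] data frame for one cell, sweeps
#'   in acquisition order.
#' @param n_baseline,n_drug sweep counts of the two phases.
#' @return list: `timecourse` (per sweep: `sweep`, `phase`, `frequency_Hz`,
#'   `percent_of_baseline`), `baseline_mean_Hz`, `drug_mean_Hz`,
#'   `percent_defined` (FALSE when the baseline mean is 0, in which case
#'   `percent_of_baseline` is NA and the cell must be excluded from %BL
#'   aggregation).
#' @export
acute_timecourse <- function(summaries, n_baseline = 2, n_drug = 20) {
  stopifnot(nrow(summaries) == n_baseline + n_drug)
  phase <- rep(c("baseline", "drug"), c(n_baseline, n_drug))
  f <- summaries$frequency_Hz
  base_mean <- mean(f[phase == "baseline"])
  pct_ok <- base_mean > 0
  tc <- data.frame(sweep = summaries$sweep, phase = phase, frequency_Hz = f,
                   percent_of_baseline = if (pct_ok) 100 * f / base_mean
                   else NA_real_)
  list(timecourse = tc,
       baseline_mean_Hz = base_mean,
       drug_mean_Hz = mean(f[phase == "drug"]),
       percent_defined = pct_ok)
}
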