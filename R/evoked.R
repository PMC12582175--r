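#' Quantify an evoked 10 Hz train response
#'
#' Trials are averaged point-wise, then for each pulse: the baseline is the
#' mean of the 5 ms preceding the pulse, the amplitude is baseline minus the
#' most negative point in the 50 ms post-pulse window, and the area is the
#' trapezoidal integral of (baseline - signal) over that window (pA*ms).
#' Each pulse amplitude is additionally normalized to the first pulse.
#' Re-measuring the baseline before every pulse keeps later pulses unbiased
#' by incomplete decay of earlier ones.
#'
#' @param x a voltage-clamp [sweepset()], one sweep per trial.
#' @param pulse_times_s pulse onset times, s; defaults to the sweep's
#'   stimulus epoch onsets.
#' @param window_ms per-pulse analysis window, ms.
#' @param baseline_ms pre-pulse baseline window, ms.
#' @return list of class `train_metrics`: `pulse_amplitudes_pA`,
#'   `pulse_areas_pA_ms`, `normalized_amplitudes` (first element exactly 1),
#'   `first_pulse_amplitude_pA`, `n_trials_averaged`, `pulse_times_s`.
#' @export
train_metrics <- function(x, pulse_times_s = NULL, window_ms = 50,
                          baseline_ms = 5) {
  stopifnot(inherits(x, "sweepset"))
  if (x$clamp_mode != "voltage_clamp")
    stop("train_metrics requires a voltage-clamp sweepset", call. = FALSE)
  if (is.null(pulse_times_s)) {
    ep <- x$stimulus[[1L]]
    if (is.null(ep) || nrow(ep) == 0L)
      stop("no pulse times available", call. = FALSE)
    pulse_times_s <- ep$onset
  }
  fs <- x$sampling_rate
  avg <- Reduce(`+`, x$sweeps) / length(x$sweeps)
  n <- length(avg)
  n_win <- round(window_ms / 1000 * fs)
  n_base <- round(baseline_ms / 1000 * fs)
  dt_ms <- 1000 / fs

  amps <- areas <- numeric(length(pulse_times_s))
  for (i in seq_along(pulse_times_s)) {
    i_on <- round(pulse_times_s[i] * fs) + 1L
    if (i_on - n_base < 1L || i_on + n_win - 1L > n)
      stop("pulse window outside sweep", call. = FALSE)
    base <- mean(avg[(i_on - n_base):(i_on - 1L)])
    seg <- base - avg[i_on:(i_on + n_win - 1L)]
    amps[i] <- max(seg)
    areas[i] <- (sum(seg) - (seg[1L] + seg[length(seg)]) / 2) * dt_ms
  }
  if (amps[1L] <= 0)
    stop("normalization undefined: first-pulse amplitude <= 0",
         call. = FALSE)
  norm <- amps / amps[1L]
  norm[1L] <- 1
  structure(list(pulse_amplitudes_pA = amps, pulse_areas_pA_ms = areas,
                 normalized_amplitudes = norm,
                 first_pulse_amplitude_pA = amps[1L],
                 n_trials_averaged = length(x$sweeps),
                 pulse_times_s = pulse_times_s),
            class = "train_metrics")
}

#' @export
print.train_metrics <- function(x, ...) {
  cat(sprintf("<train_metrics> %d pulses, %d trials averaged\n",
              length(x$pulse_amplitudes_pA), x$n_trials_averaged))
  cat("  first pulse:", round(x$first_pulse_amplitude_pA, 2), "pA\n")
  cat("  normalized:", paste(round(x$normalized_amplitudes, 3),
                             collapse = " "), "\n")
  invisible(x)
}

#' Compare evoked trains between baseline and drug conditions
#'
#' Pairs per-cell first-pulse amplitudes across conditions, runs a
#' two-tailed paired t test on them (via [compare_groups()]), and reports
#' the per-pulse normalized profiles of both conditions for the short-term
#' dynamics comparison.
#'
#' @param baseline,drug lists of [train_metrics()], one element per cell,
#'   in matching order; every train must have the same pulse count.
#' @return list: `paired_amplitudes_pA` (data frame cell, baseline, drug),
#'   `test` ([compare_groups()] result), `normalized_baseline`,
#'   `normalized_drug` (pulse x cell matrices).
#' @export
compare_baseline_drug <- function(baseline, drug) {
  if (length(baseline) != length(drug) || length(baseline) == 0L)
    stop("need matched, non-empty baseline and drug lists", call. = FALSE)
  np <- vapply(c(baseline, drug),
               function(m) length(m$pulse_amplitudes_pA), integer(1))
  if (length(unique(np)) != 1L)
    stop("structural error: mismatched pulse counts", call. = FALSE)
  a_base <- vapply(baseline, `[[`, numeric(1), "first_pulse_amplitude_pA")
  a_drug <- vapply(drug, `[[`, numeric(1), "first_pulse_amplitude_pA")
  res <- compare_groups(a_base, a_drug, design = "paired",
                        measure_class = "other")
  list(paired_amplitudes_pA = data.frame(cell = seq_along(a_base),
                                         baseline = a_base, drug = a_drug),
       test = res,
       normalized_baseline = vapply(baseline, `[[`,
                                    numeric(np[1L]), "normalized_amplitudes"),
       normalized_drug = vapply(drug, `[[`,
                                numeric(np[1L]), "normalized_amplitudes"))
}
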