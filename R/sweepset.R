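#' Construct a sweep set
#'
#' A `sweepset` is the in-memory representation of one whole-cell recording:
#' an ordered collection of uniformly sampled sweeps acquired under a single
#' clamp mode, together with the stimulus epochs applied during each sweep
#' and free-form annotations (cell id, region, condition, ...).
#'
#' Signal units follow the clamp mode: membrane potential in mV under current
#' clamp, membrane current in pA under voltage clamp (inward currents
#' negative, as recorded). All epoch times are in seconds from sweep start.
#'
#' @param sweeps list of numeric vectors, one per sweep; all the same length.
#' @param sampling_rate sampling rate in samples/s (e.g. 20000).
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param stimulus either a single data frame with columns `onset`,
#'   `duration`, `amplitude` (recycled to every sweep) or a list of such data
#'   frames, one per sweep. Amplitudes are pA in current clamp and mV in
#'   voltage clamp. May be `NULL` for stimulus-free sweeps.
#' @param holding commanded holding level in mV (`NA` if not applicable).
#' @param annotations named list of character scalars.
#' @return An object of class `sweepset`.
#' @export
sweepset <- function(sweeps, sampling_rate,
                     clamp_mode = c("current_clamp", "voltage_clamp"),
                     stimulus = NULL, holding = NA_real_,
                     annotations = list()) {
  clamp_mode <- match.arg(clamp_mode)
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("`sweeps` must be a non-empty list of numeric vectors", call. = FALSE)
  sweeps <- lapply(sweeps, as.numeric)
  lens <- lengths(sweeps)
  if (length(unique(lens)) != 1L)
    stop("structural error: sweeps have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number", call. = FALSE)

  dur <- lens[1L] / sampling_rate
  if (is.data.frame(stimulus)) stimulus <- rep(list(stimulus), length(sweeps))
  if (!is.null(stimulus)) {
    if (length(stimulus) != length(sweeps))
      stop("`stimulus` must supply one epoch table per sweep", call. = FALSE)
    stimulus <- lapply(stimulus, function(ep) {
      ep <- as.data.frame(ep)
      need <- c("onset", "duration", "amplitude")
      if (!all(need %in% names(ep)))
        stop("epoch tables need columns onset, duration, amplitude",
             call. = FALSE)
      if (nrow(ep) && any(ep$onset < 0 | ep$onset + ep$duration > dur + 1e-9))
        stop("epoch window falls outside the sweep", call. = FALSE)
      ep[, need, drop = FALSE]
    })
  }
  if (length(annotations))
    annotations <- lapply(annotations, as.character)

  structure(
    list(sweeps = sweeps, sampling_rate = sampling_rate,
         clamp_mode = clamp_mode, stimulus = stimulus,
         holding = as.numeric(holding), annotations = annotations),
    class = "sweepset")
}

#' @export
print.sweepset <- function(x, ...) {
  n <- length(x$sweeps)
  len <- length(x$sweeps[[1L]])
  cat(sprintf("<sweepset> %d sweep%s x %d samples (%.3f s) @ %g Hz, %s\n",
              n, if (n == 1L) "" else "s", len, len / x$sampling_rate,
              x$sampling_rate, x$clamp_mode))
  if (length(x$annotations))
    cat("  annotations:",
        paste(names(x$annotations), unlist(x$annotations),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of sweeps and sweep duration
#' @param x a `sweepset`.
#' @return `n_sweeps`: integer count; `sweep_duration`: seconds.
#' @export
n_sweeps <- function(x) length(x$sweeps)

#' @rdname n_sweeps
#' @export
sweep_duration <- function(x) length(x$sweeps[[1L]]) / x$sampling_rate

#' Time axis of a sweep (seconds, first sample at 0)
#' @param x a `sweepset`.
#' @keywords internal
sweep_times <- function(x) {
  (seq_len(length(x$sweeps[[1L]])) - 1L) / x$sampling_rate
}

#' Save / load a sweep set (csv + json sidecar dialect)
#'
#' The on-disk dialect is a long-format CSV with columns `sweep`, `time_s`,
#' `value` plus a JSON sidecar (same path with extension `.json`) carrying
#' `sampling_rate`, `clamp_mode`, `holding`, per-sweep stimulus `epochs`, and
#' `annotations`. Sample values are written with 17 significant digits so the
#' round trip is bit-exact for doubles.
#'
#' @param x a `sweepset`.
#' @param path path of the CSV file; the sidecar is written next to it.
#' @return `save_sweepset` returns `path` invisibly; `load_sweepset` returns
#'   a `sweepset`.
#' @export
save_sweepset <- function(x, path) {
  stopifnot(inherits(x, "sweepset"))
  tt <- sweep_times(x)
  dt <- data.table::data.table(
    sweep = rep(seq_along(x$sweeps), each = length(tt)),
    time_s = rep(tt, length(x$sweeps)),
    value = sprintf("%.17g", unlist(x$sweeps, use.names = FALSE)))
  data.table::fwrite(dt, path)
  sidecar <- list(
    sampling_rate = x$sampling_rate,
    clamp_mode = x$clamp_mode,
    holding = x$holding,
    epochs = if (is.null(x$stimulus)) NULL else x$stimulus,
    annotations = if (length(x$annotations)) x$annotations else NULL)
  jsonlite::write_json(sidecar, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' @rdname save_sweepset
#' @export
load_sweepset <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("format error: JSON sidecar missing (", sc_path, ")", call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (field in c("sampling_rate", "clamp_mode"))
    if (is.null(sc[[field]]))
      stop("format error: sidecar lacks ", field, call. = FALSE)
  dt <- data.table::fread(path, colClasses = list(character = "value"))
  if (!all(c("sweep", "value") %in% names(dt)))
    stop("format error: CSV needs columns sweep, time_s, value", call. = FALSE)
  sweeps <- lapply(split(as.numeric(dt$value), dt$sweep), unname)
  names(sweeps) <- NULL
  stim <- sc$epochs
  if (!is.null(stim) && is.data.frame(stim)) stim <- list(stim)
  ann <- sc$annotations
  sweepset(sweeps, sampling_rate = as.numeric(sc$sampling_rate),
           clamp_mode = sc$clamp_mode, stimulus = stim,
           holding = if (is.null(sc$holding)) NA_real_
           else as.numeric(sc$holding),
           annotations = if (is.null(ann)) list() else as.list(ann))
}

#' Series and input resistance from a voltage-clamp test pulse
#'
#' Decomposes the response to a brief hyperpolarizing test pulse (typically
#' -5 mV / 250 ms at the start of each sweep) into the access (series)
#' resistance and the membrane input resistance. The capacitive-transient
#' peak current deviation from the pre-pulse baseline gives
#' `Rs = dV / I_peak`; the steady-state deviation (mean over the final 50 ms
#' of the pulse) gives the total resistance, and `Rin = dV / I_ss - Rs`.
#' The baseline is the mean of the 100 ms preceding the pulse (or whatever
#' shorter pre-pulse segment exists).
#'
#' @param x a voltage-clamp `sweepset`.
#' @param sweep sweep index to analyse.
#' @param pulse numeric `c(onset, duration)` in seconds; defaults to the
#'   first stimulus epoch of the sweep.
#' @param delta_mV pulse amplitude magnitude in mV; defaults to the epoch
#'   amplitude.
#' @return list with `series_resistance_MOhm`, `input_resistance_MOhm`,
#'   `holding_current_pA` (mean over the post-pulse remainder of the sweep)
#'   and `baseline_current_pA` (pre-pulse mean).
#' @export
test_pulse_metrics <- function(x, sweep = 1L, pulse = NULL, delta_mV = NULL) {
  stopifnot(inherits(x, "sweepset"))
  if (x$clamp_mode != "voltage_clamp")
    stop("test_pulse_metrics requires a voltage-clamp sweepset", call. = FALSE)
  sig <- x$sweeps[[sweep]]
  fs <- x$sampling_rate
  if (is.null(pulse)) {
    ep <- x$stimulus[[sweep]]
    if (is.null(ep) || nrow(ep) == 0L)
      stop("no pulse epoch available", call. = FALSE)
    pulse <- c(ep$onset[1L], ep$duration[1L])
    if (is.null(delta_mV)) delta_mV <- abs(ep$amplitude[1L])
  }
  if (is.null(delta_mV)) stop("pulse amplitude unknown", call. = FALSE)
  if (!is.finite(delta_mV) || delta_mV <= 0)
    stop("degenerate input: zero-amplitude test pulse", call. = FALSE)

  i_on <- round(pulse[1L] * fs) + 1L
  i_off <- round((pulse[1L] + pulse[2L]) * fs)
  if (i_on < 2L || i_off > length(sig) || i_off <= i_on)
    stop("pulse epoch outside sweep", call. = FALSE)
  n_base <- min(i_on - 1L, round(0.1 * fs))
  base <- mean(sig[(i_on - n_base):(i_on - 1L)])
  dev <- sig[i_on:i_off] - base
  n_ss <- min(length(dev), max(1L, round(0.05 * fs)))
  i_ss <- mean(dev[(length(dev) - n_ss + 1L):length(dev)])
  i_peak <- dev[which.max(abs(dev))]
  if (max(abs(dev)) < 1e-9 || abs(i_ss) < 1e-9)
    stop("degenerate input: no detectable test-pulse response", call. = FALSE)
  # mV / pA = GOhm; x1000 -> MOhm
  rs <- 1000 * delta_mV / abs(i_peak)
  rtot <- 1000 * delta_mV / abs(i_ss)
  post <- if (i_off < length(sig)) mean(sig[(i_off + 1L):length(sig)]) else base
  list(series_resistance_MOhm = rs,
       input_resistance_MOhm = rtot - rs,
       holding_current_pA = post,
       baseline_current_pA = base)
}

#' Recording-level quality control
#'
#' Applies the standard slice-recording exclusion rules: resting membrane
#' potential more depolarized than -55 mV (-45 mV for anterodorsal-thalamus
#' recordings), uncompensated series resistance above 35 MOhm, series
#' resistance changing by more than 25% over the experiment, or input
#' resistance changing by more than 25%. Change fractions are magnitudes of
#' fractional change relative to the initial value.
#'
#' @param measures named list / vector with `rmp_mV`, `rs_MOhm`,
#'   `rs_change_frac`, `rin_change_frac` (all finite).
#' @param region_profile `"cortical"` or `"ad_thalamus"`; selects the RMP
#'   cutoff.
#' @return list of class `qc_report`: `pass` (logical), `reasons`
#'   (character vector of violated rule ids), `measured` (named numeric of
#'   rule-relevant values).
#' @export
evaluate_qc <- function(measures,
                        region_profile = c("cortical", "ad_thalamus")) {
  region_profile <- match.arg(region_profile)
  m <- as.list(measures)
  need <- c("rmp_mV", "rs_MOhm", "rs_change_frac", "rin_change_frac")
  if (!all(need %in% names(m)))
    stop("measures must supply ", paste(need, collapse = ", "), call. = FALSE)
  vals <- vapply(m[need], as.numeric, numeric(1))
  if (any(!is.finite(vals)))
    stop("all QC measurements must be finite", call. = FALSE)

  rmp_cut <- if (region_profile == "ad_thalamus") -45 else -55
  reasons <- character()
  if (vals[["rmp_mV"]] > rmp_cut) reasons <- c(reasons, "rmp")
  if (vals[["rs_MOhm"]] > 35) reasons <- c(reasons, "rs")
  if (abs(vals[["rs_change_frac"]]) > 0.25) reasons <- c(reasons, "rs_change")
  if (abs(vals[["rin_change_frac"]]) > 0.25) reasons <- c(reasons, "rin_change")

  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 measured = c(vals, rmp_cutoff_mV = rmp_cut)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s", if (x$pass) "PASS" else "FAIL"))
  if (!x$pass) cat(" (", paste(x$reasons, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
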