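# Current-clamp analysis: spike detection, single-AP waveform features,
# passive properties, F-I curves and cell-level quality control.

#' Detect action potential peaks in a voltage trace
#'
#' An AP is counted only if its peak reaches `peak_floor_mV` (default
#' -10 mV). To reject artifacts, a candidate peak must additionally be
#' preceded within `gate_window_ms` by a dV/dt upstroke exceeding
#' `upstroke_gate_mV_ms`; peaks closer than `refractory_ms` are merged
#' (the larger peak wins). Detection is invariant to DC offsets that keep
#' peaks above the floor.
#'
#' @param v Membrane potential trace (mV).
#' @param rate_hz Sampling rate (Hz).
#' @param peak_floor_mV Minimum peak voltage for a counted AP.
#' @param upstroke_gate_mV_ms Minimum preceding dV/dt (mV/ms); set 0 to
#'   disable the gate.
#' @param gate_window_ms Look-back window for the upstroke gate.
#' @param refractory_ms Merge window for multi-sample peaks.
#' @return Integer vector of peak sample indices (1-based), sorted.
#' @export
detect_spikes <- function(v, rate_hz, peak_floor_mV = -10,
                          upstroke_gate_mV_ms = 20, gate_window_ms = 2,
                          refractory_ms = 1) {
  stopifnot(rate_hz > 0, all(is.finite(v)))
  peaks <- local_maxima(v)
  peaks <- peaks[v[peaks] >= peak_floor_mV]
  if (!length(peaks)) return(integer(0))
  if (upstroke_gate_mV_ms > 0) {
    dvdt <- compute_dvdt(v, rate_hz)
    gw <- max(1L, round(gate_window_ms * rate_hz / 1000))
    ok <- vapply(peaks, function(p) {
      lo <- max(1L, p - gw)
      max(dvdt[lo:p]) >= upstroke_gate_mV_ms
    }, logical(1))
    peaks <- peaks[ok]
  }
  thin_peaks(peaks, v[peaks], max(1L, round(refractory_ms * rate_hz / 1000)))
}

#' First derivative of a voltage trace in mV/ms
#'
#' Central differences on the raw trace (one-sided at the ends), with an
#' optional boxcar pre-smoothing (default none: at the 100 kHz sampling
#' used for AP waveforms, raw differences are stable).
#'
#' @inheritParams detect_spikes
#' @param smooth_samples Boxcar width applied to `v` before
#'   differentiation; 0 or 1 disables.
#' @return Numeric vector, same length as `v`, units mV/ms.
#' @export
compute_dvdt <- function(v, rate_hz, smooth_samples = 0) {
  n <- length(v)
  if (n < 3L) stopf("trace too short for a derivative (need >= 3 samples)")
  if (smooth_samples > 1) v <- moving_mean(v, smooth_samples)
  dt_ms <- 1000 / rate_hz
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' AP threshold: 5 percent-of-upstroke criterion
#'
#' Threshold is the membrane potential at the first sample, scanning
#' forward toward the peak, where dV/dt exceeds `frac` (default 5%) of the
#' window's maximal upstroke velocity.
#'
#' @param v Voltage window containing a single spike (mV).
#' @param dvdt Matching dV/dt window (mV/ms), e.g. from [compute_dvdt()].
#' @param frac Fraction of the maximal upstroke (default 0.05).
#' @return List with `threshold_mV` and `index` (sample within the window).
#' @export
ap_threshold <- function(v, dvdt, frac = 0.05) {
  stopifnot(length(v) == length(dvdt))
  up <- max(dvdt)
  if (!(up > 0)) stopf("no threshold: window has no positive upstroke")
  idx <- which(dvdt > frac * up)[1]
  if (is.na(idx)) stopf("no threshold: criterion never met")
  list(threshold_mV = v[idx], index = idx)
}

#' Waveform features of a single action potential
#'
#' Computes, for the spike peaking at `peak_index`: threshold (5% of
#' upstroke rule), peak, amplitude (peak minus threshold), maximal
#' upstroke and downstroke velocities, APD50 (duration above the
#' half-amplitude level `threshold + amplitude/2`, crossings linearly
#' interpolated), and the afterhyperpolarization (absolute minimum of Vm
#' in a post-peak window).
#'
#' @inheritParams detect_spikes
#' @param peak_index Sample index of the AP peak (from [detect_spikes()]).
#' @param pre_ms Window before the peak searched for threshold/upstroke.
#' @param post_ms Window after the peak searched for downstroke/repolarization.
#' @param ahp_window_ms Post-peak window for the AHP minimum.
#' @return One-row data.frame: `spike_time_s`, `threshold_mV`, `peak_mV`,
#'   `amplitude_mV`, `upstroke_mV_ms`, `downstroke_mV_ms`, `apd50_ms`,
#'   `ahp_mV`.
#' @export
ap_features <- function(v, rate_hz, peak_index, pre_ms = 5, post_ms = 5,
                        ahp_window_ms = 10) {
  n <- length(v)
  spp <- function(ms) max(1L, round(ms * rate_hz / 1000))
  lo <- max(1L, peak_index - spp(pre_ms))
  hi <- min(n, peak_index + spp(post_ms))
  win <- v[lo:hi]
  pk_w <- peak_index - lo + 1L
  dvdt <- compute_dvdt(win, rate_hz)
  thr <- ap_threshold(win[seq_len(pk_w)], dvdt[seq_len(pk_w)])
  peak_mV <- v[peak_index]
  amplitude <- peak_mV - thr$threshold_mV
  if (amplitude < 0) stopf("negative amplitude: window does not bracket a spike")
  upstroke <- max(dvdt[seq_len(pk_w)])
  downstroke <- min(dvdt[pk_w:length(win)])
  # APD50 with linearly interpolated crossings of the half-amplitude level
  level <- thr$threshold_mV + amplitude / 2
  dt_ms <- 1000 / rate_hz
  cross_time <- function(i, j) {
    # linear interpolation of the crossing between window samples i < j
    (i - 1 + (level - win[i]) / (win[j] - win[i])) * dt_ms
  }
  above <- win >= level
  if (!above[pk_w]) stopf("half-amplitude level above peak; malformed spike")
  i <- pk_w
  while (i > 1L && above[i - 1L]) i <- i - 1L
  j <- pk_w
  while (j < length(win) && above[j + 1L]) j <- j + 1L
  t_up <- if (i == 1L) 0 else cross_time(i - 1L, i)
  t_dn <- if (j == length(win)) (length(win) - 1) * dt_ms else cross_time(j, j + 1L)
  apd50 <- t_dn - t_up
  ahp_hi <- min(n, peak_index + spp(ahp_window_ms))
  ahp <- min(v[peak_index:ahp_hi])
  data.frame(spike_time_s = (peak_index - 1) / rate_hz,
             threshold_mV = thr$threshold_mV, peak_mV = peak_mV,
             amplitude_mV = amplitude, upstroke_mV_ms = upstroke,
             downstroke_mV_ms = downstroke, apd50_ms = apd50, ahp_mV = ahp)
}

#' Resting membrane potential
#'
#' Median of a gap-free recording; the median is robust to the small
#' fraction of samples occupied by spontaneous spikes.
#'
#' @param v Gap-free voltage trace (mV).
#' @return Resting Vm in mV.
#' @export
resting_vm <- function(v) {
  if (!length(v)) stopf("empty trace")
  stats::median(v)
}

#' Input resistance from the -20 pA step
#'
#' R = dV_ss / I with dV_ss the mean Vm over the last 20% of the step
#' minus the mean over the pre-step baseline. A hyperpolarizing response
#' to the -20 pA injection yields a positive resistance.
#'
#' @param x A [sweep_set()] in mV with a [step_protocol()] in pA that
#'   includes a -20 pA step.
#' @param step_pA Which step to use (default -20).
#' @return Input resistance in megaohms.
#' @export
input_resistance <- function(x, step_pA = -20) {
  stopifnot(inherits(x, "sweep_set"), x$units == "mV")
  p <- x$protocol
  if (!inherits(p, "step_protocol") || p$units != "pA")
    stopf("needs a current-clamp step protocol")
  k <- which(abs(p$amplitudes - step_pA) < 1e-9)[1]
  if (is.na(k)) stopf("step of %g pA absent from protocol", step_pA)
  v <- x$sweeps[[k]]
  rate <- x$sampling_rate_hz
  on <- round(p$onset_s * rate) + 1L
  off <- round((p$onset_s + p$duration_s) * rate)
  if (on <= 1L) stopf("no pre-step baseline available")
  base <- mean(v[seq_len(on - 1L)])
  ss_lo <- off - max(1L, round(0.2 * (off - on + 1L))) + 1L
  ss <- mean(v[ss_lo:off])
  1000 * (ss - base) / step_pA
}

#' Firing-rate (F-I) curve from a step family
#'
#' Counts spikes whose peaks fall inside the step interval of each sweep;
#' frequency is count divided by the step duration.
#'
#' @param x A [sweep_set()] in mV with a current-clamp [step_protocol()].
#' @inheritParams detect_spikes
#' @return Object of class `fi_curve`: data.frame with `step_pA`,
#'   `n_spikes`, `frequency_hz`.
#' @export
fi_curve <- function(x, peak_floor_mV = -10, upstroke_gate_mV_ms = 20) {
  stopifnot(inherits(x, "sweep_set"))
  if (x$units != "mV") stopf("F-I analysis needs a voltage (mV) sweep set")
  p <- x$protocol
  if (!inherits(p, "step_protocol") || p$units != "pA")
    stopf("needs a current-clamp step protocol")
  rate <- x$sampling_rate_hz
  on <- round(p$onset_s * rate) + 1L
  off <- round((p$onset_s + p$duration_s) * rate)
  counts <- vapply(x$sweeps, function(v) {
    pk <- detect_spikes(v, rate, peak_floor_mV, upstroke_gate_mV_ms)
    sum(pk >= on & pk <= off)
  }, numeric(1))
  out <- data.frame(step_pA = p$amplitudes, n_spikes = as.integer(counts),
                    frequency_hz = counts / p$duration_s)
  out <- out[order(out$step_pA), ]
  rownames(out) <- NULL
  class(out) <- c("fi_curve", "data.frame")
  out
}

#' Rheobase: largest current step that did not evoke spikes
#'
#' Follows the study convention literally: the rheobase reported is the
#' largest step amplitude with zero spikes. The first step that did evoke
#' spikes is also returned. With non-monotonic spike counts, the literal
#' rule still applies and the result is flagged.
#'
#' @param fi An [fi_curve()] (or data.frame with `step_pA`, `n_spikes`).
#' @return List: `rheobase_pA` (largest silent step),
#'   `first_spiking_pA` (smallest step with spikes), `non_monotonic` flag.
#' @export
rheobase <- function(fi) {
  stopifnot(nrow(fi) > 0)
  fi <- fi[order(fi$step_pA), ]
  silent <- fi$step_pA[fi$n_spikes == 0]
  spiking <- fi$step_pA[fi$n_spikes > 0]
  if (!length(silent)) stopf("all steps spiking: rheobase below tested range")
  if (!length(spiking)) stopf("all steps silent: rheobase above tested range")
  nm <- max(silent) > min(spiking)
  if (nm) warnf("non-monotonic spike counts; literal rheobase rule applied")
  list(rheobase_pA = max(silent), first_spiking_pA = min(spiking),
       non_monotonic = nm)
}

#' Cell-level quality control
#'
#' A cell fails QC if its resting membrane potential is more depolarized
#' than -50 mV, or if access resistance changed by more than 20% between
#' the first and last measurement.
#'
#' @param resting_vm_mV Resting membrane potential (mV).
#' @param access_MOhm Numeric vector of access-resistance measurements
#'   over the experiment (at least start and end).
#' @param vm_floor_mV Depolarization limit (default -50 mV).
#' @param max_access_change Fractional access-resistance drift limit.
#' @return List: `pass` (logical) and `reasons` (character).
#' @export
qc_cell <- function(resting_vm_mV, access_MOhm, vm_floor_mV = -50,
                    max_access_change = 0.20) {
  stopifnot(length(access_MOhm) >= 2)
  reasons <- character(0)
  if (resting_vm_mV > vm_floor_mV)
    reasons <- c(reasons, sprintf("depolarized: Vm %.1f mV > %.0f mV",
                                  resting_vm_mV, vm_floor_mV))
  drift <- abs(access_MOhm[length(access_MOhm)] - access_MOhm[1]) / access_MOhm[1]
  if (drift > max_access_change)
    reasons <- c(reasons, sprintf("access drift %.0f%%", 100 * drift))
  list(pass = !length(reasons), reasons = reasons)
}

#' Full feature table for one cell
#'
#' Convenience wrapper assembling the per-cell row of the study's feature
#' schema from a ramp sweep (first AP), a gap-free recording, and a step
#' family.
#'
#' @param ramp A [sweep_set()] with a [ramp_protocol()] (AP features come
#'   from the first ramp-evoked spike).
#' @param gap_free Numeric gap-free trace for resting Vm, or `NULL`.
#' @param steps A step-family [sweep_set()] for F-I, input resistance and
#'   rheobase, or `NULL`.
#' @param cell_id,group Metadata columns.
#' @return One-row data.frame in the feature-table schema.
#' @export
cell_feature_row <- function(ramp, gap_free = NULL, steps = NULL,
                             cell_id = NA_character_, group = NA_character_) {
  v <- ramp$sweeps[[1]]
  rate <- ramp$sampling_rate_hz
  pk <- detect_spikes(v, rate)
  if (!length(pk)) stopf("no ramp-evoked spikes")
  f <- ap_features(v, rate, pk[1])
  rin <- if (!is.null(steps)) tryCatch(input_resistance(steps), error = function(e) NA_real_) else NA_real_
  rheo <- if (!is.null(steps)) {
    fi <- fi_curve(steps)
    tryCatch(rheobase(fi)$rheobase_pA, error = function(e) NA_real_)
  } else NA_real_
  data.frame(cell_id = cell_id, group = group,
             vm_mV = if (!is.null(gap_free)) resting_vm(gap_free) else NA_real_,
             threshold_mV = f$threshold_mV, upstroke_mV_ms = f$upstroke_mV_ms,
             downstroke_mV_ms = f$downstroke_mV_ms,
             amplitude_mV = f$amplitude_mV, apd50_ms = f$apd50_ms,
             input_resistance_MOhm = rin, rheobase_pA = rheo,
             ahp_mV = f$ahp_mV)
}
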