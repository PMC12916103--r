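#' Stimulus protocol descriptors
#'
#' A sweep set carries one protocol describing the command waveform applied
#' on every sweep. Three shapes cover the recordings analysed here: square
#' current/voltage steps, depolarizing current ramps, and presynaptic pulse
#' trains.
#'
#' @param amplitudes Per-sweep step amplitude (pA in current clamp, mV in
#'   voltage clamp).
#' @param onset_s,duration_s Step onset and duration in seconds from sweep
#'   start.
#' @param holding Holding level between steps (pA or mV).
#' @param units `"pA"` or `"mV"` for the command channel.
#' @return A protocol object (list with class `step_protocol`,
#'   `ramp_protocol` or `train_protocol`).
#' @examples
#' step_protocol(seq(-100, 500, by = 50), onset_s = 0.1, duration_s = 1)
#' @export
step_protocol <- function(amplitudes, onset_s, duration_s, holding = 0,
                          units = c("pA", "mV")) {
  units <- match.arg(units)
  if (onset_s < 0) stopf("step onset_s must be >= 0")
  if (duration_s <= 0) stopf("step duration_s must be > 0")
  structure(list(amplitudes = as.numeric(amplitudes), onset_s = onset_s,
                 duration_s = duration_s, holding = holding, units = units),
            class = c("step_protocol", "stim_protocol"))
}

#' @rdname step_protocol
#' @param slope_pA_s Ramp slope in pA/s (the study uses 100 pA/s).
#' @export
ramp_protocol <- function(slope_pA_s = 100, onset_s = 0, duration_s = Inf,
                          holding = 0) {
  structure(list(slope_pA_s = slope_pA_s, onset_s = onset_s,
                 duration_s = duration_s, holding = holding, units = "pA"),
            class = c("ramp_protocol", "stim_protocol"))
}

#' @rdname step_protocol
#' @param frequency_hz Train frequency in Hz.
#' @param n_pulses Number of pulses per train.
#' @param pulse_ms Pulse width in ms.
#' @param amplitude Pulse amplitude (pA).
#' @export
train_protocol <- function(frequency_hz, n_pulses = 10, pulse_ms = 1,
                           amplitude = 2000, onset_s = 0.1) {
  structure(list(frequency_hz = frequency_hz, n_pulses = as.integer(n_pulses),
                 pulse_ms = pulse_ms, amplitude = amplitude, onset_s = onset_s,
                 units = "pA"),
            class = c("train_protocol", "stim_protocol"))
}

#' Construct a sweep set
#'
#' The common container for patch-clamp data: an ordered collection of
#' equal-length sweeps sampled at one rate, with a unit tag per channel and
#' a stimulus protocol. Time is represented by sampling rate plus 0-based
#' sample index; no time vectors are stored.
#'
#' @param sweeps List of numeric vectors, one per sweep, all the same length.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param units Unit tag for the recorded channel: `"mV"` (membrane
#'   potential) or `"pA"` (current).
#' @param protocol A [step_protocol()], [ramp_protocol()] or
#'   [train_protocol()], or `NULL`.
#' @param metadata Named character list (cell id, genotype label, ...).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, sampling_rate_hz, units = c("mV", "pA"),
                      protocol = NULL, metadata = list()) {
  units <- match.arg(units)
  if (!is.list(sweeps)) sweeps <- list(as.numeric(sweeps))
  if (!length(sweeps)) stopf("sweep_set needs at least one sweep")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("sampling_rate_hz must be > 0")
  lens <- lengths(sweeps)
  if (length(unique(lens)) != 1L)
    stopf("ragged sweep lengths: %s", paste(unique(lens), collapse = ", "))
  sweeps <- lapply(sweeps, as.numeric)
  if (!all(vapply(sweeps, function(s) all(is.finite(s)), logical(1))))
    stopf("sweeps contain non-finite values")
  if (inherits(protocol, "step_protocol")) {
    if (protocol$onset_s + protocol$duration_s > lens[1] / sampling_rate_hz + 1e-9)
      stopf("step protocol extends past sweep end")
  }
  structure(list(sweeps = sweeps, sampling_rate_hz = sampling_rate_hz,
                 units = units, protocol = protocol, metadata = metadata),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweep(s) x %d samples @ %g Hz [%s]\n",
              length(x$sweeps), length(x$sweeps[[1]]),
              x$sampling_rate_hz, x$units))
  if (!is.null(x$protocol))
    cat("  protocol:", class(x$protocol)[1], "\n")
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' ROI fluorescence container
#'
#' Suite2p-style output layout: a cells x frames fluorescence matrix with
#' the imaging frame rate, optional per-cell labels (`"PV+"`, `"PV-"`,
#' `"unknown"`), and an optional field-of-view mean trace.
#'
#' @param F Numeric matrix, cells in rows, frames in columns.
#' @param frame_rate_hz Imaging rate in Hz (30 in the study design).
#' @param cell_labels Optional character vector, one per cell.
#' @param fov_mean Optional field-of-view (or neuropil) mean trace, one
#'   value per frame.
#' @return An object of class `roi_fluorescence`.
#' @export
roi_fluorescence <- function(F, frame_rate_hz, cell_labels = NULL,
                             fov_mean = NULL) {
  F <- as.matrix(F)
  if (frame_rate_hz <= 0) stopf("frame_rate_hz must be > 0")
  bad <- which(!apply(F, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stopf("non-finite fluorescence in ROI(s): %s", paste(bad, collapse = ", "))
  if (is.null(cell_labels)) cell_labels <- rep("unknown", nrow(F))
  if (length(cell_labels) != nrow(F))
    stopf("cell_labels length (%d) != number of cells (%d)",
          length(cell_labels), nrow(F))
  if (!is.null(fov_mean) && length(fov_mean) != ncol(F))
    stopf("fov_mean length != number of frames")
  structure(list(F = F, frame_rate_hz = frame_rate_hz,
                 cell_labels = cell_labels, fov_mean = fov_mean),
            class = "roi_fluorescence")
}

#' @export
print.roi_fluorescence <- function(x, ...) {
  cat(sprintf("<roi_fluorescence> %d cells x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$F), ncol(x$F), x$frame_rate_hz,
              ncol(x$F) / x$frame_rate_hz))
  invisible(x)
}

#' EEG record container
#'
#' A single-channel EEG trace in microvolts with its sampling rate and an
#' optional behaviour annotation table from video review
#' (`onset_s`, `offset_s`, `label`).
#'
#' @param signal_uV Numeric vector, EEG in microvolts.
#' @param sampling_rate_hz Sampling rate in Hz (500 in the study design).
#' @param annotations Optional data.frame with columns `onset_s`,
#'   `offset_s`, `label`.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal_uV, sampling_rate_hz, annotations = NULL) {
  if (sampling_rate_hz <= 0) stopf("sampling_rate_hz must be > 0")
  if (!is.null(annotations)) {
    need <- c("onset_s", "offset_s", "label")
    if (!all(need %in% names(annotations)))
      stopf("annotations must have columns %s", paste(need, collapse = ", "))
  }
  structure(list(signal_uV = as.numeric(signal_uV),
                 sampling_rate_hz = sampling_rate_hz,
                 annotations = annotations),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %.1f s @ %g Hz, %d annotation(s)\n",
              length(x$signal_uV) / x$sampling_rate_hz, x$sampling_rate_hz,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}
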