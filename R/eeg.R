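# EEG preprocessing, adaptive-threshold epileptiform spike detection,
# ISI-grouped spike-train detection, and rule-based classification of
# events into runs of spikes, seizures, myoclonic seizures and
# seizure-induced sudden death, using behaviour annotations.

#' Preprocess an EEG trace
#'
#' Zero-phase 60 Hz powerline notch (2nd-order Butterworth band-stop,
#' Q = 30, i.e. 59-61 Hz) followed by a zero-phase 1 Hz high-pass
#' (2nd-order Butterworth).
#'
#' @param x An [eeg_record()] or numeric trace (uV).
#' @param sampling_rate_hz Sampling rate when `x` is a bare vector.
#' @param notch_hz Powerline frequency.
#' @param notch_q Notch quality factor (bandwidth = notch_hz / Q).
#' @param highpass_hz High-pass corner.
#' @return Filtered numeric trace (uV).
#' @export
preprocess_eeg <- function(x, sampling_rate_hz = NULL, notch_hz = 60,
                           notch_q = 30, highpass_hz = 1) {
  if (inherits(x, "eeg_record")) {
    sig <- x$signal_uV; rate <- x$sampling_rate_hz
  } else {
    sig <- as.numeric(x)
    if (is.null(sampling_rate_hz)) stopf("sampling_rate_hz required")
    rate <- sampling_rate_hz
  }
  nyq <- rate / 2
  if (notch_hz >= nyq)
    stopf("sampling rate %g Hz below Nyquist for a %g Hz notch", rate, notch_hz)
  bw <- notch_hz / notch_q
  stopb <- signal::butter(2, c(notch_hz - bw / 2, notch_hz + bw / 2) / nyq,
                          type = "stop")
  out <- signal::filtfilt(stopb, sig)
  hp <- signal::butter(2, highpass_hz / nyq, type = "high")
  signal::filtfilt(hp, out)
}

#' Causal rolling RMS over the preceding minute
#'
#' RMS of the window ending at each sample and extending `window_s` back;
#' before `window_s` has elapsed the window expands from the record
#' start.
#'
#' @param x Numeric trace.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param window_s Window length in seconds (60).
#' @return Numeric trace of the same length.
#' @export
rolling_rms <- function(x, sampling_rate_hz, window_s = 60) {
  n <- length(x)
  if (!n) return(numeric(0))
  w <- max(1L, round(window_s * sampling_rate_hz))
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  lo <- pmax(i - w + 1L, 1L)
  sqrt((cs[i + 1L] - cs[lo]) / (i - lo + 1L))
}

#' Detect epileptiform spikes
#'
#' A spike sample must exceed both the absolute floor (200 uV) and the
#' causal RMS of the preceding minute; amplitude is the absolute
#' deviation of the filtered trace from zero. Candidate peaks closer than
#' `refractory_ms` (50 ms) are merged into one spike complex (largest
#' peak wins). Width is measured at half amplitude around the peak.
#'
#' @param x Filtered EEG trace (uV), e.g. from [preprocess_eeg()].
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param rms Optional precomputed [rolling_rms()] trace; computed when
#'   `NULL`.
#' @param floor_uV Absolute amplitude floor (200 uV).
#' @param refractory_ms Merge window for multi-peaked complexes.
#' @param rms_window_s RMS window (60 s).
#' @return Data.frame `time_s`, `amplitude_uV`, `width_ms`,
#'   `in_rms_warmup` (event within the first RMS window, where the
#'   expanding-window estimate is provisional).
#' @export
detect_spikes_eeg <- function(x, sampling_rate_hz, rms = NULL,
                              floor_uV = 200, refractory_ms = 50,
                              rms_window_s = 60) {
  rate <- sampling_rate_hz
  if (is.null(rms)) rms <- rolling_rms(x, rate, rms_window_s)
  a <- abs(x)
  cand <- which(a > floor_uV & a > rms)
  empty <- data.frame(time_s = numeric(0), amplitude_uV = numeric(0),
                      width_ms = numeric(0), in_rms_warmup = logical(0))
  if (!length(cand)) return(empty)
  # local maxima of |x| restricted to candidate samples
  pk <- local_maxima(a)
  pk <- pk[pk %in% cand]
  # candidates at run boundaries (e.g. single-sample exceedances) fall back
  # to the run maximum
  if (!length(pk)) {
    runs <- split(cand, cumsum(c(1, diff(cand) > 1)))
    pk <- vapply(runs, function(r) r[which.max(a[r])], integer(1))
  }
  pk <- thin_peaks(pk, a[pk], max(1L, round(refractory_ms / 1000 * rate)))
  half_width <- function(p) {
    lev <- a[p] / 2
    l <- p; while (l > 1L && a[l - 1L] >= lev) l <- l - 1L
    r <- p; while (r < length(a) && a[r + 1L] >= lev) r <- r + 1L
    (r - l + 1L) * 1000 / rate
  }
  data.frame(time_s = (pk - 1) / rate, amplitude_uV = a[pk],
             width_ms = vapply(pk, half_width, numeric(1)),
             in_rms_warmup = (pk - 1) / rate < rms_window_s)
}

#' Group spikes into trains by inter-spike interval
#'
#' Greedy left-to-right chaining: consecutive spikes are joined while the
#' ISI stays within `isi_band` (0.05-0.6 s); an out-of-band ISI breaks
#' the chain. A chain qualifies as a train when it has at least
#' `min_spikes` (5) spikes and spans at least `min_duration_s` (3 s).
#'
#' @param spike_times Sorted spike times in seconds (or a
#'   [detect_spikes_eeg()] table).
#' @param isi_band Allowed inter-spike interval range (s).
#' @param min_spikes Minimum spikes per train.
#' @param min_duration_s Minimum train span (last minus first spike).
#' @return Data.frame `onset_s`, `offset_s`, `n_spikes`, `duration_s`,
#'   `mean_isi_s`.
#' @export
detect_trains <- function(spike_times, isi_band = c(0.05, 0.6),
                          min_spikes = 5, min_duration_s = 3) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$time_s
  t <- sort(spike_times)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0),
                      mean_isi_s = numeric(0))
  if (length(t) < 2L) return(empty)
  isi <- diff(t)
  ok <- isi >= isi_band[1] & isi <= isi_band[2]
  # chains = maximal runs of in-band ISIs
  grp <- cumsum(c(1, !ok))
  rows <- lapply(split(seq_along(t), grp), function(idx) {
    if (length(idx) < min_spikes) return(NULL)
    span <- t[idx[length(idx)]] - t[idx[1]]
    if (span < min_duration_s) return(NULL)
    data.frame(onset_s = t[idx[1]], offset_s = t[idx[length(idx)]],
               n_spikes = length(idx), duration_s = span,
               mean_isi_s = span / (length(idx) - 1L))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

overlaps_any <- function(a_on, a_off, b_on, b_off) {
  any(a_on <= b_off & b_on <= a_off)
}

#' Classify detected EEG events using behaviour annotations
#'
#' Rules, each event receiving exactly one label:
#' * a spike train overlapping a `convulsive` or `loss_of_balance`
#'   annotation is a `seizure`;
#' * a train without such overlap is a `run_of_spikes`;
#' * an isolated spike (not inside any train) with width < 200 ms
#'   overlapping a `spasm` annotation is `myoclonic`;
#' * a seizure overlapping a `hindlimb_extension` annotation whose
#'   post-event RMS falls below 25% of the pre-event RMS for at least
#'   `suppression_s` (30 s) is a `fatal_seizure`.
#' Annotation intervals carrying contradictory labels over the same event
#' are flagged in the evidence string rather than silently resolved.
#'
#' @param trains [detect_trains()] table.
#' @param spikes [detect_spikes_eeg()] table.
#' @param annotations Data.frame `onset_s`, `offset_s`, `label` with
#'   labels among convulsive, loss_of_balance, spasm, hindlimb_extension
#'   (may be empty or NULL).
#' @param signal Filtered EEG trace, needed for the post-ictal
#'   suppression test.
#' @param sampling_rate_hz Sampling rate of `signal`.
#' @param myoclonic_max_width_ms Maximum single-spike width (200 ms).
#' @param suppression_ratio Post/pre RMS ratio defining suppression.
#' @param suppression_s Required suppression duration (30 s).
#' @return Data.frame `onset_s`, `offset_s`, `duration_s`, `label`,
#'   `evidence`.
#' @export
classify_events <- function(trains, spikes, annotations = NULL,
                            signal = NULL, sampling_rate_hz = NULL,
                            myoclonic_max_width_ms = 200,
                            suppression_ratio = 0.25, suppression_s = 30) {
  ann <- annotations
  if (is.null(ann))
    ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0))
  ann_over <- function(on, off, labels) {
    sel <- ann$label %in% labels
    overlaps_any(on, off, ann$onset_s[sel], ann$offset_s[sel])
  }
  rows <- list()
  for (i in seq_len(nrow(trains))) {
    on <- trains$onset_s[i]; off <- trains$offset_s[i]
    behav <- ann_over(on, off, c("convulsive", "loss_of_balance"))
    label <- if (behav) "seizure" else "run_of_spikes"
    evidence <- if (behav) "train + convulsive/loss-of-balance overlap"
                else "train without behavioral manifestation"
    if (label == "seizure" && ann_over(on, off, "hindlimb_extension")) {
      if (is.null(signal) || is.null(sampling_rate_hz)) {
        evidence <- paste(evidence,
                          "; hindlimb extension but no signal for suppression test")
      } else if (post_event_suppressed(signal, sampling_rate_hz, off,
                                       pre_on = on, ratio = suppression_ratio,
                                       min_s = suppression_s)) {
        label <- "fatal_seizure"
        evidence <- "seizure + hindlimb extension + post-ictal EEG suppression"
      } else {
        evidence <- paste(evidence, "; hindlimb extension without suppression")
      }
    }
    if (behav && ann_over(on, off, "spasm"))
      evidence <- paste(evidence, "[flag: contradictory spasm annotation]")
    rows[[length(rows) + 1L]] <-
      data.frame(onset_s = on, offset_s = off, duration_s = off - on,
                 label = label, evidence = evidence)
  }
  # isolated spikes: outside every detected train
  if (nrow(spikes)) {
    in_train <- vapply(spikes$time_s, function(tt) {
      nrow(trains) > 0 &&
        any(tt >= trains$onset_s - 1e-9 & tt <= trains$offset_s + 1e-9)
    }, logical(1))
    iso <- spikes[!in_train & spikes$width_ms < myoclonic_max_width_ms, ,
                  drop = FALSE]
    for (j in seq_len(nrow(iso))) {
      tt <- iso$time_s[j]
      if (ann_over(tt, tt, "spasm")) {
        rows[[length(rows) + 1L]] <-
          data.frame(onset_s = tt, offset_s = tt, duration_s = 0,
                     label = "myoclonic",
                     evidence = sprintf("isolated %.0f ms spike + spasm overlap",
                                        iso$width_ms[j]))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), label = character(0),
                      evidence = character(0))
  out[order(out$onset_s), , drop = FALSE]
}

# Post-ictal suppression: RMS over [off, off + min_s] below `ratio` times
# the pre-event baseline RMS (the min_s window before the event onset;
# comparing against the ictal RMS itself would be dominated by the
# seizure's own spikes).
post_event_suppressed <- function(signal, rate, off_s, pre_on,
                                  ratio = 0.25, min_s = 30, gap_s = 1) {
  n <- length(signal)
  # skip gap_s after the last spike so its own tail is not measured
  post_lo <- min(n, round((off_s + gap_s) * rate) + 1L)
  post_hi <- min(n, round((off_s + gap_s + min_s) * rate))
  if (post_hi - post_lo < 0.9 * min_s * rate) return(FALSE)  # record too short
  pre_hi <- max(1L, round(pre_on * rate))
  pre_lo <- max(1L, pre_hi - round(min_s * rate))
  rms <- function(v) sqrt(mean(v^2))
  rms(signal[post_lo:post_hi]) < ratio * rms(signal[pre_lo:pre_hi])
}

#' Raster table of classified events across animals
#'
#' One row per event with the animal id, label, onset and duration, ready
#' for raster plotting or export through [write_event_table()].
#'
#' @param events Named list of [classify_events()] tables (names = animal
#'   ids), or a single table.
#' @return Data.frame `animal_id`, `label`, `onset_s`, `duration_s`,
#'   `amplitude` (NA; kept for the event-CSV schema).
#' @export
export_raster <- function(events) {
  if (is.data.frame(events)) events <- list(animal_1 = events)
  rows <- lapply(seq_along(events), function(i) {
    e <- events[[i]]
    if (!nrow(e))
      return(NULL)
    data.frame(animal_id = names(events)[i] %||% as.character(i),
               label = e$label, onset_s = e$onset_s,
               duration_s = e$duration_s, amplitude = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(animal_id = character(0), label = character(0),
                      onset_s = numeric(0), duration_s = numeric(0),
                      amplitude = numeric(0))
  rownames(out) <- NULL
  out
}
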