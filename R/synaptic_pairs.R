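# Paired-recording analysis: unitary postsynaptic currents per presynaptic
# AP, failure rates, amplitude-by-frequency profiles, paired-pulse ratios,
# synaptic latency, and connection probability with its exact test.

#' Paired recording sweep
#'
#' One presynaptic voltage trace plus the simultaneous postsynaptic
#' current trace, recorded while the presynaptic cell is driven with a
#' pulse train (5/10/20/40/80/120 Hz, 10 pulses in the study design).
#'
#' @param pre_mV Presynaptic membrane potential (mV).
#' @param post_pA Postsynaptic current (pA), same length and rate.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param frequency_hz Train frequency (Hz).
#' @param n_pulses Pulses per train.
#' @param direction Deflection direction of the unitary PSC on the post
#'   trace. With the study's chloride-loaded internal (E_Cl = -17 mV) and
#'   a -70 mV holding potential, uIPSCs are inward (negative), as are
#'   uEPSCs; the detector never assumes a direction.
#' @return Object of class `paired_sweep`.
#' @export
paired_sweep <- function(pre_mV, post_pA, sampling_rate_hz, frequency_hz,
                         n_pulses = 10, direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  if (length(pre_mV) != length(post_pA))
    stopf("pre and post traces must share length")
  structure(list(pre_mV = as.numeric(pre_mV), post_pA = as.numeric(post_pA),
                 sampling_rate_hz = sampling_rate_hz,
                 frequency_hz = frequency_hz, n_pulses = as.integer(n_pulses),
                 direction = direction),
            class = "paired_sweep")
}

#' Measure unitary postsynaptic currents for each presynaptic AP
#'
#' For every presynaptic AP peak, the search window runs from the peak to
#' the next AP or `window_ms` (50 ms), whichever comes first. Amplitude is
#' the absolute deviation of the windowed extremum (in the declared
#' direction) from a local pre-pulse baseline (mean of `baseline_ms`
#' before the AP peak). Events whose amplitude does not exceed
#' `floor_pA` (10 pA) are failures; their amplitude is recorded as 0 for
#' averaging (the raw measurement is kept in `raw_amplitude_pA`). Onset is
#' the first excursion beyond `onset_sd_mult` times the baseline SD
#' sustained for `onset_sustain_ms`.
#'
#' @param x A [paired_sweep()].
#' @param floor_pA Detection floor; amplitude must strictly exceed it.
#' @param window_ms Maximum post-AP search window.
#' @param baseline_ms Local baseline window before each AP peak.
#' @param onset_sd_mult Onset threshold in baseline SDs.
#' @param onset_sustain_ms Time the excursion must stay beyond threshold.
#' @param sweep Sweep identifier copied into the output.
#' @return Data.frame, one row per pulse: `sweep`, `frequency_hz`,
#'   `pulse`, `ap_peak_time_s`, `amplitude_pA` (0 on failure),
#'   `raw_amplitude_pA`, `onset_latency_ms`, `peak_latency_ms`,
#'   `is_failure`.
#' @export
measure_upsc <- function(x, floor_pA = 10, window_ms = 50, baseline_ms = 2,
                         onset_sd_mult = 2, onset_sustain_ms = 0.5,
                         sweep = 1L) {
  stopifnot(inherits(x, "paired_sweep"))
  rate <- x$sampling_rate_hz
  pk <- detect_spikes(x$pre_mV, rate)
  if (!length(pk)) stopf("no presynaptic APs detected")
  sgn <- if (x$direction == "inward") -1 else 1
  post <- x$post_pA * sgn          # work with positive-going deflections
  nb <- max(2L, round(baseline_ms / 1000 * rate))
  nw <- round(window_ms / 1000 * rate)
  nsus <- max(1L, round(onset_sustain_ms / 1000 * rate))
  n <- length(post)
  rows <- lapply(seq_along(pk), function(i) {
    p <- pk[i]
    hi <- min(n, p + nw, if (i < length(pk)) pk[i + 1] - 1L else n)
    lo <- p + 1L
    if (hi <= lo) return(NULL)
    bwin <- post[max(1L, p - nb):p]
    base <- mean(bwin)
    bsd <- stats::sd(bwin)
    w <- post[lo:hi]
    ext_i <- which.max(w)
    raw_amp <- w[ext_i] - base
    fail <- !(raw_amp > floor_pA)
    onset_lat <- NA_real_
    if (!fail && is.finite(bsd) && bsd > 0) {
      over <- w - base > onset_sd_mult * bsd
      run <- which(vapply(seq_len(length(w) - nsus + 1L),
                          function(j) all(over[j:(j + nsus - 1L)]), logical(1)))
      if (length(run)) onset_lat <- run[1] * 1000 / rate
    }
    data.frame(sweep = sweep, frequency_hz = x$frequency_hz, pulse = i,
               ap_peak_time_s = (p - 1) / rate,
               amplitude_pA = if (fail) 0 else raw_amp,
               raw_amplitude_pA = raw_amp,
               onset_latency_ms = onset_lat,
               peak_latency_ms = ext_i * 1000 / rate,
               is_failure = fail)
  })
  do.call(rbind, rows)
}

#' Failure probability per stimulation frequency
#'
#' Fraction of failures among the first `first_n` pulses (the study uses
#' the first five APs), pooled over sweeps.
#'
#' @param events Row-bound [measure_upsc()] tables across sweeps.
#' @param first_n Number of leading pulses considered.
#' @return Data.frame `frequency_hz`, `n_pulses`, `failure_rate`.
#' @export
failure_rate_by_frequency <- function(events, first_n = 5) {
  e <- events[events$pulse <= first_n, ]
  agg <- stats::aggregate(is_failure ~ frequency_hz, data = e,
                          FUN = function(z) c(n = length(z), rate = mean(z)))
  data.frame(frequency_hz = agg$frequency_hz,
             n_pulses = as.integer(agg$is_failure[, "n"]),
             failure_rate = agg$is_failure[, "rate"])
}

#' Mean uPSC amplitude per pulse index and frequency
#'
#' Failures contribute 0 pA by default (magnitude including failures);
#' set `failures_as_zero = FALSE` to average successes only.
#'
#' @inheritParams failure_rate_by_frequency
#' @param failures_as_zero Include failures as 0 pA (default) or drop them.
#' @return Data.frame `frequency_hz`, `pulse`, `mean_amplitude_pA`, `n`.
#' @export
amplitude_profile <- function(events, first_n = 5, failures_as_zero = TRUE) {
  e <- events[events$pulse <= first_n, ]
  if (!failures_as_zero) e <- e[!e$is_failure, ]
  agg <- stats::aggregate(amplitude_pA ~ frequency_hz + pulse, data = e,
                          FUN = function(z) c(m = mean(z), n = length(z)))
  out <- data.frame(frequency_hz = agg$frequency_hz, pulse = agg$pulse,
                    mean_amplitude_pA = agg$amplitude_pA[, "m"],
                    n = as.integer(agg$amplitude_pA[, "n"]))
  out[order(out$frequency_hz, out$pulse), ]
}

#' Paired-pulse ratios per frequency
#'
#' PPR_21 = mean amplitude of pulse 2 / mean amplitude of pulse 1;
#' PPR_last1 uses the last pulse of the train. Ratios of means (not means
#' of per-sweep ratios), so pulse-1 failures do not create undefined
#' terms.
#'
#' @inheritParams failure_rate_by_frequency
#' @return Data.frame `frequency_hz`, `ppr_21`, `ppr_last1`.
#' @export
paired_pulse_ratios <- function(events) {
  prof <- amplitude_profile(events, first_n = max(events$pulse))
  out <- do.call(rbind, lapply(split(prof, prof$frequency_hz), function(d) {
    m1 <- d$mean_amplitude_pA[d$pulse == 1]
    if (!length(m1) || m1 <= 0) stopf("pulse-1 mean amplitude is zero")
    last <- max(d$pulse)
    data.frame(frequency_hz = d$frequency_hz[1],
               ppr_21 = d$mean_amplitude_pA[d$pulse == 2] / m1,
               ppr_last1 = d$mean_amplitude_pA[d$pulse == last] / m1)
  }))
  rownames(out) <- NULL
  out
}

#' Mean synaptic latency (AP peak to uPSC onset)
#'
#' Averages `onset_latency_ms` over non-failure events. Events with
#' non-positive latency (onset apparently before the AP peak, an
#' artifact) are excluded with a warning. The peak latency variant is
#' also reported.
#'
#' @inheritParams failure_rate_by_frequency
#' @return List: `onset_latency_ms`, `peak_latency_ms`, `n_events`.
#' @export
synaptic_latency <- function(events) {
  e <- events[!events$is_failure & !is.na(events$onset_latency_ms), ]
  if (!nrow(e)) stopf("all events are failures; latency undefined")
  bad <- e$onset_latency_ms <= 0
  if (any(bad)) {
    warnf("excluded %d event(s) with onset at/before the AP peak", sum(bad))
    e <- e[!bad, ]
  }
  list(onset_latency_ms = mean(e$onset_latency_ms),
       peak_latency_ms = mean(e$peak_latency_ms),
       n_events = nrow(e))
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Sums the hypergeometric probabilities of all tables (with the observed
#' margins) whose probability does not exceed that of the observed table.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return Two-sided p-value.
#' @export
fisher_exact_test <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  m <- x1 + x2                      # total successes
  support <- max(0L, m - n2):min(n1, m)
  probs <- stats::dhyper(support, m, n1 + n2 - m, n1)
  p_obs <- stats::dhyper(x1, m, n1 + n2 - m, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Connection probability summary with exact test
#'
#' @param n_connected,n_tested Connected and tested pair counts for the
#'   primary group.
#' @param n_connected_ref,n_tested_ref Optional comparison group; when
#'   given, a two-sided Fisher exact p-value is included.
#' @return List: `n_connected`, `n_tested`, `probability`,
#'   `percent` (rounded to 0.1), and `fisher_p` when a comparison group is
#'   supplied.
#' @export
connection_stats <- function(n_connected, n_tested,
                             n_connected_ref = NULL, n_tested_ref = NULL) {
  stopifnot(n_connected >= 0, n_connected <= n_tested)
  out <- list(n_connected = n_connected, n_tested = n_tested,
              probability = n_connected / n_tested,
              percent = round(100 * n_connected / n_tested, 1))
  if (!is.null(n_connected_ref)) {
    out$fisher_p <- fisher_exact_test(n_connected, n_tested,
                                      n_connected_ref, n_tested_ref)
  }
  out
}
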