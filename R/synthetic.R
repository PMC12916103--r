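# Seed-controlled ground-truth generators for every modality. Each
# generator returns both the data (in the package's containers) and the
# generating parameters/event truth, so every detector can be scored
# without re-deriving anything. Identical seed => bit-identical output.

#' Piecewise-linear AP template with grid-exact geometry
#'
#' Builds a spike template rising at `upstroke_mV_ms` from the threshold
#' to the peak and falling linearly back to `reset_mV`, with the falling
#' slope chosen so the half-amplitude duration equals `apd50_ms`. Segment
#' breakpoints are snapped to the sample grid and the realized slopes /
#' APD50 are reported, so extractor accuracy can be judged against exact
#' truth.
#'
#' @param threshold_mV,amplitude_mV,upstroke_mV_ms,apd50_ms Target shape.
#' @param reset_mV Voltage at the end of the falling limb.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @return List: `wave` (mV samples, first sample at threshold), and the
#'   realized `threshold_mV`, `peak_mV`, `amplitude_mV`,
#'   `upstroke_mV_ms`, `downstroke_mV_ms`, `apd50_ms`.
#' @export
make_ap_template <- function(threshold_mV = -40, amplitude_mV = 52,
                             upstroke_mV_ms = 250, apd50_ms = 0.40,
                             reset_mV = -70, sampling_rate_hz = 1e5) {
  dt_ms <- 1000 / sampling_rate_hz
  half <- amplitude_mV / 2
  t_rise <- amplitude_mV / upstroke_mV_ms
  if (apd50_ms <= half / upstroke_mV_ms)
    stopf("apd50_ms too short for the requested upstroke")
  down <- half / (apd50_ms - half / upstroke_mV_ms)
  drop <- amplitude_mV + (threshold_mV - reset_mV)
  if (down <= 0) stopf("inconsistent template: fall slope must be > 0")
  t_fall <- drop / down
  # snap breakpoints to the grid and recompute realized slopes
  n_rise <- max(2L, round(t_rise / dt_ms))
  n_fall <- max(2L, round(t_fall / dt_ms))
  s_real <- amplitude_mV / (n_rise * dt_ms)
  d_real <- drop / (n_fall * dt_ms)
  peak <- threshold_mV + amplitude_mV
  wave <- c(threshold_mV + s_real * dt_ms * (0:n_rise),
            peak - d_real * dt_ms * seq_len(n_fall))
  wave[1] <- threshold_mV
  apd50_real <- half / s_real + half / d_real
  list(wave = wave, threshold_mV = threshold_mV, peak_mV = peak,
       amplitude_mV = amplitude_mV, upstroke_mV_ms = s_real,
       downstroke_mV_ms = -d_real, apd50_ms = apd50_real,
       peak_index = n_rise + 1L)
}

#' Synthetic current-clamp recordings from a leaky integrate-and-fire cell
#'
#' Subthreshold dynamics follow a single-compartment RC membrane
#' (resistance `r_MOhm`, time constant `tau_ms`, rest `v_rest_mV`); when
#' the trajectory reaches `v_thr_mV` an AP template is inserted and the
#' membrane restarts from `reset_mV`. The analytic rheobase is
#' `(v_thr - v_rest)/R` and spike times within steps follow the closed
#' form of the RC charging curve. Returns a step family (F-I protocol), a
#' depolarizing ramp sweep (AP-feature protocol, 100 pA/s) and a gap-free
#' trace.
#'
#' @param seed RNG seed (only used when `noise_sd_mV > 0`).
#' @param sampling_rate_hz Sampling rate (100 kHz by default, matching
#'   AP-waveform acquisition).
#' @param steps_pA Current steps for the F-I protocol.
#' @param step_onset_s,step_duration_s Step timing (1 s steps).
#' @param ramp_slope_pA_s Ramp slope (100 pA/s).
#' @param r_MOhm,tau_ms,v_rest_mV,v_thr_mV Membrane parameters.
#' @param template AP template from [make_ap_template()]; built from the
#'   membrane parameters when NULL.
#' @param noise_sd_mV Additive Gaussian noise (default 0: template
#'   recovery is judged at the geometry level).
#' @return List: `steps`, `ramp`, `gap_free` ([sweep_set()]s) and `truth`
#'   (template truth, analytic `rheobase_pA`, per-step spike counts and
#'   times, ramp first-spike time).
#' @export
gen_current_clamp <- function(seed = 1, sampling_rate_hz = 1e5,
                              steps_pA = seq(-100, 500, by = 50),
                              step_onset_s = 0.1, step_duration_s = 1,
                              ramp_slope_pA_s = 100,
                              r_MOhm = 150, tau_ms = 15,
                              v_rest_mV = -70, v_thr_mV = -40,
                              template = NULL, noise_sd_mV = 0) {
  rate <- sampling_rate_hz
  dt <- 1 / rate
  if (is.null(template))
    template <- make_ap_template(threshold_mV = v_thr_mV,
                                 reset_mV = v_rest_mV,
                                 sampling_rate_hz = rate)
  tw <- template$wave
  ntw <- length(tw)
  dv_thr <- v_thr_mV - v_rest_mV
  tau_s <- tau_ms / 1000

  step_sweep <- function(i_pA) {
    n <- round((step_onset_s + step_duration_s + 0.1) * rate)
    v <- rep(v_rest_mV, n)
    on <- round(step_onset_s * rate) + 1L
    off <- round((step_onset_s + step_duration_s) * rate)
    dv_inf <- i_pA * r_MOhm / 1000
    spike_times <- numeric(0)
    if (dv_inf <= dv_thr) {           # subthreshold: exact RC charging
      t_rel <- (seq(on, off) - on) * dt
      v[on:off] <- v_rest_mV + dv_inf * (1 - exp(-t_rel / tau_s))
      v_end <- v[off]
      t_rel2 <- (seq(off + 1L, n) - off) * dt
      v[(off + 1L):n] <- v_rest_mV + (v_end - v_rest_mV) * exp(-t_rel2 / tau_s)
    } else {                          # periodic firing, closed-form ISI
      t_fire <- tau_s * log(dv_inf / (dv_inf - dv_thr))
      cur <- on
      while (cur <= off) {
        n_sub <- min(off, cur + round(t_fire * rate)) - cur
        if (n_sub > 0) {
          t_rel <- seq_len(n_sub) * dt
          v[cur + seq_len(n_sub) - 1L] <-
            v_rest_mV + dv_inf * (1 - exp(-(t_rel - dt) / tau_s))
        }
        cross <- cur + round(t_fire * rate)
        if (cross > off) break
        hi <- min(n, cross + ntw - 1L)
        v[cross:hi] <- tw[seq_len(hi - cross + 1L)]
        spike_times <- c(spike_times, (cross - 1L + template$peak_index - 1L) * dt)
        cur <- cross + ntw
      }
      if (cur <= n) v[cur:n] <- v_rest_mV
    }
    list(v = v, spike_times = spike_times)
  }

  # steps_pA = NULL skips the (large) step family, e.g. for pure
  # AP-waveform studies
  sims <- if (is.null(steps_pA)) list() else lapply(steps_pA, step_sweep)
  step_sweeps <- lapply(sims, `[[`, "v")
  counts <- vapply(sims, function(s) length(s$spike_times), integer(1))

  # ramp: v(t) = v_rest + cR(t - tau (1 - exp(-t/tau))) until threshold
  cR <- ramp_slope_pA_s * r_MOhm / 1000        # mV/s asymptotic slope
  vsub <- function(t) v_rest_mV + cR * (t - tau_s * (1 - exp(-t / tau_s)))
  t_cross <- stats::uniroot(function(t) vsub(t) - v_thr_mV,
                            c(1e-6, 60))$root
  n_ramp <- round(t_cross * rate) + ntw + round(0.01 * rate)
  tvec <- (seq_len(n_ramp) - 1) * dt
  vr <- vsub(tvec)
  ins <- which(vr >= v_thr_mV)[1]
  vr[ins:(ins + ntw - 1L)] <- tw
  if (ins + ntw <= n_ramp) vr[(ins + ntw):n_ramp] <- v_rest_mV
  ramp_first_peak_s <- (ins - 1L + template$peak_index - 1L) * dt

  gap_free <- rep(v_rest_mV, round(2 * rate))

  add_noise <- function(v) if (noise_sd_mV > 0) v + stats::rnorm(length(v), 0, noise_sd_mV) else v
  with_seed(seed, {
    step_sweeps <- lapply(step_sweeps, add_noise)
    vr <- add_noise(vr)
    gap_free <- add_noise(gap_free)
  })

  list(
    steps = if (is.null(steps_pA)) NULL else
      sweep_set(step_sweeps, rate, units = "mV",
                protocol = step_protocol(steps_pA, step_onset_s,
                                         step_duration_s, units = "pA")),
    ramp = sweep_set(list(vr), rate, units = "mV",
                     protocol = ramp_protocol(ramp_slope_pA_s, 0,
                                              n_ramp / rate)),
    gap_free = gap_free,
    truth = list(template = template[setdiff(names(template), "wave")],
                 rheobase_pA = dv_thr / r_MOhm * 1000,
                 v_rest_mV = v_rest_mV, v_thr_mV = v_thr_mV,
                 r_MOhm = r_MOhm, tau_ms = tau_ms,
                 step_counts = counts,
                 step_spike_times = lapply(sims, `[[`, "spike_times"),
                 ramp_first_peak_s = ramp_first_peak_s))
}

#' Internal/external solutions of the macropatch K+ current protocol
#'
#' Convenience pair for computing the potassium reversal potential of the
#' slice voltage-clamp recordings (K-gluconate internal vs ACSF).
#'
#' @return List of two [solution_composition()] objects, `internal` and
#'   `external`.
#' @export
macropatch_solutions <- function() {
  list(
    internal = solution_composition(
      c(`K-gluconate` = 130, KCl = 6.3, MgCl2 = 1), temperature_C = 32),
    external = solution_composition(
      c(NaCl = 125, KCl = 2.5, NaH2PO4 = 1.25, CaCl2 = 2, MgCl2 = 1,
        NaHCO3 = 25), temperature_C = 32))
}

#' Synthetic voltage-step K+ current family
#'
#' I(V, t) = Gmax / (1 + exp(-(V - Vhalf)/k)) * (V - E_rev) *
#' (1 - exp(-t/tau(V))) during the step, plus Gaussian noise. The
#' activation time constant decreases with depolarization following a
#' sigmoid between `tau_max_ms` and `tau_min_ms`.
#'
#' @param seed RNG seed.
#' @param gmax_nS,vhalf_mV,k_mV Boltzmann activation parameters.
#' @param e_rev_mV K+ reversal potential; defaults to the Nernst value of
#'   [macropatch_solutions()] (about -105 mV at 32 C).
#' @param steps_mV Step potentials.
#' @param sampling_rate_hz,onset_s,duration_ms Protocol timing.
#' @param tau_min_ms,tau_max_ms,tau_vhalf_mV,tau_k_mV Kinetics of
#'   activation tau versus voltage.
#' @param noise_frac Current noise SD as a fraction of the largest ideal
#'   current magnitude (0.05 emulates the recovery-study condition).
#' @param capacitance_pF Reported membrane capacitance.
#' @return List: `family` ([voltage_step_family()]) and `truth`.
#' @export
gen_vclamp_family <- function(seed = 1, gmax_nS = 10, vhalf_mV = -5,
                              k_mV = 8, e_rev_mV = NULL,
                              steps_mV = seq(-80, 40, by = 5),
                              sampling_rate_hz = 2e4, onset_s = 0.01,
                              duration_ms = 100, tau_min_ms = 1,
                              tau_max_ms = 7, tau_vhalf_mV = -20,
                              tau_k_mV = 12, noise_frac = 0.05,
                              capacitance_pF = 5) {
  if (k_mV <= 0) stopf("k_mV must be > 0")
  if (is.null(e_rev_mV)) {
    sol <- macropatch_solutions()
    e_rev_mV <- nernst_potential(sol$internal, sol$external, "K", +1)
  }
  rate <- sampling_rate_hz
  n <- round((onset_s + duration_ms / 1000 + 0.01) * rate)
  on <- round(onset_s * rate) + 1L
  off <- round((onset_s + duration_ms / 1000) * rate)
  tau_of <- function(v) tau_min_ms + (tau_max_ms - tau_min_ms) /
    (1 + exp((v - tau_vhalf_mV) / tau_k_mV))
  ideal <- lapply(steps_mV, function(v) {
    tr <- numeric(n)
    t_ms <- (seq(on, off) - on) * 1000 / rate
    amp <- gmax_nS * boltzmann(v, vhalf_mV, k_mV) * (v - e_rev_mV)  # nS*mV = pA
    tr[on:off] <- amp * (1 - exp(-t_ms / tau_of(v)))
    if (off < n) {
      t2 <- (seq(off + 1L, n) - off) * 1000 / rate
      tr[(off + 1L):n] <- tr[off] * exp(-t2 / (tau_of(v) / 3))
    }
    tr
  })
  sd_pA <- noise_frac * max(abs(unlist(ideal)))
  traces <- with_seed(seed, lapply(ideal, function(tr)
    if (sd_pA > 0) tr + stats::rnorm(length(tr), 0, sd_pA) else tr))
  list(family = voltage_step_family(traces, steps_mV, rate, onset_s,
                                    duration_ms, holding_mV = min(steps_mV),
                                    capacitance_pF = capacitance_pF),
       truth = list(gmax_nS = gmax_nS, vhalf_mV = vhalf_mV, k_mV = k_mV,
                    e_rev_mV = e_rev_mV, noise_sd_pA = sd_pA,
                    tau_ms = stats::setNames(tau_of(steps_mV), steps_mV)))
}

#' Synthetic paired recording with stochastic release
#'
#' The presynaptic trace carries AP templates at the commanded pulse
#' times; the postsynaptic current is a sum over pulses of
#' Bernoulli(1 - p_fail) successes with geometrically depressing
#' amplitude A1 * r^(i-1), a difference-of-exponentials PSC kernel, and
#' a Gaussian-jittered synaptic latency, plus current noise.
#'
#' @param seed RNG seed.
#' @param n_sweeps Sweeps to generate.
#' @param frequency_hz,n_pulses Train protocol.
#' @param a1_pA First-pulse amplitude.
#' @param depression_ratio Per-pulse amplitude ratio r (> 1 facilitates).
#' @param p_fail Per-pulse failure probability.
#' @param latency_mean_ms,latency_sd_ms Synaptic latency distribution
#'   (AP peak to PSC onset).
#' @param rise_ms,decay_ms PSC kernel time constants.
#' @param noise_sd_pA Postsynaptic current noise.
#' @param sampling_rate_hz Sampling rate.
#' @param direction PSC deflection direction (inward by default).
#' @return List: `sweeps` (list of [paired_sweep()]) and `truth`
#'   (per-sweep/pulse amplitude, failure, latency).
#' @export
gen_paired_recording <- function(seed = 1, n_sweeps = 10, frequency_hz = 40,
                                 n_pulses = 10, a1_pA = 50,
                                 depression_ratio = 0.7, p_fail = 0.3,
                                 latency_mean_ms = 1.2, latency_sd_ms = 0.1,
                                 rise_ms = 0.5, decay_ms = 8,
                                 noise_sd_pA = 2, sampling_rate_hz = 2e4,
                                 direction = "inward") {
  if (depression_ratio <= 0) stopf("depression_ratio must be > 0")
  rate <- sampling_rate_hz
  dt_ms <- 1000 / rate
  tmpl <- make_ap_template(sampling_rate_hz = rate)
  onset_s <- 0.05
  dur_s <- onset_s + n_pulses / frequency_hz + 0.1
  n <- round(dur_s * rate)
  pulse_idx <- round((onset_s + (seq_len(n_pulses) - 1) / frequency_hz) * rate) + 1L
  ap_peak_idx <- pulse_idx + tmpl$peak_index - 1L
  # PSC kernel, peak-normalized
  tk <- seq(0, 10 * decay_ms, by = dt_ms)
  kern <- exp(-tk / decay_ms) - exp(-tk / rise_ms)
  kern <- kern / max(kern)
  sgn <- if (direction == "inward") -1 else 1
  amps_det <- a1_pA * depression_ratio^(seq_len(n_pulses) - 1)
  with_seed(seed, {
    sweeps <- vector("list", n_sweeps)
    truth_rows <- vector("list", n_sweeps)
    for (s in seq_len(n_sweeps)) {
      pre <- rep(-70, n)
      for (p in pulse_idx) {
        hi <- min(n, p + length(tmpl$wave) - 1L)
        pre[p:hi] <- tmpl$wave[seq_len(hi - p + 1L)]
      }
      post <- numeric(n)
      fail <- stats::runif(n_pulses) < p_fail
      lat <- stats::rnorm(n_pulses, latency_mean_ms, latency_sd_ms)
      for (i in seq_len(n_pulses)) {
        if (fail[i]) next
        start <- ap_peak_idx[i] + round(lat[i] / dt_ms)
        hi <- min(n, start + length(kern) - 1L)
        post[start:hi] <- post[start:hi] + sgn * amps_det[i] * kern[seq_len(hi - start + 1L)]
      }
      if (noise_sd_pA > 0) post <- post + stats::rnorm(n, 0, noise_sd_pA)
      sweeps[[s]] <- paired_sweep(pre, post, rate, frequency_hz, n_pulses,
                                  direction = direction)
      truth_rows[[s]] <- data.frame(sweep = s, pulse = seq_len(n_pulses),
                                    amplitude_pA = ifelse(fail, 0, amps_det),
                                    latency_ms = ifelse(fail, NA, lat),
                                    is_failure = fail)
    }
    list(sweeps = sweeps,
         truth = list(events = do.call(rbind, truth_rows), a1_pA = a1_pA,
                      depression_ratio = depression_ratio, p_fail = p_fail,
                      latency_mean_ms = latency_mean_ms,
                      ap_peak_times_s = (ap_peak_idx - 1) / rate))
  })
}

#' Synthetic ROI calcium recording
#'
#' Per-cell Poisson transient events (state-dependent rate: quiet rest
#' versus locomotion) convolved with an instantaneous-rise /
#' exponential-decay kernel, on a per-cell baseline with slow sinusoidal
#' drift and Gaussian noise; optional global hypersynchronous discharges
#' added to every cell. Defaults emulate quiet GCaMP8m imaging at 30 Hz:
#' transient amplitude ~0.5 dF/F against 0.02 dF/F frame noise.
#'
#' @param seed RNG seed.
#' @param n_cells,duration_s,frame_rate_hz Recording geometry.
#' @param rate_rest_per_min,rate_loco_per_min Transient rates by
#'   locomotor state.
#' @param amplitude_dff Mean transient peak amplitude (dF/F0 units).
#' @param amplitude_cv Lognormal coefficient of variation of amplitudes.
#' @param decay_s Transient decay time constant.
#' @param noise_sd_dff Per-frame noise SD in dF/F0 units.
#' @param drift_amp_dff Amplitude of the slow baseline drift.
#' @param baseline_F Mean raw-fluorescence baseline (a.u.).
#' @param discharge_times_s Times of global discharges (NULL for none).
#' @param discharge_amp_dff,discharge_decay_s Discharge kernel.
#' @param rest_block_s,loco_block_s Alternating locomotor schedule.
#' @return List: `roi` ([roi_fluorescence()]), `speed` (cm/s per frame),
#'   and `truth` (per-cell event times, discharge times, parameters).
#' @export
gen_calcium <- function(seed = 1, n_cells = 100, duration_s = 600,
                        frame_rate_hz = 30, rate_rest_per_min = 1.2,
                        rate_loco_per_min = 3, amplitude_dff = 0.5,
                        amplitude_cv = 0.2, decay_s = 0.7,
                        noise_sd_dff = 0.02, drift_amp_dff = 0.05,
                        baseline_F = 100, discharge_times_s = NULL,
                        discharge_amp_dff = 1.0, discharge_decay_s = 0.3,
                        rest_block_s = 60, loco_block_s = 30) {
  if (rate_rest_per_min < 0 || rate_loco_per_min < 0)
    stopf("transient rates must be >= 0")
  nf <- round(duration_s * frame_rate_hz)
  tt <- (seq_len(nf) - 1) / frame_rate_hz
  # locomotor schedule: rest block, then locomotion block, repeating
  cyc <- tt %% (rest_block_s + loco_block_s)
  running <- cyc >= rest_block_s
  kern_len <- round(5 * decay_s * frame_rate_hz)
  kern <- exp(-(seq_len(kern_len) - 1) / (decay_s * frame_rate_hz))
  dis_kern <- exp(-(seq_len(round(5 * discharge_decay_s * frame_rate_hz)) - 1) /
                    (discharge_decay_s * frame_rate_hz))
  rate_frame <- ifelse(running, rate_loco_per_min, rate_rest_per_min) /
    60 / frame_rate_hz
  with_seed(seed, {
    speed <- ifelse(running, stats::rnorm(nf, 5, 0.5),
                    abs(stats::rnorm(nf, 0, 0.05)))
    dis_tr <- numeric(nf)
    if (!is.null(discharge_times_s)) {
      for (d in discharge_times_s) {
        i0 <- round(d * frame_rate_hz) + 1L
        hi <- min(nf, i0 + length(dis_kern) - 1L)
        dis_tr[i0:hi] <- dis_tr[i0:hi] + discharge_amp_dff * dis_kern[seq_len(hi - i0 + 1L)]
      }
    }
    sdlog <- sqrt(log(1 + amplitude_cv^2))
    F <- matrix(0, n_cells, nf)
    events <- vector("list", n_cells)
    for (c_ in seq_len(n_cells)) {
      ev <- which(stats::runif(nf) < rate_frame)
      sig <- numeric(nf)
      if (length(ev)) {
        amps <- stats::rlnorm(length(ev), log(amplitude_dff) - sdlog^2 / 2, sdlog)
        for (j in seq_along(ev)) {
          hi <- min(nf, ev[j] + kern_len - 1L)
          sig[ev[j]:hi] <- sig[ev[j]:hi] + amps[j] * kern[seq_len(hi - ev[j] + 1L)]
        }
      }
      drift <- drift_amp_dff * sin(2 * pi * tt / 300 + stats::runif(1, 0, 2 * pi))
      f0 <- baseline_F * stats::rlnorm(1, 0, 0.2)
      F[c_, ] <- f0 * (1 + drift + sig + dis_tr +
                         stats::rnorm(nf, 0, noise_sd_dff))
      events[[c_]] <- (ev - 1) / frame_rate_hz
    }
    roi <- roi_fluorescence(F, frame_rate_hz)
    list(roi = roi, speed = speed,
         truth = list(event_times_s = events,
                      discharge_times_s = discharge_times_s %||% numeric(0),
                      running = running, amplitude_dff = amplitude_dff,
                      noise_sd_dff = noise_sd_dff, decay_s = decay_s))
  })
}

#' Synthetic EEG record with embedded epileptiform events
#'
#' Background is 1/f^alpha colored noise; epileptiform spikes are
#' biphasic (one sine cycle) templates. Spike trains, isolated myoclonic
#' spikes and an optional fatal-seizure scenario (train followed by
#' EEG amplitude collapse) are inserted at known times, and a matching
#' behaviour annotation track is produced.
#'
#' @param seed RNG seed.
#' @param duration_s,sampling_rate_hz Record geometry (500 Hz).
#' @param noise_sd_uV Background SD.
#' @param alpha Spectral exponent of the background (1 = pink).
#' @param spike_amp_uV,spike_width_ms Spike template (biphasic, one
#'   cycle).
#' @param train_times_s Onset times of inserted spike trains.
#' @param train_n,train_isi_s Spikes per train and their spacing (defaults span 3.6 s, satisfying the 3 s train rule).
#' @param train_labels Intended label per train: "seizure" trains get a
#'   convulsive annotation, "run_of_spikes" trains none.
#' @param myoclonic_times_s Times of isolated spikes with spasm
#'   annotations.
#' @param fatal Insert a terminal seizure: the last train also gets a
#'   hindlimb-extension annotation and the signal collapses to 5% of its
#'   amplitude afterwards.
#' @return List: `record` ([eeg_record()] with annotations) and `truth`
#'   (all inserted spike times, train spans, intended labels).
#' @export
gen_eeg <- function(seed = 1, duration_s = 3600, sampling_rate_hz = 500,
                    noise_sd_uV = 30, alpha = 1, spike_amp_uV = 400,
                    spike_width_ms = 80, train_times_s = NULL,
                    train_n = 10, train_isi_s = 0.4,
                    train_labels = NULL, myoclonic_times_s = NULL,
                    fatal = FALSE) {
  if (spike_amp_uV <= 0) stopf("spike_amp_uV must be > 0")
  rate <- sampling_rate_hz
  n <- round(duration_s * rate)
  with_seed(seed, {
    # 1/f^alpha background via spectral shaping of white noise
    wh <- stats::rnorm(n)
    sp <- stats::fft(wh)
    fr <- c(1, seq_len(n - 1))
    fr <- pmin(fr, n - fr + 1)                     # two-sided frequencies
    shape <- fr^(-alpha / 2)
    shape[1] <- 0                                  # no DC
    bg <- Re(stats::fft(sp * shape, inverse = TRUE)) / n
    bg <- bg / stats::sd(bg) * noise_sd_uV
    sig <- bg
    tmpl_n <- round(spike_width_ms / 1000 * rate)
    # asymmetric biphasic spike-and-wave: a sharp Hann spike over the
    # first third, then a smaller opposite slow wave; smooth edges avoid
    # ringing through the powerline notch filter
    n1 <- max(3L, round(tmpl_n / 3)); n2 <- tmpl_n - n1
    hann <- function(m) 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = m)))
    tmpl <- spike_amp_uV * c(hann(n1), -0.45 * hann(n2))
    pk_off <- which.max(abs(tmpl)) - 1L
    insert_spike <- function(t0) {
      i0 <- round(t0 * rate) + 1L
      hi <- min(n, i0 + tmpl_n - 1L)
      if (i0 >= 1 && i0 <= n)
        sig[i0:hi] <<- sig[i0:hi] + tmpl[seq_len(hi - i0 + 1L)]
      (i0 - 1L + pk_off) / rate                    # largest-lobe peak time
    }
    spike_truth <- numeric(0)
    train_spans <- NULL
    if (!is.null(train_times_s)) {
      if (is.null(train_labels))
        train_labels <- rep("seizure", length(train_times_s))
      for (k in seq_along(train_times_s)) {
        times <- train_times_s[k] + (seq_len(train_n) - 1) * train_isi_s
        pk <- vapply(times, insert_spike, numeric(1))
        spike_truth <- c(spike_truth, pk)
        train_spans <- rbind(train_spans,
                             data.frame(onset_s = pk[1],
                                        offset_s = pk[length(pk)],
                                        label = train_labels[k]))
      }
    }
    myo_truth <- numeric(0)
    for (t0 in myoclonic_times_s) {
      myo_truth <- c(myo_truth, insert_spike(t0))
      spike_truth <- c(spike_truth, myo_truth[length(myo_truth)])
    }
    ann <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0))
    if (!is.null(train_spans)) {
      sz <- train_spans[train_spans$label == "seizure", , drop = FALSE]
      if (nrow(sz))
        ann <- rbind(ann, data.frame(onset_s = sz$onset_s - 0.5,
                                     offset_s = sz$offset_s + 0.5,
                                     label = "convulsive"))
    }
    for (t0 in myo_truth)
      ann <- rbind(ann, data.frame(onset_s = t0 - 0.5, offset_s = t0 + 0.5,
                                   label = "spasm"))
    if (fatal) {
      if (is.null(train_spans)) stopf("fatal scenario needs at least one train")
      last <- train_spans[nrow(train_spans), ]
      ann <- rbind(ann, data.frame(onset_s = last$offset_s - 1,
                                   offset_s = last$offset_s + 1,
                                   label = "hindlimb_extension"))
      cut <- round((last$offset_s + 0.5) * rate)
      if (cut < n) sig[cut:n] <- sig[cut:n] * 0.05
      train_spans$label[nrow(train_spans)] <- "fatal_seizure"
    }
    rec <- eeg_record(sig, rate, annotations = if (nrow(ann)) ann else NULL)
    list(record = rec,
         truth = list(spike_times_s = sort(spike_truth),
                      train_spans = train_spans,
                      myoclonic_times_s = myo_truth,
                      noise_sd_uV = noise_sd_uV))
  })
}
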