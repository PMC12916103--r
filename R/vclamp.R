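# Voltage-clamp analysis of K+ current families: current density,
# conductance-voltage curves, Boltzmann fits, activation kinetics, and
# solution-based Nernst reversal potentials.

#' Voltage-step current family
#'
#' Container for a family of current traces recorded under square voltage
#' steps (nucleated macropatch: -80 to +40 mV in 5 mV increments from
#' -80 mV holding; heterologous cells: -85 to +55 mV from -120 mV).
#'
#' @param traces List of current traces (pA), one per step, aligned and
#'   equal length.
#' @param steps_mV Strictly increasing step potentials.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param onset_s Step onset (s from trace start); a pre-step baseline of
#'   at least `baseline_ms` must precede it for baseline subtraction.
#' @param duration_ms Step duration (ms), 100 in the study protocols.
#' @param holding_mV Holding potential (mV).
#' @param capacitance_pF Optional membrane capacitance for current density.
#' @return Object of class `voltage_step_family`.
#' @export
voltage_step_family <- function(traces, steps_mV, sampling_rate_hz,
                                onset_s = 0.01, duration_ms = 100,
                                holding_mV = -80, capacitance_pF = NULL) {
  if (length(traces) != length(steps_mV))
    stopf("one trace per step required")
  if (is.unsorted(steps_mV, strictly = TRUE))
    stopf("steps_mV must be strictly increasing")
  n <- unique(lengths(traces))
  if (length(n) != 1L) stopf("ragged trace lengths")
  rate <- sampling_rate_hz
  if (round((onset_s + duration_ms / 1000) * rate) > n)
    stopf("step interval outside trace")
  structure(list(traces = lapply(traces, as.numeric),
                 steps_mV = as.numeric(steps_mV),
                 sampling_rate_hz = rate, onset_s = onset_s,
                 duration_ms = duration_ms, holding_mV = holding_mV,
                 capacitance_pF = capacitance_pF),
            class = "voltage_step_family")
}

#' @export
print.voltage_step_family <- function(x, ...) {
  cat(sprintf("<voltage_step_family> %d steps (%g..%g mV) @ %g Hz, %g ms\n",
              length(x$steps_mV), min(x$steps_mV), max(x$steps_mV),
              x$sampling_rate_hz, x$duration_ms))
  invisible(x)
}

family_windows <- function(x) {
  rate <- x$sampling_rate_hz
  on <- round(x$onset_s * rate) + 1L
  off <- round((x$onset_s + x$duration_ms / 1000) * rate)
  list(on = on, off = off, rate = rate)
}

baseline_subtract <- function(x, baseline_ms = 5) {
  w <- family_windows(x)
  nb <- max(1L, round(baseline_ms / 1000 * w$rate))
  lo <- max(1L, w$on - nb)
  lapply(x$traces, function(tr) tr - mean(tr[lo:(w$on - 1L)]))
}

#' Peak and steady-state current per step
#'
#' Traces are baseline-subtracted (mean of the 5 ms pre-step window).
#' Peak is the extremum of largest magnitude over the step interval;
#' steady-state is the mean over the last 10% of the step. For the
#' non-inactivating Kv3-like currents analysed here, both are nearly
#' equal at 100 ms.
#'
#' @param x A [voltage_step_family()].
#' @param baseline_ms Pre-step baseline window for subtraction.
#' @return Named numeric vector of currents (pA), one per step.
#' @export
peak_current <- function(x, baseline_ms = 5) {
  w <- family_windows(x)
  tr <- baseline_subtract(x, baseline_ms)
  out <- vapply(tr, function(v) {
    seg <- v[w$on:w$off]
    seg[which.max(abs(seg))]
  }, numeric(1))
  stats::setNames(out, x$steps_mV)
}

#' @rdname peak_current
#' @export
steady_state_current <- function(x, baseline_ms = 5) {
  w <- family_windows(x)
  tr <- baseline_subtract(x, baseline_ms)
  lo <- w$off - max(1L, round(0.1 * (w$off - w$on + 1L))) + 1L
  out <- vapply(tr, function(v) mean(v[lo:w$off]), numeric(1))
  stats::setNames(out, x$steps_mV)
}

#' Current density (pA/pF)
#'
#' @param peaks_pA Currents per step (pA), e.g. from [peak_current()].
#' @param capacitance_pF Membrane capacitance (> 0).
#' @return Current densities in pA/pF.
#' @export
current_density <- function(peaks_pA, capacitance_pF) {
  if (is.null(capacitance_pF) || !is.finite(capacitance_pF))
    stopf("capacitance missing: supply capacitance_pF or work in raw pA")
  if (capacitance_pF <= 0) stopf("capacitance_pF must be > 0")
  peaks_pA / capacitance_pF
}

#' Normalized conductance-voltage curve
#'
#' G(V) = I / (V - E_rev), normalized to its maximum. Steps within 1 mV of
#' the reversal potential are dropped (undefined driving force); small
#' negative values from leak noise are clamped to zero.
#'
#' @param peaks_pA Currents per step (pA).
#' @param steps_mV Step potentials (mV).
#' @param e_rev_mV Reversal potential of the conducting ion (mV); compute
#'   from solutions with [nernst_potential()] or override.
#' @return Data.frame `step_mV`, `g_nS`, `g_norm`.
#' @export
conductance_curve <- function(peaks_pA, steps_mV, e_rev_mV) {
  keep <- abs(steps_mV - e_rev_mV) >= 1
  if (!any(keep)) stopf("all steps within 1 mV of the reversal potential")
  if (any(!keep))
    warnf("dropped %d step(s) within 1 mV of E_rev", sum(!keep))
  v <- steps_mV[keep]
  g <- peaks_pA[keep] / (v - e_rev_mV)   # pA/mV = nS
  g <- pmax(g, 0)
  gmax <- max(g)
  if (gmax <= 0) stopf("no positive conductance in the family")
  data.frame(step_mV = v, g_nS = as.numeric(g), g_norm = as.numeric(g / gmax))
}

#' Boltzmann activation function
#'
#' G/Gmax = 1 / (1 + exp(-(V - Vhalf)/k)).
#'
#' @param v Voltage (mV).
#' @param vhalf Half-activation voltage (mV).
#' @param k Slope factor (mV, > 0).
#' @export
boltzmann <- function(v, vhalf, k) 1 / (1 + exp(-(v - vhalf) / k))

#' Fit a Boltzmann function to a normalized G-V curve
#'
#' Least-squares fit of `g ~ gmax / (1 + exp(-(V - Vhalf)/k))`.
#' Initialization: Vhalf from linear interpolation of the half-maximum
#' crossing, k = 8 mV; k is bounded to [0.5, 50] mV. A quality flag is
#' raised when the residual RMS exceeds 0.05 (on the normalized scale).
#'
#' @param g_norm Normalized conductances (unitless, max ~ 1).
#' @param steps_mV Matching step potentials (mV).
#' @param fit_gmax Also fit the saturating amplitude (default TRUE; with
#'   FALSE the amplitude is fixed at 1).
#' @return Object of class `boltzmann_fit`: list with `vhalf_mV`, `k_mV`,
#'   `gmax`, `residual_rms`, `quality_ok`, and the `fit` object.
#' @export
fit_boltzmann <- function(g_norm, steps_mV, fit_gmax = TRUE) {
  stopifnot(length(g_norm) == length(steps_mV))
  ord <- order(steps_mV)
  v <- steps_mV[ord]; g <- g_norm[ord]
  if (length(v) < 5) stopf("need >= 5 points spanning the activation rise")
  # initializer: voltage at half-max by interpolation
  half <- max(g) / 2
  ix <- which(g >= half)[1]
  v0 <- if (is.na(ix) || ix == 1L) stats::median(v)
        else v[ix - 1] + (half - g[ix - 1]) / (g[ix] - g[ix - 1]) * (v[ix] - v[ix - 1])
  dat <- data.frame(v = v, g = g)
  fit <- tryCatch({
    if (fit_gmax)
      minpack.lm::nlsLM(g ~ gmax / (1 + exp(-(v - vhalf) / k)), data = dat,
                        start = list(gmax = max(g), vhalf = v0, k = 8),
                        lower = c(gmax = 1e-6, vhalf = -200, k = 0.5),
                        upper = c(gmax = 10, vhalf = 200, k = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(g ~ 1 / (1 + exp(-(v - vhalf) / k)), data = dat,
                        start = list(vhalf = v0, k = 8),
                        lower = c(vhalf = -200, k = 0.5),
                        upper = c(vhalf = 200, k = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e)
    stopf("Boltzmann fit failed (initializer vhalf = %.1f mV, k = 8): %s",
          v0, conditionMessage(e)))
  cf <- stats::coef(fit)
  rms <- sqrt(mean(stats::residuals(fit)^2))
  structure(list(vhalf_mV = unname(cf["vhalf"]), k_mV = unname(cf["k"]),
                 gmax = if (fit_gmax) unname(cf["gmax"]) else 1,
                 residual_rms = rms, quality_ok = rms <= 0.05, fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> Vhalf = %.2f mV, k = %.2f mV, Gmax = %.3f, RMS = %.4f%s\n",
              x$vhalf_mV, x$k_mV, x$gmax, x$residual_rms,
              if (x$quality_ok) "" else " [poor fit]"))
  invisible(x)
}

#' Activation time constant from a single step trace
#'
#' Least-squares fit of I(t) = A (1 - exp(-t/tau)) from 0.5 ms after the
#' step onset (skipping the clamp artifact) to the time of the current
#' peak. Errors on non-activating (decaying) traces.
#'
#' @param trace Current trace (pA), baseline-subtracted or raw.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param onset_s Step onset (s).
#' @param duration_ms Step duration (ms).
#' @param skip_ms Initial portion of the step excluded from the fit.
#' @return Fitted `tau_ms` (numeric scalar > 0).
#' @export
fit_activation_tau <- function(trace, sampling_rate_hz, onset_s = 0.01,
                               duration_ms = 100, skip_ms = 0.5) {
  rate <- sampling_rate_hz
  on <- round(onset_s * rate) + 1L
  off <- min(length(trace), round((onset_s + duration_ms / 1000) * rate))
  seg <- trace[on:off]
  pk <- which.max(abs(seg))
  if (abs(seg[pk]) <= 0) stopf("non-activating trace")
  sgn <- sign(seg[pk])
  seg <- seg * sgn
  start_i <- max(2L, round(skip_ms / 1000 * rate) + 1L)
  # a decaying current peaks at (or immediately after) the step onset
  if (pk <= start_i + 3L) stopf("non-activating trace: peak precedes fit window")
  t_ms <- (seq_along(seg) - 1) * 1000 / rate
  dat <- data.frame(t = t_ms[start_i:pk], y = seg[start_i:pk])
  a0 <- max(dat$y)
  tau0 <- {
    i63 <- which(dat$y >= 0.632 * a0)[1]
    if (is.na(i63)) duration_ms / 4 else max(dat$t[i63], 1e-3)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * (1 - exp(-t / tau)), data = dat,
                      start = list(A = a0, tau = tau0),
                      lower = c(A = 1e-9, tau = 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stopf("activation fit failed: %s", conditionMessage(e)))
  unname(stats::coef(fit)["tau"])
}

#' Activation tau across a step family
#'
#' @param x A [voltage_step_family()].
#' @param min_step_mV Steps below this command potential are skipped
#'   (little activation; fits are unstable).
#' @return Data.frame `step_mV`, `tau_ms` (NA where the fit fails).
#' @export
activation_tau_curve <- function(x, min_step_mV = -20) {
  tr <- baseline_subtract(x)
  keep <- x$steps_mV >= min_step_mV
  tau <- rep(NA_real_, length(x$steps_mV))
  for (i in which(keep)) {
    tau[i] <- tryCatch(
      fit_activation_tau(tr[[i]], x$sampling_rate_hz, x$onset_s, x$duration_ms),
      error = function(e) NA_real_)
  }
  data.frame(step_mV = x$steps_mV, tau_ms = tau)[keep, ]
}

# --- solutions and Nernst potentials ---------------------------------------

# Stoichiometric chloride/potassium/sodium/etc. contributions of the salts
# appearing in the study's solution recipes. Values are ions per formula
# unit after full dissociation.
salt_table <- list(
  NaCl = c(Na = 1, Cl = 1),
  KCl = c(K = 1, Cl = 1),
  CaCl2 = c(Ca = 1, Cl = 2),
  MgCl2 = c(Mg = 1, Cl = 2),
  `K-gluconate` = c(K = 1, gluconate = 1),
  KOH = c(K = 1, OH = 1),
  NaOH = c(Na = 1, OH = 1),
  NaH2PO4 = c(Na = 1, H2PO4 = 1),
  NaHCO3 = c(Na = 1, HCO3 = 1),
  `Na2-ATP` = c(Na = 2, ATP = 1),
  HEPES = c(HEPES = 1),
  EGTA = c(EGTA = 1),
  glucose = c(glucose = 1)
)

#' Solution composition from salt recipe
#'
#' Assembles total free-ion concentrations from a named vector of salt
#' concentrations (mM), accounting for stoichiometry under full
#' dissociation (e.g. 2 mM MgCl2 contributes 4 mM Cl-). Ions may also be
#' given directly via `ions`.
#'
#' @param salts Named numeric vector of salt concentrations in mM; names
#'   must appear in the built-in salt table.
#' @param ions Named numeric vector of additional free-ion concentrations
#'   in mM, added to the salt-derived totals.
#' @param temperature_C Solution/recording temperature in Celsius.
#' @return Object of class `solution_composition`: list with `ions`
#'   (named mM vector) and `temperature_C`.
#' @examples
#' # the study's whole-cell internal: 65 mM KCl + 2 mM MgCl2 -> 69 mM Cl-
#' sol <- solution_composition(c(KCl = 65, `K-gluconate` = 65, MgCl2 = 2),
#'                             temperature_C = 32)
#' sol$ions[["Cl"]]
#' @export
solution_composition <- function(salts = NULL, ions = NULL,
                                 temperature_C = 32) {
  if (any(c(salts, ions) < 0)) stopf("concentrations must be >= 0")
  tot <- c()
  for (nm in names(salts)) {
    st <- salt_table[[nm]]
    if (is.null(st)) stopf("unknown salt '%s'", nm)
    for (ion in names(st)) {
      tot[ion] <- (if (ion %in% names(tot)) tot[[ion]] else 0) +
        st[[ion]] * salts[[nm]]
    }
  }
  for (ion in names(ions))
    tot[ion] <- (if (ion %in% names(tot)) tot[[ion]] else 0) + ions[[ion]]
  structure(list(ions = tot, temperature_C = temperature_C),
            class = "solution_composition")
}

#' Nernst reversal potential
#'
#' E = (RT / zF) ln([ion]_out / [ion]_in), in mV at the external
#' solution's temperature. With the study's whole-cell internal
#' (69 mM Cl-) against ACSF (133.5 mM Cl-) at 32 C this gives
#' E_Cl = -17 mV to the nearest integer.
#'
#' @param internal,external [solution_composition()] objects (or named mM
#'   ion vectors).
#' @param ion Ion name, e.g. `"Cl"` or `"K"`.
#' @param z Ion valence (e.g. -1 for chloride, +1 for potassium).
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(internal, external, ion, z) {
  get_conc <- function(s) {
    v <- if (inherits(s, "solution_composition")) s$ions else s
    if (!ion %in% names(v) || v[[ion]] <= 0)
      stopf("ion '%s' absent or zero on one side", ion)
    v[[ion]]
  }
  cin <- get_conc(internal)
  cout <- get_conc(external)
  tC <- if (inherits(external, "solution_composition")) external$temperature_C else 32
  R <- 8.314462618; F_ <- 96485.33212
  TK <- tC + 273.15
  1000 * R * TK / (z * F_) * log(cout / cin)
}
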