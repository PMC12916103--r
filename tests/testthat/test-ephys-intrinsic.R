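rate100k <- 1e5

test_that("spike detection honours the -10 mV peak floor", {
  flat <- rep(-70, 1000)
  expect_length(detect_spikes(flat, rate100k), 0)

  tmpl <- make_ap_template(sampling_rate_hz = rate100k)
  v <- rep(-70, 5000)
  at <- c(500, 1500, 2500, 3500, 4300)
  for (i in at) v[i:(i + length(tmpl$wave) - 1)] <- tmpl$wave
  expect_length(detect_spikes(v, rate100k), 5)

  # same shape scaled to peak -15 mV: below the floor
  low <- rep(-70, 2000)
  scaled <- -70 + (tmpl$wave + 70) * (55 / 82)   # peak -70 + 55 = -15
  low[500:(499 + length(scaled))] <- scaled
  expect_length(detect_spikes(low, rate100k), 0)

  # DC offset that keeps peaks above the floor changes nothing
  expect_equal(detect_spikes(v + 3, rate100k), detect_spikes(v, rate100k))
})

test_that("dV/dt is a calibrated central difference", {
  # 1 mV per ms ramp
  ramp <- seq(0, 10, by = 1e-2)           # 100 kHz, 1 mV/ms
  d <- compute_dvdt(ramp, rate100k)
  expect_equal(d, rep(1, length(ramp)), tolerance = 1e-9)
  expect_equal(compute_dvdt(rep(5, 100), rate100k), rep(0, 100))
  # sine: max derivative 2*pi*f*A
  f <- 100; A <- 30
  t <- seq(0, 0.05, by = 1 / rate100k)
  s <- A * sin(2 * pi * f * t)
  expect_equal(max(compute_dvdt(s, rate100k)), 2 * pi * f * A / 1000,
               tolerance = 5e-3)
  expect_error(compute_dvdt(c(1, 2), rate100k), "too short")
})

test_that("threshold follows the 5%-of-upstroke rule", {
  dvdt <- c(0, 1, 2, 6, 100, 400)
  vm <- c(-70, -69, -67, -55, -40, -10)
  th <- ap_threshold(vm, dvdt)
  expect_equal(th$threshold_mV, -40)   # first dvdt > 20 (5% of 400)
  # independent linear-scan oracle
  expect_equal(th$index, min(which(dvdt > 0.05 * max(dvdt))))
  # threshold can never exceed Vm at the max-dvdt sample
  expect_lte(th$threshold_mV, vm[which.max(dvdt)])
  expect_error(ap_threshold(c(-70, -70), c(0, 0)), "no threshold")
})

test_that("AP features recover template geometry", {
  # symmetric triangle: rise 100 mV/ms, fall -100 mV/ms, amplitude 50
  # => APD50 = 25/100 + 25/100 = 0.5 ms (dense-grid crossing oracle below)
  tmpl <- make_ap_template(threshold_mV = -40, amplitude_mV = 50,
                           upstroke_mV_ms = 100, apd50_ms = 0.5,
                           reset_mV = -90, sampling_rate_hz = rate100k)
  expect_equal(tmpl$downstroke_mV_ms, -100, tolerance = 1e-6)
  # shallow sub-threshold approach (1 mV/ms, well under 5% of upstroke)
  v <- c(rep(-45, 200), seq(-45, -40, length.out = 501)[-501], tmpl$wave,
         rep(-90, 600))
  pk <- detect_spikes(v, rate100k)
  f <- ap_features(v, rate100k, pk[1])
  expect_equal(f$amplitude_mV, 50, tolerance = 0.5)
  expect_equal(f$threshold_mV, -40, tolerance = 0.5)
  expect_equal(f$apd50_ms, 0.5, tolerance = 0.011)
  # dense-sampled crossing-search oracle for APD50
  level <- f$threshold_mV + f$amplitude_mV / 2
  dense_t <- seq(0, (length(v) - 1) / rate100k, by = 1e-8)
  dense_v <- stats::approx(seq_along(v) / rate100k, v, xout = dense_t)$y
  oracle_apd <- sum(dense_v >= level, na.rm = TRUE) * 1e-8 * 1000
  expect_equal(f$apd50_ms, oracle_apd, tolerance = 0.011)
  # AHP: absolute post-spike minimum
  expect_equal(f$ahp_mV, -90)
})

test_that("feature recovery on generated cells meets stated accuracy", {
  set.seed(11)
  for (s in 1:8) {
    g <- gen_current_clamp(seed = s, steps_pA = NULL,
                           v_thr_mV = runif(1, -45, -38),
                           r_MOhm = runif(1, 100, 200))
    v <- g$ramp$sweeps[[1]]
    pk <- detect_spikes(v, rate100k)
    f <- ap_features(v, rate100k, pk[1])
    tr <- g$truth$template
    expect_lt(abs(f$threshold_mV - tr$threshold_mV), 1)
    expect_lt(abs(f$apd50_ms - tr$apd50_ms), 1000 / rate100k + 1e-9)
    expect_lt(abs(f$upstroke_mV_ms / tr$upstroke_mV_ms - 1), 0.02)
    expect_lt(abs(f$downstroke_mV_ms / tr$downstroke_mV_ms - 1), 0.02)
  }
})

test_that("resting Vm is the median and robust to spikes", {
  expect_equal(resting_vm(rep(-72, 100)), -72)
  v <- rep(-70, 1000); v[sample(1000, 10)] <- 0
  expect_equal(resting_vm(v), -70)
  set.seed(1)
  expect_equal(resting_vm(rnorm(1e6, -65, 2)), -65, tolerance = 0.01)
})

test_that("input resistance follows Ohm's law on the -20 pA step", {
  rate <- 1e4
  mk <- function(dv) {
    n <- round(1.4 * rate)
    v <- rep(-70, n)
    on <- round(0.2 * rate) + 1; off <- round(1.2 * rate)
    v[on:off] <- -70 + dv
    sweep_set(list(v), rate, "mV",
              protocol = step_protocol(-20, 0.2, 1, units = "pA"))
  }
  expect_equal(input_resistance(mk(-2)), 100)
  expect_equal(input_resistance(mk(-4)), 200)
  # RC sweep: R = 150 MOhm, tau = 15 ms settles within 0.1% over 1 s
  n <- round(1.4 * rate); t <- (seq_len(n) - 1) / rate
  v <- rep(-70, n); on <- round(0.2 * rate) + 1; off <- round(1.2 * rate)
  v[on:off] <- -70 - 3 * (1 - exp(-(t[on:off] - 0.2) / 0.015))
  rc <- sweep_set(list(v), rate, "mV",
                  protocol = step_protocol(-20, 0.2, 1, units = "pA"))
  expect_equal(input_resistance(rc), 150, tolerance = 1 / 150)
  expect_error(input_resistance(mk(-2), step_pA = -40), "absent")
})

test_that("rheobase applies the largest-silent-step rule literally", {
  fi <- data.frame(step_pA = c(0, 50, 100, 150, 200),
                   n_spikes = c(0, 0, 0, 2, 5))
  expect_equal(rheobase(fi)$rheobase_pA, 100)
  expect_equal(rheobase(fi)$first_spiking_pA, 150)
  nm <- data.frame(step_pA = c(0, 50, 100, 150), n_spikes = c(0, 1, 0, 3))
  expect_warning(r <- rheobase(nm), "non-monotonic")
  expect_equal(r$rheobase_pA, 100)
  expect_true(r$non_monotonic)
  expect_error(rheobase(data.frame(step_pA = 1:3, n_spikes = c(1, 2, 3))),
               "all steps spiking")
  expect_error(rheobase(data.frame(step_pA = 1:3, n_spikes = c(0, 0, 0))),
               "all steps silent")
})

test_that("F-I counts restrict to the step window and match LIF truth", {
  g <- gen_current_clamp(seed = 2, sampling_rate_hz = 2e4,
                         steps_pA = seq(-100, 500, by = 100))
  fi <- fi_curve(g$steps)
  expect_equal(fi$n_spikes, g$truth$step_counts[order(g$steps$protocol$amplitudes)])
  # closed-form LIF rate check at each suprathreshold step
  tr <- g$truth
  for (i in seq_along(fi$step_pA)) {
    I <- fi$step_pA[i]
    dv_inf <- I * tr$r_MOhm / 1000
    dv_thr <- tr$v_thr_mV - tr$v_rest_mV
    if (dv_inf <= dv_thr) {
      expect_equal(fi$n_spikes[i], 0L)
    } else {
      period <- tr$tau_ms / 1000 * log(dv_inf / (dv_inf - dv_thr)) +
        (length(make_ap_template(threshold_mV = tr$v_thr_mV,
                                 reset_mV = tr$v_rest_mV,
                                 sampling_rate_hz = 2e4)$wave) - 1) / 2e4
      expect_lte(abs(fi$n_spikes[i] - floor(1 / period)), 1)
    }
  }
  # spikes outside the step window are not counted
  tmpl <- make_ap_template(sampling_rate_hz = 1e4)
  v <- rep(-70, 1e4)
  v[100:(99 + length(tmpl$wave))] <- tmpl$wave   # before step onset
  ss <- sweep_set(list(v), 1e4, "mV",
                  protocol = step_protocol(100, 0.5, 0.4, units = "pA"))
  expect_equal(fi_curve(ss)$n_spikes, 0L)
})

test_that("cell QC applies the -50 mV and 20% access-drift rules", {
  expect_false(qc_cell(-49, c(10, 10))$pass)
  expect_match(qc_cell(-49, c(10, 10))$reasons, "depolarized")
  r <- qc_cell(-65, c(10, 12.1))
  expect_false(r$pass)
  expect_match(r$reasons, "21%")
  expect_true(qc_cell(-65, c(10, 11))$pass)
})
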