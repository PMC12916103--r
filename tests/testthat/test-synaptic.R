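test_that("uPSC measurement recovers generated amplitudes and failures", {
  g <- gen_paired_recording(seed = 4, n_sweeps = 1, frequency_hz = 20,
                            n_pulses = 5, a1_pA = 50,
                            depression_ratio = 0.85, p_fail = 0,
                            noise_sd_pA = 1)
  ev <- measure_upsc(g$sweeps[[1]])
  expect_equal(nrow(ev), 5L)
  expect_false(any(ev$is_failure))
  truth_amp <- g$truth$events$amplitude_pA
  expect_true(all(abs(ev$amplitude_pA - truth_amp) < 5))

  # pure noise post trace: every pulse is a failure, amplitudes average 0
  noise <- g$sweeps[[1]]
  noise$post_pA <- rnorm(length(noise$post_pA), 0, 2)
  evn <- measure_upsc(noise)
  expect_true(all(evn$is_failure))
  expect_true(all(evn$amplitude_pA == 0))

  # boundary: an event of exactly 10.0 pA is a failure ("exceeded")
  ps <- g$sweeps[[1]]
  ps$post_pA <- numeric(length(ps$post_pA))
  ap_idx <- round(g$truth$ap_peak_times_s * ps$sampling_rate_hz) + 1
  ps$post_pA[ap_idx + 40] <- -10.0
  evb <- measure_upsc(ps)
  expect_true(all(evb$is_failure))

  # scale consistency: amplifying the post trace never adds failures
  amp2 <- g$sweeps[[1]]
  amp2$post_pA <- amp2$post_pA * 2
  expect_lte(sum(measure_upsc(amp2)$is_failure), sum(ev$is_failure))
})

test_that("failure rates and amplitude profiles match the release model", {
  g <- gen_paired_recording(seed = 8, n_sweeps = 100, frequency_hz = 40,
                            p_fail = 0.3, depression_ratio = 0.7,
                            a1_pA = 50)
  ev <- do.call(rbind, lapply(seq_along(g$sweeps), function(i)
    measure_upsc(g$sweeps[[i]], sweep = i)))
  fr <- failure_rate_by_frequency(ev)
  expect_lt(abs(fr$failure_rate - 0.3), 0.06)
  # truth-level agreement (detector vs generator bookkeeping)
  truth5 <- g$truth$events[g$truth$events$pulse <= 5, ]
  expect_lt(abs(fr$failure_rate - mean(truth5$is_failure)), 0.02)

  # with 50% random failures of constant 40 pA events, means halve
  gh <- gen_paired_recording(seed = 9, n_sweeps = 150, frequency_hz = 20,
                             n_pulses = 3, a1_pA = 40,
                             depression_ratio = 1, p_fail = 0.5,
                             noise_sd_pA = 1)
  evh <- do.call(rbind, lapply(seq_along(gh$sweeps), function(i)
    measure_upsc(gh$sweeps[[i]], sweep = i)))
  ph <- amplitude_profile(evh, first_n = 3)
  expect_true(all(abs(ph$mean_amplitude_pA - 20) < 3))
})

test_that("depression profile and PPR recover the release-model ratio", {
  # release variance is turned off so the paired-pulse ratio isolates the
  # deterministic depression ratio (the stated +-0.05 condition)
  g <- gen_paired_recording(seed = 8, n_sweeps = 100, frequency_hz = 40,
                            p_fail = 0, depression_ratio = 0.7,
                            a1_pA = 50, noise_sd_pA = 1)
  ev <- do.call(rbind, lapply(seq_along(g$sweeps), function(i)
    measure_upsc(g$sweeps[[i]], sweep = i)))
  prof <- amplitude_profile(ev)
  expected <- 50 * 0.7^(0:4)
  expect_true(all(abs(prof$mean_amplitude_pA - expected) < 3))
  ppr <- paired_pulse_ratios(ev)
  expect_lt(abs(ppr$ppr_21 - 0.7), 0.05)
})

test_that("degenerate profiles behave: constant and facilitating trains", {
  g <- gen_paired_recording(seed = 2, n_sweeps = 40, frequency_hz = 20,
                            p_fail = 0, depression_ratio = 1,
                            noise_sd_pA = 0.5, a1_pA = 40)
  ev <- do.call(rbind, lapply(seq_along(g$sweeps), function(i)
    measure_upsc(g$sweeps[[i]], sweep = i)))
  expect_equal(failure_rate_by_frequency(ev)$failure_rate, 0)
  expect_equal(amplitude_profile(ev)$mean_amplitude_pA, rep(40, 5),
               tolerance = 1)
  expect_equal(paired_pulse_ratios(ev)$ppr_21, 1, tolerance = 0.03)

  gf <- gen_paired_recording(seed = 3, n_sweeps = 40, frequency_hz = 20,
                             n_pulses = 4, p_fail = 0,
                             depression_ratio = 1.15, noise_sd_pA = 0.5)
  evf <- do.call(rbind, lapply(seq_along(gf$sweeps), function(i)
    measure_upsc(gf$sweeps[[i]], sweep = i)))
  expect_gt(paired_pulse_ratios(evf)$ppr_21, 1)

  # all failures: p_fail = 1
  g1 <- gen_paired_recording(seed = 5, n_sweeps = 5, p_fail = 1)
  ev1 <- do.call(rbind, lapply(g1$sweeps, measure_upsc))
  expect_equal(failure_rate_by_frequency(ev1)$failure_rate, 1)
  expect_error(synaptic_latency(ev1), "failures")
})

test_that("synaptic latency recovers the generated delay", {
  g <- gen_paired_recording(seed = 6, n_sweeps = 50, frequency_hz = 10,
                            n_pulses = 3, p_fail = 0, a1_pA = 80,
                            latency_mean_ms = 1.2, latency_sd_ms = 0.05,
                            noise_sd_pA = 1)
  ev <- do.call(rbind, lapply(seq_along(g$sweeps), function(i)
    measure_upsc(g$sweeps[[i]], sweep = i)))
  lat <- synaptic_latency(ev)
  expect_equal(lat$onset_latency_ms, 1.2, tolerance = 0.25)
  expect_gt(lat$peak_latency_ms, lat$onset_latency_ms)
})

test_that("exact test matches the enumeration oracle on all small tables", {
  # exhaustive sweep over margins <= 12 inside the unit suite; the
  # acceptance suite extends to 30
  for (n1 in c(3, 7, 12)) for (n2 in c(4, 9, 12)) {
    for (x1 in 0:n1) for (x2 in 0:n2) {
      expect_equal(fisher_exact_test(x1, n1, x2, n2),
                   oracle_fisher_p(x1, n1, x2, n2), tolerance = 1e-12)
    }
  }
  # cross-check against the established implementation on study counts
  p_pkg <- fisher_exact_test(21, 64, 15, 43)
  p_ref <- stats::fisher.test(matrix(c(21, 64 - 21, 15, 43 - 15), 2,
                                     byrow = TRUE))$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-12)
})

test_that("connection summaries reproduce the study percentages", {
  expect_equal(connection_stats(21, 64)$percent, 32.8)
  expect_equal(connection_stats(14, 36)$percent, 38.9)
  expect_equal(connection_stats(9, 61)$percent, 14.8)
  expect_equal(connection_stats(0, 10)$percent, 0)
  cs <- connection_stats(21, 64, 15, 43)
  expect_equal(cs$fisher_p, oracle_fisher_p(21, 64, 15, 43),
               tolerance = 1e-12)
})
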