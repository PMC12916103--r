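test_that("peak and steady-state currents agree for fast activation", {
  g <- gen_vclamp_family(seed = 1, noise_frac = 0)
  pk <- peak_current(g$family)
  ss <- steady_state_current(g$family)
  # non-inactivating current with tau <= 10 ms: within 1% at 100 ms
  big <- abs(pk) > 1
  expect_true(all(abs(ss[big] / pk[big] - 1) < 0.01))
  # zero traces give zero
  z <- voltage_step_family(list(numeric(400), numeric(400)), c(-80, -75),
                           2e4, onset_s = 0.005, duration_ms = 10)
  expect_equal(unname(peak_current(z)), c(0, 0))
  # pre-step artifact is outside the measurement window
  tr <- numeric(2400); tr[20] <- 500
  a <- voltage_step_family(list(tr), 0, 2e4, onset_s = 0.01)
  expect_equal(unname(peak_current(a, baseline_ms = 0.25)), 0)
})

test_that("current density is elementwise and guarded", {
  expect_equal(current_density(500, 5), 100)
  expect_equal(current_density(c(0, 0), 5), c(0, 0))
  p <- c(100, 250, 400)
  expect_equal(current_density(2 * p, 5), 2 * current_density(p, 5))
  expect_error(current_density(p, NULL), "capacitance")
  expect_error(current_density(p, -1), "> 0")
})

test_that("conductance inversion is exact on Boltzmann synthesis", {
  v <- seq(-80, 40, by = 5)
  e_rev <- -105
  gnorm_true <- boltzmann(v, -5, 8)
  I <- 10 * gnorm_true * (v - e_rev)
  cc <- conductance_curve(I, v, e_rev)
  expect_equal(cc$g_norm, gnorm_true / max(gnorm_true), tolerance = 1e-12)
  # a step at E_rev is dropped with a warning
  expect_warning(cc2 <- conductance_curve(c(I, 0), c(v, e_rev + 0.5), e_rev),
                 "dropped")
  expect_equal(nrow(cc2), length(v))
  # pure linear leak appears flat after clamping at zero driving force
  leak <- 0.5 * (v - e_rev)
  ccl <- conductance_curve(leak, v, e_rev)
  expect_true(all(abs(ccl$g_norm - 1) < 1e-9))
})

test_that("Boltzmann fit recovers exact samples and its own identity", {
  v <- seq(-80, 40, by = 5)
  g <- boltzmann(v, -5, 8)
  ft <- fit_boltzmann(g, v)
  expect_equal(ft$vhalf_mV, -5, tolerance = 1e-6)
  expect_equal(ft$k_mV, 8, tolerance = 1e-6)
  # functional identity at the fitted Vhalf
  expect_equal(boltzmann(ft$vhalf_mV, ft$vhalf_mV, ft$k_mV), 0.5)
  # invariance to point order and uniform scaling of unnormalized G
  shuf <- sample(length(v))
  ft2 <- fit_boltzmann(g[shuf] * 7, v[shuf])
  expect_equal(ft2$vhalf_mV, ft$vhalf_mV, tolerance = 1e-5)
  expect_equal(ft2$k_mV, ft$k_mV, tolerance = 1e-5)
  expect_error(fit_boltzmann(g[1:3], v[1:3]), ">= 5 points")
})

test_that("noisy G-V recovery is unbiased against the grid oracle", {
  set.seed(21)
  n_rep <- 30
  err_v <- err_k <- gap_v <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    vh <- runif(1, -20, 10); k <- runif(1, 5, 12)
    v <- seq(-80, 40, by = 5)
    g <- boltzmann(v, vh, k) + rnorm(length(v), 0, 0.05)
    ft <- fit_boltzmann(g, v)
    orc <- oracle_boltzmann_grid(g, v)
    err_v[i] <- ft$vhalf_mV - vh
    err_k[i] <- (ft$k_mV - k) / k
    gap_v[i] <- abs(ft$vhalf_mV - orc$vhalf)
  }
  expect_lt(median(abs(err_v)), 1)
  expect_lt(median(abs(err_k)), 0.10)
  # least-squares fit agrees with the brute-force grid to half a grid step
  expect_lt(median(gap_v), 0.125)
})

test_that("activation tau fits recover the generating constant", {
  rate <- 2e4
  mk <- function(tau_ms, sd = 0) {
    n <- round(0.12 * rate)
    tr <- numeric(n)
    on <- round(0.01 * rate) + 1
    t_ms <- (seq(on, n) - on) * 1000 / rate
    tr[on:n] <- 500 * (1 - exp(-t_ms / tau_ms))
    if (sd > 0) tr <- tr + rnorm(n, 0, sd)
    tr
  }
  expect_equal(fit_activation_tau(mk(2), rate), 2, tolerance = 1e-3)
  set.seed(5)
  est <- replicate(50, fit_activation_tau(mk(2, sd = 25), rate))
  expect_lt(abs(median(est) / 2 - 1), 0.10)
  # decaying trace errors
  n <- round(0.12 * rate); dec <- numeric(n)
  on <- round(0.01 * rate) + 1
  dec[on:n] <- 500 * exp(-(seq(on, n) - on) / (0.002 * rate))
  expect_error(fit_activation_tau(dec, rate), "non-activating")
})

test_that("Nernst potential reproduces the study's chloride reversal", {
  internal <- solution_composition(
    c(`K-gluconate` = 65, KCl = 65, MgCl2 = 2), temperature_C = 32)
  external <- solution_composition(
    c(NaCl = 125, KCl = 2.5, NaH2PO4 = 1.25, CaCl2 = 2, MgCl2 = 1,
      NaHCO3 = 25), temperature_C = 32)
  expect_equal(internal$ions[["Cl"]], 69)     # 65 + 2*2
  expect_equal(external$ions[["Cl"]], 133.5)  # 125 + 2.5 + 4 + 2
  e_cl <- nernst_potential(internal, external, "Cl", z = -1)
  expect_equal(round(e_cl), -17)
  # antisymmetry and the symmetric-concentration zero
  expect_equal(nernst_potential(external, internal, "Cl", -1), -e_cl)
  expect_equal(nernst_potential(internal, internal, "Cl", -1), 0)
  # monotone in the concentration ratio
  hi <- solution_composition(ions = c(Cl = 200), temperature_C = 32)
  expect_lt(nernst_potential(internal, hi, "Cl", -1),
            nernst_potential(internal, external, "Cl", -1))
  expect_error(nernst_potential(internal, external, "Br", -1), "absent")
})
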