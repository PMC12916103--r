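test_that("dF/F0 is ratio-invariant, zero on constants, and interpolated", {
  F <- matrix(rep(100, 3000), nrow = 1)
  d <- compute_dff(F, 30)
  expect_equal(d$dff, matrix(0, 1, 3000))

  set.seed(3)
  F2 <- matrix(100 + abs(rnorm(2 * 4000, 0, 5)), nrow = 2)
  d1 <- compute_dff(F2, 30)
  d2 <- compute_dff(3.7 * F2, 30)
  expect_equal(d1$dff, d2$dff, tolerance = 1e-12)

  # two-block trace with block percentiles 100 and 200:
  # F0 at the midpoint between block centres is 150
  f <- c(rep(100, 1000), rep(200, 1000))
  d3 <- compute_dff(matrix(f, 1), 30)
  centers <- c(500.5, 1500.5)
  mid <- round(mean(centers))
  # dense piecewise-linear oracle
  oracle_f0 <- stats::approx(centers, c(100, 200), xout = mid, rule = 2)$y
  expect_equal(d3$F0[1, mid], oracle_f0, tolerance = 0.5)
  expect_equal(d3$F0[1, 1], 100)      # constant extrapolation at the edges
  expect_equal(d3$F0[1, 2000], 200)
  # F0 is continuous (piecewise-linear): bounded single-step increments
  expect_lt(max(abs(diff(d3$F0[1, ]))), 0.11)

  expect_error(compute_dff(matrix(c(0, 0, 0, 0), 1), 30), "F0 <= 0")
})

test_that("discharge detector finds inserted global events and no others", {
  fr <- 30
  set.seed(9)
  # white noise only, 5 min: no z > 5 events expected
  n_noise_hits <- sum(vapply(1:10, function(s) {
    set.seed(s)
    nrow(detect_discharges(rnorm(fr * 300, 0, 0.02), fr))
  }, numeric(1)) > 0)
  expect_lte(n_noise_hits, 1)   # >= 95% of seeds clean (allow 1 of 10)

  # noise + 3 fast large deflections at known frames
  x <- rnorm(fr * 300, 0, 0.02)
  at <- c(1000, 4000, 7000)
  for (i in at) x[i] <- x[i] + 0.4                   # 20 sigma, one frame
  dd <- detect_discharges(x, fr)
  expect_equal(nrow(dd), 3L)
  expect_true(all(abs(dd$frame - at) <= 1))

  # slow sinusoid riding on noise is removed by the 1 Hz high-pass
  t <- seq(0, 300, by = 1 / fr)
  slow <- 5 * sin(2 * pi * 0.1 * t) + rnorm(length(t), 0, 0.02)
  expect_equal(nrow(detect_discharges(slow, fr)), 0L)
  # constant trace: no events
  expect_equal(nrow(detect_discharges(rep(1, 9000), fr)), 0L)
})

test_that("transient detector honours its three criteria", {
  fr <- 30
  set.seed(4)
  n <- fr * 120
  kern <- exp(-(0:60) / (0.7 * fr))
  base <- rnorm(n, 0, 0.005)

  # a single well-resolved transient is reported once, at its peak
  x <- base; x[1800:1860] <- x[1800:1860] + 0.5 * kern
  tt <- detect_transients(x, fr)
  expect_equal(nrow(tt), 1L)
  expect_lte(abs(tt$frame - 1800), 3)

  # two transients 100 ms apart merge under the 200 ms distance rule
  x2 <- base
  x2[1800:1860] <- x2[1800:1860] + 0.5 * kern
  x2[1803:1863] <- x2[1803:1863] + 0.5 * kern
  expect_equal(nrow(detect_transients(x2, fr)), 1L)

  # flat trace: none
  expect_equal(nrow(detect_transients(rep(0.3, n), fr)), 0L)
})

test_that("robustness sweep counts are monotone and consistent", {
  g <- gen_calcium(seed = 12, n_cells = 1, duration_s = 300)
  dff <- compute_dff(g$roi)$dff[1, ]
  sw <- threshold_robustness_sweep(dff, 30)
  # default grid point reproduces the default detector count
  n_def <- nrow(detect_transients(dff, 30))
  expect_equal(sw$n_transients[sw$min_z == 1 & sw$min_prominence_z == 0.5],
               n_def)
  # monotone non-increasing in each threshold
  for (p in unique(sw$min_prominence_z)) {
    s <- sw[sw$min_prominence_z == p, ]
    expect_true(all(diff(s$n_transients[order(s$min_z)]) <= 0))
  }
  for (z in unique(sw$min_z)) {
    s <- sw[sw$min_z == z, ]
    expect_true(all(diff(s$n_transients[order(s$min_prominence_z)]) <= 0))
  }
  # well-separated 5-sigma events: counts stable across min_z in [1, 3]
  fr <- 30
  set.seed(7)
  x <- rnorm(fr * 600, 0, 0.02)
  at <- seq(500, 17500, length.out = 10)
  kern <- 0.5 * exp(-(0:60) / (0.7 * fr))
  for (i in at) x[i:(i + 60)] <- x[i:(i + 60)] + kern
  sw2 <- threshold_robustness_sweep(x, fr, min_z_grid = c(1, 2, 3),
                                    min_prominence_grid = 0.5)
  expect_equal(sw2$n_transients, rep(10, 3))
})

test_that("epoch segmentation matches constructed schedules", {
  fr <- 30
  expect_equal(segment_epochs(rep(0, fr * 60), fr),
               data.frame(onset_s = 0, offset_s = 60, label = "quiet_rest"))
  # sub-threshold jitter is still one rest epoch
  set.seed(2)
  expect_equal(nrow(segment_epochs(abs(rnorm(fr * 60, 0, 0.1)), fr)), 1L)
  # 0/5 cm/s square wave with 10 s period alternates at the transitions
  sq <- rep(c(rep(0, fr * 5), rep(5, fr * 5)), 6)
  ep <- segment_epochs(sq, fr)
  expect_equal(nrow(ep), 12L)
  expect_equal(unique(ep$label[c(TRUE, FALSE)]), "quiet_rest")
  expect_equal(ep$offset_s - ep$onset_s, rep(5, 12))
})

test_that("per-cell metrics count rest transients per rest minute", {
  ep <- data.frame(onset_s = c(0, 300), offset_s = c(120, 420),
                   label = c("quiet_rest", "quiet_rest"))
  tt <- data.frame(peak_time_s = c(10, 50, 100, 310, 400, 200),
                   frame = 1:6, peak_z = rep(3, 6), peak_dff = rep(0.5, 6),
                   prominence_z = rep(2, 6))
  m <- per_cell_metrics(list(cell_a = tt), ep)
  # 5 of 6 transients inside 4 rest minutes
  expect_equal(m$transients_per_min_rest, 5 / 4)
  expect_true(m$active)
  # empty cell: inactive, undefined height
  m0 <- per_cell_metrics(list(c0 = tt[0, ]), ep)
  expect_false(m0$active)
  expect_true(is.na(m0$mean_peak_z))
  # Poisson generator rate recovery at rest
  g <- gen_calcium(seed = 5, n_cells = 40, duration_s = 600,
                   rate_rest_per_min = 1.2, rate_loco_per_min = 1.2)
  dff <- compute_dff(g$roi)
  trans <- lapply(seq_len(40), function(i)
    detect_transients(dff$dff[i, ], 30))
  ep2 <- segment_epochs(g$speed, 30)
  m2 <- per_cell_metrics(trans, ep2)
  expect_equal(mean(m2$transients_per_min_rest), 1.2, tolerance = 0.12)
})
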