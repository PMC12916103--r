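test_that("preprocessing removes 60 Hz and DC, preserves 10 Hz", {
  rate <- 500
  t <- seq(0, 10, by = 1 / rate)
  hum <- 300 * sin(2 * pi * 60 * t)
  out <- preprocess_eeg(hum, rate)
  expect_lt(max(abs(out[500:4500])), 0.05 * 300)
  # DC offset removed
  dc <- preprocess_eeg(rep(300, 5001), rate)
  expect_lt(abs(mean(dc[500:4500])), 1)
  # 10 Hz passband preserved within 2%
  s10 <- 100 * sin(2 * pi * 10 * t)
  o10 <- preprocess_eeg(s10, rate)
  expect_equal(max(abs(o10[1000:4000])), 100, tolerance = 0.02)
  expect_error(preprocess_eeg(s10, 100), "Nyquist")
})

test_that("rolling RMS is causal with an expanding warm-up window", {
  rate <- 500
  expect_equal(rolling_rms(rep(3, 1000), rate), rep(3, 1000))
  set.seed(1)
  x <- rnorm(rate * 120)
  r <- rolling_rms(x, rate)
  expect_equal(mean(r[(60 * rate):(120 * rate)]), 1, tolerance = 0.02)
  # variance step: RMS rises monotonically (smoothed) after the step
  x2 <- c(rnorm(rate * 60, 0, 1), rnorm(rate * 60, 0, 10))
  r2 <- rolling_rms(x2, rate)
  after <- r2[seq(60 * rate, 115 * rate, by = rate)]
  expect_true(all(diff(after) > -0.2))
  expect_gt(r2[rate * 119], 8)
})

test_that("spike detection needs both the 200 uV floor and the RMS gate", {
  rate <- 500
  set.seed(2)
  # noise alone (sigma 30 uV, 10 min): no 6.7-sigma exceedances
  noise <- rnorm(rate * 600, 0, 30)
  expect_equal(nrow(detect_spikes_eeg(noise, rate)), 0L)
  # 150 uV spikes stay below the absolute floor (quiet background so the
  # spike peak itself, not spike + noise, is what is judged)
  x <- rnorm(rate * 600, 0, 10)
  at <- seq(1000, 200000, by = 25000)
  for (i in at) x[i:(i + 20)] <- x[i:(i + 20)] + 150 * sin(seq(0, pi, length.out = 21))
  expect_equal(nrow(detect_spikes_eeg(x, rate)), 0L)
  # 400 uV biphasic spikes are all found within 10 ms
  g <- gen_eeg(seed = 3, duration_s = 600,
               myoclonic_times_s = seq(30, 570, by = 60))
  filt <- preprocess_eeg(g$record)
  sp <- detect_spikes_eeg(filt, rate)
  truth <- g$truth$spike_times_s
  expect_equal(nrow(sp), length(truth))
  expect_true(all(vapply(truth, function(tt)
    min(abs(sp$time_s - tt)) <= 0.010, logical(1))))
  # raising the floor never increases counts
  expect_lte(nrow(detect_spikes_eeg(filt, rate, floor_uV = 300)), nrow(sp))
})

test_that("train grouping equals the maximal-segment oracle", {
  # worked arithmetic cases
  tr <- detect_trains(seq(0, by = 0.4, length.out = 10))
  expect_equal(tr$n_spikes, 10L)
  expect_equal(tr$duration_s, 3.6)
  expect_equal(nrow(detect_trains(seq(0, by = 0.4, length.out = 6))), 0L)
  # randomized property vs oracle
  set.seed(31)
  for (rep_i in 1:200) {
    times <- random_spike_set(sample(2:20, 1))
    got <- detect_trains(times)
    want <- oracle_trains(times)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$onset_s, want$onset_s, tolerance = 1e-12)
      expect_equal(got$n_spikes, want$n_spikes)
    }
  }
})

test_that("classification applies the stated behavioural rules", {
  trains <- data.frame(onset_s = 100, offset_s = 104, n_spikes = 10,
                       duration_s = 4, mean_isi_s = 0.44)
  spikes <- data.frame(time_s = c(seq(100, 104, length.out = 10), 200),
                       amplitude_uV = 400, width_ms = c(rep(40, 10), 150),
                       in_rms_warmup = FALSE)
  # no annotations: the train is a run of spikes, the isolated spike nothing
  ev0 <- classify_events(trains, spikes, NULL)
  expect_equal(ev0$label, "run_of_spikes")
  # convulsive overlap upgrades to seizure; spasm makes the single spike
  # myoclonic
  ann <- data.frame(onset_s = c(99, 199.5), offset_s = c(105, 200.5),
                    label = c("convulsive", "spasm"))
  ev <- classify_events(trains, spikes, ann)
  expect_setequal(ev$label, c("seizure", "myoclonic"))
  # wide isolated spikes are never myoclonic
  wide <- spikes; wide$width_ms[11] <- 250
  evw <- classify_events(trains, wide, ann)
  expect_false("myoclonic" %in% evw$label)
  # every event carries exactly one label
  expect_true(all(table(paste(ev$onset_s, ev$label)) == 1))
})

test_that("the full synthetic fatal scenario classifies as fatal_seizure", {
  g <- gen_eeg(seed = 13, duration_s = 600, train_times_s = 300,
               fatal = TRUE)
  filt <- preprocess_eeg(g$record)
  sp <- detect_spikes_eeg(filt, 500)
  tr <- detect_trains(sp)
  expect_equal(nrow(tr), 1L)
  ev <- classify_events(tr, sp, g$record$annotations, filt, 500)
  expect_equal(ev$label, "fatal_seizure")
  # without the amplitude collapse the same train is a plain seizure
  g2 <- gen_eeg(seed = 13, duration_s = 600, train_times_s = 300,
                train_labels = "seizure")
  f2 <- preprocess_eeg(g2$record)
  s2 <- detect_spikes_eeg(f2, 500)
  t2 <- detect_trains(s2)
  ann2 <- rbind(g2$record$annotations,
                data.frame(onset_s = t2$offset_s - 1,
                           offset_s = t2$offset_s + 1,
                           label = "hindlimb_extension"))
  e2 <- classify_events(t2, s2, ann2, f2, 500)
  expect_equal(e2$label, "seizure")
})

test_that("raster export flattens labelled events per animal", {
  ev <- data.frame(onset_s = c(10, 50), offset_s = c(14, 50),
                   duration_s = c(4, 0),
                   label = c("seizure", "myoclonic"), evidence = "x")
  r <- export_raster(list(m1 = ev, m2 = ev[1, ]))
  expect_equal(nrow(r), 3L)
  expect_equal(r$animal_id, c("m1", "m1", "m2"))
  # empty set gives a header-only table, and round-trips through the
  # event CSV writer
  r0 <- export_raster(list(m1 = ev[0, ]))
  expect_equal(nrow(r0), 0L)
  p <- file.path(withr::local_tempdir(), "raster.csv")
  write_event_table(data.frame(onset_s = r$onset_s,
                               duration_s = r$duration_s,
                               amplitude = NA_real_, label = r$label,
                               animal_id = r$animal_id), p)
  back <- read_event_table(p)
  expect_equal(back$label, r$label)
  expect_equal(back$onset_s, r$onset_s)
})
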