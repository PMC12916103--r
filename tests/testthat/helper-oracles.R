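# Independent oracles used to cross-check the package's implementations.
# Each is deliberately brute-force and shares no code with the functions
# it checks.

# Two-sided Fisher p by direct enumeration of all tables with the
# observed margins, probabilities from choose() products.
oracle_fisher_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  ks <- max(0, m - n2):min(n1, m)
  probs <- vapply(ks, function(k)
    choose(n1, k) * choose(n2, m - k) / choose(n1 + n2, m), numeric(1))
  p_obs <- choose(n1, x1) * choose(n2, x2) / choose(n1 + n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Spike-train grouping oracle: test every contiguous segment of the
# sorted spike times, keep segments that are ISI-valid throughout and
# maximal, then apply the n/duration rules.
oracle_trains <- function(times, isi_band = c(0.05, 0.6), min_spikes = 5,
                          min_duration = 3) {
  t <- sort(times)
  n <- length(t)
  if (n < 2) return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                               n_spikes = integer(0)))
  valid <- function(i, j) {
    if (j <= i) return(TRUE)
    d <- diff(t[i:j])
    all(d >= isi_band[1] & d <= isi_band[2])
  }
  segs <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!valid(i, j)) next
    maximal <- (i == 1 || !valid(i - 1, j)) && (j == n || !valid(i, j + 1))
    if (maximal && (j - i + 1) >= min_spikes && (t[j] - t[i]) >= min_duration)
      segs[[length(segs) + 1]] <- c(i, j)
  }
  if (!length(segs)) return(data.frame(onset_s = numeric(0),
                                       offset_s = numeric(0),
                                       n_spikes = integer(0)))
  do.call(rbind, lapply(segs, function(s)
    data.frame(onset_s = t[s[1]], offset_s = t[s[2]],
               n_spikes = s[2] - s[1] + 1L)))
}

# Brute-force grid search for the Boltzmann fit, amplitude solved in
# closed form per grid point.
oracle_boltzmann_grid <- function(g, v, vhalf_grid = seq(-30, 20, by = 0.25),
                                  k_grid = seq(3, 15, by = 0.1)) {
  best <- c(Inf, NA, NA)
  for (vh in vhalf_grid) for (k in k_grid) {
    b <- 1 / (1 + exp(-(v - vh) / k))
    a <- sum(g * b) / sum(b * b)
    sse <- sum((g - a * b)^2)
    if (sse < best[1]) best <- c(sse, vh, k)
  }
  list(vhalf = best[2], k = best[3])
}

# Greedy event matcher for detector scoring: counts of matched truth
# events (recall) and matched detections (precision) within a tolerance.
match_events <- function(detected_s, truth_s, tol_s) {
  used <- rep(FALSE, length(detected_s))
  tp <- 0L
  for (tt in truth_s) {
    m <- which(!used & abs(detected_s - tt) <= tol_s)
    if (length(m)) { used[m[which.min(abs(detected_s[m] - tt))]] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fn = length(truth_s) - tp, fp = sum(!used))
}

# Random ISI sequences mixing in-band, too-short and too-long gaps, for
# the train-grouping property test.
random_spike_set <- function(n_spikes) {
  gaps <- sample(c(stats::runif(n_spikes, 0.05, 0.6),
                   stats::runif(n_spikes, 0.0, 0.049),
                   stats::runif(n_spikes, 0.61, 3)),
                 n_spikes - 1, replace = TRUE)
  cumsum(c(stats::runif(1, 0, 5), gaps))
}
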