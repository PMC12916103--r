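# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Moving-mean smoothing with edge shrinkage (window w samples, centred).
#' @keywords internal
moving_mean <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# z-score a trace; robust = median/MAD variant. Constant traces return zeros.
#' @keywords internal
zscore_trace <- function(x, robust = FALSE) {
  if (robust) {
    ctr <- stats::median(x)
    sc <- stats::mad(x, center = ctr)
  } else {
    ctr <- mean(x)
    sc <- stats::sd(x)
  }
  if (!is.finite(sc) || sc == 0) return(rep(0, length(x)))
  (x - ctr) / sc
}

# Indices of strict local maxima (plateaus take the first sample).
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  s <- sign(diff(x))
  # compress zero runs: a peak is a +...0...- pattern
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  runs_sign <- s[nz]
  flips <- which(runs_sign[-length(runs_sign)] > 0 & runs_sign[-1] < 0)
  if (!length(flips)) return(integer(0))
  nz[flips] + 1L
}

# Peak prominence: for each peak index, drop to the highest minimum on the
# path to the nearest higher point on either side (standard definition).
#' @keywords internal
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # left
    left <- x[seq_len(p)]
    higher_l <- which(left > h)
    lbase <- if (length(higher_l)) min(left[seq(max(higher_l), p)]) else min(left)
    # right
    right <- x[p:length(x)]
    higher_r <- which(right > h)
    rbase <- if (length(higher_r)) min(right[seq(1, min(higher_r))]) else min(right)
    h - max(lbase, rbase)
  }, numeric(1))
}

# Greedy min-distance thinning: keep peaks in decreasing height order,
# discard any peak within min_dist samples of an already kept one.
#' @keywords internal
thin_peaks <- function(peaks, heights, min_dist) {
  if (!length(peaks)) return(integer(0))
  ord <- order(heights, decreasing = TRUE)
  kept <- integer(0)
  for (p in peaks[ord]) {
    if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
  }
  sort(kept)
}

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic seeded evaluation that does not disturb the caller's RNG.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
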