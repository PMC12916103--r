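# Small defined computations outside the main time-series chains:
# immunofluorescence membrane/cytosol ratio, PV-labeling validation
# ratios, cell density, and Y-maze spontaneous alternation.

#' Membrane-to-cytosol intensity ratio of a traced cell
#'
#' The membrane compartment is the outermost `band_um` (1 um) of the
#' soma mask; the cytosol is the remaining soma interior outside the
#' nucleus mask. The erosion uses a Euclidean distance transform
#' thresholded at `band_um`, which stays faithful to the physical band
#' width on anisotropy-free pixel grids. The ratio is the mean intensity
#' in the membrane band over the mean intensity in the cytosol, and is
#' invariant under uniform intensity scaling.
#'
#' @param soma Logical/0-1 matrix, the traced soma mask.
#' @param nucleus Logical/0-1 matrix, the nucleus mask (subset of soma).
#' @param intensity Numeric matrix of the channel intensity (a.u.).
#' @param pixel_size_um Pixel size in micrometres (> 0).
#' @param band_um Membrane band width in micrometres.
#' @return List: `ratio`, `membrane_mean`, `cytosol_mean`,
#'   `n_membrane_px`, `n_cytosol_px`.
#' @export
membrane_cytosol_ratio <- function(soma, nucleus, intensity, pixel_size_um,
                                   band_um = 1) {
  stopifnot(pixel_size_um > 0)
  soma <- soma > 0; nucleus <- nucleus > 0
  if (any(nucleus & !soma)) stopf("nucleus mask extends outside the soma")
  if (!all(dim(soma) == dim(intensity)))
    stopf("mask and intensity dimensions differ")
  # distance of each soma pixel to the nearest background pixel, in um
  d <- EBImage::distmap(EBImage::Image(soma * 1), metric = "euclidean")
  d <- as.matrix(EBImage::imageData(d)) * pixel_size_um
  membrane <- soma & d <= band_um
  interior <- soma & d > band_um
  cytosol <- interior & !nucleus
  if (!any(membrane)) stopf("empty membrane compartment")
  if (!any(cytosol))
    stopf("empty cytosol compartment (soma too thin or nucleus fills the interior)")
  mm <- mean(intensity[membrane]); cm <- mean(intensity[cytosol])
  list(ratio = mm / cm, membrane_mean = mm, cytosol_mean = cm,
       n_membrane_px = sum(membrane), n_cytosol_px = sum(cytosol))
}

#' Cell density and labeling-validation ratios
#'
#' @param count Number of cells counted.
#' @param area_mm2 Counting area in mm^2 (> 0).
#' @return `pv_density`: cells per mm^2.
#' @export
pv_density <- function(count, area_mm2) {
  stopifnot(count >= 0)
  if (area_mm2 <= 0) stopf("area_mm2 must be > 0")
  count / area_mm2
}

#' @rdname pv_density
#' @param true_pos Correctly labeled cells.
#' @param false_pos Incorrectly labeled cells.
#' @param total_true Total ground-truth positive cells.
#' @return `labeling_validation`: list with `sensitivity`
#'   (true_pos / total_true) and `false_positive_rate`
#'   (false_pos / (true_pos + false_pos)).
#' @export
labeling_validation <- function(true_pos, false_pos, total_true) {
  if (total_true <= 0) stopf("total_true must be > 0")
  labeled <- true_pos + false_pos
  if (labeled <= 0) stopf("no labeled cells")
  list(sensitivity = true_pos / total_true,
       false_positive_rate = false_pos / labeled)
}

#' Y-maze spontaneous alternation percentage
#'
#' An alternation is a sliding window of three consecutive arm entries
#' visiting three different arms; the score is alternations divided by
#' total possible alternations (entries minus 2), times 100. Immediate
#' self-repeats must already be collapsed upstream.
#'
#' @param entries Character vector of arm labels (e.g. from
#'   `c("A","B","C")`), length >= 3, no immediate repeats.
#' @return Percentage in \[0, 100\].
#' @export
spontaneous_alternation <- function(entries) {
  n <- length(entries)
  if (n < 3L) stopf("need at least 3 arm entries")
  if (any(entries[-1] == entries[-n]))
    stopf("immediate arm re-entries present; collapse them before scoring")
  a <- entries[1:(n - 2)]; b <- entries[2:(n - 1)]; c_ <- entries[3:n]
  alternations <- sum(a != b & b != c_ & a != c_)
  100 * alternations / (n - 2)
}

#' Apply the escape-latency cap to a Barnes-maze trial table
#'
#' Trials without an escape (latency missing) are assigned the cap
#' (150 s); recorded latencies above the cap are truncated to it. A
#' data-ingest rule, not an analysis.
#'
#' @param trials Data.frame with a `latency_s` column (NA = no escape).
#' @param cap_s Latency cap in seconds.
#' @return The table with capped `latency_s`.
#' @export
cap_escape_latency <- function(trials, cap_s = 150) {
  lat <- trials$latency_s
  lat[is.na(lat)] <- cap_s
  trials$latency_s <- pmin(lat, cap_s)
  trials
}
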