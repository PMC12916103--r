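# Reading and writing external formats and the package's internal tidy
# outputs. No science here: readers never resample or rescale, and unit
# handling is by explicit declared tags only.

path_sans_ext <- function(path) sub("\\.(csv|yaml|yml|edf)$", "", path)

#' Write / read a sweep set (CSV + YAML sidecar)
#'
#' The internal exchange format is a plain CSV (one column per sweep,
#' header `sweep_1 ... sweep_n`) next to a YAML sidecar holding the
#' sampling rate, unit tag, protocol and metadata. Round-tripping is the
#' identity to within float-text precision.
#'
#' @param x A [sweep_set()].
#' @param path Output path; `.csv` and `.yaml` extensions are added to the
#'   common stem.
#' @return `write_sweepset` returns `path` (stem) invisibly;
#'   `read_sweepset` returns a [sweep_set()].
#' @export
write_sweepset <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  stem <- path_sans_ext(path)
  m <- do.call(cbind, x$sweeps)
  colnames(m) <- paste0("sweep_", seq_along(x$sweeps))
  utils::write.csv(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  side <- list(sampling_rate_hz = x$sampling_rate_hz, units = x$units,
               metadata = x$metadata)
  if (!is.null(x$protocol)) {
    side$protocol <- unclass(x$protocol)
    side$protocol_type <- class(x$protocol)[1]
  }
  yaml::write_yaml(side, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_sweepset
#' @param format Input format. Only the self-sufficient `"csv"` path is
#'   implemented; `"abf"` and `"hdf5"` error with conversion guidance.
#' @export
read_sweepset <- function(path, format = c("csv", "abf", "hdf5")) {
  format <- match.arg(format)
  if (format != "csv")
    stopf("format '%s' is not supported in this build; convert to CSV + YAML sidecar",
          format)
  stem <- path_sans_ext(path)
  side_path <- paste0(stem, ".yaml")
  if (!file.exists(side_path)) stopf("missing sidecar config: %s", side_path)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$sampling_rate_hz)) stopf("sidecar lacks sampling rate")
  if (is.null(side$units)) stopf("unknown units: sidecar lacks a unit tag")
  if (!side$units %in% c("mV", "pA")) stopf("unknown units: '%s'", side$units)
  m <- utils::read.csv(paste0(stem, ".csv"))
  protocol <- NULL
  if (!is.null(side$protocol)) {
    p <- side$protocol
    protocol <- switch(side$protocol_type,
      step_protocol = step_protocol(unlist(p$amplitudes), p$onset_s,
                                    p$duration_s, p$holding, p$units),
      ramp_protocol = ramp_protocol(p$slope_pA_s, p$onset_s, p$duration_s,
                                    p$holding),
      train_protocol = train_protocol(p$frequency_hz, p$n_pulses, p$pulse_ms,
                                      p$amplitude, p$onset_s),
      stopf("unknown protocol type '%s'", side$protocol_type))
  }
  sweep_set(lapply(seq_len(ncol(m)), function(j) m[[j]]),
            sampling_rate_hz = side$sampling_rate_hz, units = side$units,
            protocol = protocol, metadata = side$metadata %||% list())
}

#' Write / read an ROI fluorescence matrix (CSV + YAML sidecar)
#'
#' The CSV stores one row per ROI; the sidecar records the frame rate,
#' the matrix orientation (always declared, never guessed from shape) and
#' per-cell labels.
#'
#' @param x A [roi_fluorescence()].
#' @param path Output stem; `.csv`/`.yaml` are appended.
#' @return `read_roi_fluorescence` returns a [roi_fluorescence()].
#' @export
write_roi_fluorescence <- function(x, path) {
  stopifnot(inherits(x, "roi_fluorescence"))
  stem <- path_sans_ext(path)
  utils::write.table(format(x$F, digits = 17, trim = TRUE, scientific = FALSE),
                     paste0(stem, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(frame_rate_hz = x$frame_rate_hz,
                        orientation = "cells_x_frames",
                        cell_labels = x$cell_labels),
                   paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_roi_fluorescence
#' @export
read_roi_fluorescence <- function(path) {
  stem <- path_sans_ext(path)
  side_path <- paste0(stem, ".yaml")
  if (!file.exists(side_path)) stopf("missing sidecar config: %s", side_path)
  side <- yaml::read_yaml(side_path)
  if (is.null(side$frame_rate_hz)) stopf("sidecar lacks frame rate")
  if (is.null(side$orientation))
    stopf("sidecar lacks matrix orientation; it is never guessed from shape")
  m <- as.matrix(utils::read.csv(paste0(stem, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  if (side$orientation == "frames_x_cells") m <- t(m)
  else if (side$orientation != "cells_x_frames")
    stopf("unknown orientation '%s'", side$orientation)
  roi_fluorescence(m, side$frame_rate_hz,
                   cell_labels = unlist(side$cell_labels) %||% NULL)
}

#' Read an EEG record
#'
#' Supports plain CSV (single `signal_uV` column plus a YAML sidecar with
#' `sampling_rate_hz`) and EDF (16-bit European Data Format, read-only,
#' channel selected by label). Acquisition-filter settings present in EDF
#' headers are passed through as metadata, never acted upon.
#'
#' @param path File path (stem for CSV, `.edf` file for EDF).
#' @param format `"csv"` or `"edf"`.
#' @param channel For EDF: channel label to extract (required when the
#'   file has more than one signal).
#' @param annotations Optional behaviour annotation data.frame attached to
#'   the returned record.
#' @return An [eeg_record()].
#' @export
read_eeg <- function(path, format = c("csv", "edf"), channel = NULL,
                     annotations = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    stem <- path_sans_ext(path)
    side_path <- paste0(stem, ".yaml")
    if (!file.exists(side_path)) stopf("missing sidecar config: %s", side_path)
    side <- yaml::read_yaml(side_path)
    if (is.null(side$sampling_rate_hz)) stopf("sidecar lacks sampling rate")
    d <- utils::read.csv(paste0(stem, ".csv"))
    if (!"signal_uV" %in% names(d)) stopf("CSV lacks a signal_uV column")
    return(eeg_record(d$signal_uV, side$sampling_rate_hz, annotations))
  }
  read_edf(path, channel = channel, annotations = annotations)
}

#' @rdname read_eeg
#' @param x An [eeg_record()] (CSV writer, for round trips and synthetic
#'   output).
#' @export
write_eeg_csv <- function(x, path) {
  stopifnot(inherits(x, "eeg_record"))
  stem <- path_sans_ext(path)
  utils::write.csv(data.frame(signal_uV = format(x$signal_uV, digits = 17,
                                                 trim = TRUE,
                                                 scientific = FALSE)),
                   paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sampling_rate_hz = x$sampling_rate_hz),
                   paste0(stem, ".yaml"))
  invisible(stem)
}

# --- minimal EDF (European Data Format) support ----------------------------
# EDF is a fixed-layout ASCII header followed by int16 little-endian data
# records. No installed R package reads it, so a minimal reader/writer pair
# lives here; physical scaling follows the EDF specification.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' @rdname read_eeg
#' @export
read_edf <- function(path, channel = NULL, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                      # version
  read_ascii(con, 80); read_ascii(con, 80)  # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)    # start date / time
  read_ascii(con, 8)                      # header bytes
  read_ascii(con, 44)                     # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), character(1))
  for (i in seq_len(ns)) read_ascii(con, 80)  # transducer
  dims <- vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  prefilt <- vapply(seq_len(ns), function(i) read_ascii(con, 80), character(1))
  nsamp <- as.integer(vapply(seq_len(ns), function(i) read_ascii(con, 8), character(1)))
  for (i in seq_len(ns)) read_ascii(con, 32)  # reserved
  if (is.null(channel)) {
    if (ns > 1L)
      stopf("EDF has %d channels (%s); pick one with `channel`",
            ns, paste(labels, collapse = ", "))
    ch <- 1L
  } else {
    ch <- match(channel, labels)
    if (is.na(ch))
      stopf("channel '%s' absent; available: %s", channel,
            paste(labels, collapse = ", "))
  }
  sig <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[s], size = 2L, endian = "little")
      if (s == ch) sig[[r]] <- v
    }
  }
  dig <- unlist(sig)
  phys <- (dig - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) /
    (dmax_[ch] - dmin_[ch]) + pmin_[ch]
  rec <- eeg_record(phys, nsamp[ch] / rec_dur, annotations)
  rec$metadata <- list(channel = labels[ch], physical_dim = dims[ch],
                       prefiltering = prefilt[ch])
  rec
}

pad_ascii <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  sprintf(paste0("%-", n, "s"), x)
}

#' @rdname read_eeg
#' @param physical_range Symmetric physical range of the int16 encoding in
#'   microvolts; samples outside it are clipped.
#' @export
write_edf <- function(x, path, channel = "EEG", physical_range = 5000) {
  stopifnot(inherits(x, "eeg_record"))
  rate <- x$sampling_rate_hz
  nsamp <- as.integer(round(rate))          # one-second records
  n_rec <- floor(length(x$signal_uV) / nsamp)
  if (n_rec < 1L) stopf("record shorter than one EDF data record")
  sig <- x$signal_uV[seq_len(n_rec * nsamp)]
  pmin_ <- -physical_range; pmax_ <- physical_range
  dmin_ <- -32768; dmax_ <- 32767
  dig <- as.integer(round((pmin(pmax(sig, pmin_), pmax_) - pmin_) /
                            (pmax_ - pmin_) * (dmax_ - dmin_) + dmin_))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_ascii("0", 8), pad_ascii("X", 80), pad_ascii("X", 80),
                pad_ascii("01.01.26", 8), pad_ascii("00.00.00", 8),
                pad_ascii(256 + 256, 8), pad_ascii("", 44),
                pad_ascii(n_rec, 8), pad_ascii("1", 8), pad_ascii("1", 4),
                pad_ascii(channel, 16), pad_ascii("", 80), pad_ascii("uV", 8),
                pad_ascii(pmin_, 8), pad_ascii(pmax_, 8),
                pad_ascii(dmin_, 8), pad_ascii(dmax_, 8), pad_ascii("", 80),
                pad_ascii(nsamp, 8), pad_ascii("", 32))
  writeBin(charToRaw(hdr), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Write / read detected-event tables (fixed CSV schema)
#'
#' All event detectors report through one schema so downstream tools (e.g.
#' raster plotting) consume a single format: `onset_s`, `duration_s`,
#' `amplitude`, `label`, plus any extra columns the detector adds.
#'
#' @param events Data.frame containing at least the schema columns.
#' @param path CSV path.
#' @return `read_event_table` returns a data.frame (header-only inputs give
#'   zero rows).
#' @export
write_event_table <- function(events, path) {
  need <- c("onset_s", "duration_s", "amplitude", "label")
  if (!nrow(events) && !all(need %in% names(events)))
    events <- stats::setNames(
      as.data.frame(rep(list(numeric(0)), length(need))), need)
  if (!all(need %in% names(events)))
    stopf("event table lacks column(s): %s",
          paste(setdiff(need, names(events)), collapse = ", "))
  utils::write.csv(events[c(need, setdiff(names(events), need))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  utils::read.csv(path, colClasses = c(label = "character"))
}

#' Write a JSON summary
#'
#' @param x A named list of scalar values or nested lists.
#' @param path Output path.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
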