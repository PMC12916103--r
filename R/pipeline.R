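# Config-driven entry points wiring io -> analysis -> reports. Each
# command takes a validated config list (from a YAML file), runs one
# analysis chain deterministically under the configured seed, and writes
# CSV/JSON outputs plus the resolved config next to them.

config_known_keys <- c("seed", "out_dir", "log_level", "simulate", "ephys",
                       "vclamp", "pairs", "calcium", "eeg", "compare")

#' Read and validate a run configuration
#'
#' YAML with a `seed`, `out_dir`, optional `log_level`, and one block per
#' analysis module. Unknown top-level keys are rejected (typo guard).
#'
#' @param path YAML file path, or a list (validated in place).
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg$seed <- cfg$seed %||% 1L
  cfg$out_dir <- cfg$out_dir %||% "."
  structure(cfg, class = "run_config")
}

# 32-bit polynomial hash of the canonical YAML serialization, for
# provenance logs (double arithmetic keeps every intermediate exact)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

finish_run <- function(cfg, out_dir, outputs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(c(unclass(cfg), list(config_hash = config_hash(cfg),
                                        package_version =
                                          as.character(utils::packageVersion("pvephys")))),
                   file.path(out_dir, "resolved_config.yaml"))
  invisible(outputs)
}

#' Pipeline commands
#'
#' Thin deterministic wrappers chaining the io readers, the analysis
#' modules and the CSV/JSON writers. Every command writes its outputs
#' under `config$out_dir` together with the resolved config (including a
#' config hash and the package version) and returns the result tables
#' invisibly.
#'
#' @param config A [read_run_config()] list. Relevant blocks:
#'   `simulate` (modality and generator overrides), `ephys` (paths to
#'   ramp/step sweep sets), `vclamp` (family path, `erev_mode`),
#'   `pairs`, `calcium`, `eeg`.
#' @return Invisibly, a named list of the tables written.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config) {
  cfg <- read_run_config(config)
  sim <- cfg$simulate %||% list()
  modality <- sim$modality %||% "calcium"
  out <- file.path(cfg$out_dir, "simulate")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  args <- sim[setdiff(names(sim), "modality")]
  args$seed <- cfg$seed
  res <- switch(modality,
    current_clamp = do.call(gen_current_clamp, args),
    vclamp_family = do.call(gen_vclamp_family, args),
    paired_recording = do.call(gen_paired_recording, args),
    calcium = do.call(gen_calcium, args),
    eeg = do.call(gen_eeg, args),
    stopf("unknown modality '%s'", modality))
  if (modality == "calcium") {
    write_roi_fluorescence(res$roi, file.path(out, "roi"))
    utils::write.csv(data.frame(
      time_s = (seq_along(res$speed) - 1) / res$roi$frame_rate_hz,
      speed = res$speed), file.path(out, "speed.csv"), row.names = FALSE)
  } else if (modality == "eeg") {
    write_eeg_csv(res$record, file.path(out, "eeg"))
    if (!is.null(res$record$annotations))
      utils::write.csv(res$record$annotations,
                       file.path(out, "annotations.csv"), row.names = FALSE)
  } else if (modality == "current_clamp") {
    if (!is.null(res$steps)) write_sweepset(res$steps, file.path(out, "steps"))
    write_sweepset(res$ramp, file.path(out, "ramp"))
  } else if (modality == "vclamp_family") {
    fam <- res$family
    write_sweepset(
      sweep_set(fam$traces, fam$sampling_rate_hz, units = "pA",
                protocol = step_protocol(fam$steps_mV, fam$onset_s,
                                         fam$duration_ms / 1000,
                                         holding = fam$holding_mV,
                                         units = "mV"),
                metadata = list(capacitance_pF =
                                  as.character(fam$capacitance_pF %||% ""))),
      file.path(out, "family"))
  }
  truth <- res$truth
  truth$events <- NULL                       # large frames stay in memory
  write_summary(rapply(truth, unclass, how = "replace"),
                file.path(out, "truth.json"))
  finish_run(cfg, out, res)
}

#' @rdname pipeline
#' @export
cmd_ephys <- function(config) {
  cfg <- read_run_config(config)
  blk <- cfg$ephys %||% stopf("config lacks an 'ephys' block")
  ramp <- read_sweepset(blk$ramp_path)
  steps <- if (!is.null(blk$steps_path)) read_sweepset(blk$steps_path) else NULL
  out <- file.path(cfg$out_dir, "ephys")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  row <- cell_feature_row(ramp, steps = steps,
                          cell_id = blk$cell_id %||% "cell_1",
                          group = blk$group %||% NA_character_)
  utils::write.csv(row, file.path(out, "features.csv"), row.names = FALSE)
  fi <- NULL
  if (!is.null(steps)) {
    fi <- fi_curve(steps)
    utils::write.csv(cbind(cell_id = blk$cell_id %||% "cell_1", fi),
                     file.path(out, "fi_curve.csv"), row.names = FALSE)
  }
  finish_run(cfg, out, list(features = row, fi = fi))
}

#' @rdname pipeline
#' @export
cmd_vclamp <- function(config) {
  cfg <- read_run_config(config)
  blk <- cfg$vclamp %||% stopf("config lacks a 'vclamp' block")
  ss <- read_sweepset(blk$family_path)
  p <- ss$protocol
  fam <- voltage_step_family(ss$sweeps, p$amplitudes, ss$sampling_rate_hz,
                             p$onset_s, p$duration_s * 1000, p$holding,
                             capacitance_pF = blk$capacitance_pF)
  e_rev <- if (identical(blk$erev_mode %||% "nernst", "fixed"))
    blk$erev_mV else {
      sol <- macropatch_solutions()
      nernst_potential(sol$internal, sol$external, "K", +1)
    }
  peaks <- peak_current(fam)
  gv <- conductance_curve(peaks, fam$steps_mV, e_rev)
  fit <- fit_boltzmann(gv$g_norm, gv$step_mV)
  taus <- activation_tau_curve(fam)
  out <- file.path(cfg$out_dir, "vclamp")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rep_ <- data.frame(cell_id = blk$cell_id %||% "cell_1",
                     gmax = fit$gmax, vhalf_mV = fit$vhalf_mV,
                     k_mV = fit$k_mV, residual_rms = fit$residual_rms,
                     e_rev_mV = e_rev)
  utils::write.csv(rep_, file.path(out, "boltzmann_fit.csv"), row.names = FALSE)
  utils::write.csv(taus, file.path(out, "activation_tau.csv"), row.names = FALSE)
  finish_run(cfg, out, list(fit = rep_, tau = taus, gv = gv))
}

#' @rdname pipeline
#' @export
cmd_pairs <- function(config) {
  cfg <- read_run_config(config)
  blk <- cfg$pairs %||% list()
  # paired sweeps come from the simulator in this build; measured tables
  # may also be passed pre-assembled via blk$events
  events <- blk$events %||% {
    sim <- do.call(gen_paired_recording,
                   c(list(seed = cfg$seed), blk$generator %||% list()))
    do.call(rbind, lapply(seq_along(sim$sweeps), function(i)
      measure_upsc(sim$sweeps[[i]], sweep = i)))
  }
  out <- file.path(cfg$out_dir, "pairs")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(events, file.path(out, "events.csv"), row.names = FALSE)
  summ <- list(failure = failure_rate_by_frequency(events),
               profile = amplitude_profile(events),
               ppr = paired_pulse_ratios(events))
  utils::write.csv(summ$failure, file.path(out, "failure_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$ppr, file.path(out, "ppr.csv"), row.names = FALSE)
  finish_run(cfg, out, c(list(events = events), summ))
}

#' @rdname pipeline
#' @export
cmd_calcium <- function(config) {
  cfg <- read_run_config(config)
  blk <- cfg$calcium %||% stopf("config lacks a 'calcium' block")
  roi <- read_roi_fluorescence(blk$roi_path)
  speed <- if (!is.null(blk$speed_path))
    utils::read.csv(blk$speed_path)$speed else NULL
  dff <- compute_dff(roi, block_frames = blk$block_frames %||% 1000,
                     percentile = blk$percentile %||% 0.1)
  fr <- roi$frame_rate_hz
  trans <- lapply(seq_len(nrow(dff$dff)), function(i)
    detect_transients(dff$dff[i, ], fr,
                      min_z = blk$min_z %||% 1,
                      min_prominence_z = blk$min_prominence_z %||% 0.5))
  names(trans) <- paste0("cell_", seq_along(trans))
  fov <- colMeans(dff$dff)
  disch <- detect_discharges(fov, fr, speed = speed)
  epochs <- if (!is.null(speed)) segment_epochs(speed, fr)
            else data.frame(onset_s = numeric(0), offset_s = numeric(0),
                            label = character(0))
  metrics <- per_cell_metrics(trans, epochs, roi$cell_labels)
  out <- file.path(cfg$out_dir, "calcium")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  all_trans <- do.call(rbind, lapply(names(trans), function(nm)
    if (nrow(trans[[nm]])) cbind(cell = nm, trans[[nm]]) else NULL))
  utils::write.csv(all_trans %||% data.frame(),
                   file.path(out, "transients.csv"), row.names = FALSE)
  utils::write.csv(disch, file.path(out, "discharges.csv"), row.names = FALSE)
  utils::write.csv(metrics, file.path(out, "cell_metrics.csv"),
                   row.names = FALSE)
  finish_run(cfg, out, list(transients = trans, discharges = disch,
                            metrics = metrics, epochs = epochs))
}

#' @rdname pipeline
#' @export
cmd_eeg <- function(config) {
  cfg <- read_run_config(config)
  blk <- cfg$eeg %||% stopf("config lacks an 'eeg' block")
  ann <- if (!is.null(blk$annotations_path))
    utils::read.csv(blk$annotations_path,
                    colClasses = c(label = "character")) else NULL
  rec <- read_eeg(blk$eeg_path, format = blk$format %||% "csv",
                  channel = blk$channel, annotations = ann)
  filt <- preprocess_eeg(rec)
  rate <- rec$sampling_rate_hz
  spikes <- detect_spikes_eeg(filt, rate,
                              floor_uV = blk$floor_uV %||% 200)
  trains <- detect_trains(spikes,
                          isi_band = unlist(blk$isi_band %||% c(0.05, 0.6)),
                          min_spikes = blk$min_spikes %||% 5,
                          min_duration_s = blk$min_duration_s %||% 3)
  events <- classify_events(trains, spikes, rec$annotations, filt, rate)
  out <- file.path(cfg$out_dir, "eeg")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(spikes, file.path(out, "spikes.csv"), row.names = FALSE)
  utils::write.csv(trains, file.path(out, "trains.csv"), row.names = FALSE)
  raster <- export_raster(stats::setNames(list(events),
                                          blk$animal_id %||% "animal_1"))
  write_event_table(
    data.frame(onset_s = raster$onset_s, duration_s = raster$duration_s,
               amplitude = raster$amplitude, label = raster$label,
               animal_id = raster$animal_id),
    file.path(out, "raster.csv"))
  finish_run(cfg, out, list(spikes = spikes, trains = trains,
                            events = events, raster = raster))
}

#' Delegated standard statistics for group comparisons
#'
#' A thin wrapper over established routines, kept out of the bespoke
#' analysis paths: unpaired Welch t-test for two numeric groups, the
#' exact test for two proportions, and repeated-measures two-way ANOVA
#' (`stats::aov` with an Error(subject) stratum). Significance stars are
#' display only (* p<0.05, ** p<0.01, *** p<0.001).
#'
#' @param x,y Numeric vectors (t-test) or `c(successes, n)` pairs
#'   (proportions).
#' @param method `"ttest"` or `"fisher"`.
#' @return List: `method`, `p_value`, `estimate`, `stars`.
#' @export
compare_groups <- function(x, y, method = c("ttest", "fisher")) {
  method <- match.arg(method)
  if (method == "ttest") {
    tt <- stats::t.test(x, y)
    p <- tt$p.value
    est <- unname(diff(rev(tt$estimate)))
  } else {
    p <- fisher_exact_test(x[1], x[2], y[1], y[2])
    est <- x[1] / x[2] - y[1] / y[2]
  }
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "ns"
  list(method = method, p_value = p, estimate = est, stars = stars)
}

#' @rdname pipeline
#' @param groups Named list of numeric vectors to compare pairwise with
#'   [compare_groups()].
#' @export
cmd_compare <- function(config, groups) {
  cfg <- read_run_config(config)
  nms <- names(groups)
  rows <- list()
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    cp <- compare_groups(groups[[i]], groups[[j]])
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = nms[i], group_b = nms[j], p_value = cp$p_value,
                 estimate = cp$estimate, stars = cp$stars)
  }
  out <- file.path(cfg$out_dir, "compare")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(out, "comparisons.csv"), row.names = FALSE)
  finish_run(cfg, out, list(comparisons = tab))
}
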