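#' Write spike times to a plain-text file
#'
#' One spike time per line, seconds, no header.
#'
#' @param train a `spike_train`.
#' @param path output file.
#' @export
write_spikes <- function(train, path) {
  writeLines(sprintf("%.17g", train$times), path)
  invisible(path)
}

#' Read spike times from a plain-text file
#'
#' @param path file with one spike time per line.
#' @param duration trial duration in seconds.
#' @param cell_id,trial_id optional identifiers.
#' @return A `spike_train`.
#' @export
read_spikes <- function(path, duration, cell_id = NA, trial_id = NA) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  spike_train(as.numeric(lines), duration, cell_id, trial_id)
}

#' Write a synthetic study to a directory
#'
#' Layout: `stimulus.csv` (time, value), `cells.json` (parameters,
#' positions, delays, ground truth) and `spikes/<cell>/<trial>.csv` with
#' one spike time per line (`baseline.csv` holds the baseline train).
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stim <- data.frame(time = signal_times(study$stimulus),
                     value = study$stimulus$values)
  write.csv(stim, file.path(dir, "stimulus.csv"), row.names = FALSE)
  meta <- list(
    velocity = study$velocity, body_length = study$body_length,
    contrast = study$contrast, seed = study$seed,
    stimulus_rate = study$stimulus$rate,
    baseline_duration = study$cells[[1L]]$baseline$duration,
    trial_duration = study$cells[[1L]]$trials[[1L]]$duration,
    cells = lapply(study$cells, function(cell)
      c(unclass(cell$params), list(delay = cell$delay,
                                   n_trials = length(cell$trials)))))
  jsonlite::write_json(meta, file.path(dir, "cells.json"),
                       auto_unbox = TRUE, digits = NA)
  for (ci in seq_along(study$cells)) {
    cdir <- file.path(dir, "spikes", sprintf("cell%03d", ci))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    write_spikes(study$cells[[ci]]$baseline,
                 file.path(cdir, "baseline.csv"))
    for (ti in seq_along(study$cells[[ci]]$trials))
      write_spikes(study$cells[[ci]]$trials[[ti]],
                   file.path(cdir, sprintf("trial%03d.csv", ti)))
  }
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return A `synthetic_study`.
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cells.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  stim_df <- read.csv(file.path(dir, "stimulus.csv"))
  stimulus <- sampled_signal(stim_df$value, meta$stimulus_rate,
                             t0 = stim_df$time[1L])
  cells <- lapply(seq_along(meta$cells), function(ci) {
    cm <- meta$cells[[ci]]
    p <- punit_params(eod_frequency = cm$eod_frequency,
                      locking_strength = cm$locking_strength,
                      bias_current = cm$bias_current,
                      noise_intensity = cm$noise_intensity,
                      am_gain = cm$am_gain, position = cm$position,
                      body_length = cm$body_length, tau_m = cm$tau_m,
                      refractory = cm$refractory)
    cdir <- file.path(dir, "spikes", sprintf("cell%03d", ci))
    baseline <- read_spikes(file.path(cdir, "baseline.csv"),
                            meta$baseline_duration, cell_id = ci)
    trials <- lapply(seq_len(cm$n_trials), function(ti)
      read_spikes(file.path(cdir, sprintf("trial%03d.csv", ti)),
                  meta$trial_duration, cell_id = ci, trial_id = ti))
    list(params = p, delay = cm$delay, baseline = baseline,
         trials = trials)
  })
  structure(list(cells = cells, stimulus = stimulus,
                 velocity = meta$velocity, body_length = meta$body_length,
                 contrast = meta$contrast, seed = meta$seed),
            class = "synthetic_study")
}
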