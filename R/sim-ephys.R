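#' Simulate a panel of single-sensillum recordings
#'
#' Spikes are drawn as a homogeneous Poisson process at `baseline_rate`
#' over the whole recording, with an additional Poisson process at the
#' odor-evoked rate confined to the response window
#' `[onset + 0.2, onset + 0.7)` seconds. Each simulated sensillum is
#' recorded once per odorant and once with the solvent control (evoked
#' rate 0). Output is reproducible for a fixed spec seed.
#'
#' @param spec an [ephys_sim_spec()].
#' @param duration recording length in seconds; default covers the
#'   stimulus window plus 1 s of tail.
#' @return a list of `spike_train` objects (see [spike_train()]).
#' @export
gen_spike_trains <- function(spec, duration = NULL) {
  stopifnot(inherits(spec, "ephys_sim_spec"))
  onset <- spec$stimulus_onset
  if (is.null(duration)) duration <- onset + spec$stimulus_duration + 1
  odorants <- rownames(spec$response_rate_map)
  classes <- colnames(spec$response_rate_map)

  with_seed(spec$seed, {
    trains <- list()
    for (cls in classes) {
      for (trial in seq_len(spec$trial_count)) {
        sensillum <- sprintf("%s_%02d", cls, trial)
        for (od in c(odorants, ".solvent")) {
          evoked <- if (od == ".solvent") 0 else spec$response_rate_map[od, cls]
          base_times <- runif(rpois(1L, spec$baseline_rate * duration),
                              0, duration)
          resp_times <- runif(rpois(1L, evoked * 0.5),
                              onset + 0.2, onset + 0.7)
          trains[[length(trains) + 1L]] <- spike_train(
            spike_times = sort(c(base_times, resp_times)),
            stimulus_onset = onset,
            stimulus_duration = spec$stimulus_duration,
            sensillum = sensillum, neuron = "a",
            odorant = if (od == ".solvent") "solvent" else od,
            concentration = spec$concentration,
            solvent = od == ".solvent",
            class_truth = cls)
        }
      }
    }
    trains
  })
}

#' Write / read spike trains as a TSV table
#'
#' One row per trial; spike times are stored semicolon-separated so the
#' table stays a flat, diff-able text file.
#'
#' @param trains list of `spike_train` objects.
#' @param path file path.
#' @return `read_spike_trains` returns a list of `spike_train` objects.
#' @export
write_spike_trains <- function(trains, path) {
  df <- data.frame(
    trial_id = seq_along(trains),
    sensillum = vapply(trains, function(t) t$sensillum, character(1)),
    neuron = vapply(trains, function(t) t$neuron, character(1)),
    odorant = vapply(trains, function(t) t$odorant, character(1)),
    concentration = vapply(trains, function(t) t$concentration, numeric(1)),
    solvent = vapply(trains, function(t) t$solvent, logical(1)),
    onset_s = vapply(trains, function(t) t$stimulus_onset, numeric(1)),
    duration_s = vapply(trains, function(t) t$stimulus_duration, numeric(1)),
    spike_times = vapply(trains, function(t)
      paste(formatC(t$spike_times, format = "fg", digits = 10), collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    times <- if (nzchar(df$spike_times[i]))
      as.numeric(strsplit(df$spike_times[i], ";", fixed = TRUE)[[1]])
    else numeric(0)
    spike_train(spike_times = times,
                stimulus_onset = df$onset_s[i],
                stimulus_duration = df$duration_s[i],
                sensillum = df$sensillum[i], neuron = df$neuron[i],
                odorant = df$odorant[i], concentration = df$concentration[i],
                solvent = df$solvent[i])
  })
}
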