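#' Simulation specification for single-sensillum recordings
#'
#' Describes a panel of extracellular recordings: spontaneous (baseline)
#' firing, odor-evoked firing per odorant and sensillum class, and the
#' stimulus timing. One "trial" is one sensillum recorded once per odorant
#' plus once with the solvent control, so a spec with `trial_count = n`
#' yields `n` sensilla per class.
#'
#' @param baseline_rate spontaneous firing rate, spikes/s (>= 0).
#' @param response_rate_map numeric matrix of odor-evoked rate increments
#'   (spikes/s, >= 0) with odorants as rows and sensillum classes as columns;
#'   dimnames are required.
#' @param trial_count sensilla per class (>= 1).
#' @param stimulus_onset stimulus onset in seconds (>= 0.5 so a baseline
#'   window exists).
#' @param stimulus_duration stimulus duration, seconds; 1 s air pulse by
#'   default.
#' @param concentration odorant dilution, vol/vol fraction.
#' @param seed integer seed; required, generators hold no global state.
#' @return an object of class `ephys_sim_spec`.
#' @export
ephys_sim_spec <- function(baseline_rate, response_rate_map, trial_count,
                           stimulus_onset = 1, stimulus_duration = 1,
                           concentration = 0.01, seed) {
  stop_if_not_scalar_number(baseline_rate, "baseline_rate", lower = 0)
  if (!is.matrix(response_rate_map) || !is.numeric(response_rate_map) ||
      is.null(rownames(response_rate_map)) || is.null(colnames(response_rate_map)))
    stop("'response_rate_map' must be a numeric matrix with odorant rownames and class colnames")
  if (any(!is.finite(response_rate_map)) || any(response_rate_map < 0))
    stop("response rates must be finite and >= 0")
  stop_if_not_scalar_number(trial_count, "trial_count", lower = 1)
  stop_if_not_scalar_number(stimulus_onset, "stimulus_onset", lower = 0.5)
  structure(list(
    baseline_rate = baseline_rate,
    response_rate_map = response_rate_map,
    trial_count = as.integer(trial_count),
    stimulus_onset = stimulus_onset,
    stimulus_duration = stimulus_duration,
    concentration = concentration,
    seed = as.integer(seed)
  ), class = "ephys_sim_spec")
}

#' Simulation specification for a dose-response series
#'
#' @param true_ec50 ground-truth EC50, vol/vol fraction (> 0).
#' @param hill Hill slope (> 0).
#' @param max_response plateau response, spikes/s.
#' @param noise_sd Gaussian noise SD on responses, spikes/s (>= 0).
#' @param concentrations strictly positive vol/vol fractions, ascending.
#' @param replicates responses drawn per concentration (default 1).
#' @param seed integer seed.
#' @return an object of class `dose_sim_spec`.
#' @export
dose_sim_spec <- function(true_ec50, hill, max_response, noise_sd,
                          concentrations, replicates = 1L, seed) {
  stop_if_not_scalar_number(true_ec50, "true_ec50", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(hill, "hill", lower = 0, strict = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (length(concentrations) == 0)
    stop("'concentrations' must be non-empty")
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("'concentrations' must be strictly positive and sorted ascending")
  structure(list(
    true_ec50 = true_ec50, hill = hill, max_response = max_response,
    noise_sd = noise_sd, concentrations = as.numeric(concentrations),
    replicates = as.integer(replicates), seed = as.integer(seed)
  ), class = "dose_sim_spec")
}

#' Simulation specification for a paralog structure-model pair
#'
#' Ground truth for the in-silico substitution screen: an idealized
#' seven-helix Calpha bundle ("background", the Or42a3-like paralog) and a
#' "target" copy (Or42a4-like) carrying localized Gaussian displacement
#' fields centered on each causal substitution position inside the S5-S6
#' ligand-binding helices. Sequence differences comprise the causal
#' positions plus `n_decoys` structurally silent decoy substitutions.
#'
#' The default `perturb_amplitude` of 4.7 Angstrom is fixed by closed form:
#' a Gaussian bump of width w = 3 residues contributes
#' sum_i exp(-(i-p)^2/w^2) ~ w*sqrt(pi) ~ 5.32 squared displacement, so two
#' bumps over the default 80-residue S5-S6 block give a regional RMSD of
#' about A * sqrt(2 * 5.32 / 80) ~ 0.36 A per Angstrom of amplitude; 4.7 A
#' thus emulates the ~1.7 A divergence scale seen between receptor paralogs.
#'
#' @param n_residues chain length (default 400, typical for an insect
#'   odorant receptor).
#' @param regions named list of `c(start, end)` 1-based inclusive residue
#'   ranges for helices S1..S7; the default lays out seven 40-residue
#'   helices separated by 16-residue loops with 10-residue termini.
#' @param causal_positions residue indices carrying displacement fields;
#'   must lie inside S5 or S6.
#' @param n_decoys structurally silent sequence differences planted outside
#'   the causal set.
#' @param perturb_amplitude displacement amplitude, Angstrom (> 0).
#' @param field_width Gaussian width of each displacement field, residues.
#' @param plddt_profile per-residue confidence 0-100; default 90 everywhere
#'   with unreliable (< 70) termini of 10 residues each.
#' @param seed integer seed.
#' @return an object of class `struct_sim_spec`.
#' @export
struct_sim_spec <- function(n_residues = 400L,
                            regions = NULL,
                            causal_positions,
                            n_decoys = 30L,
                            perturb_amplitude = 4.7,
                            field_width = 3,
                            plddt_profile = NULL,
                            seed) {
  n_residues <- as.integer(n_residues)
  if (is.null(regions)) {
    ## 7 helices with inter-helix loops and free termini, scaled to fit
    helix_len <- max(5L, n_residues %/% 10L)
    nterm <- max(1L, n_residues %/% 40L)
    loop_len <- max(1L, (n_residues - 2L * nterm - 7L * helix_len) %/% 6L)
    starts <- nterm + (0:6) * (helix_len + loop_len) + 1L
    regions <- lapply(starts, function(s) c(s, s + helix_len - 1L))
    names(regions) <- paste0("S", 1:7)
  }
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("'regions' must be a uniquely named list of c(start, end) ranges")
  for (r in regions) {
    if (length(r) != 2L || r[1] < 1L || r[2] > n_residues || r[1] > r[2])
      stop("region ranges must lie within [1, n_residues]")
  }
  causal_positions <- sort(unique(as.integer(causal_positions)))
  s56 <- c(seq.int(regions$S5[1], regions$S5[2]),
           seq.int(regions$S6[1], regions$S6[2]))
  if (!all(causal_positions %in% s56))
    stop("all 'causal_positions' must fall inside regions S5 or S6")
  stop_if_not_scalar_number(perturb_amplitude, "perturb_amplitude",
                            lower = 0, strict = TRUE)
  if (is.null(plddt_profile)) {
    plddt_profile <- rep(90, n_residues)
    tail_n <- min(10L, n_residues %/% 4L)
    if (tail_n > 0) {
      plddt_profile[seq_len(tail_n)] <- 50
      plddt_profile[seq.int(n_residues - tail_n + 1L, n_residues)] <- 50
    }
  }
  if (length(plddt_profile) != n_residues ||
      any(plddt_profile < 0 | plddt_profile > 100))
    stop("'plddt_profile' must give one value in [0, 100] per residue")
  structure(list(
    n_residues = n_residues, regions = regions,
    causal_positions = causal_positions, n_decoys = as.integer(n_decoys),
    perturb_amplitude = perturb_amplitude, field_width = field_width,
    plddt_profile = as.numeric(plddt_profile), seed = as.integer(seed)
  ), class = "struct_sim_spec")
}
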