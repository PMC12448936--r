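AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

## Idealized Calpha geometry: each named region is an alpha-helix (2.3 A
## radius, 1.5 A rise, 100 deg/residue) on a 7-fold bundle; helix axes
## alternate up/down like a transmembrane fold. Loop residues between
## helices are interpolated linearly between the flanking helix ends;
## terminal residues extend outward from the first/last helix.
.helix_bundle <- function(n_residues, regions) {
  xyz <- matrix(NA_real_, n_residues, 3)
  for (k in seq_along(regions)) {
    rng <- regions[[k]]
    idx <- seq.int(rng[1], rng[2])
    j <- seq_along(idx) - 1L
    len <- length(idx)
    ang0 <- 2 * pi * (k - 1) / length(regions)
    cx <- 11 * cos(ang0); cy <- 11 * sin(ang0)
    up <- k %% 2L == 1L
    z <- if (up) 1.5 * j else 1.5 * (len - 1L - j)
    theta <- (100 * pi / 180) * j
    xyz[idx, ] <- cbind(cx + 2.3 * cos(theta), cy + 2.3 * sin(theta), z)
  }
  placed <- which(!is.na(xyz[, 1]))
  first <- min(placed); last <- max(placed)
  gaps <- which(is.na(xyz[, 1]))
  for (i in gaps) {
    if (i < first) {            # N-terminal tail: radiate outward
      d <- xyz[first, ] - c(0, 0, xyz[first, 3])
      d <- d / sqrt(sum(d[1:2]^2))
      xyz[i, ] <- xyz[first, ] + d * 3.8 * (first - i)
    } else if (i > last) {      # C-terminal tail
      d <- xyz[last, ] - c(0, 0, xyz[last, 3])
      d <- d / sqrt(sum(d[1:2]^2))
      xyz[i, ] <- xyz[last, ] + d * 3.8 * (i - last)
    } else {                    # loop: interpolate between flanking helices
      lo <- max(placed[placed < i]); hi <- min(placed[placed > i])
      w <- (i - lo) / (hi - lo)
      xyz[i, ] <- (1 - w) * xyz[lo, ] + w * xyz[hi, ]
    }
  }
  xyz
}

#' Simulate a background/target structure-model pair with planted causal
#' substitutions
#'
#' Builds an idealized seven-helix Calpha bundle (the background paralog)
#' and a target copy whose S5-S6 coordinates are displaced by Gaussian
#' fields (width `field_width` residues, amplitude `perturb_amplitude`
#' Angstrom) centered on each causal position; displacement is truncated
#' to the S5-S6 residue union so the two models are bitwise identical
#' everywhere else. Sequences differ at the causal positions plus
#' `n_decoys` structurally silent decoys, mimicking a paralog pair where
#' only a minority of the residue differences move the binding pocket.
#'
#' @param spec a [struct_sim_spec()].
#' @return a list of class `struct_pair` with elements `background` and
#'   `target` (both [structure_model()]), plus the per-position
#'   displacement `fields`, the `candidates` (causal + decoy positions),
#'   and the originating `spec`.
#' @export
gen_structure_pair <- function(spec) {
  stopifnot(inherits(spec, "struct_sim_spec"))
  n <- spec$n_residues
  base_xyz <- .helix_bundle(n, spec$regions)
  s56 <- c(seq.int(spec$regions$S5[1], spec$regions$S5[2]),
           seq.int(spec$regions$S6[1], spec$regions$S6[2]))

  with_seed(spec$seed, {
    background_seq <- sample(AA_ALPHABET, n, replace = TRUE)

    fields <- list()
    for (p in spec$causal_positions) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      g <- exp(-((seq_len(n) - p)^2) / (2 * spec$field_width^2))
      g[-s56] <- 0
      fields[[as.character(p)]] <- outer(g, u) * spec$perturb_amplitude
    }

    free <- setdiff(seq_len(n), spec$causal_positions)
    decoys <- sort(sample(free, spec$n_decoys))
    target_seq <- background_seq
    for (p in c(spec$causal_positions, decoys))
      target_seq[p] <- sample(setdiff(AA_ALPHABET, background_seq[p]), 1L)

    target_xyz <- base_xyz
    for (f in fields) target_xyz <- target_xyz + f

    background <- structure_model(xyz = base_xyz, sequence = background_seq,
                                  plddt = spec$plddt_profile,
                                  model_id = "background")
    target <- structure_model(xyz = target_xyz, sequence = target_seq,
                              plddt = spec$plddt_profile,
                              model_id = "target")
    structure(list(background = background, target = target,
                   fields = fields,
                   causal_positions = spec$causal_positions,
                   decoy_positions = decoys, spec = spec),
              class = "struct_pair")
  })
}

#' Deterministic mock structure-prediction backend
#'
#' Stands in for a folding engine in tests and simulations. The returned
#' predictor is a pure function of the input sequence: it emits the
#' background bundle coordinates plus, for each causal position at which
#' the query sequence carries the target's residue, that position's
#' displacement field. Confidence scores come from the simulation spec's
#' pLDDT profile. Feeding it the background sequence reproduces the
#' background model; feeding it the target sequence reproduces the target.
#'
#' @param pair a `struct_pair` from [gen_structure_pair()].
#' @return a function `(sequence) -> structure_model` satisfying the
#'   screen's backend contract (see [run_screen()]).
#' @export
mock_predictor <- function(pair) {
  stopifnot(inherits(pair, "struct_pair"))
  base_xyz <- pair$background$xyz
  target_seq <- pair$target$sequence
  plddt <- pair$background$plddt
  fields <- pair$fields
  causal <- pair$causal_positions
  n <- nrow(base_xyz)
  function(sequence) {
    sequence <- as_residue_vector(sequence)
    if (length(sequence) != n)
      stop(sprintf("predictor expects a %d-residue sequence, got %d",
                   n, length(sequence)))
    xyz <- base_xyz
    for (p in causal)
      if (sequence[p] == target_seq[p])
        xyz <- xyz + fields[[as.character(p)]]
    structure_model(xyz = xyz, sequence = sequence, plddt = plddt,
                    model_id = "predicted")
  }
}
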