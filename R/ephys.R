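#' A single-sensillum recording trial
#'
#' Timestamped extracellular spike events for one stimulation trial, with
#' stimulus timing and recording labels.
#'
#' @param spike_times sorted spike timestamps in seconds (>= 0).
#' @param stimulus_onset stimulus onset, seconds; must be >= 0.5 s so a
#'   0.5-s pre-stimulus baseline window exists.
#' @param stimulus_duration stimulus duration, seconds (1 s air pulse).
#' @param sensillum,neuron,odorant,concentration,solvent trial labels:
#'   sensillum id, neuron id ("a"/"b"), odorant name, vol/vol dilution,
#'   and whether this is a solvent-control trial.
#' @param class_truth optional ground-truth sensillum class (simulations).
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(spike_times, stimulus_onset, stimulus_duration = 1,
                        sensillum = "s1", neuron = "a", odorant = "odor",
                        concentration = 0.01, solvent = FALSE,
                        class_truth = NA_character_) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("'spike_times' must be sorted ascending")
  if (length(spike_times) && spike_times[1] < 0)
    stop("'spike_times' must be >= 0")
  if (stimulus_onset < 0.5)
    stop("'stimulus_onset' must be >= 0.5 s (baseline window must exist)")
  structure(list(spike_times = spike_times, stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration, sensillum = sensillum,
                 neuron = neuron, odorant = odorant,
                 concentration = concentration, solvent = solvent,
                 class_truth = class_truth),
            class = "spike_train")
}

#' Net odor-evoked response of one trial, in spikes/s
#'
#' Counts spikes in the 0.5-s response window starting 0.2 s after
#' stimulus onset, subtracts the count in the 0.5-s baseline window
#' immediately preceding onset, and doubles the difference to express it
#' per second. Both windows are closed on the left and open on the right,
#' so a spike exactly on a boundary belongs to the earlier window. The
#' result can be negative (suppression below baseline).
#'
#' @param train a [spike_train()].
#' @return net response in spikes/s.
#' @export
net_response <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  t0 <- train$stimulus_onset
  s <- train$spike_times
  n_resp <- sum(s >= t0 + 0.2 & s < t0 + 0.7)
  n_base <- sum(s >= t0 - 0.5 & s < t0)
  2 * (n_resp - n_base)
}

#' Control-subtracted response panel
#'
#' Computes the net response of every trial and subtracts, per sensillum,
#' the mean net response of that sensillum's solvent-control trials from
#' each odorant response. Negative values are retained.
#'
#' @param trains list of [spike_train()] objects; every sensillum needs at
#'   least one solvent trial.
#' @return a `response_panel`: a numeric matrix (sensillum x odorant) of
#'   control-subtracted net spikes/s, with per-sensillum metadata in
#'   `attr(, "info")` (including ground-truth class labels when the
#'   trains came from the simulator). The solvent column is consumed by
#'   the subtraction and absent from the panel. Repeated trials of the
#'   same sensillum-odorant pair are averaged.
#' @export
control_subtract <- function(trains) {
  stopifnot(length(trains) > 0,
            all(vapply(trains, inherits, logical(1), "spike_train")))
  sens <- vapply(trains, function(t) t$sensillum, character(1))
  od <- vapply(trains, function(t) t$odorant, character(1))
  solv <- vapply(trains, function(t) t$solvent, logical(1))
  net <- vapply(trains, net_response, numeric(1))

  sensilla <- unique(sens)
  missing <- sensilla[!sensilla %in% sens[solv]]
  if (length(missing))
    stop("no solvent-control trial for sensillum: ",
         paste(missing, collapse = ", "))
  solvent_mean <- tapply(net[solv], sens[solv], mean)

  odorants <- unique(od[!solv])
  panel <- matrix(NA_real_, length(sensilla), length(odorants),
                  dimnames = list(sensilla, odorants))
  for (s in sensilla) for (o in odorants) {
    i <- !solv & sens == s & od == o
    if (any(i)) panel[s, o] <- mean(net[i]) - solvent_mean[[s]]
  }
  info <- data.frame(
    sensillum = sensilla,
    class_truth = vapply(sensilla, function(s)
      trains[[match(s, sens)]]$class_truth, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(panel, info = info, class = c("response_panel", "matrix", "array"))
}

#' Spike ratio of an aversive over an attractive ligand response
#'
#' `r_bitc / (r_bitc + r_ghex)` on control-subtracted net responses. The
#' summed denominator is used because the attractant response can come out
#' negative after control subtraction; when the denominator is <= 0 the
#' ratio is undefined and `NA` is returned rather than an error.
#'
#' @param r_bitc,r_ghex control-subtracted net responses (spikes/s) to the
#'   aversive (BITC) and attractive (gamma-hexalactone) ligand.
#' @return the ratio, or `NA_real_` when undefined.
#' @export
spike_ratio <- function(r_bitc, r_ghex) {
  denom <- r_bitc + r_ghex
  ifelse(denom <= 0, NA_real_, r_bitc / denom)
}

#' Classify sensilla into functional types from their response profiles
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances between response vectors) of the panel rows, cut at
#' `n_classes`. The procedure is deterministic and invariant to row order;
#' labels are renumbered by first appearance in the input so they are
#' stable, but label identity is arbitrary (a partition, not a naming).
#'
#' @param panel a `response_panel` from [control_subtract()], or any
#'   numeric matrix of sensilla x odorant responses without missing values.
#' @param n_classes number of functional classes to cut at (default 3,
#'   the number of palp basiconic sensillum types).
#' @return integer class labels named by sensillum.
#' @export
classify_sensilla <- function(panel, n_classes = 3L) {
  m <- unclass(panel)
  attr(m, "info") <- NULL
  if (anyNA(m)) stop("panel has missing odorant responses; complete rows required")
  if (n_classes > nrow(m))
    stop("n_classes exceeds the number of sensilla")
  ord <- order(rownames(m))            # row-order invariance
  hc <- stats::hclust(stats::dist(m[ord, , drop = FALSE]), method = "ward.D2")
  lab <- stats::cutree(hc, k = n_classes)[match(rownames(m), rownames(m)[ord])]
  lab <- match(lab, unique(lab))       # renumber by first appearance
  names(lab) <- rownames(m)
  lab
}
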