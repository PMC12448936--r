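#' Simulate behavioral assay tables
#'
#' Generates the three behavioral input families with known ground truth:
#'
#' * mobility: per-fly immobilization times drawn from an exponential
#'   with the arm's hazard (per minute), discretized upward to the 10-min
#'   observation grid and right-censored at 60 min; immobility is treated
#'   as absorbing, so mobile counts are non-increasing;
#' * tube choice: at each time point of the 5-min grid (5..35 plus
#'   65 min) each released fly participates with probability
#'   `participation` and, given participation, sits in the odor tube with
#'   probability `choice_prob`;
#' * feeding: per-vial counts over the 5-point score categories
#'   (0, 0.25, 0.5, 1, 2) drawn from a multinomial with probabilities
#'   `feeding_dist`.
#'
#' @param choice_prob probability a participating fly chooses the odor
#'   side (0.5 = no preference).
#' @param hazard_map named numeric vector of immobilization hazards per
#'   minute, one per arm (e.g. `c(control = 0, treatment = 0.05)`).
#' @param feeding_dist probability vector of length 5 over the score
#'   categories, or a named list of such vectors (one per condition).
#' @param seed integer seed.
#' @param n_flies flies per vial / per assay (default 10).
#' @param n_assays replicate assays (choice) or vials (mobility, feeding)
#'   per condition.
#' @param participation probability a fly makes a choice at a time point.
#' @return a list with data frames `mobility` (arm, vial, time_min,
#'   mobile, total), `choice` (assay, time_min, odor, control, released)
#'   and `feeding` (condition, day, vial plus category counts n0..n2).
#' @export
gen_behavior_tables <- function(choice_prob = 0.5,
                                hazard_map = c(control = 0, treatment = 0.05),
                                feeding_dist = c(0.1, 0.2, 0.3, 0.25, 0.15),
                                seed,
                                n_flies = 10L, n_assays = 10L,
                                participation = 0.8) {
  stopifnot(choice_prob >= 0, choice_prob <= 1, all(hazard_map >= 0),
            participation >= 0, participation <= 1)
  if (!is.list(feeding_dist)) feeding_dist <- list(test = feeding_dist)
  stopifnot(all(vapply(feeding_dist, length, 1L) == 5L))
  grid10 <- seq(10, 60, by = 10)
  grid5 <- c(seq(5, 35, by = 5), 65)

  with_seed(seed, {
    ## mobility: continuous exponential immobilization times, read off on
    ## the 10-min grid; time recorded is the first grid point at which the
    ## fly is scored immobile
    mobility <- do.call(rbind, lapply(names(hazard_map), function(arm) {
      h <- hazard_map[[arm]]
      do.call(rbind, lapply(seq_len(n_assays), function(v) {
        t_im <- if (h == 0) rep(Inf, n_flies) else stats::rexp(n_flies, h)
        t_grid <- 10 * ceiling(t_im / 10)
        data.frame(arm = arm, vial = v, time_min = grid10,
                   mobile = vapply(grid10, function(tt)
                     sum(t_grid > tt), integer(1)),
                   total = n_flies)
      }))
    }))

    choice <- do.call(rbind, lapply(seq_len(n_assays), function(a) {
      do.call(rbind, lapply(grid5, function(tt) {
        chose <- stats::rbinom(1L, n_flies, participation)
        odor <- stats::rbinom(1L, chose, choice_prob)
        data.frame(assay = a, time_min = tt, odor = odor,
                   control = chose - odor, released = n_flies)
      }))
    }))

    feeding <- do.call(rbind, lapply(names(feeding_dist), function(cond) {
      do.call(rbind, lapply(seq_len(n_assays), function(v) {
        counts <- as.integer(stats::rmultinom(1L, n_flies,
                                              feeding_dist[[cond]]))
        data.frame(condition = cond, day = ((v - 1L) %% 4L) + 1L, vial = v,
                   n0 = counts[1], n0.25 = counts[2], n0.5 = counts[3],
                   n1 = counts[4], n2 = counts[5])
      }))
    }))

    list(mobility = mobility, choice = choice, feeding = feeding)
  })
}
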