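#' Simulate a dose-response series
#'
#' Responses follow a two-parameter logistic in concentration,
#' `max_response / (1 + (true_ec50 / x)^hill)`, plus Gaussian noise with
#' standard deviation `noise_sd`, truncated below at `-max_response`.
#'
#' @param spec a [dose_sim_spec()].
#' @param chemical,species labels carried on the output series.
#' @return a `dose_response_series` (see [dose_response_series()]).
#' @export
gen_dose_response <- function(spec, chemical = "odorant", species = "sp") {
  stopifnot(inherits(spec, "dose_sim_spec"))
  x <- rep(spec$concentrations, each = spec$replicates)
  mu <- spec$max_response / (1 + (spec$true_ec50 / x)^spec$hill)
  y <- with_seed(spec$seed, mu + stats::rnorm(length(mu), 0, spec$noise_sd))
  y <- pmax(y, -spec$max_response)
  dose_response_series(concentration = x, response = y,
                       chemical = chemical, species = species)
}
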