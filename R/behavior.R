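#' Percent mobile flies per time point
#'
#' @param mobile,total counts of mobile flies and flies present at each
#'   time point (vectors of equal length).
#' @return percentages, `100 * mobile / total`.
#' @export
percent_mobile <- function(mobile, total) {
  if (any(total <= 0)) stop("'total' must be positive")
  if (any(mobile > total) || any(mobile < 0))
    stop("'mobile' must lie in [0, total]")
  100 * mobile / total
}

#' Convert a gridded mobility table to immobilization times
#'
#' Immobility is treated as absorbing: a fly's event time is the first
#' grid time point at which it is scored immobile; flies still mobile at
#' the last observation are right-censored there. The resulting
#' time/event pairs feed [logrank_test()].
#'
#' @param record data frame with columns `time_min` (ascending grid),
#'   `mobile`, `total` for one vial.
#' @return data frame with columns `time`, `event` (1 = immobilized,
#'   0 = censored), one row per fly.
#' @export
mobility_to_survival <- function(record) {
  record <- record[order(record$time_min), , drop = FALSE]
  if (any(diff(record$mobile) > 0))
    stop("mobile counts must be non-increasing in time within a vial")
  n <- record$total[1]
  prev <- n
  out <- list()
  for (i in seq_len(nrow(record))) {
    newly <- prev - record$mobile[i]
    if (newly > 0)
      out[[length(out) + 1L]] <- data.frame(time = record$time_min[i],
                                            event = 1L)[rep(1, newly), ]
    prev <- record$mobile[i]
  }
  if (prev > 0)
    out[[length(out) + 1L]] <- data.frame(time = max(record$time_min),
                                          event = 0L)[rep(1, prev), ]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Choice-assay percentages
#'
#' From counts at one time point: the percentage of released insects that
#' made a choice for either tube,
#' `100 * (odor + control) / released`, and the percentage of choosers on
#' the odor side, `100 * odor / (odor + control)`. The odor-side
#' percentage is undefined (`NA`) when no fly chose; downstream tests
#' drop it as missing.
#'
#' @param odor,control,released counts in the odor tube, control tube,
#'   and the number released.
#' @return list with `pct_choice` and `pct_odor_side`.
#' @export
choice_metrics <- function(odor, control, released) {
  if (any(odor < 0 | control < 0) || any(odor + control > released))
    stop("counts must satisfy 0 <= odor + control <= released")
  chose <- odor + control
  list(pct_choice = 100 * chose / released,
       pct_odor_side = ifelse(chose == 0, NA_real_, 100 * odor / chose))
}

#' Participation-based assay exclusion
#'
#' An assay is discarded only if fewer than 40% of insects made a choice
#' at every time point; a single time point at or above 40% keeps it.
#'
#' @param pct_choice vector of percent-choice values over the assay's
#'   time points.
#' @param threshold exclusion threshold in percent (default 40).
#' @return `TRUE` to keep the assay, `FALSE` to discard it.
#' @export
apply_exclusion <- function(pct_choice, threshold = 40) {
  if (length(pct_choice) == 0) stop("empty assay time series")
  any(pct_choice >= threshold)
}

#' Feeding score of one vial
#'
#' Weighted mean of the 5-point dye scale:
#' `(0*n0 + 0.25*n0.25 + 0.5*n0.5 + 1*n1 + 2*n2) / N`.
#'
#' @param n0,n0.25,n0.5,n1,n2 counts of flies per score category.
#' @return score in [0, 2].
#' @export
feeding_score <- function(n0, n0.25, n0.5, n1, n2) {
  counts <- cbind(n0, n0.25, n0.5, n1, n2)
  if (any(counts < 0)) stop("category counts must be >= 0")
  N <- rowSums(counts)
  if (any(N == 0)) stop("empty vial: N = 0")
  as.numeric(counts %*% c(0, 0.25, 0.5, 1, 2) / N)
}

#' Normalize feeding scores to same-day controls
#'
#' Each test vial's score is divided by the mean score of control vials
#' assayed on the same day for the same genotype; the null value is 1
#' (no aversion or enhancement). The downstream test is a one-sample
#' signed rank against 1.
#'
#' @param test data frame with columns `score`, `day`, `genotype`.
#' @param control data frame with the same columns.
#' @return `test` with an added `norm_score` column.
#' @export
normalize_feeding <- function(test, control) {
  need <- c("score", "day", "genotype")
  stopifnot(all(need %in% names(test)), all(need %in% names(control)))
  key <- function(d) paste(d$day, d$genotype, sep = "\r")
  ctrl_mean <- tapply(control$score, key(control), mean)
  k <- key(test)
  if (any(!k %in% names(ctrl_mean))) {
    miss <- unique(test[!k %in% names(ctrl_mean), c("day", "genotype")])
    stop("no same-day control vials for: ",
         paste(sprintf("day %s / %s", miss$day, miss$genotype), collapse = "; "))
  }
  test$norm_score <- test$score / as.numeric(ctrl_mean[k])
  test
}
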