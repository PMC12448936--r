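#' Reads-per-million normalization
#'
#' Scales each column (sample) of a gene x sample count matrix by its
#' library size: `count / colSums(counts) * 1e6`. The denominator is the
#' sum over all genes present in the table.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @return numeric matrix of RPM values with the same dimnames.
#' @export
rpm <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size in column(s): ",
                          paste(which(lib == 0), collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter genes on median log2(RPM + 1)
#'
#' A gene is retained when its median over replicates of
#' `log2(RPM + 1)` is at least `threshold` (strictly-below-threshold
#' genes are excluded) in at least one sample group - or in every group
#' when `all_groups = TRUE`.
#'
#' @param rpm_table RPM matrix from [rpm()].
#' @param groups factor/character vector assigning each column to a
#'   sample group (e.g. species x sex); a single group by default.
#' @param threshold exclusion threshold on the median log2(RPM + 1)
#'   scale (default 1).
#' @param all_groups require the criterion in every group instead of at
#'   least one.
#' @return character vector of retained gene names (or row indices when
#'   unnamed).
#' @export
filter_low_expression <- function(rpm_table, groups = NULL, threshold = 1,
                                  all_groups = FALSE) {
  rpm_table <- as.matrix(rpm_table)
  if (is.null(groups)) groups <- rep("all", ncol(rpm_table))
  stopifnot(length(groups) == ncol(rpm_table))
  lg <- log2(rpm_table + 1)
  med <- sapply(unique(groups), function(g)
    apply(lg[, groups == g, drop = FALSE], 1, stats::median))
  med <- matrix(med, nrow = nrow(rpm_table))
  pass <- med >= threshold
  keep <- if (all_groups) rowSums(pass) == ncol(pass) else rowSums(pass) > 0
  genes <- rownames(rpm_table)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(rpm_table)))
  genes[keep]
}

#' Receptor-positive cell-count ratios and species comparison
#'
#' Per animal, the ratio of receptor-positive neurons to co-receptor
#' (Orco)-positive neurons - the fraction of olfactory sensory neurons
#' expressing the receptor. Groups are compared with a two-sided
#' Mann-Whitney U test.
#'
#' @param records data frame with columns `species`, `positive`
#'   (receptor-positive count) and `orco` (Orco-positive count,
#'   `positive <= orco`, `orco > 0`).
#' @return list with `ratios` (records plus a `ratio` column) and `test`
#'   (an `np_test`; `NULL` when fewer than two species are present).
#' @export
cellcount_ratio <- function(records) {
  stopifnot(all(c("species", "positive", "orco") %in% names(records)))
  if (any(records$orco <= 0)) stop("Orco-positive count must be > 0")
  if (any(records$positive < 0 | records$positive > records$orco))
    stop("'positive' must lie in [0, orco]")
  records$ratio <- records$positive / records$orco
  sp <- unique(records$species)
  test <- if (length(sp) == 2)
    mann_whitney_u(records$ratio[records$species == sp[1]],
                   records$ratio[records$species == sp[2]])
  else NULL
  list(ratios = records, test = test)
}
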