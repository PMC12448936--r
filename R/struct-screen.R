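#' Confidence-reliable residue set
#'
#' Residues whose predicted local distance difference test score (pLDDT)
#' strictly exceeds the threshold; lower-confidence residues (typically
#' the N- and C-termini of receptor models) are unreliable and excluded
#' from superposition and RMSD.
#'
#' @param model a [structure_model()].
#' @param threshold pLDDT cutoff (default 70, strict).
#' @return integer vector of reliable residue indices.
#' @export
confidence_mask <- function(model, threshold = 70) {
  stopifnot(inherits(model, "structure_model"))
  which(model$plddt > threshold)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares Calpha superposition of `mobile` onto `reference` over a
#' residue mask: the closed-form SVD solution for the proper rotation
#' (det = +1) and translation minimizing the RMSD of paired coordinates.
#'
#' @param mobile,reference [structure_model()]s (or n x 3 coordinate
#'   matrices) with identical residue numbering over the mask.
#' @param residue_mask residue indices to fit on (default: all shared
#'   residues).
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `rmsd` (Angstrom, over the mask), and `transform(xyz)` applying the
#'   fit to arbitrary coordinates.
#' @export
kabsch_superpose <- function(mobile, reference, residue_mask = NULL) {
  P_all <- if (inherits(mobile, "structure_model")) mobile$xyz else as.matrix(mobile)
  Q_all <- if (inherits(reference, "structure_model")) reference$xyz else as.matrix(reference)
  if (is.null(residue_mask)) residue_mask <- seq_len(min(nrow(P_all), nrow(Q_all)))
  if (length(residue_mask) < 3)
    stop("need >= 3 residues in the superposition mask")
  P <- P_all[residue_mask, , drop = FALSE]
  Q <- Q_all[residue_mask, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) point set; superposition not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transform <- function(xyz) sweep(sweep(as.matrix(xyz), 2, pc) %*% t(R), 2, qc, "+")
  rmsd <- sqrt(mean(rowSums((transform(P) - Q)^2)))
  list(rotation = R, translation = qc - as.numeric(pc %*% t(R)),
       rmsd = rmsd, transform = transform, mask = residue_mask)
}

#' Regional RMSD under a global superposition
#'
#' Superposes `mobile` onto `reference` over `alignment_mask` once, then
#' measures the RMSD of each named region's masked residues under that
#' single global transform (no per-region refitting) - so a divergence
#' localized to one region shows up in that region's RMSD instead of
#' being absorbed by a local fit.
#'
#' @param mobile,reference [structure_model()]s.
#' @param regions named list of `c(start, end)` 1-based inclusive ranges.
#' @param alignment_mask residues to superpose on (default: residues
#'   with pLDDT > 70 in both models).
#' @return list with `rmsd` (named vector, Angstrom per region),
#'   `per_residue` (deviation profile in Angstrom, NA outside the mask),
#'   `global_rmsd` and the `superposition`.
#' @export
region_rmsd <- function(mobile, reference, regions, alignment_mask = NULL) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  if (is.null(alignment_mask))
    alignment_mask <- intersect(confidence_mask(mobile), confidence_mask(reference))
  sup <- kabsch_superpose(mobile, reference, alignment_mask)
  moved <- sup$transform(mobile$xyz)
  dev <- sqrt(rowSums((moved - reference$xyz)^2))
  per_residue <- rep(NA_real_, nrow(mobile$xyz))
  per_residue[alignment_mask] <- dev[alignment_mask]

  rmsd <- vapply(regions, function(rng) {
    idx <- intersect(seq.int(rng[1], rng[2]), alignment_mask)
    if (length(idx) == 0)
      stop("region empty after confidence masking")
    sqrt(mean(dev[idx]^2))
  }, numeric(1))
  list(rmsd = rmsd, per_residue = per_residue,
       global_rmsd = sup$rmsd, superposition = sup)
}

#' Residue differences between two aligned paralog sequences
#'
#' @param seq_a,seq_b equal-length one-letter sequences (pre-aligned
#'   paralogs); `seq_a` is the background, `seq_b` the donor.
#' @return data frame of substitution candidates with columns `position`,
#'   `from`, `to`, `label` (e.g. "A181D").
#' @export
diff_positions <- function(seq_a, seq_b) {
  a <- as_residue_vector(seq_a); b <- as_residue_vector(seq_b)
  if (length(a) != length(b))
    stop("sequences differ in length; align them first")
  pos <- which(a != b)
  data.frame(position = pos, from = a[pos], to = b[pos],
             label = paste0(a[pos], pos, b[pos]),
             stringsAsFactors = FALSE)
}

## Apply donor residues at the given candidate rows to a background
## sequence, checking the background residue matches.
apply_substitutions <- function(sequence, candidates) {
  sequence <- as_residue_vector(sequence)
  for (i in seq_len(nrow(candidates))) {
    p <- candidates$position[i]
    if (sequence[p] != candidates$from[i])
      stop(sprintf("background residue at %d is %s, expected %s",
                   p, sequence[p], candidates$from[i]))
    sequence[p] <- candidates$to[i]
  }
  sequence
}

#' Greedy in-silico substitution screen for a localized structural
#' divergence
#'
#' Searches for the minimal set of residue substitutions (donor residues
#' placed into the background paralog sequence) that abolishes the
#' structural difference between the predicted background structure and
#' a target paralog model in the named target regions (the S5-S6
#' ligand-binding helices by default).
#'
#' Each round predicts the structure of the background sequence carrying
#' the accepted substitutions plus one additional candidate, superposes
#' it onto the target over the confidence mask, and measures the target
#' regions' RMSD; the candidate giving the largest reduction is fixed
#' (ties broken by lowest position index). The screen stops when the
#' regional RMSD falls to the stop threshold - by default
#' `max(0.15, median RMSD of the non-target regions)`, i.e. "comparable
#' to the other regions" - when no candidate improves it, or when
#' candidates are exhausted. Accepted steps are strictly decreasing in
#' regional RMSD.
#'
#' @param background_seq background paralog sequence (e.g. Or42a3-like).
#' @param donor_seq donor paralog sequence supplying substitutions (e.g.
#'   Or42a4-like); same length.
#' @param target_model [structure_model()] of the donor paralog to match.
#' @param predictor backend: a pure function `(sequence) ->
#'   structure_model`, deterministic for a fixed input (see
#'   [mock_predictor()]). Results are cached per sequence within a run.
#' @param regions named list of helix ranges including the target
#'   regions.
#' @param target_regions names of the regions whose divergence is to be
#'   abolished (default `c("S5", "S6")`).
#' @param plddt_threshold confidence mask cutoff (default 70).
#' @param stop_threshold override for the stop rule (Angstrom).
#' @return object of class `screen_result`: `accepted` (candidate data
#'   frame, in acceptance order), `trajectory` (regional RMSD after each
#'   accepted step, starting from the unmutated background), `converged`,
#'   `threshold`, `evaluations` (full log: round, label, rmsd), and
#'   `baseline_rmsd` (per-region, unmutated background vs target).
#' @export
run_screen <- function(background_seq, donor_seq, target_model, predictor,
                       regions, target_regions = c("S5", "S6"),
                       plddt_threshold = 70, stop_threshold = NULL) {
  background_seq <- as_residue_vector(background_seq)
  donor_seq <- as_residue_vector(donor_seq)
  stopifnot(inherits(target_model, "structure_model"), is.function(predictor))
  if (!all(target_regions %in% names(regions)))
    stop("target_regions missing from 'regions'")
  candidates <- diff_positions(background_seq, donor_seq)

  cache <- new.env(parent = emptyenv())
  predict_cached <- function(sequence) {
    key <- paste(sequence, collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <- predictor(sequence)
    cache[[key]]
  }
  target_rmsd <- function(sequence) {
    model <- predict_cached(sequence)
    mask <- intersect(which(model$plddt > plddt_threshold),
                      which(target_model$plddt > plddt_threshold))
    rr <- region_rmsd(model, target_model, regions, alignment_mask = mask)
    idx <- unlist(lapply(regions[target_regions], function(r)
      intersect(seq.int(r[1], r[2]), mask)))
    combined <- sqrt(mean(rr$per_residue[idx]^2))
    list(combined = combined, per_region = rr$rmsd)
  }

  base <- target_rmsd(background_seq)
  others <- setdiff(names(regions), target_regions)
  threshold <- if (!is.null(stop_threshold)) stop_threshold
               else max(0.15, stats::median(base$per_region[others]))

  accepted <- candidates[0, ]
  trajectory <- base$combined
  evaluations <- data.frame(round = integer(0), label = character(0),
                            rmsd = numeric(0), stringsAsFactors = FALSE)
  current <- base$combined
  remaining <- candidates
  round_i <- 0L

  while (current > threshold && nrow(remaining) > 0) {
    round_i <- round_i + 1L
    rmsds <- vapply(seq_len(nrow(remaining)), function(i) {
      trial <- rbind(accepted, remaining[i, ])
      target_rmsd(apply_substitutions(background_seq, trial))$combined
    }, numeric(1))
    evaluations <- rbind(evaluations,
                         data.frame(round = round_i, label = remaining$label,
                                    rmsd = rmsds, stringsAsFactors = FALSE))
    best <- which(rmsds == min(rmsds))
    best <- best[which.min(remaining$position[best])]   # tie: lowest position
    if (rmsds[best] >= current) break                   # no reducer left
    accepted <- rbind(accepted, remaining[best, ])
    trajectory <- c(trajectory, rmsds[best])
    current <- rmsds[best]
    remaining <- remaining[-best, , drop = FALSE]
  }

  structure(list(accepted = accepted, trajectory = trajectory,
                 converged = current <= threshold, threshold = threshold,
                 final_rmsd = current, baseline_rmsd = base$per_region,
                 evaluations = evaluations,
                 target_regions = target_regions),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("In-silico substitution screen over %s\n",
              paste(x$target_regions, collapse = "-")))
  cat(sprintf("  stop threshold: %.3f A, converged: %s\n",
              x$threshold, x$converged))
  cat(sprintf("  regional RMSD: %.3f -> %.3f A in %d step(s)\n",
              x$trajectory[1], x$final_rmsd, nrow(x$accepted)))
  if (nrow(x$accepted))
    cat("  accepted:", paste(x$accepted$label, collapse = " + "), "\n")
  invisible(x)
}
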