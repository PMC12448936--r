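np_test <- function(statistic, p_value, method, exact, n,
                    alternative = "two.sided") {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = statistic, p_value = min(p_value, 1),
                 method = method, exact = exact, n = n,
                 alternative = alternative),
            class = "np_test")
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$method, x$alternative))
  cat(sprintf("  statistic = %.6g, p = %.6g, %s, n = %s\n",
              x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation",
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Tests the location of a sample against a hypothesized median `mu0`.
#' Values equal to `mu0` are dropped (Wilcoxon convention). The p-value
#' is exact (from the enumerated null distribution of the positive-rank
#' sum) for n <= 25 without ties in the absolute differences; otherwise
#' a normal approximation with tie correction and continuity correction
#' is used.
#'
#' @param values sample values.
#' @param mu0 null median (e.g. 50 for a random tube choice, 1 for
#'   normalized feeding scores).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return an `np_test` with statistic V (positive-rank sum).
#' @export
signed_rank_one_sample <- function(values, mu0 = 0,
                                   alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  d <- values[!is.na(values)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all values equal mu0; test undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0

  if (!ties && n <= 25) {
    p_less <- stats::psignrank(V, n)
    p_greater <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less, greater = p_greater)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- 0.5
    z_greater <- (V - mu - cc) / sqrt(sigma2)
    z_less <- (V - mu + cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_less),
                                           stats::pnorm(z_greater,
                                                        lower.tail = FALSE))),
                less = stats::pnorm(z_less),
                greater = stats::pnorm(z_greater, lower.tail = FALSE))
    exact <- FALSE
  }
  np_test(V, p, "Wilcoxon signed rank (one sample)", exact, n, alternative)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Exact p-values (from
#' the enumerated null of U) for n + m <= 20 without ties; otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y the two samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (`"greater"`
#'   means x tends larger than y).
#' @return an `np_test` with statistic U (number of (x, y) pairs with
#'   x > y, ties counted half).
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0) stop("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0

  if (!ties && n + m <= 20) {
    p_less <- stats::pwilcox(U, n, m)
    p_greater <- stats::pwilcox(U - 1, n, m, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_less, p_greater)),
                less = p_less, greater = p_greater)
    exact <- TRUE
  } else {
    N <- n + m
    mu <- n * m / 2
    tie_tab <- table(c(x, y))
    sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- 0.5
    p <- switch(alternative,
                two.sided = min(1, 2 * min(
                  stats::pnorm((U - mu + cc) / sqrt(sigma2)),
                  stats::pnorm((U - mu - cc) / sqrt(sigma2),
                               lower.tail = FALSE))),
                less = stats::pnorm((U - mu + cc) / sqrt(sigma2)),
                greater = stats::pnorm((U - mu - cc) / sqrt(sigma2),
                                       lower.tail = FALSE))
    exact <- FALSE
  }
  np_test(U, p, "Mann-Whitney U", exact, c(n, m), alternative)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across k >= 3 groups, followed by
#' Dunn's z for every pair with multiplicity adjustment (Bonferroni by
#' default).
#'
#' @param groups named list of numeric vectors (>= 3 groups, none empty).
#' @param correction multiplicity adjustment passed to
#'   [stats::p.adjust()].
#' @return list with `omnibus` (an `np_test` for H, chi-square df = k-1)
#'   and `pairwise` (data frame: group1, group2, z, p, p_adj).
#' @export
kruskal_wallis_dunn <- function(groups, correction = "bonferroni") {
  if (length(groups) < 3) stop("need >= 3 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ni <- vapply(groups, length, 1L)
  N <- sum(ni)
  r <- rank(unlist(groups, use.names = FALSE))
  grp <- rep(names(groups), ni)
  Ri <- tapply(r, factor(grp, levels = names(groups)), sum)

  H <- 12 / (N * (N + 1)) * sum(Ri^2 / ni) - 3 * (N + 1)
  tie_tab <- table(unlist(groups, use.names = FALSE))
  tie_corr <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (tie_corr > 0) H <- H / tie_corr
  p_omni <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  omnibus <- np_test(H, p_omni, "Kruskal-Wallis", FALSE, ni)

  Rbar <- Ri / ni
  dunn_var <- N * (N + 1) / 12 - sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    (Rbar[[pr[1]]] - Rbar[[pr[2]]]) /
      sqrt(dunn_var * (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
  })
  p_pair <- 2 * stats::pnorm(-abs(z))
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p = p_pair,
                         p_adj = stats::p.adjust(p_pair, method = correction),
                         stringsAsFactors = FALSE)
  list(omnibus = omnibus, pairwise = pairwise)
}

#' Log-rank (Mantel-Cox) test for two arms
#'
#' Compares event-time distributions (e.g. immobilization under an
#' odorant vs solvent) via the Mantel-Cox chi-square with 1 df:
#' observed-minus-expected events in arm 1 summed over distinct event
#' times, scaled by the hypergeometric variance.
#'
#' @param time event or censoring times.
#' @param event 1 = event (immobilized), 0 = right-censored.
#' @param arm two-level grouping vector.
#' @return an `np_test` with the chi-square statistic.
#' @export
logrank_test <- function(time, event, arm) {
  stopifnot(length(time) == length(event), length(time) == length(arm))
  arm <- as.factor(arm)
  if (nlevels(arm) != 2) stop("exactly two arms required")
  if (sum(event) == 0) stop("no events in either arm")
  a1 <- levels(arm)[1]
  ev_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tj in ev_times) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    n1j <- sum(at_risk & arm == a1)
    dj <- sum(time == tj & event == 1)
    d1j <- sum(time == tj & event == 1 & arm == a1)
    O1 <- O1 + d1j
    E1 <- E1 + dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  np_test(chi2, stats::pchisq(chi2, df = 1, lower.tail = FALSE),
          "Log-rank (Mantel-Cox)", FALSE, as.integer(table(arm)))
}
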