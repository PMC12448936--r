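## Independent brute-force oracles used to validate the package's exact
## statistics and superposition code. These deliberately share no code
## with the implementation under test.

## Full 2^n enumeration of the signed-rank null: every sign assignment of
## the ranked absolute differences is equally likely under H0.
oracle_signed_rank <- function(values, mu0 = 0, alternative = "two.sided") {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_V <- as.numeric(signs %*% r)
  p_greater <- mean(null_V >= V)
  p_less <- mean(null_V <= V)
  switch(alternative,
         greater = p_greater, less = p_less,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

## Full choose(n+m, n) enumeration of the Mann-Whitney null: every
## placement of the x sample among the pooled ranks is equally likely.
oracle_mann_whitney <- function(x, y, alternative = "two.sided") {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  pool <- sort(r)
  combs <- utils::combn(n + m, n)
  null_U <- apply(combs, 2, function(i) sum(pool[i]) - n * (n + 1) / 2)
  p_greater <- mean(null_U >= U)
  p_less <- mean(null_U <= U)
  switch(alternative,
         greater = p_greater, less = p_less,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

## Brute-force rigid superposition: coarse search over Euler angles
## (translation handled by centroid alignment, which is optimal for any
## fixed rotation), polished with Nelder-Mead. Returns the minimal RMSD.
oracle_rigid_rmsd <- function(P, Q, grid_n = 10) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    Rz2 <- matrix(c(ca[3], -sa[3], 0, sa[3], ca[3], 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  f <- function(ang) sqrt(mean(rowSums((Pc %*% t(rot(ang)) - Qc)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = grid_n),
                      b = seq(0, pi, length.out = grid_n),
                      c = seq(0, 2 * pi, length.out = grid_n))
  vals <- apply(grid, 1, f)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  opt <- stats::optim(opt$par, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  opt$value
}

## Monte-Carlo permutation null for the two-arm log-rank statistic.
oracle_logrank_perm_p <- function(time, event, arm, n_perm = 2000, seed = 1) {
  obs <- logrank_test(time, event, arm)$statistic
  set.seed(seed)
  perm <- replicate(n_perm, logrank_test(time, event, sample(arm))$statistic)
  mean(perm >= obs)
}

## Random rigid transform of a coordinate matrix.
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  ca <- cos(ang); sa <- sin(ang)
  R <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, runif(3, -20, 20), "+")
}

## Exact logistic series on the percent-of-maximum scale.
percent_logistic_series <- function(ec50, hill, concentrations) {
  dose_response_series(concentrations,
                       100 / (1 + (ec50 / concentrations)^hill),
                       normalized = TRUE)
}
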