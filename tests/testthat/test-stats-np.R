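test_that("signed-rank exact path matches the full 2^n enumeration", {
  ## all values above mu0, n = 6, one-sided: p = 1/2^6
  p <- signed_rank_one_sample(1:6, 0, "greater")
  expect_true(p$exact)
  expect_equal(p$p_value, 1 / 64)

  ## symmetric sample around mu0 sits at the null center
  sym <- signed_rank_one_sample(c(-3, -2, -1, 1, 2, 3) + 10, 10)
  expect_gt(sym$p_value, 0.9)

  ## 50 random small untied samples against the brute-force oracle
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:11, 1)
    v <- round(rnorm(n, sd = 3), 6) + runif(n, -1e-4, 1e-4)
    alt <- sample(c("two.sided", "less", "greater"), 1)
    expect_equal(signed_rank_one_sample(v, 0, alt)$p_value,
                 oracle_signed_rank(v, 0, alt), info = paste("case", i))
  }
  expect_error(signed_rank_one_sample(rep(5, 4), 5), "undefined")
})

test_that("Mann-Whitney exact path matches the full enumeration", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_true(r$exact)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 orderings

  ## identical multisets carry no evidence (ties -> approximate path)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p_value, 0.9)

  set.seed(202)
  for (i in 1:50) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- rnorm(n); y <- rnorm(m, mean = runif(1, -1, 1))
    alt <- sample(c("two.sided", "less", "greater"), 1)
    expect_equal(mann_whitney_u(x, y, alt)$p_value,
                 oracle_mann_whitney(x, y, alt), info = paste("case", i))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("approximate paths agree with exact paths at boundary sizes", {
  set.seed(33)
  for (i in 1:20) {
    v <- rnorm(25)   # boundary of the signed-rank exact path
    p_exact <- signed_rank_one_sample(v, 0)$p_value
    d <- v
    r <- rank(abs(d)); V <- sum(r[d > 0]); n <- length(d)
    z <- (V - n * (n + 1) / 4 - 0.5 * sign(V - n * (n + 1) / 4)) /
      sqrt(n * (n + 1) * (2 * n + 1) / 24)
    p_approx <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)   # n + m = 20 boundary
    p_exact <- mann_whitney_u(x, y)$p_value
    r <- rank(c(x, y)); U <- sum(r[1:10]) - 55
    z <- (U - 50 - 0.5 * sign(U - 50)) / sqrt(10 * 10 * 21 / 12)
    p_approx <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("results agree with the standard library implementations", {
  set.seed(7)
  v <- rnorm(12); x <- rnorm(9); y <- rnorm(11, 0.5)
  expect_equal(signed_rank_one_sample(v, 0)$p_value,
               wilcox.test(v, mu = 0, exact = TRUE)$p.value)
  expect_equal(mann_whitney_u(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  expect_equal(kruskal_wallis_dunn(g)$omnibus$statistic,
               unname(kruskal.test(g)$statistic))
  skip_if_not_installed("survival")
  set.seed(8)
  tm <- c(rexp(30, 0.05), rexp(30, 0.1)); ev <- rbinom(60, 1, 0.8)
  arm <- rep(c("a", "b"), each = 30)
  sd_ref <- survival::survdiff(survival::Surv(tm, ev) ~ arm)
  expect_equal(logrank_test(tm, ev, arm)$statistic,
               unname(sd_ref$chisq), tolerance = 1e-8)
})

test_that("Kruskal-Wallis/Dunn behaves on identical groups and textbook ranks", {
  g_same <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(1, 5, 9))
  expect_lt(kruskal_wallis_dunn(g_same)$omnibus$statistic, 1e-8)

  ## hand computation, no ties: groups {1,2}, {3,4}, {5,6};
  ## rank sums 3, 7, 11; H = 12/(6*7) * (9/2 + 49/2 + 121/2) - 3*7 = 4.571428...
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  res <- kruskal_wallis_dunn(g)
  expect_equal(res$omnibus$statistic, 12 / 42 * (9 + 49 + 121) / 2 - 21)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))
  expect_error(kruskal_wallis_dunn(list(1:3, 4:6)), ">= 3")
  expect_error(kruskal_wallis_dunn(list(1:3, 4:6, numeric(0))), "empty")
})

test_that("Dunn familywise rejections do not exceed omnibus rejections under the null", {
  set.seed(404)
  n_rep <- 500
  omni <- dunn <- 0L
  for (i in seq_len(n_rep)) {
    g <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    res <- kruskal_wallis_dunn(g)
    if (res$omnibus$p_value < 0.05) omni <- omni + 1L
    if (any(res$pairwise$p_adj < 0.05)) dunn <- dunn + 1L
  }
  expect_lte(dunn / n_rep, omni / n_rep + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("log-rank matches a hand-computed single-event-time case", {
  ## all treatment flies immobilized at t = 10, all controls censored at 60:
  ## one event time, O1 = 10, E1 = 10 * (10/20), V = 10 * .5 * .5 * (10/19)
  tm <- c(rep(10, 10), rep(60, 10))
  ev <- c(rep(1, 10), rep(0, 10))
  arm <- rep(c("trt", "ctl"), each = 10)
  lr <- logrank_test(tm, ev, arm)
  O1 <- 10; E1 <- 5; V <- 10 * 0.25 * 10 / 19
  expect_equal(lr$statistic, (O1 - E1)^2 / V)
  expect_error(logrank_test(tm, rep(0, 20), arm), "no events")
  expect_error(logrank_test(tm, ev, rep("a", 20)), "two arms")
})

test_that("log-rank p agrees with its permutation null", {
  set.seed(55)
  tm <- c(rexp(20, 0.08), rexp(20, 0.04))
  tm <- pmin(tm, 60)
  ev <- as.integer(tm < 60)
  arm <- rep(c("trt", "ctl"), each = 20)
  p_chisq <- logrank_test(tm, ev, arm)$p_value
  p_perm <- oracle_logrank_perm_p(tm, ev, arm, n_perm = 4000, seed = 9)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(p_chisq - p_perm), 4 * mc_se + 0.01)
})

test_that("tests are invariant to input order and group relabeling", {
  set.seed(66)
  v <- rnorm(15)
  expect_equal(signed_rank_one_sample(v, 0)$p_value,
               signed_rank_one_sample(rev(v), 0)$p_value)
  x <- rnorm(8); y <- rnorm(9)
  expect_equal(mann_whitney_u(x, y, "greater")$p_value,
               mann_whitney_u(y, x, "less")$p_value)
  tm <- rexp(30, 0.05); ev <- rbinom(30, 1, 0.9)
  arm <- rep(c("a", "b"), 15)
  expect_equal(logrank_test(tm, ev, arm)$statistic,
               logrank_test(tm, ev, ifelse(arm == "a", "zzz", "aaa"))$statistic)
})

test_that("empirical type-I error sits at the nominal level for every test", {
  n_rep <- 500
  alpha <- 0.05
  ci <- 3 * sqrt(alpha * (1 - alpha) / n_rep)
  set.seed(777)
  rej <- c(signed_rank = 0L, mann_whitney = 0L, kruskal = 0L, logrank = 0L)
  for (i in seq_len(n_rep)) {
    if (signed_rank_one_sample(rnorm(15), 0)$p_value < alpha)
      rej["signed_rank"] <- rej["signed_rank"] + 1L
    if (mann_whitney_u(rnorm(12), rnorm(12))$p_value < alpha)
      rej["mann_whitney"] <- rej["mann_whitney"] + 1L
    if (kruskal_wallis_dunn(list(rnorm(8), rnorm(8), rnorm(8)))$omnibus$p_value < alpha)
      rej["kruskal"] <- rej["kruskal"] + 1L
    tm <- rexp(60, 0.05); ev <- rep(1L, 60); arm <- rep(c("a", "b"), 30)
    if (logrank_test(tm, ev, arm)$p_value < alpha)
      rej["logrank"] <- rej["logrank"] + 1L
  }
  rates <- rej / n_rep
  for (nm in names(rates)) {
    expect_gt(rates[[nm]], alpha - ci)
    expect_lt(rates[[nm]], alpha + ci)
  }
})
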