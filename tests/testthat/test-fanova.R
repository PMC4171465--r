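test_that("the F-type statistic matches hand computation on a toy curve set", {
  # 4 subjects, T = 2: group A curves (0,0) and (2,2); group B (1,1), (3,3)
  X <- rbind(c(0, 0), c(2, 2), c(1, 1), c(3, 3))
  groups <- c("A", "A", "B", "B")
  st <- fanova_statistic(X, groups)
  expect_equal(st$SSR_int, 1)   # Delta = 1/2, group means 1 and 2, grand 1.5
  expect_equal(st$SSE_int, 4)
  expect_equal(st$F_stat, 0.5)
  expect_equal(dim(st$pooled_cov), c(2, 2))
  expect_equal(sum(diag(st$pooled_cov)), st$trace_cov)

  # all-identical curves: SSR = 0, F = 0
  X0 <- matrix(1, 6, 4)
  st0 <- fanova_statistic(X0, rep(c("A", "B"), 3))
  expect_equal(st0$F_stat, 0)
  expect_true(st0$degenerate)

  expect_error(fanova_statistic(X, c("A", "A", "A", "B")), "at least 2")
})

test_that("T = 1 reduces exactly to classical one-way ANOVA", {
  set.seed(51)
  for (k in 2:3) {
    groups <- factor(rep(letters[1:k], times = c(7, 9, 8)[1:k]))
    x <- rnorm(length(groups))
    st <- fanova_statistic(matrix(x, ncol = 1), groups)
    sat <- satterthwaite_pvalue(st$F_stat, st, k = k, n = length(x))
    a <- anova(lm(x ~ groups))
    expect_equal(st$F_stat, a[1, "F value"], tolerance = 1e-12)
    expect_equal(sat$kappa_hat, 1, tolerance = 1e-12)
    expect_equal(sat$p_asymptotic, a[1, "Pr(>F)"], tolerance = 1e-12)
  }
})

test_that("the adjustment factor is the trace ratio, with exact bias removal", {
  sat <- satterthwaite_pvalue(1, diag(c(2, 1)), k = 2, n = 20,
                              method = "naive")
  expect_equal(sat$kappa_hat, 9 / 5)
  expect_equal(sat$df1, 1.8)
  expect_equal(sat$df2, 18 * 1.8)

  # rank-one covariance: kappa = 1 under both estimators, classical F tail
  v <- c(1, 2, 3)
  for (m in c("naive", "bias-reduced")) {
    sat1 <- satterthwaite_pvalue(2.5, outer(v, v), k = 2, n = 30, method = m)
    expect_equal(sat1$kappa_hat, 1, tolerance = 1e-10)
    expect_equal(sat1$p_asymptotic, pf(2.5, 1, 28, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # white-noise curves: true kappa = T; the naive plug-in shrinks it by
  # about 1 + T/(n-k) while the bias-reduced estimator recovers T
  set.seed(58)
  Tn <- 40; n <- 50
  kap <- replicate(200, {
    st <- fanova_statistic(matrix(rnorm(n * Tn), n),
                           rep(c("a", "b"), each = 25), return_cov = FALSE)
    c(satterthwaite_pvalue(1, st, 2, n, "naive")$kappa_hat,
      satterthwaite_pvalue(1, st, 2, n, "bias-reduced")$kappa_hat)
  })
  expect_lt(abs(mean(kap[2, ]) - Tn), 2)
  expect_lt(mean(kap[1, ]), Tn / (1 + Tn / 48) + 2)

  expect_equal(satterthwaite_pvalue(0, matrix(0, 2, 2), 2, 10)$p_asymptotic,
               1)
})

test_that("squared L2 distances are exact, symmetric, and metric", {
  X <- rbind(c(0, 0), c(2, 2), c(1, 1), c(3, 3))
  D2 <- distance_matrix(X)
  expect_equal(D2[1, 2], 4)  # (1/2) * (4 + 4)
  expect_equal(D2, t(D2))
  expect_equal(diag(D2), rep(0, 4), ignore_attr = TRUE)

  expect_equal(distance_matrix(matrix(1, 5, 3)), matrix(0, 5, 5),
               ignore_attr = TRUE, tolerance = 1e-12)

  set.seed(52)
  X <- matrix(rnorm(20 * 15), 20)
  D <- sqrt(distance_matrix(X))
  for (trial in 1:50) {
    ijk <- sample(20, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("distance-matrix F equals the direct F to 1e-10", {
  set.seed(53)
  for (trial in 1:20) {
    n <- sample(10:30, 1)
    Tn <- sample(5:100, 1)
    k <- sample(2:3, 1)
    groups <- factor(sample(letters[1:k], n, replace = TRUE))
    while (any(table(groups) < 2)) {
      groups <- factor(sample(letters[1:k], n, replace = TRUE))
    }
    X <- matrix(rnorm(n * Tn), n)
    st <- fanova_statistic(X, groups, return_cov = FALSE)
    fd <- fanovaseq:::.fanova_from_dist(distance_matrix(X), groups)
    expect_lt(abs(st$F_stat - fd$F), 1e-10)
  }
})

test_that("permutation p agrees with exhaustive enumeration and stays in bounds", {
  set.seed(54)
  X <- matrix(rnorm(6 * 8), 6)
  groups <- factor(rep(c("A", "B"), each = 3))
  D2 <- distance_matrix(X)
  F_obs <- fanovaseq:::.fanova_from_dist(D2, groups)$F
  # exact null: all 20 balanced labelings, uniformly likely under shuffling
  combos <- combn(6, 3)
  F_all <- apply(combos, 2, function(idx) {
    g <- factor(ifelse(seq_len(6) %in% idx, "A", "B"))
    fanovaseq:::.fanova_from_dist(D2, g)$F
  })
  p_exact <- mean(F_all >= F_obs - 1e-12)
  res <- permutation_pvalue(D2, groups, B = 10000, seed = 55)
  expect_lt(abs(res$p_permutation - p_exact), 0.02)
  expect_gte(res$p_permutation, 1 / 10001)
  expect_lte(res$p_permutation, 1)

  # degenerate all-zero distances
  expect_equal(permutation_pvalue(matrix(0, 4, 4),
                                  c("A", "A", "B", "B"))$p_permutation, 1)
})

test_that("F and both p-values are invariant to rescaling all curves", {
  set.seed(56)
  X <- matrix(rnorm(20 * 12), 20)
  groups <- rep(c("A", "B"), each = 10)
  r1 <- fanova_test(as_curves(X, groups), B = 99, seed = 7)
  r2 <- fanova_test(as_curves(-3.7 * X, groups), B = 99, seed = 7)
  expect_equal(r1$F_stat, r2$F_stat, tolerance = 1e-12)
  expect_equal(r1$p_asymptotic, r2$p_asymptotic, tolerance = 1e-12)
  expect_equal(r1$p_permutation, r2$p_permutation)
})

test_that("asymptotic p-values are near-uniform for Gaussian-process null curves", {
  gp_pvalues <- function(len) {
    Tn <- 40; tt <- seq(0, 1, length.out = Tn)
    L <- chol(outer(tt, tt, function(a, b) exp(-abs(a - b) / len)) +
                1e-9 * diag(Tn))
    groups <- rep(c("a", "b"), each = 25)
    replicate(2000, {
      X <- matrix(rnorm(50 * Tn), 50) %*% L
      st <- fanova_statistic(X, groups, return_cov = FALSE)
      satterthwaite_pvalue(st$F_stat, st, 2, 50)$p_asymptotic
    })
  }
  set.seed(57)
  # short-range dependence: the chi-square mixture is nearly spherical and
  # the Satterthwaite F reference is uniform across the whole distribution
  ps_short <- gp_pvalues(0.02)
  expect_gt(ks.test(ps_short, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps_short <= 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
  # long-range dependence: the two-moment approximation still calibrates
  # the 0.05 rejection rate (its body may deviate, its tail is right)
  ps_long <- gp_pvalues(0.25)
  expect_lt(abs(mean(ps_long <= 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 2000))
})
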