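test_that("knot placement and basis counts follow the three strategies", {
  s81 <- seq(0, 1, length.out = 81)
  b_small <- build_basis("small", s81)
  expect_equal(length(b_small$knots), 6)
  expect_equal(b_small$n_basis, 8)  # (6 - 2) interior + order 4

  b_eo <- build_basis("every-other", s81)
  expect_equal(length(b_eo$knots), 42)  # every other position plus both ends
  expect_equal(b_eo$n_basis, 44)

  s20 <- seq(0, 1, length.out = 20)
  b_pen <- build_basis("penalized", s20)
  expect_equal(length(b_pen$knots), 20)
  expect_equal(b_pen$n_basis, 22)  # p + 2 for cubic order

  expect_error(build_basis("small", c(0, 0.5, 1)), "at least 4")
})

test_that("B-splines sum to one and the penalty annihilates straight lines", {
  s <- seq(0, 1, length.out = 11)
  b <- build_basis("penalized", s)
  x <- seq(0, 1, length.out = 57)
  expect_equal(rowSums(eval_basis(b, x)), rep(1, 57), tolerance = 1e-12)

  P <- penalty_matrix(b)
  expect_equal(P, t(P))
  # coefficients reproducing f(t) = a + b t lie in the null space
  x_dense <- seq(0, 1, length.out = 100)
  line_coef <- qr.coef(qr(eval_basis(b, x_dense)), 2 + 3 * x_dense)
  expect_lt(max(abs(P %*% line_coef)), 1e-8)
  expect_true(all(eigen(P, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
})

test_that("penalized solve agrees with the direct normal-equations oracle", {
  set.seed(41)
  s <- sort(runif(25)); s <- (s - min(s)) / (max(s) - min(s))
  b <- build_basis("penalized", s)
  B <- eval_basis(b, s)
  P <- penalty_matrix(b)
  y <- rnorm(25)
  dr <- fanovaseq:::.dr_setup(B, P)
  z <- fanovaseq:::.dr_z(dr, matrix(y, ncol = 1))
  for (lam in c(1e-6, 1e-2, 1, 1e3)) {
    direct <- solve(crossprod(B) + lam * P, crossprod(B, y))
    expect_equal(drop(fanovaseq:::.dr_coef(dr, z, lam)), drop(direct),
                 tolerance = 1e-6)
    H <- B %*% solve(crossprod(B) + lam * P, t(B))
    expect_equal(fanovaseq:::.dr_trace(dr, lam), sum(diag(H)),
                 tolerance = 1e-6)
    expect_equal(drop(fanovaseq:::.dr_rss(dr, z, sum(y^2), lam)),
                 sum((y - B %*% direct)^2), tolerance = 1e-6)
  }
})

test_that("GCV selection: linear data hits the penalty null space, noise does not interpolate", {
  s <- seq(0, 1, length.out = 30)
  b <- build_basis("penalized", s)
  grid <- default_lambda_grid()

  # exactly linear data: every lambda fits it perfectly, RSS ~ 0
  y_line <- 1 + 2 * s
  sel <- select_lambda_gcv(y_line, s, b, grid)
  B <- eval_basis(b, s)
  coef_max <- fanovaseq:::.dr_coef(
    fanovaseq:::.dr_setup(B, penalty_matrix(b)),
    fanovaseq:::.dr_z(fanovaseq:::.dr_setup(B, penalty_matrix(b)),
                      matrix(y_line, ncol = 1)),
    sel$lambda)
  expect_lt(sum((y_line - B %*% coef_max)^2), 1e-10)

  # constant input is degenerate: grid maximum by convention
  sel_const <- select_lambda_gcv(rep(2, 30), s, b, grid)
  expect_equal(sel_const$lambda, max(grid))

  # hat-matrix trace is non-increasing in lambda
  expect_true(all(diff(sel$grid_trace) <= 1e-8))

  # noisy sine: selected RSS strictly between interpolant and straight line
  set.seed(42)
  s81 <- seq(0, 1, length.out = 81)
  b81 <- build_basis("penalized", s81)
  y <- sin(2 * pi * s81) + rnorm(81, sd = 0.3)
  sel <- select_lambda_gcv(y, s81, b81, grid)
  dr <- fanovaseq:::.dr_setup(eval_basis(b81, s81), penalty_matrix(b81))
  z <- fanovaseq:::.dr_z(dr, matrix(y, ncol = 1))
  rss_sel <- fanovaseq:::.dr_rss(dr, z, sum(y^2), sel$lambda)
  rss_interp <- fanovaseq:::.dr_rss(dr, z, sum(y^2), min(grid))
  rss_line <- sum(resid(lm(y ~ s81))^2)
  expect_gt(rss_sel, rss_interp + 1e-6)
  expect_lt(rss_sel, rss_line - 1e-6)

  expect_error(select_lambda_gcv(c(1, 2, 3), c(0, 0.5, 1), b), "at least 4")
})

test_that("lambda limits: interpolation at 0, straight line at infinity", {
  set.seed(43)
  s <- seq(0, 1, length.out = 15)
  b <- build_basis("penalized", s)
  B <- eval_basis(b, s)
  P <- penalty_matrix(b)
  y <- rnorm(15)
  dr <- fanovaseq:::.dr_setup(B, P)
  z <- fanovaseq:::.dr_z(dr, matrix(y, ncol = 1))

  fit0 <- B %*% fanovaseq:::.dr_coef(dr, z, 1e-12)
  expect_equal(drop(fit0), y, tolerance = 1e-6)

  fit_inf <- B %*% fanovaseq:::.dr_coef(dr, z, 1e10)
  rss_line <- sum(resid(lm(y ~ s))^2)
  expect_equal(sum((y - fit_inf)^2) / rss_line, 1, tolerance = 0.01)
})

test_that("smooth_all reproduces constants, matches OLS for the small basis, and sizes the grid", {
  set.seed(44)
  G <- rand_gm(6, 12, seed = 44)
  G$codes[1, ] <- 2  # constant subject
  G <- scale_positions(G)

  cs <- smooth_all(G, "small")
  expect_equal(ncol(cs$values), 24)  # T = 2p
  expect_equal(unname(cs$values[1, ]), rep(2, 24), tolerance = 1e-8)

  # small-basis fit is the OLS projection onto the 8 basis functions
  b <- build_basis("small", G$scaled_positions)
  B <- eval_basis(b, G$scaled_positions)
  coefs <- solve(crossprod(B), crossprod(B, t(G$codes)))
  oracle <- t(eval_basis(b, cs$grid) %*% coefs)
  expect_equal(unname(cs$values), unname(oracle), tolerance = 1e-8)

  # grid multiplier honored at a realistic region scale
  G155 <- scale_positions(rand_gm(3, 155, seed = 45))
  expect_equal(length(smooth_all(G155, "small")$grid), 310)
})

test_that("penalized smoothing works per subject on incomplete data", {
  G <- rand_gm(8, 20, miss = 0.15, seed = 46)
  G <- scale_positions(G)
  cs <- smooth_all(G, "penalized")
  expect_false(anyNA(cs$values))
  expect_equal(length(cs$lambda), 8)
  expect_true(all(cs$lambda > 0))

  # a complete-data subject gets the same fit whether or not others have
  # missing entries (each subject is fitted on their own observations)
  Gc <- G; Gc$codes <- G$codes
  Gc$codes[2:8, ] <- rand_codes(7, 20, seed = 47)  # complete rows
  stopifnot(!anyNA(Gc$codes[2:8, ]))
  cs_mixed <- smooth_all(Gc, "penalized")
  Gc2 <- Gc; Gc2$codes[1, ] <- rand_codes(1, 20, seed = 48)
  cs_complete <- smooth_all(Gc2, "penalized")
  expect_equal(cs_mixed$values[3, ], cs_complete$values[3, ])
})

test_that("relabeling changes penalized-GCV curves but barely moves small-basis group means", {
  # alternating-repulsion block: persistent 0-2 pattern across subjects
  set.seed(49)
  n <- 20; p <- 16
  base <- matrix(rep(c(0, 2), length.out = p), n, p, byrow = TRUE)
  noise <- matrix(sample(0:1, n * p, replace = TRUE, prob = c(0.8, 0.2)),
                  n, p)
  codes <- pmin(pmax(base + noise - noise * base, 0), 2)
  G <- scale_positions(genotype_matrix(codes))
  rl <- minimize_flips(G)
  expect_lt(rl$flip_vector$cost_after, rl$flip_vector$cost_before)

  pen_orig <- smooth_all(G, "penalized")$values
  pen_rel <- smooth_all(rl$genotypes, "penalized")$values
  expect_gt(mean(abs(pen_orig - pen_rel)), 0.05)

  # sequencing-like region where only isolated variants are in repulsion
  # (the typical minor-allele-coded case: few beneficial flips): the heavily
  # smoothed small-basis group means barely move relative to within-group
  # spread, while penalized-GCV curves move more
  set.seed(60)
  p2 <- 60
  upper <- rep(FALSE, p2); upper[c(15, 30, 45)] <- TRUE
  region <- list(maf = runif(p2, 0.05, 0.4), upper = upper)
  codes2 <- fanovaseq:::.draw_genotypes(40, region, rho = 0.95)
  Gs <- scale_positions(genotype_matrix(codes2,
                                        groups = rep(c("a", "b"), 20)))
  rls <- minimize_flips(Gs)
  expect_lt(sum(rls$flip_vector$flips), p2 / 4)
  sm_orig <- smooth_all(Gs, "small")$values
  sm_rel <- smooth_all(rls$genotypes, "small")$values
  ng <- table(Gs$groups)
  gm_shift <- abs(rowsum(sm_orig, Gs$groups) / as.vector(ng) -
                    rowsum(sm_rel, Gs$groups) / as.vector(ng))
  expect_lt(mean(gm_shift), mean(apply(sm_orig, 2, sd)))
  pen_o <- smooth_all(Gs, "penalized")$values
  pen_r <- smooth_all(rls$genotypes, "penalized")$values
  expect_gt(mean(abs(pen_o - pen_r)), mean(abs(sm_orig - sm_rel)))
})
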