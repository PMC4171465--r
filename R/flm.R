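#' Scalar-on-function design matrix
#'
#' Expands the coefficient function of the functional linear model in a
#' B-spline basis, which reduces the regression of a scalar phenotype on a
#' genotype function to ordinary multiple regression: the design entry for
#' subject i and basis function k is the numerical integral of
#' `x_i(t) phi_k(t)` over the common grid (trapezoid rule, whose O(1/T^2)
#' error keeps the design stable under grid refinement).
#'
#' @param curves A `curve_set` or n x T matrix with an attached grid.
#' @param beta_basis A `basis_spec` for the coefficient function; default is
#'   the small 6-knot cubic basis (8 functions), keeping the number of
#'   tested coefficients well below n.
#' @return n x K design matrix (no intercept; one is appended by
#'   [flm_wald()]).
#' @export
flm_design <- function(curves, beta_basis = NULL) {
  if (inherits(curves, "curve_set")) {
    X <- curves$values; grid <- curves$grid
  } else {
    X <- as.matrix(curves)
    grid <- seq(0, 1, length.out = ncol(X))
  }
  if (is.null(beta_basis)) {
    beta_basis <- build_basis(smooth_strategy("small"), grid)
  }
  K <- beta_basis$n_basis
  n <- nrow(X)
  if (K >= n - 2) {
    stop("beta basis has ", K, " functions for only ", n,
         " subjects; shrink beta_basis (fewer knots)")
  }
  Phi <- eval_basis(beta_basis, grid)        # T x K
  Tn <- ncol(X)
  w <- rep(1 / (Tn - 1), Tn)                 # trapezoid weights on [0, 1]
  w[c(1, Tn)] <- w[c(1, Tn)] / 2
  D <- X %*% (Phi * w)
  colnames(D) <- paste0("b", seq_len(K))
  D
}

#' Wald test of the functional linear model
#'
#' Fits the phenotype (0/1 for case/control, justified for dichotomous
#' traits by the equivalence of the chi-squared and ANOVA tests on binary
#' data) by least squares on the intercept-augmented design, and tests all
#' K coefficient-function coefficients jointly with
#' `W = b' V^{-1} b ~ chi^2_K` under the null, where `V` is the estimated
#' sampling covariance of the slope block. Rank-deficient designs are
#' handled by dropping pivoted-out columns and reducing K accordingly.
#'
#' @param y Length-n phenotype: numeric, logical, or a 2-level factor
#'   (second level treated as case).
#' @param X Design from [flm_design()].
#' @return An object of class `flm_result`: `W`, `K`, `p_chisq`,
#'   `p_permutation` (`NA` here), `B` (0 here).
#' @export
flm_wald <- function(y, X) {
  y <- .as_numeric_response(y)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("length(y) must equal nrow(X)")
  fit <- .flm_fit(X)
  if (n <= fit$K + 2) stop("too few subjects for ", fit$K, " coefficients")
  res <- .flm_wald_stat(fit, y)
  structure(list(W = res$W, K = fit$K, p_chisq = res$p,
                 p_permutation = NA_real_, B = 0L),
            class = "flm_result")
}

.as_numeric_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("phenotype factor must have exactly 2 levels")
    y <- as.integer(y) - 1L
  }
  as.numeric(y)
}

# One-time decomposition of the intercept-augmented design shared across
# permutations: pivoted QR, retained columns, and the inverse cross-product
# block of the slopes.
.flm_fit <- function(X) {
  n <- nrow(X)
  Xt <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xt)
  r <- qrX$rank
  keep <- sort(qrX$pivot[seq_len(r)])
  if (r < ncol(Xt)) {
    Xt <- Xt[, keep, drop = FALSE]
    qrX <- qr(Xt)
  }
  if (!(1 %in% keep)) stop("intercept dropped by pivoting; degenerate design")
  XtXinv <- chol2inv(chol(crossprod(Xt)))
  slope <- which(keep != 1)
  list(qr = qrX, n = n, K = r - 1L, slope = slope,
       Cinv = solve(XtXinv[slope, slope, drop = FALSE]))
}

.flm_wald_stat <- function(fit, y) {
  coefs <- qr.coef(fit$qr, y)
  res <- qr.resid(fit$qr, y)
  sigma2 <- sum(res^2) / (fit$n - fit$K - 1)
  b <- coefs[fit$slope]
  W <- if (sigma2 <= 0) Inf else drop(t(b) %*% fit$Cinv %*% b) / sigma2
  list(W = W, p = stats::pchisq(W, df = fit$K, lower.tail = FALSE))
}

#' Permutation p-value for the functional linear model
#'
#' Permutes the phenotype vector B times, recomputes the chi-square p-value
#' of [flm_wald()] for each shuffle, and reports the add-one proportion of
#' permuted p-values at or below the observed one,
#' `p = (1 + #\{p_b <= p_obs\}) / (B + 1)`. This accounts for the smoothing
#' and basis choice that the chi-square reference ignores.
#'
#' @inheritParams flm_wald
#' @param B Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A complete `flm_result` (with `p_permutation` and `B`).
#' @export
flm_permutation <- function(y, X, B = 999, seed = NULL) {
  y <- .as_numeric_response(y)
  X <- as.matrix(X)
  fit <- .flm_fit(X)
  if (length(y) <= fit$K + 2) {
    stop("too few subjects for ", fit$K, " coefficients")
  }
  obs <- .flm_wald_stat(fit, y)
  if (!is.null(seed)) set.seed(seed)
  p_perm_vals <- vapply(seq_len(B), function(b) {
    .flm_wald_stat(fit, sample(y))$p
  }, numeric(1))
  p <- (1 + sum(p_perm_vals <= obs$p)) / (B + 1)
  structure(list(W = obs$W, K = fit$K, p_chisq = obs$p,
                 p_permutation = p, B = as.integer(B)),
            class = "flm_result")
}

#' @export
print.flm_result <- function(x, ...) {
  cat("FLM Wald test\n")
  cat("  W = ", format(x$W, digits = 4), " on K = ", x$K,
      " coefficients; p (chi-square) = ", format(x$p_chisq, digits = 4),
      "\n", sep = "")
  if (!is.na(x$p_permutation)) {
    cat("  p (permutation, B = ", x$B, ") = ",
        format(x$p_permutation, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
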