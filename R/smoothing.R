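#' Smoothing strategy specification
#'
#' The three ways this package turns a discrete genotype profile into a
#' curve, all based on cubic B-splines on the scaled region `[0, 1]`:
#' \describe{
#'   \item{`"small"`}{a fixed small number of equally spaced knots (default
#'     6, giving 8 cubic B-splines) and unpenalized least squares - a heavily
#'     smoothed fit that is insensitive to genotype relabeling.}
#'   \item{`"every-other"`}{an unpenalized large basis with a knot at every
#'     other variant position (plus the region endpoints) - an oscillating
#'     fit that tracks the data closely.}
#'   \item{`"penalized"`}{a knot at every variant position with an
#'     integrated-squared-second-derivative roughness penalty, the smoothing
#'     parameter lambda chosen separately for each subject by generalized
#'     cross validation (GCV).}
#' }
#'
#' @param kind `"penalized"`, `"small"` or `"every-other"`.
#' @param n_knots_small Number of equally spaced knots for `"small"`.
#' @param lambda_grid Strictly positive increasing candidate lambdas for the
#'   GCV search; default 50 log-spaced values spanning `1e-8` to `1e8` (the
#'   upper end is reached e.g. when all of a subject's codes coincide and the
#'   fit is a straight line).
#' @return An object of class `smooth_strategy`.
#' @export
smooth_strategy <- function(kind = c("penalized", "small", "every-other"),
                            n_knots_small = 6,
                            lambda_grid = default_lambda_grid()) {
  kind <- match.arg(kind)
  stopifnot(n_knots_small >= 2, all(lambda_grid > 0),
            !is.unsorted(lambda_grid, strictly = TRUE))
  structure(list(kind = kind, n_knots_small = n_knots_small,
                 lambda_grid = lambda_grid),
            class = "smooth_strategy")
}

#' @rdname smooth_strategy
#' @export
default_lambda_grid <- function() {
  exp(seq(log(1e-8), log(1e8), length.out = 50))
}

.as_strategy <- function(strategy) {
  if (inherits(strategy, "smooth_strategy")) strategy
  else smooth_strategy(strategy)
}

#' Build the cubic B-spline basis for a strategy
#'
#' Knot placement follows the strategy: `"small"` uses `n_knots_small`
#' equally spaced breakpoints on `[0, 1]`; `"every-other"` places a
#' breakpoint at every other variant position (the even-index positions)
#' plus both region endpoints, so 81 positions give 42 knots;
#' `"penalized"` places a breakpoint at every variant position. For cubic
#' splines (order 4) a breakpoint sequence with K knots spans
#' `n_basis = K + 2` B-splines.
#'
#' @param strategy A [smooth_strategy()] or its `kind` string.
#' @param scaled_positions At least 4 strictly increasing positions in
#'   `[0, 1]` with endpoints 0 and 1.
#' @return An object of class `basis_spec`: `order` (4), `knots`
#'   (breakpoints including endpoints), `n_basis`, and the internal
#'   augmented knot sequence.
#' @export
build_basis <- function(strategy, scaled_positions) {
  strategy <- .as_strategy(strategy)
  s <- scaled_positions
  p <- length(s)
  if (p < 4) stop("need at least 4 positions for a cubic spline fit")
  if (is.unsorted(s, strictly = TRUE)) {
    stop("scaled positions must be strictly increasing")
  }
  knots <- switch(strategy$kind,
    "small" = seq(0, 1, length.out = strategy$n_knots_small),
    "every-other" = unique(c(0, s[seq(2, p - 1, by = 2)], 1)),
    "penalized" = s)
  order <- 4L
  aug <- c(rep(knots[1], order - 1), knots,
           rep(knots[length(knots)], order - 1))
  structure(list(order = order, knots = knots,
                 n_basis = length(knots) + order - 2L, aug_knots = aug),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("basis_spec: order-", x$order, " B-splines, ", length(x$knots),
      " knots, ", x$n_basis, " basis functions\n", sep = "")
  invisible(x)
}

#' Evaluate the basis functions (or a derivative) at given points
#'
#' @param basis A `basis_spec`.
#' @param x Evaluation points in `[knots[1], knots[K]]`.
#' @param deriv Derivative order (0 = function values).
#' @return Matrix `length(x)` x `n_basis`.
#' @export
eval_basis <- function(basis, x, deriv = 0) {
  splines::splineDesign(basis$aug_knots, x, ord = basis$order,
                        derivs = rep(deriv, length(x)))
}

#' Roughness penalty matrix of a basis
#'
#' The exact Gram matrix of second derivatives,
#' `P[j, k] = integral phi_j''(t) phi_k''(t) dt`, computed by Gauss-Legendre
#' quadrature on each inter-knot interval (the integrand is piecewise
#' quadratic for cubic splines, so 3-point quadrature is exact). Its null
#' space is the straight lines, so the large-lambda limit of the penalized
#' fit is exactly the least-squares line.
#'
#' @param basis A `basis_spec`.
#' @return Symmetric positive semidefinite `n_basis` x `n_basis` matrix.
#' @export
penalty_matrix <- function(basis) {
  knots <- basis$knots
  # 3-point Gauss-Legendre nodes/weights on [-1, 1]
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  gw <- c(5, 8, 5) / 9
  P <- matrix(0, basis$n_basis, basis$n_basis)
  for (i in seq_len(length(knots) - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    if (b <= a) next
    x <- (a + b) / 2 + (b - a) / 2 * gx
    w <- (b - a) / 2 * gw
    D2 <- eval_basis(basis, x, deriv = 2)
    P <- P + crossprod(D2 * sqrt(w))
  }
  (P + t(P)) / 2
}

# Demmler-Reinsch-type reparameterization of the penalized least squares
# problem: with A = B'B and S = A + P (positive definite because no straight
# line vanishes at >= 4 distinct points), factor S = L L' and diagonalize
# M = L^{-1} A L^{-T} = U diag(d) U', d in [0, 1]. Then for any lambda,
#   (A + lambda P)^{-1} = L^{-T} U diag(g) U' L^{-1},
#   g = 1 / (d + lambda (1 - d)),
# so hat-matrix traces, residual sums of squares and coefficients for a
# whole lambda grid cost O(q) per subject per lambda after one O(q^3) setup.
.dr_setup <- function(B, P) {
  A <- crossprod(B)
  S <- A + P
  R <- tryCatch(chol(S), error = function(e) {
    chol(S + diag(1e-10 * max(diag(S)), nrow(S)))
  })
  X1 <- backsolve(R, A, transpose = TRUE)        # L^{-1} A
  M <- t(backsolve(R, t(X1), transpose = TRUE))  # L^{-1} A L^{-T}
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- pmin(pmax(eg$values, 0), 1)
  list(R = R, U = eg$vectors, d = d, B = B)
}

# z = U' L^{-1} B' Y for one or several response columns
.dr_z <- function(dr, Y) {
  crossprod(dr$U, backsolve(dr$R, crossprod(dr$B, Y), transpose = TRUE))
}

.dr_trace <- function(dr, lambda) {
  sum(dr$d / (dr$d + lambda * (1 - dr$d)))
}

# residual sum of squares for each column of z at a given lambda
.dr_rss <- function(dr, z, ynorm2, lambda) {
  g <- 1 / (dr$d + lambda * (1 - dr$d))
  pmax(ynorm2 - colSums(z^2 * (g * (2 - dr$d * g))), 0)
}

# spline coefficients at lambda: L^{-T} U (g * z)
.dr_coef <- function(dr, z, lambda) {
  g <- 1 / (dr$d + lambda * (1 - dr$d))
  backsolve(dr$R, dr$U %*% (z * g))
}

.gcv_value <- function(m, rss, trh) {
  denom <- (m - trh)^2
  out <- m * rss / denom  # rss may be an n_lambda x nsub matrix; denom recycles
  bad <- denom <= .Machine$double.eps
  if (any(bad)) {
    if (is.matrix(out)) out[bad, ] <- Inf else out[bad] <- Inf
  }
  out
}

#' Select the smoothing parameter by generalized cross validation
#'
#' Minimizes `GCV(lambda) = m * RSS(lambda) / (m - tr H_lambda)^2` over the
#' candidate grid, where `H_lambda` is the hat matrix of the penalized
#' least-squares fit with the [penalty_matrix()] roughness penalty, then
#' refines the grid minimum with one golden-section search between its
#' neighboring grid points (in log lambda). A constant input (zero variance)
#' makes GCV flat, and the grid maximum is returned so the fit is the
#' maximally smoothed straight line.
#'
#' @param y Observed codes at the observed positions (>= 4 points).
#' @param positions The observed scaled positions (same length as `y`).
#' @param basis A `basis_spec` covering `[0, 1]`.
#' @param lambda_grid Increasing positive candidates.
#' @return A list: `lambda` (the selected value), `gcv` (its criterion
#'   value), `grid_gcv` and `grid_trace` (per-grid-point criterion and hat
#'   trace, for diagnostics).
#' @export
select_lambda_gcv <- function(y, positions, basis,
                              lambda_grid = default_lambda_grid()) {
  m <- length(y)
  if (m < 4) stop("GCV selection needs at least 4 observed points")
  stopifnot(length(positions) == m)
  B <- eval_basis(basis, positions)
  P <- penalty_matrix(basis)
  dr <- .dr_setup(B, P)
  z <- .dr_z(dr, matrix(y, ncol = 1))
  ynorm2 <- sum(y^2)
  grid_trace <- vapply(lambda_grid, function(l) .dr_trace(dr, l), numeric(1))
  grid_rss <- vapply(lambda_grid, function(l) .dr_rss(dr, z, ynorm2, l),
                     numeric(1))
  grid_gcv <- .gcv_value(m, grid_rss, grid_trace)

  if (stats::var(y) == 0) {
    lmax <- lambda_grid[length(lambda_grid)]
    return(list(lambda = lmax, gcv = grid_gcv[length(grid_gcv)],
                grid_gcv = grid_gcv, grid_trace = grid_trace))
  }

  i <- which.min(grid_gcv)
  lo <- lambda_grid[max(i - 1, 1)]
  hi <- lambda_grid[min(i + 1, length(lambda_grid))]
  f <- function(loglam) {
    l <- exp(loglam)
    .gcv_value(m, .dr_rss(dr, z, ynorm2, l), .dr_trace(dr, l))
  }
  opt <- .golden_min(f, log(lo), log(hi))
  if (opt$value <= grid_gcv[i]) {
    list(lambda = exp(opt$x), gcv = opt$value,
         grid_gcv = grid_gcv, grid_trace = grid_trace)
  } else {
    list(lambda = lambda_grid[i], gcv = grid_gcv[i],
         grid_gcv = grid_gcv, grid_trace = grid_trace)
  }
}

# one golden-section pass over [a, b]
.golden_min <- function(f, a, b, tol = 1e-3, max_iter = 40) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  iter <- 0
  while (abs(b - a) > tol && iter < max_iter) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
    iter <- iter + 1
  }
  if (f1 <= f2) list(x = x1, value = f1) else list(x = x2, value = f2)
}

#' Smooth all subjects' genotype profiles into curves
#'
#' Fits each subject's (possibly incomplete) genotype profile with the given
#' strategy and evaluates every fitted curve on a common grid of
#' `grid_multiplier * p` equally spaced points spanning `[0, 1]` - the
#' discretization resolution is twice the number of variants by default.
#' Missing entries are handled by fitting each subject on their observed
#' positions only. Unpenalized strategies (`"small"`, `"every-other"`) use
#' ordinary least squares; if the design is rank-deficient (too few observed
#' points for the basis) the fit falls back to a ridge jitter
#' `lambda = 1e-8` with a warning. The `"penalized"` strategy selects
#' lambda per subject via [select_lambda_gcv()].
#'
#' @param G A QC'd [genotype_matrix()]; positions are scaled on the fly when
#'   `scaled_positions` is absent.
#' @param strategy A [smooth_strategy()] or its `kind` string.
#' @param grid_multiplier Grid resolution as a multiple of p (default 2).
#' @return An object of class `curve_set`: `grid` (T points), `values`
#'   (n x T matrix), `strategy`, `basis`, `lambda` (per-subject, penalized
#'   strategy only) and `groups` carried over from `G`.
#' @export
smooth_all <- function(G, strategy = "penalized", grid_multiplier = 2) {
  stopifnot(inherits(G, "genotype_matrix"))
  strategy <- .as_strategy(strategy)
  if (is.null(G$scaled_positions)) G <- scale_positions(G)
  s <- G$scaled_positions
  codes <- G$codes
  n <- nrow(codes); p <- ncol(codes)
  Tn <- as.integer(round(grid_multiplier * p))
  grid <- seq(0, 1, length.out = Tn)
  basis <- build_basis(strategy, s)
  Bgrid <- eval_basis(basis, grid)
  penalized <- strategy$kind == "penalized"
  P <- if (penalized) penalty_matrix(basis) else NULL

  values <- matrix(NA_real_, n, Tn, dimnames = list(G$sample_ids, NULL))
  lambda <- if (penalized) rep(NA_real_, n) else NULL

  complete <- !apply(codes, 1, anyNA)
  fit_block <- function(Y, obs_pos) {
    # Y: m x (number of subjects) observed codes at shared positions
    B <- eval_basis(basis, obs_pos)
    m <- nrow(Y)
    if (!penalized) {
      qrB <- qr(B)
      if (qrB$rank < ncol(B)) {
        warning("singular unpenalized system; falling back to ridge ",
                "lambda = 1e-8")
        Ppen <- penalty_matrix(basis)
        dr <- .dr_setup(B, Ppen)
        coefs <- .dr_coef(dr, .dr_z(dr, Y), 1e-8)
      } else {
        coefs <- qr.coef(qrB, Y)
      }
      list(values = t(Bgrid %*% coefs), lambda = NULL)
    } else {
      dr <- .dr_setup(B, P)
      z <- .dr_z(dr, Y)
      ynorm2 <- colSums(Y^2)
      nsub <- ncol(Y)
      lg <- strategy$lambda_grid
      grid_trace <- vapply(lg, function(l) .dr_trace(dr, l), numeric(1))
      rss_mat <- vapply(lg, function(l) .dr_rss(dr, z, ynorm2, l),
                        numeric(nsub))
      if (nsub == 1) rss_mat <- matrix(rss_mat, nrow = 1)
      gcv_mat <- t(.gcv_value(m, t(rss_mat), grid_trace))  # nsub x n_lambda
      lam <- numeric(nsub)
      coefs <- matrix(0, basis$n_basis, nsub)
      for (i in seq_len(nsub)) {
        if (stats::var(Y[, i]) == 0) {
          lam[i] <- lg[length(lg)]
        } else {
          jmin <- which.min(gcv_mat[i, ])
          lo <- lg[max(jmin - 1, 1)]; hi <- lg[min(jmin + 1, length(lg))]
          zi <- z[, i, drop = FALSE]
          f <- function(loglam) {
            l <- exp(loglam)
            .gcv_value(m, .dr_rss(dr, zi, ynorm2[i], l), .dr_trace(dr, l))
          }
          opt <- .golden_min(f, log(lo), log(hi))
          lam[i] <- if (opt$value <= gcv_mat[i, jmin]) exp(opt$x) else lg[jmin]
        }
        coefs[, i] <- .dr_coef(dr, z[, i, drop = FALSE], lam[i])
      }
      list(values = t(Bgrid %*% coefs), lambda = lam)
    }
  }

  if (any(complete)) {
    fb <- fit_block(t(codes[complete, , drop = FALSE]), s)
    values[complete, ] <- fb$values
    if (penalized) lambda[complete] <- fb$lambda
  }
  for (i in which(!complete)) {
    obs <- !is.na(codes[i, ])
    if (sum(obs) < 4) {
      stop("subject ", G$sample_ids[i], " has fewer than 4 observed variants; ",
           "impute or QC first")
    }
    fb <- fit_block(matrix(codes[i, obs], ncol = 1), s[obs])
    values[i, ] <- fb$values
    if (penalized) lambda[i] <- fb$lambda
  }

  structure(list(grid = grid, values = values, strategy = strategy,
                 basis = basis, lambda = lambda, groups = G$groups,
                 region_id = G$region_id),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("curve_set: ", nrow(x$values), " curves on a grid of ",
      length(x$grid), " points (strategy '", x$strategy$kind, "')\n", sep = "")
  if (!is.null(x$lambda)) {
    cat("  GCV lambda range: ", format(min(x$lambda), digits = 3), " .. ",
        format(max(x$lambda), digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Export a curve set to TSV (grid row, then one row per subject)
#'
#' @param curves A `curve_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curves_tsv <- function(curves, path) {
  stopifnot(inherits(curves, "curve_set"))
  out <- rbind(grid = curves$grid, curves$values)
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
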