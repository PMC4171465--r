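#' Monte-Carlo harness: FANOVA p-values over simulated replicate datasets
#'
#' Repeatedly draws case-control datasets from [simulate_dataset()], runs
#' the standard pipeline (impute, scale, optional relabel, smooth) and
#' collects FANOVA p-values for one or several smoothing strategies. This is
#' the engine behind empirical type-I-error and power estimates: with
#' `causal_fraction = 0` in `cfg` the returned p-values sample the null,
#' otherwise the alternative.
#'
#' @param cfg A [sim_config()].
#' @param n_reps Number of replicate datasets.
#' @param strategies Character vector of smoothing strategies to apply to
#'   each replicate (shared imputation/relabeling, one smoothing + test per
#'   strategy).
#' @param relabel Apply flip-minimizing relabeling before smoothing.
#' @param B Permutation count; when `B > 0`, distance-matrix permutation
#'   p-values are collected alongside the asymptotic ones.
#' @param seed Integer seed for the whole experiment (a single RNG stream
#'   drives all replicates, so the experiment is reproducible end to end).
#' @return A list: `asymptotic` (`n_reps` x `length(strategies)` matrix of
#'   p-values), `permutation` (same shape, or `NULL` when `B = 0`).
#' @export
simulate_pvalues <- function(cfg, n_reps, strategies = "penalized",
                             relabel = FALSE, B = 0, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  set.seed(seed)
  p_asym <- matrix(NA_real_, n_reps, length(strategies),
                   dimnames = list(NULL, strategies))
  p_perm <- if (B > 0) p_asym else NULL
  for (i in seq_len(n_reps)) {
    G <- simulate_dataset(cfg)
    G <- impute_missing(G, method = "mode")
    G <- scale_positions(G)
    if (relabel) G <- minimize_flips(G)$genotypes
    for (s in strategies) {
      curves <- smooth_all(G, s)
      ft <- fanova_test(curves, G$groups, B = B)
      p_asym[i, s] <- ft$p_asymptotic
      if (B > 0) p_perm[i, s] <- ft$p_permutation
    }
  }
  list(asymptotic = p_asym, permutation = p_perm)
}

#' Empirical rejection rate of the FANOVA test over simulated replicates
#'
#' Thin wrapper over [simulate_pvalues()]: the fraction of asymptotic
#' p-values at or below `alpha`. With a null configuration this estimates
#' the empirical type I error; with causal variants, power.
#'
#' @inheritParams simulate_pvalues
#' @param alpha Nominal level (default 0.05).
#' @return Named vector of rejection rates, one per strategy.
#' @export
simulate_rejection_rate <- function(cfg, n_reps, strategies = "penalized",
                                    relabel = FALSE, alpha = 0.05,
                                    seed = 1) {
  ps <- simulate_pvalues(cfg, n_reps, strategies, relabel = relabel,
                         seed = seed)
  colMeans(ps$asymptotic <= alpha)
}
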