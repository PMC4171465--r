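#' Configuration for the sequencing-data simulator
#'
#' Parameterizes the synthetic case-control generator: a region of biallelic
#' variants whose haplotypes come from a latent AR(1) Gaussian copula with a
#' random per-variant tail orientation (LD decays with distance, and minor
#' alleles of neighboring variants are in attraction or repulsion - positive
#' or negative pairwise LD - depending on whether they share a latent tail,
#' as real sequence data mixes both), an L-shaped allele
#' frequency spectrum mixing rare (MAF < 0.01) and common variants, a
#' logistic disease model on a random causal subset, retrospective
#' case-control quota sampling, and missing-completely-at-random genotype
#' dropout.
#'
#' @param n_cases,n_controls Quota of cases and controls (default 25/25,
#'   i.e. a 50-subject study).
#' @param n_variants Number of variants simulated in the region (default
#'   100; variants monomorphic in the sampled cohort are removed by
#'   [simulate_dataset()], so the delivered count is somewhat lower).
#' @param rare_fraction Share of variants given a rare (MAF < 0.01) target
#'   frequency (default 0.5).
#' @param maf_rare,maf_common `c(shape1, shape2)` of the Beta distributions
#'   from which MAFs are drawn, truncated to (0.0005, 0.01) for rare and
#'   (0.01, 0.5) for common variants. The defaults (`c(0.2, 20)` and
#'   `c(0.5, 2)`) give the L-shaped spectrum typical of sequencing data.
#' @param ld_rho Latent AR(1) correlation between adjacent variants in
#'   `[0, 1)`. The default 0.95 makes the latent correlation halve roughly
#'   every 4 kb at the default ~300 bp variant spacing, mimicking the
#'   kilobase-scale LD decay of real common variants.
#' @param causal_fraction Fraction of variants made causal (0 = null model).
#' @param effect_mean,effect_sd Mean and SD of the per-allele log-odds
#'   effects, drawn once per causal variant from
#'   `Normal(effect_mean, effect_sd^2)`; `effect_mean = 0` is the
#'   both-deleterious-and-protective disease model, `effect_mean > 0` the
#'   mostly-deleterious one.
#' @param baseline_prevalence Disease probability of a subject carrying no
#'   minor alleles (default 0.1).
#' @param missing_rate MCAR genotype dropout applied last (default 0.02).
#' @param seed Optional integer seed making a dataset fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 25, n_controls = 25, n_variants = 100,
                       rare_fraction = 0.5, maf_rare = c(0.2, 20),
                       maf_common = c(0.5, 2), ld_rho = 0.95,
                       causal_fraction = 0, effect_mean = 0,
                       effect_sd = 0.25, baseline_prevalence = 0.1,
                       missing_rate = 0.02, seed = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_variants >= 2,
            rare_fraction >= 0, rare_fraction <= 1,
            length(maf_rare) == 2, all(maf_rare > 0),
            length(maf_common) == 2, all(maf_common > 0),
            ld_rho >= 0, ld_rho < 1,
            causal_fraction >= 0, causal_fraction <= 1,
            effect_sd >= 0,
            baseline_prevalence > 0, baseline_prevalence < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_variants = n_variants, rare_fraction = rare_fraction,
                 maf_rare = maf_rare, maf_common = maf_common,
                 ld_rho = ld_rho, causal_fraction = causal_fraction,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 baseline_prevalence = baseline_prevalence,
                 missing_rate = missing_rate, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_cases, " cases / ", x$n_controls, " controls, ",
      x$n_variants, " variants (", round(100 * x$rare_fraction),
      "% rare), AR(1) rho = ", x$ld_rho, "\n", sep = "")
  cat("  causal fraction ", x$causal_fraction, ", effects ~ N(",
      x$effect_mean, ", ", x$effect_sd, "^2), prevalence ",
      x$baseline_prevalence, ", missing rate ", x$missing_rate, "\n",
      sep = "")
  invisible(x)
}

# Beta draw truncated to (lo, hi) by inverse-CDF sampling.
.rtrunc_beta <- function(n, shape, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape[1], shape[2]),
                    stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

# Region architecture drawn once per dataset: target MAFs and, per variant,
# which latent tail carries the minor allele. Variants thresholded in
# opposite tails of the shared AR(1) latent are in repulsion (negative
# pairwise LD between their minor alleles), variants in the same tail in
# attraction - mixing both as real sequence data does.
.draw_region <- function(cfg) {
  p <- cfg$n_variants
  n_rare <- round(cfg$rare_fraction * p)
  maf <- numeric(p)
  rare_idx <- if (n_rare > 0) sort(sample.int(p, n_rare)) else integer(0)
  maf[rare_idx] <- .rtrunc_beta(n_rare, cfg$maf_rare, 5e-4, 0.01)
  common_idx <- setdiff(seq_len(p), rare_idx)
  maf[common_idx] <- .rtrunc_beta(length(common_idx), cfg$maf_common,
                                  0.01, 0.5)
  list(maf = maf, upper = stats::runif(p) < 0.5)
}

# 2 * n_subjects haplotypes from the latent AR(1) copula, thresholded at
# each variant's MAF quantile in the variant's tail; genotype = sum of the
# two haplotypes (minor-allele count).
.draw_genotypes <- function(n_subjects, region, rho) {
  maf <- region$maf
  p <- length(maf)
  nh <- 2 * n_subjects
  Z <- matrix(stats::rnorm(nh * p), nh, p)
  if (rho > 0 && p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) Z[, j] <- rho * Z[, j - 1] + s * Z[, j]
  }
  thr <- ifelse(region$upper, stats::qnorm(1 - maf), stats::qnorm(maf))
  cmp <- sweep(Z, 2, thr, "<")
  H <- sweep(cmp, 2, region$upper, "!=") * 1  # upper-tail variants: z >= thr
  H[seq_len(n_subjects), , drop = FALSE] +
    H[n_subjects + seq_len(n_subjects), , drop = FALSE]
}

.region_positions <- function(p, span = 30000) {
  round(seq(1, span, length.out = p))
}

#' Simulate region genotypes (no phenotype)
#'
#' Draws target MAFs from the configured spectrum and genotypes from the
#' latent AR(1) haplotype copula; positions are equally spaced over a 30 kb
#' region. MCAR missingness at `cfg$missing_rate` is applied last. No
#' phenotype is attached; see [simulate_dataset()] for the full case-control
#' generator.
#'
#' @param cfg A [sim_config()].
#' @param n_subjects Number of subjects to draw.
#' @param seed Optional integer seed (falls back to `cfg$seed`).
#' @return A [genotype_matrix()] without groups.
#' @export
simulate_genotypes <- function(cfg, n_subjects, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  region <- .draw_region(cfg)
  codes <- .draw_genotypes(n_subjects, region, cfg$ld_rho)
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(codes)) < cfg$missing_rate,
                   nrow(codes), ncol(codes))
    codes[drop] <- NA
  }
  genotype_matrix(codes, positions = .region_positions(cfg$n_variants),
                  sample_ids = sprintf("S%04d", seq_len(n_subjects)),
                  region_id = "simulated")
}

# Causal architecture drawn once per dataset: causal subset, per-variant
# log-odds effects, and the intercept anchoring the genotype-free disease
# probability at the baseline prevalence.
.draw_effects <- function(cfg) {
  m <- round(cfg$causal_fraction * cfg$n_variants)
  causal <- if (m > 0) sort(sample.int(cfg$n_variants, m)) else integer(0)
  beta <- if (m > 0) stats::rnorm(m, cfg$effect_mean, cfg$effect_sd)
          else numeric(0)
  list(causal = causal, beta = beta,
       beta0 = stats::qlogis(cfg$baseline_prevalence))
}

#' Simulate a binary phenotype from genotypes by the logistic disease model
#'
#' Each subject's disease probability is
#' `logit P(case) = beta0 + sum_c beta_c g_c` over the causal variants,
#' with effects drawn once from `Normal(effect_mean, effect_sd^2)` and
#' `beta0 = logit(baseline_prevalence)`. With `causal_fraction = 0` the
#' phenotype is independent of every variant.
#'
#' @param G A [genotype_matrix()] (complete codes; causal columns must not
#'   be missing).
#' @param cfg A [sim_config()].
#' @param effects Optional pre-drawn architecture (list with `causal`,
#'   `beta`, `beta0`) for reuse across cohort batches; drawn fresh
#'   otherwise.
#' @param seed Optional integer seed.
#' @return Character vector of `"case"`/`"control"` labels.
#' @export
simulate_phenotype <- function(G, cfg, effects = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  codes <- .codes(G)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effects)) effects <- .draw_effects(cfg)
  eta <- rep(effects$beta0, nrow(codes))
  if (length(effects$causal) > 0) {
    eta <- eta + codes[, effects$causal, drop = FALSE] %*% effects$beta
  }
  ifelse(stats::runif(nrow(codes)) < stats::plogis(eta), "case", "control")
}

#' Simulate a complete case-control dataset
#'
#' The full retrospective design: the causal architecture and the region's
#' MAF spectrum are drawn once, then cohorts are sampled in batches -
#' genotypes from the haplotype copula, disease status from the logistic
#' model - and subjects are accepted until the case and control quotas are
#' both filled exactly. Variants monomorphic across the final cohort are
#' removed, and MCAR missingness is applied last. The same seed reproduces
#' the dataset end to end.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed (falls back to `cfg$seed`).
#' @return A [genotype_matrix()] with `groups` set to case/control.
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  region <- .draw_region(cfg)
  effects <- .draw_effects(cfg)

  need <- c(case = cfg$n_cases, control = cfg$n_controls)
  got <- list(case = NULL, control = NULL)
  n_total <- cfg$n_cases + cfg$n_controls
  batch <- max(100, 2 * n_total)
  max_draws <- 2000 * n_total
  drawn <- 0
  while (nrow(got$case %||% matrix(nrow = 0, ncol = 0)) < need["case"] ||
         nrow(got$control %||% matrix(nrow = 0, ncol = 0)) < need["control"]) {
    if (drawn >= max_draws) {
      stop("case/control quota unattainable after ", drawn, " draws; ",
           "check baseline_prevalence")
    }
    codes <- .draw_genotypes(batch, region, cfg$ld_rho)
    lab <- simulate_phenotype(codes, cfg, effects = effects)
    drawn <- drawn + batch
    for (cl in c("case", "control")) {
      short <- need[cl] - if (is.null(got[[cl]])) 0 else nrow(got[[cl]])
      if (short > 0) {
        idx <- which(lab == cl)
        take <- idx[seq_len(min(short, length(idx)))]
        got[[cl]] <- rbind(got[[cl]], codes[take, , drop = FALSE])
      }
    }
  }
  codes <- rbind(got$case, got$control)
  groups <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))

  poly <- apply(codes, 2, function(x) max(x) - min(x)) > 0
  codes <- codes[, poly, drop = FALSE]
  positions <- .region_positions(cfg$n_variants)[poly]

  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(codes)) < cfg$missing_rate,
                   nrow(codes), ncol(codes))
    # never blank out a variant entirely
    full <- colSums(!drop) == 0
    drop[1, full] <- FALSE
    codes[drop] <- NA
  }

  genotype_matrix(codes, positions = positions,
                  sample_ids = sprintf("S%04d", seq_len(nrow(codes))),
                  groups = groups, region_id = "simulated")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
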