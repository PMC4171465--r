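#' End-to-end region association test
#'
#' Runs the full pipeline on one genomic region: read, QC filtering,
#' imputation, position scaling, flip-minimizing relabeling (on by default),
#' curve smoothing, the FANOVA test (asymptotic always, permutation when
#' `B > 0`) and optionally the FLM comparator. The default configuration -
#' penalized cubic B-splines with per-subject GCV after relabeling, and the
#' asymptotic p-value - is the recommended one.
#'
#' @param genotypes A [genotype_matrix()], or a path passed to
#'   [read_genotypes()].
#' @param phenotype Phenotype source for [read_genotypes()] (ignored when
#'   `genotypes` already carries groups).
#' @param region Optional region window for [read_genotypes()].
#' @param strategy Smoothing strategy (`"penalized"`, `"small"`,
#'   `"every-other"` or a [smooth_strategy()]).
#' @param relabel Apply [minimize_flips()] before smoothing.
#' @param impute_method Passed to [impute_missing()].
#' @param grid_multiplier Curve grid resolution multiple (default 2).
#' @param B Permutation count for FANOVA (and FLM when requested); 0 for
#'   asymptotic only.
#' @param flm Also run the FLM Wald test (with permutations when `B > 0`).
#' @param seed Integer seed covering imputation draws and permutations.
#' @param max_subject_missing,min_variant_callrate QC thresholds, see
#'   [apply_qc()].
#' @return An object of class `region_test_report`: region id, dimensions
#'   before/after QC, the options used, `fanova` (a `fanova_result`),
#'   `flm` (a `flm_result` or `NULL`), `flips` (a `flip_vector` or `NULL`),
#'   `elapsed` seconds and `seed`.
#' @export
run_region_test <- function(genotypes, phenotype = NULL, region = NULL,
                            strategy = "penalized", relabel = TRUE,
                            impute_method = "mode", grid_multiplier = 2,
                            B = 0, flm = FALSE, seed = NULL,
                            max_subject_missing = 0.30,
                            min_variant_callrate = 0.70) {
  t0 <- proc.time()["elapsed"]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  G <- stage("read", {
    if (inherits(genotypes, "genotype_matrix")) genotypes
    else read_genotypes(genotypes, phenotype = phenotype, region = region)
  })
  if (is.null(G$groups)) stop("[read] no phenotype groups attached")
  n_variants_pre <- ncol(G$codes)

  G <- stage("qc", apply_qc(G, max_subject_missing = max_subject_missing,
                            min_variant_callrate = min_variant_callrate))
  G <- stage("impute", impute_missing(G, method = impute_method, seed = seed))
  G <- stage("scale", scale_positions(G))

  flips <- NULL
  if (relabel) {
    rl <- stage("relabel", minimize_flips(G))
    flips <- rl$flip_vector
    G <- rl$genotypes
  }

  curves <- stage("smooth",
                  smooth_all(G, strategy, grid_multiplier = grid_multiplier))
  fan <- stage("fanova", fanova_test(curves, G$groups, B = B, seed = seed))

  flm_res <- NULL
  if (flm) {
    flm_res <- stage("flm", {
      X <- flm_design(curves)
      y <- as.integer(G$groups == levels(G$groups)[1])
      if (B > 0) flm_permutation(y, X, B = B, seed = seed)
      else flm_wald(y, X)
    })
  }

  structure(list(region_id = G$region_id, n_subjects = nrow(G$codes),
                 n_variants_pre = n_variants_pre,
                 n_variants_post = ncol(G$codes),
                 strategy = .as_strategy(strategy)$kind, relabel = relabel,
                 fanova = fan, flm = flm_res, flips = flips,
                 elapsed = unname(proc.time()["elapsed"] - t0), seed = seed),
            class = "region_test_report")
}

#' @export
print.region_test_report <- function(x, ...) {
  cat("Region test report: ", x$region_id, "\n", sep = "")
  cat("  ", x$n_subjects, " subjects; ", x$n_variants_post, "/",
      x$n_variants_pre, " variants after QC\n", sep = "")
  cat("  smoothing '", x$strategy, "', relabel = ", x$relabel, "\n", sep = "")
  if (!is.null(x$flips)) {
    cat("  flip cost ", x$flips$cost_before, " -> ", x$flips$cost_after,
        " (", sum(x$flips$flips), " variants flipped)\n", sep = "")
  }
  print(x$fanova)
  if (!is.null(x$flm)) print(x$flm)
  cat("  elapsed: ", round(x$elapsed, 2), " s\n", sep = "")
  invisible(x)
}

#' Serialize one or several region test reports to TSV
#'
#' One row per report and method, with Bonferroni adjustment across regions
#' when requested.
#'
#' @param reports A `region_test_report` or list of them.
#' @param path Output TSV path, or `NULL` to just return the data frame.
#' @param bonferroni Add a `p_adjusted` column (asymptotic p multiplied by
#'   the number of regions, capped at 1).
#' @return The report data frame, invisibly when written.
#' @export
report_table <- function(reports, path = NULL, bonferroni = FALSE) {
  if (inherits(reports, "region_test_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    f <- r$fanova
    out <- data.frame(
      region = r$region_id, method = "FANOVA", n = r$n_subjects,
      p_variants = r$n_variants_post, T = f$T, statistic = f$F_stat,
      kappa = f$kappa_hat, df1 = f$df1, df2 = f$df2,
      p_asym = f$p_asymptotic, p_perm = f$p_permutation, B = f$B,
      strategy = r$strategy, relabel = r$relabel,
      degenerate = f$degenerate, seed = r$seed %||% NA)
    if (!is.null(r$flm)) {
      out <- rbind(out, data.frame(
        region = r$region_id, method = "FLM", n = r$n_subjects,
        p_variants = r$n_variants_post, T = f$T, statistic = r$flm$W,
        kappa = NA, df1 = r$flm$K, df2 = NA, p_asym = r$flm$p_chisq,
        p_perm = r$flm$p_permutation, B = r$flm$B, strategy = r$strategy,
        relabel = r$relabel, degenerate = FALSE, seed = r$seed %||% NA))
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (bonferroni) {
    n_regions <- length(unique(tab$region))
    tab$p_adjusted <- pmin(tab$p_asym * n_regions, 1)
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
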