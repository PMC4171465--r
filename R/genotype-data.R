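#' Construct a region genotype matrix
#'
#' Container for the genotype data of one genomic region: an n subjects by
#' p variants matrix of minor-allele counts (0, 1, 2 or `NA`), the physical
#' positions of the variants, optional phenotype group labels, and (after
#' [scale_positions()]) positions rescaled to the unit interval.
#'
#' @param codes Integer-valued matrix, n subjects x p variants, entries in
#'   `{0, 1, 2}` or `NA` for missing genotypes.
#' @param positions Numeric vector of p strictly increasing physical
#'   coordinates (base pairs), or `NULL` when positions are unknown.
#' @param sample_ids Character vector of n subject identifiers; defaults to
#'   the rownames of `codes` or `S1..Sn`.
#' @param groups Vector of n phenotype labels (k >= 2 levels, e.g.
#'   case/control), or `NULL` before a phenotype is attached.
#' @param region_id Free-text region label.
#' @param scaled_positions Optional p positions already mapped to `[0, 1]`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `positions`, `scaled_positions`, `sample_ids`, `groups`,
#'   `region_id`.
#' @seealso [read_genotypes()], [apply_qc()], [impute_missing()],
#'   [scale_positions()]
#' @export
genotype_matrix <- function(codes, positions = NULL, sample_ids = NULL,
                            groups = NULL, region_id = "region",
                            scaled_positions = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  bad <- !is.na(codes) & !(codes %in% c(0, 1, 2))
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(codes[bad])[1:min(3, sum(bad))], collapse = ", "))
  }
  n <- nrow(codes); p <- ncol(codes)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(codes)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (length(sample_ids) != n) stop("sample_ids length must equal nrow(codes)")
  if (!is.null(positions)) {
    if (length(positions) != p) stop("positions length must equal ncol(codes)")
    if (p >= 2 && any(diff(positions) <= 0)) {
      stop("positions must be strictly increasing")
    }
  }
  if (!is.null(groups)) {
    if (length(groups) != n) stop("groups length must equal nrow(codes)")
    groups <- factor(groups)
  }
  rownames(codes) <- sample_ids
  structure(
    list(codes = codes, positions = positions,
         scaled_positions = scaled_positions,
         sample_ids = as.character(sample_ids), groups = groups,
         region_id = region_id),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix '", x$region_id, "': ",
      nrow(x$codes), " subjects x ", ncol(x$codes), " variants\n", sep = "")
  nm <- sum(is.na(x$codes))
  if (nm > 0) cat("  missing entries: ", nm, "\n", sep = "")
  if (!is.null(x$groups)) {
    tb <- table(x$groups)
    cat("  groups: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$positions)) {
    cat("  positions: ", x$positions[1], " .. ",
        x$positions[length(x$positions)], "\n", sep = "")
  }
  invisible(x)
}

# Extract the code matrix from either a genotype_matrix or a plain matrix.
.codes <- function(G) {
  if (inherits(G, "genotype_matrix")) G$codes else as.matrix(G)
}

#' Read region genotypes from VCF or TSV
#'
#' Reads a biallelic-SNP genotype matrix for one region and attaches
#' phenotype labels. Codes are minor-allele counts: after reading, the sample
#' allele frequency of the coded allele is computed over all retained
#' subjects and dosages at variants where that frequency exceeds 0.5 are
#' recoded `d -> 2 - d`, so that the coded allele is always the minor one
#' (at an exact 0.5 tie the ALT allele stays coded). Variants are ordered by
#' position and subjects by identifier.
#'
#' @param source Path to a VCF (v4.x, possibly gzipped) or a plain TSV whose
#'   first row holds variant positions and whose first column holds sample
#'   identifiers.
#' @param phenotype Either a path to a two-column TSV (sample id, label) or a
#'   named vector mapping sample ids to labels; `NULL` to attach no groups.
#' @param region Optional half-open coordinate window `c(start, end)` (or
#'   `"chr:start-end"` for VCF input, in which case the chromosome is matched
#'   as well); variants with `start <= pos < end` are kept.
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#'
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(source, phenotype = NULL, region = NULL,
                           format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("cannot read genotype file: ", source)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) {
      "vcf"
    } else "tsv"
  }
  G <- if (format == "vcf") {
    .read_vcf(source, region)
  } else {
    .read_tsv(source, region)
  }
  if (ncol(G$codes) == 0) stop("zero variants in region")

  if (!is.null(phenotype)) {
    ph <- .read_phenotype(phenotype)
    lab <- ph[G$sample_ids]
    if (all(is.na(lab))) stop("phenotype labels missing for all samples")
    if (anyNA(lab)) {
      warning(sum(is.na(lab)), " sample(s) without phenotype label dropped")
      keep <- !is.na(lab)
      G$codes <- G$codes[keep, , drop = FALSE]
      G$sample_ids <- G$sample_ids[keep]
      lab <- lab[keep]
    }
    G$groups <- factor(unname(lab))
  }

  # deterministic ordering: variants by position, subjects by id
  if (!is.null(G$positions)) {
    ov <- order(G$positions)
    G$codes <- G$codes[, ov, drop = FALSE]
    G$positions <- G$positions[ov]
  }
  os <- order(G$sample_ids)
  G$codes <- G$codes[os, , drop = FALSE]
  G$sample_ids <- G$sample_ids[os]
  if (!is.null(G$groups)) G$groups <- G$groups[os]

  # minor-allele recoding from sample allele frequency over retained subjects
  af <- colMeans(G$codes, na.rm = TRUE) / 2
  flip <- !is.na(af) & af > 0.5
  if (any(flip)) G$codes[, flip] <- 2 - G$codes[, flip]

  genotype_matrix(G$codes, positions = G$positions,
                  sample_ids = G$sample_ids, groups = G$groups,
                  region_id = G$region_id)
}

.read_phenotype <- function(phenotype) {
  if (is.character(phenotype) && length(phenotype) == 1 &&
      file.exists(phenotype)) {
    tab <- utils::read.table(phenotype, header = FALSE, sep = "\t",
                             colClasses = "character",
                             col.names = c("sample_id", "label"))
    # tolerate a header line
    if (tolower(tab$sample_id[1]) %in% c("sample", "sample_id", "id")) {
      tab <- tab[-1, , drop = FALSE]
    }
    stats::setNames(tab$label, tab$sample_id)
  } else {
    if (is.null(names(phenotype))) stop("phenotype vector must be named")
    phenotype
  }
}

.parse_region <- function(region) {
  if (is.character(region) && length(region) == 1) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chr:start-end' or c(start, end)")
    list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  } else {
    list(chrom = NULL, start = as.numeric(region[1]),
         end = as.numeric(region[2]))
  }
}

.read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  alt <- fix[, "ALT"]
  keep <- !grepl(",", alt) & !is.na(alt) & alt != "."
  if (any(!keep)) {
    warning(sum(!keep), " multi-allelic or ALT-less site(s) skipped")
  }
  if (!is.null(region)) {
    w <- .parse_region(region)
    keep <- keep & pos >= w$start & pos < w$end
    if (!is.null(w$chrom)) keep <- keep & fix[, "CHROM"] == w$chrom
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  # dosage of the ALT allele; "./." and partial calls -> NA
  alt_count <- function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (length(a) != 2 || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }
  codes <- t(apply(gt, 2, function(col) vapply(col, alt_count, numeric(1))))
  if (nrow(gt) == 1) codes <- matrix(codes, ncol = 1)
  dimnames(codes) <- list(colnames(gt), NULL)
  if (anyDuplicated(pos)) {
    # distinct records can share POS (e.g. decomposed indels); keep first
    warning("duplicate positions in VCF; keeping first record at each")
    first <- !duplicated(pos)
    codes <- codes[, first, drop = FALSE]
    pos <- pos[first]
  }
  list(codes = codes, positions = pos, sample_ids = rownames(codes),
       groups = NULL, region_id = basename(path))
}

.read_tsv <- function(path, region = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  pos <- suppressWarnings(as.numeric(colnames(tab)))
  codes <- as.matrix(tab)
  if (anyNA(pos)) pos <- NULL
  if (!is.null(region) && !is.null(pos)) {
    w <- .parse_region(region)
    keep <- pos >= w$start & pos < w$end
    codes <- codes[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  list(codes = codes, positions = pos, sample_ids = rownames(codes),
       groups = NULL, region_id = basename(path))
}

#' Write a genotype matrix (and optional phenotype) to TSV
#'
#' The genotype TSV has variant positions as the header row and sample ids
#' as the first column, the format accepted back by [read_genotypes()]
#' (round trip is the identity on codes, positions and groups).
#'
#' @param G A [genotype_matrix()].
#' @param geno_path Output path for the genotype TSV.
#' @param pheno_path Optional output path for the two-column phenotype TSV.
#' @return Invisibly, `geno_path`.
#' @export
write_genotypes_tsv <- function(G, geno_path, pheno_path = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  pos <- G$positions
  if (is.null(pos)) pos <- seq_len(ncol(G$codes))
  tab <- as.data.frame(G$codes)
  colnames(tab) <- pos
  tab <- cbind(sample_id = G$sample_ids, tab)
  utils::write.table(tab, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pheno_path)) {
    if (is.null(G$groups)) stop("no groups to write")
    utils::write.table(
      data.frame(sample_id = G$sample_ids, label = as.character(G$groups)),
      pheno_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(geno_path)
}

#' Quality-control filtering of a region genotype matrix
#'
#' Filters in three passes, in this order: subjects whose fraction of missing
#' variants exceeds `max_subject_missing` are removed; then variants called
#' in fewer than `min_variant_callrate` of the remaining subjects are
#' removed; then variants whose (non-missing) codes are constant across all
#' remaining subjects are removed. Row and column order is preserved and the
#' removal counts are reported via `message()`. The operation is idempotent.
#'
#' @param G A [genotype_matrix()].
#' @param max_subject_missing Maximum tolerated per-subject missing fraction
#'   (default 0.30: subjects with over 30% missing variants are excluded).
#' @param min_variant_callrate Minimum per-variant call rate (default 0.70:
#'   variants with information for less than 70% of subjects are excluded).
#' @param drop_monomorphic Drop variants constant across all subjects.
#' @return The filtered [genotype_matrix()].
#' @export
apply_qc <- function(G, max_subject_missing = 0.30,
                     min_variant_callrate = 0.70, drop_monomorphic = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (nrow(G$codes) == 0 || ncol(G$codes) == 0) stop("empty genotype matrix")

  subj_miss <- rowMeans(is.na(G$codes))
  keep_s <- subj_miss <= max_subject_missing
  if (sum(!keep_s) > 0) {
    message("QC: removed ", sum(!keep_s), " subject(s) with missingness > ",
            max_subject_missing)
  }
  if (!any(keep_s)) stop("empty after QC: all subjects removed")
  codes <- G$codes[keep_s, , drop = FALSE]

  callrate <- colMeans(!is.na(codes))
  keep_v <- callrate >= min_variant_callrate
  if (sum(!keep_v) > 0) {
    message("QC: removed ", sum(!keep_v), " variant(s) with call rate < ",
            min_variant_callrate)
  }
  codes <- codes[, keep_v, drop = FALSE]

  keep_m <- rep(TRUE, ncol(codes))
  if (drop_monomorphic && ncol(codes) > 0) {
    rng <- apply(codes, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0) 0 else max(x) - min(x)
    })
    keep_m <- rng > 0
    if (sum(!keep_m) > 0) {
      message("QC: removed ", sum(!keep_m), " monomorphic variant(s)")
    }
    codes <- codes[, keep_m, drop = FALSE]
  }
  if (ncol(codes) == 0) stop("empty after QC: all variants removed")

  keep_var <- which(keep_v)[keep_m]
  genotype_matrix(
    codes,
    positions = if (!is.null(G$positions)) G$positions[keep_var],
    sample_ids = G$sample_ids[keep_s],
    groups = if (!is.null(G$groups)) droplevels(G$groups[keep_s]),
    region_id = G$region_id,
    scaled_positions = if (!is.null(G$scaled_positions)) {
      G$scaled_positions[keep_var]
    })
}

#' Impute missing genotype codes
#'
#' Single imputation of missing entries, either by the per-variant modal
#' code (`"mode"`; ties resolved toward the smaller code) or by sampling
#' from the variant's observed code frequencies (`"empirical"`). Complete
#' matrices pass through unchanged. This is deliberately simple, single-pass
#' imputation; it does not model uncertainty across imputations.
#'
#' @param G A [genotype_matrix()] with no variant entirely missing.
#' @param method `"mode"` or `"empirical"`.
#' @param seed Integer seed used by the `"empirical"` draw; same seed, same
#'   imputed matrix.
#' @return A complete [genotype_matrix()].
#' @export
impute_missing <- function(G, method = c("mode", "empirical"), seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  method <- match.arg(method)
  codes <- G$codes
  if (!anyNA(codes)) return(G)
  fully_missing <- colSums(!is.na(codes)) == 0
  if (any(fully_missing)) {
    stop(sum(fully_missing), " variant(s) entirely missing; run apply_qc first")
  }
  if (!is.null(seed)) set.seed(seed)
  for (j in which(colSums(is.na(codes)) > 0)) {
    x <- codes[, j]
    obs <- x[!is.na(x)]
    miss <- which(is.na(x))
    if (method == "mode") {
      tb <- table(factor(obs, levels = c(0, 1, 2)))
      fill <- as.numeric(names(tb)[which.max(tb)])  # which.max: first max,
      codes[miss, j] <- fill                        # i.e. smaller code on tie
    } else {
      codes[miss, j] <- sample(obs, length(miss), replace = TRUE)
    }
  }
  G$codes <- codes
  G
}

#' Rescale variant positions to the unit interval
#'
#' Maps physical positions affinely onto `[0, 1]`:
#' `s_j = (pos_j - pos_1) / (pos_p - pos_1)`. When the matrix carries no
#' positions, variants are assumed equally spaced: `s_j = (j - 1)/(p - 1)`.
#' The result is invariant to shifting all physical positions by a constant.
#'
#' @param G A [genotype_matrix()] with at least two variants.
#' @return `G` with `scaled_positions` filled in.
#' @export
scale_positions <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- ncol(G$codes)
  if (p < 2) stop("need at least 2 variants to scale positions")
  if (is.null(G$positions)) {
    G$scaled_positions <- (seq_len(p) - 1) / (p - 1)
  } else {
    if (anyDuplicated(G$positions)) stop("duplicate physical positions")
    rng <- range(G$positions)
    G$scaled_positions <- (G$positions - rng[1]) / (rng[2] - rng[1])
  }
  G
}
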