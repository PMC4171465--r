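# Shared fixture builders; everything is generated in code at test time.

# random 0/1/2 matrix with optional missingness
rand_codes <- function(n, p, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  if (miss > 0) m[matrix(runif(n * p) < miss, n, p)] <- NA
  m
}

rand_gm <- function(n, p, miss = 0, seed = NULL, groups = NULL) {
  genotype_matrix(rand_codes(n, p, miss, seed),
                  positions = seq(100, by = 50, length.out = p),
                  groups = groups)
}

# brute-force flip count: explicit double loop, independent of flip_cost()
naive_flip_cost <- function(codes) {
  total <- 0
  for (i in seq_len(nrow(codes))) {
    for (j in seq_len(ncol(codes) - 1)) {
      a <- codes[i, j]; b <- codes[i, j + 1]
      if ((a == 0 && b == 2) || (a == 2 && b == 0)) total <- total + 1
    }
  }
  total
}

# exhaustive flip minimization over all 2^p flip vectors (the flip count
# itself is vectorized for speed; its correctness is pinned separately by
# naive_flip_cost)
exhaustive_min_flips <- function(codes) {
  p <- ncol(codes)
  best <- Inf
  for (mask in 0:(2^p - 1)) {
    flips <- as.integer(intToBits(mask)[seq_len(p)])
    m <- codes
    w <- which(flips == 1)
    if (length(w)) m[, w] <- 2 - m[, w]
    a <- m[, -p, drop = FALSE]; b <- m[, -1, drop = FALSE]
    best <- min(best, sum((a == 0 & b == 2) | (a == 2 & b == 0)))
  }
  best
}

# a 6-sample, 3-variant toy VCF written to a tempfile; variant 2 has ALT
# allele frequency 0.8 (hand count: alleles 1/1,1/1,0/1,1/1,0/1,1/0 ->
# 9 ALT + ... see test), variant 3 carries a missing call
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste0("N", 1:6, collapse = "\t")),
    "1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0\t0/0\t0/1\t0/0",
    "1\t205\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1\t1/1\t0/1\t1/1",
    "1\t309\t.\tG\tA\t.\tPASS\t.\tGT\t0/1\t./.\t0/0\t0/0\t0/0\t0/1")
  writeLines(lines, path)
  path
}

# two-group curve set built directly from a value matrix
as_curves <- function(values, groups = NULL) {
  structure(list(grid = seq(0, 1, length.out = ncol(values)),
                 values = values, strategy = smooth_strategy("small"),
                 basis = NULL, lambda = NULL, groups = groups,
                 region_id = "test"),
            class = "curve_set")
}
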