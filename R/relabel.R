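#' Count adjacent 0-2 genotype flips
#'
#' The flip count of a region is the number of subject-level adjacent variant
#' pairs whose codes jump directly between the two homozygotes: summed over
#' subjects i and adjacent pairs (j, j+1), the indicator that
#' `(code_ij, code_i,j+1)` is `(0,2)` or `(2,0)`. Persistent flips are the
#' signature of negative pairwise LD between minor alleles and force
#' high-frequency oscillations into fitted genotype curves.
#'
#' @param G A complete (imputed) [genotype_matrix()] or plain 0/1/2 matrix.
#' @return Non-negative integer flip count.
#' @seealso [minimize_flips()]
#' @export
flip_cost <- function(G) {
  codes <- .codes(G)
  if (anyNA(codes)) stop("flip_cost requires a complete (imputed) matrix")
  p <- ncol(codes)
  if (p < 2) return(0L)
  a <- codes[, -p, drop = FALSE]
  b <- codes[, -1, drop = FALSE]
  sum((a == 0 & b == 2) | (a == 2 & b == 0))
}

# Transition cost between adjacent variant columns a, b under flip states
# (s1, s2); flipping maps code x -> 2 - x for all subjects at that variant.
.pair_cost <- function(a, b, s1, s2) {
  if (s1 == 1) a <- 2 - a
  if (s2 == 1) b <- 2 - b
  sum((a == 0 & b == 2) | (a == 2 & b == 0))
}

#' Flip-minimizing genotype relabeling
#'
#' Chooses, for each variant, whether to swap which homozygote is coded 0
#' versus 2 (applied to all subjects simultaneously) so that the total
#' adjacent 0-2 flip count [flip_cost()] of the region is minimized. Because
#' variants form a chain and each variant has only two states, the exact
#' optimum is found by dynamic programming over the p variants with the four
#' pairwise transition costs per adjacent pair; no greedy approximation is
#' involved. Among cost-optimal solutions the one with fewer flipped
#' variants is preferred, remaining ties resolved toward "not flipped" at
#' the leftmost differing variant, so the result is deterministic (and a
#' cost-0 input is returned unchanged).
#'
#' @param G A complete (imputed) [genotype_matrix()] or plain 0/1/2 matrix.
#' @return A list with components
#'   \describe{
#'     \item{flip_vector}{object of class `flip_vector`: binary `flips`
#'       (1 = variant recoded 0<->2), `cost_before`, `cost_after`.}
#'     \item{genotypes}{the relabeled genotype matrix, same class as `G`.}
#'   }
#' @export
minimize_flips <- function(G) {
  codes <- .codes(G)
  if (anyNA(codes)) stop("minimize_flips requires a complete (imputed) matrix")
  p <- ncol(codes)
  cost_before <- flip_cost(codes)

  if (p < 2 || cost_before == 0) {
    fv <- structure(list(flips = integer(p), cost_before = cost_before,
                         cost_after = cost_before), class = "flip_vector")
    return(list(flip_vector = fv, genotypes = G))
  }

  # four transition costs per adjacent pair, states indexed [s_j+1, s_{j+1}+1]
  trans <- array(0, dim = c(2, 2, p - 1))
  for (j in seq_len(p - 1)) {
    a <- codes[, j]; b <- codes[, j + 1]
    for (s1 in 0:1) for (s2 in 0:1) {
      trans[s1 + 1, s2 + 1, j] <- .pair_cost(a, b, s1, s2)
    }
  }

  # suffix DP on (cost, n_flips) combined lexicographically; n_flips <= p so
  # cost * (p + 1) + n_flips is an exact total order in doubles
  big <- p + 1
  g <- matrix(0, 2, p)            # best score from variant j onward given state
  g[, p] <- c(0, 1)               # flipping the last variant costs one flip
  for (j in (p - 1):1) {
    for (s in 0:1) {
      g[s + 1, j] <- s + min(trans[s + 1, 1, j] * big + g[1, j + 1],
                             trans[s + 1, 2, j] * big + g[2, j + 1])
    }
  }
  flips <- integer(p)
  flips[1] <- if (g[1, 1] <= g[2, 1]) 0L else 1L   # prefer unflipped on ties
  for (j in 2:p) {
    s_prev <- flips[j - 1]
    score0 <- trans[s_prev + 1, 1, j - 1] * big + g[1, j]
    score1 <- trans[s_prev + 1, 2, j - 1] * big + g[2, j]
    flips[j] <- if (score0 <= score1) 0L else 1L
  }

  relabeled <- apply_flips(G, flips)
  cost_after <- flip_cost(.codes(relabeled))
  fv <- structure(list(flips = flips, cost_before = cost_before,
                       cost_after = cost_after), class = "flip_vector")
  list(flip_vector = fv, genotypes = relabeled)
}

#' @export
print.flip_vector <- function(x, ...) {
  cat("flip_vector: ", sum(x$flips), "/", length(x$flips),
      " variants flipped; flip cost ", x$cost_before, " -> ", x$cost_after,
      "\n", sep = "")
  invisible(x)
}

#' Apply (or undo) a flip vector
#'
#' Recodes `x -> 2 - x` at every variant with flip indicator 1, for all
#' subjects. Applying the same flips twice restores the input.
#'
#' @param G A [genotype_matrix()] or plain matrix.
#' @param flips Binary vector of length p, or a `flip_vector`.
#' @return Same class as `G`, relabeled.
#' @export
apply_flips <- function(G, flips) {
  if (inherits(flips, "flip_vector")) flips <- flips$flips
  codes <- .codes(G)
  if (length(flips) != ncol(codes)) stop("flips length must equal p")
  w <- which(flips == 1)
  if (length(w)) codes[, w] <- 2 - codes[, w]
  if (inherits(G, "genotype_matrix")) {
    G$codes <- codes
    G
  } else {
    codes
  }
}

#' Serialize a flip vector for audit
#'
#' @param fv A `flip_vector` from [minimize_flips()].
#' @param positions Optional variant positions for the first column.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_flips_tsv <- function(fv, path, positions = NULL) {
  stopifnot(inherits(fv, "flip_vector"))
  if (is.null(positions)) positions <- seq_along(fv$flips)
  utils::write.table(
    data.frame(position = positions, flipped = fv$flips),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
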