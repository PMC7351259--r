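#' Two-level orthogonal array L_n(2^(n-1))
#'
#' Builds the canonical two-level orthogonal array with `n = 2^k` runs and
#' `n - 1` columns. Column j corresponds to the non-empty subset of the k
#' basis bits obtained by bit-reversing j; the entry for run i (0-based) is
#' `1 + parity(popcount(i AND mask))`. This ordering reproduces the standard
#' Taguchi L4/L8/L16 layouts: every column holds each level `n/2` times and
#' every pair of columns holds each of the four level pairs `n/4` times.
#'
#' @param k Positive integer; the array has `2^k` runs.
#' @return Integer matrix of levels 1/2 with `2^k` rows and `2^k - 1`
#'   columns.
#' @export
#' @examples
#' orthogonal_array(3)  # the L8(2^7) array
orthogonal_array <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1)
    stop("'k' must be a positive integer")
  k <- as.integer(k)
  n <- 2L^k
  bitrev <- function(j) {
    bits <- as.integer(intToBits(j))[seq_len(k)]
    as.integer(sum(rev(bits) * 2^(seq_len(k) - 1L)))
  }
  masks <- vapply(seq_len(n - 1L), bitrev, integer(1))
  oa <- matrix(0L, n, n - 1L)
  for (i in 0:(n - 1L)) {
    for (j in seq_along(masks)) {
      pc <- sum(as.integer(intToBits(bitwAnd(i, masks[j]))))
      oa[i + 1L, j] <- 1L + pc %% 2L
    }
  }
  oa
}

#' Signal-to-noise value of a fitness response
#'
#' Larger-the-better, sign-preserving square: `y^2` for `y >= 0`, `-(y^2)`
#' for negative `y`.
#'
#' @param y Numeric fitness value(s).
#' @return Numeric of the same length.
#' @export
snr_value <- function(y) sign(y) * y^2

#' Per-factor level effects from an orthogonal-array experiment
#'
#' `E[f, l]` is the sum of the run SNR values over the runs in which factor
#' f (assigned to array column f) sits at level l; for every factor the two
#' level effects sum to the grand SNR total. The better level is the argmax,
#' with ties resolved to level 1.
#'
#' @param oa Orthogonal array from [orthogonal_array()].
#' @param etas Numeric vector of SNR values, one per array run.
#' @param q Number of factors (`q <= ncol(oa)`).
#' @return List with matrix `effects` (q x 2) and integer vector
#'   `best_level` (length q).
#' @export
factor_effects <- function(oa, etas, q) {
  if (length(etas) != nrow(oa))
    stop("'etas' must have one value per orthogonal-array run")
  if (q < 1L || q > ncol(oa))
    stop("'q' must be between 1 and the number of array columns")
  eff <- matrix(0, q, 2L, dimnames = list(NULL, c("level1", "level2")))
  for (f in seq_len(q)) {
    eff[f, 1L] <- sum(etas[oa[, f] == 1L])
    eff[f, 2L] <- sum(etas[oa[, f] == 2L])
  }
  list(effects = eff,
       best_level = ifelse(eff[, 1L] >= eff[, 2L], 1L, 2L))
}

# replace duplicated SNP slots left-to-right by uniform draws from the
# unused SNPs, keeping each slot's genotype; consumes the RNG stream
repair_duplicates <- function(snps, genotypes, n_snps) {
  for (j in seq_along(snps)) {
    if (snps[j] %in% snps[seq_len(j - 1L)]) {
      free <- setdiff(seq_len(n_snps), snps)  # SNPs not in the barcode now
      snps[j] <- free[sample.int(length(free), 1L)]
    }
  }
  list(snps = snps, genotypes = genotypes)
}

#' Taguchi refinement of two parent barcodes into one offspring
#'
#' Runs a matrix experiment on the smallest two-level orthogonal array with
#' at least m columns (m = barcode order): each run composes a candidate
#' barcode taking slot j (SNP index plus its genotype) from parent 1 at
#' level 1 or parent 2 at level 2, repairs any duplicate SNP indices, and
#' scores it by the sign-preserving squared fitness. Per-slot level effects
#' then pick each slot from its better parent, and the composed
#' predicted-optimal barcode is repaired, evaluated and returned as-is.
#' Each call costs `n_runs + 1` fitness evaluations.
#'
#' With slots mapped to the first m array columns, a factor can be aliased
#' with an interaction of others whenever `m > log2(n_runs)`, so the
#' predicted optimum is a heuristic, not the guaranteed best of the `2^m`
#' slot selections (it is guaranteed only when the used columns form a full
#' factorial, e.g. m = 2).
#'
#' @param parent1,parent2 `snp_barcode`s of equal order.
#' @param fitness_fn Function `(snps, genotypes) -> numeric` scoring a
#'   candidate barcode.
#' @param n_snps Number of SNPs available (for duplicate repair).
#' @return An `snp_barcode`.
#' @export
taguchi_combine <- function(parent1, parent2, fitness_fn, n_snps) {
  m <- length(parent1$snps)
  if (length(parent2$snps) != m)
    stop("parents must have the same barcode order")
  k <- max(1L, ceiling(log2(m + 1L)))
  oa <- orthogonal_array(k)
  compose <- function(lev) {
    s <- parent2$snps; g <- parent2$genotypes
    take1 <- lev == 1L
    s[take1] <- parent1$snps[take1]
    g[take1] <- parent1$genotypes[take1]
    repair_duplicates(s, g, n_snps)
  }
  etas <- numeric(nrow(oa))
  for (i in seq_len(nrow(oa))) {
    cand <- compose(oa[i, seq_len(m)])
    etas[i] <- snr_value(fitness_fn(cand$snps, cand$genotypes))
  }
  opt <- compose(factor_effects(oa, etas, m)$best_level)
  fitness_fn(opt$snps, opt$genotypes)  # evaluated as part of the budget
  barcode(opt$snps, opt$genotypes)
}
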