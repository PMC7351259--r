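#' SNP barcode objects
#'
#' An order-m barcode pairs m distinct SNP indices with m genotype codes in
#' `{1, 2, 3}`; a sample carries the barcode iff it matches every one of the
#' m genotypes. Slot j (its SNP together with its genotype) is the unit that
#' all search operators exchange.
#'
#' @param snps Integer vector of distinct 1-based SNP indices.
#' @param genotypes Integer vector of genotype codes (1/2/3), same length.
#' @return An object of class `snp_barcode`.
#' @export
#' @examples
#' barcode(c(10, 17), c(2, 1))
barcode <- function(snps, genotypes) {
  snps <- as.integer(snps); genotypes <- as.integer(genotypes)
  if (length(snps) < 1L) stop("a barcode must contain at least one SNP")
  if (length(snps) != length(genotypes))
    stop("'snps' and 'genotypes' must have the same length")
  if (anyDuplicated(snps)) stop("barcode SNP indices must be distinct")
  if (any(is.na(snps)) || any(snps < 1L))
    stop("barcode SNP indices must be positive integers")
  if (any(is.na(genotypes)) || any(!genotypes %in% 1:3))
    stop("genotype codes must be 1, 2 or 3")
  structure(list(snps = snps, genotypes = genotypes), class = "snp_barcode")
}

#' @export
format.snp_barcode <- function(x, ...) {
  paste0("snps=", paste(x$snps, collapse = ","),
         " genotypes=", paste(x$genotypes, collapse = "-"))
}

#' @export
print.snp_barcode <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse the barcode text form `snps=1,10,17 genotypes=1-2-1`
#'
#' @param text A single string in the format produced by
#'   `format()` on an `snp_barcode`.
#' @return An `snp_barcode`.
#' @export
parse_barcode <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*snps=([0-9,]+)\\s+genotypes=([0-9-]+)\\s*$", text))[[1]]
  if (length(m) != 3L)
    stop("malformed barcode text '", text,
         "' (expected e.g. 'snps=1,10 genotypes=1-2')")
  barcode(as.integer(strsplit(m[2], ",")[[1]]),
          as.integer(strsplit(m[3], "-")[[1]]))
}

# deterministic total order: lexicographic on (sorted SNP indices, their
# genotype codes); used for all tie-breaks when fitness values are equal
barcode_key <- function(b) {
  o <- order(b$snps)
  paste(sprintf("%03d", c(b$snps[o], b$genotypes[o])), collapse = "")
}

#' Does a sample carry a barcode?
#'
#' @param sample_genotypes Integer vector of genotype codes for one sample,
#'   covering all SNP indices the barcode uses.
#' @param bc An `snp_barcode`.
#' @return `TRUE` iff the sample matches every (SNP, genotype) pair.
#' @export
matches <- function(sample_genotypes, bc) {
  if (any(bc$snps > length(sample_genotypes)))
    stop("barcode SNP index out of range for this sample")
  all(sample_genotypes[bc$snps] == bc$genotypes)
}

#' 2x2 contingency table of a barcode against a cohort
#'
#' Counts barcode carriers and non-carriers among cases and controls:
#' `tp` cases matching, `fp` controls matching, `fn` cases not matching,
#' `tn` controls not matching.
#'
#' @param cohort An `snp_cohort`.
#' @param bc An `snp_barcode`.
#' @return An object of class `contingency2x2` (list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @export
contingency <- function(cohort, bc) {
  stopifnot(inherits(cohort, "snp_cohort"), inherits(bc, "snp_barcode"))
  is_case <- cohort$labels == "case"
  cnt <- match_counts_cpp(cohort$genotypes, is_case, bc$snps, bc$genotypes)
  contingency2x2(tp = cnt[1], fp = cnt[2],
                 fn = sum(is_case) - cnt[1], tn = sum(!is_case) - cnt[2])
}

#' Build a 2x2 contingency table from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (cases matching,
#'   controls matching, cases not matching, controls not matching).
#' @return An object of class `contingency2x2`.
#' @export
contingency2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0))
    stop("contingency cells must be non-negative counts")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("match", "no match"),
                              c("case", "control")))
  print(m)
  invisible(x)
}

#' Case-control fitness of a barcode
#'
#' The difference between the number of controls carrying the barcode and
#' the number of cases carrying it. Large positive values flag putatively
#' protective combinations (odds ratio < 1).
#'
#' @inheritParams contingency
#' @return Integer fitness value.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 200, seed = 1)
#' barcode_fitness(ch, barcode(c(10, 17), c(2, 1)))
barcode_fitness <- function(cohort, bc) {
  ct <- contingency(cohort, bc)
  ct$fp - ct$tp
}

# fast closure over a cohort: fitness(snps, genotypes) with an eval counter;
# carrier indicators are packed into per-(SNP, genotype) bitsets once, so an
# evaluation is m AND-reductions plus popcounts
make_evaluator <- function(cohort) {
  cache <- build_mask_cache(cohort$genotypes, cohort$labels == "case")
  n_evals <- 0L
  list(
    fitness = function(snps, genotypes) {
      n_evals <<- n_evals + 1L
      cnt <- masked_counts_cpp(cache, snps, genotypes)
      cnt[2] - cnt[1]
    },
    cache = cache,
    count = function() n_evals,
    n_snps = ncol(cohort$genotypes)
  )
}

#' Draw a random barcode
#'
#' SNP indices are drawn uniformly without replacement; genotypes uniformly
#' from `{1, 2, 3}`. Consumes the current RNG stream.
#'
#' @param m Barcode order.
#' @param n_snps Number of SNPs available.
#' @return An `snp_barcode`.
#' @export
random_barcode <- function(m, n_snps) {
  if (m < 1L || m > n_snps)
    stop("barcode order must be between 1 and the number of SNPs")
  barcode(sample.int(n_snps, m), sample.int(3L, m, replace = TRUE))
}
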