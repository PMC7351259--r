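# Independent naive oracles (pure R, sample-by-sample double loops) and
# small fixture builders used across the test files.

# cohort from an explicit genotype matrix and label vector
toy_cohort <- function(geno, labels) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  snpbarcode:::new_snp_cohort(
    geno, factor(labels, levels = c("case", "control")),
    sample_ids = paste0("s", seq_len(nrow(geno))),
    snp_defs = snpbarcode:::observed_defs(
      geno, factor(labels, levels = c("case", "control")), colnames(geno)))
}

# small random cohort (codes uniform, half cases / half controls)
random_toy_cohort <- function(n_per_group, n_snps) {
  geno <- matrix(sample(1:3, 2 * n_per_group * n_snps, replace = TRUE),
                 nrow = 2 * n_per_group)
  toy_cohort(geno, rep(c("case", "control"), each = n_per_group))
}

# naive double-loop contingency count, independent of the C++ kernel
naive_contingency <- function(cohort, bc) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(cohort$genotypes))) {
    hit <- TRUE
    for (j in seq_along(bc$snps)) {
      if (cohort$genotypes[i, bc$snps[j]] != bc$genotypes[j]) {
        hit <- FALSE
        break
      }
    }
    if (cohort$labels[i] == "case") {
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (hit) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  contingency2x2(tp, fp, fn, tn)
}

naive_fitness <- function(cohort, bc) {
  ct <- naive_contingency(cohort, bc)
  ct$fp - ct$tp
}

strip_events <- function(b) {
  attr(b, "n_events") <- NULL
  b
}

# additive slot fitness over a weight matrix w[snp, genotype]
additive_fitness_fn <- function(w) {
  function(snps, genos) sum(w[cbind(snps, genos)])
}

# brute-force argmax over the 2^m parent-slot selections (no repair needed
# when parent SNP sets are disjoint)
bruteforce_slot_argmax <- function(parent1, parent2, fitness_fn) {
  m <- length(parent1$snps)
  grid <- as.matrix(expand.grid(rep(list(1:2), m)))
  vals <- apply(grid, 1, function(lev) {
    take1 <- lev == 1
    s <- parent2$snps; g <- parent2$genotypes
    s[take1] <- parent1$snps[take1]
    g[take1] <- parent1$genotypes[take1]
    fitness_fn(s, g)
  })
  max(vals)
}
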