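#' Odds ratio of a 2x2 barcode contingency table
#'
#' `OR = (tp * tn) / (fp * fn)`, where tp/fp are the cases/controls carrying
#' the barcode and fn/tn those not carrying it. OR < 1 reads as a protective
#' association. A zero denominator is reported as `NA` (the convention used
#' for reference rows in published tables).
#'
#' @param ct A `contingency2x2` (see [contingency()], [contingency2x2()]).
#' @return Numeric odds ratio, or `NA` if undefined.
#' @export
#' @examples
#' odds_ratio(contingency2x2(tp = 1179, fp = 1309, fn = 3821, tn = 3691))
odds_ratio <- function(ct) {
  stopifnot(inherits(ct, "contingency2x2"))
  if (ct$fp == 0L || ct$fn == 0L) return(NA_real_)
  (as.numeric(ct$tp) * ct$tn) / (as.numeric(ct$fp) * ct$fn)
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-scale interval `exp(log(OR) +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`.
#' Undefined (all `NA`) when any cell is zero.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level, default 0.95.
#' @return Numeric `c(low, high)`.
#' @export
or_confidence_interval <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "contingency2x2"))
  cells <- c(ct$tp, ct$fp, ct$fn, ct$tn)
  if (any(cells == 0L)) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  exp(log(odds_ratio(ct)) + c(-1, 1) * z * se)
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Uncorrected Pearson statistic
#' `N (tp*tn - fp*fn)^2 / ((tp+fp)(fn+tn)(tp+fn)(fp+tn))` referred to the
#' chi-square distribution with one degree of freedom. Undefined (`NA`) when
#' any margin is zero.
#'
#' @inheritParams odds_ratio
#' @return P-value in `[0, 1]`, or `NA`.
#' @export
or_p_value <- function(ct) {
  stopifnot(inherits(ct, "contingency2x2"))
  tp <- as.numeric(ct$tp); fp <- as.numeric(ct$fp)
  fn <- as.numeric(ct$fn); tn <- as.numeric(ct$tn)
  margins <- c(tp + fp, fn + tn, tp + fn, fp + tn)
  if (any(margins == 0)) return(NA_real_)
  n <- tp + fp + fn + tn
  stat <- n * (tp * tn - fp * fn)^2 / prod(margins)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Single-SNP odds ratio against the genotype-1 reference
#'
#' For one SNP, compares carriers of genotype `g` (2 or 3) with carriers of
#' the reference genotype 1: `OR = (case_g * control_1) / (control_g *
#' case_1)`, with Woolf CI and chi-square p-value on the same 2x2 table.
#'
#' @param def One row of [snp_table()] (or a list with fields `case1..3`,
#'   `control1..3`).
#' @param genotype Genotype code 2 or 3.
#' @return A `barcode_assoc` (see [barcode_association()]).
#' @export
#' @examples
#' single_snp_odds_ratio(snp_table()[8, ], 3)  # rs2229765 AA, OR 0.82
single_snp_odds_ratio <- function(def, genotype) {
  if (!genotype %in% 2:3)
    stop("'genotype' must be 2 or 3 (genotype 1 is the reference)")
  ct <- contingency2x2(tp = def[[paste0("case", genotype)]],
                       fp = def[[paste0("control", genotype)]],
                       fn = def[["case1"]], tn = def[["control1"]])
  new_assoc(ct, label = paste0(def[["rsid"]], " genotype ", genotype,
                               " vs 1"))
}

#' Association statistics for a barcode in a cohort
#'
#' Contingency table, odds ratio, Woolf 95% CI, Pearson chi-square p-value
#' and the control-minus-case carrier difference (the search fitness).
#'
#' @param cohort An `snp_cohort`.
#' @param bc An `snp_barcode`.
#' @return An object of class `barcode_assoc`: list with `barcode`, `table`
#'   (`contingency2x2`), `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `difference`.
#' @export
barcode_association <- function(cohort, bc) {
  new_assoc(contingency(cohort, bc), barcode = bc,
            label = format(bc))
}

new_assoc <- function(ct, barcode = NULL, label = "") {
  ci <- or_confidence_interval(ct)
  structure(list(barcode = barcode, label = label, table = ct,
                 odds_ratio = odds_ratio(ct), ci_low = ci[1],
                 ci_high = ci[2], p_value = or_p_value(ct),
                 difference = ct$fp - ct$tp),
            class = "barcode_assoc")
}

#' @export
print.barcode_assoc <- function(x, ...) {
  cat(x$label, "\n")
  cat(sprintf("  controls matching %d, cases matching %d (difference %d)\n",
              x$table$fp, x$table$tp, x$difference))
  cat(sprintf("  OR %s, 95%% CI %s, p %s\n", fmt_or(x$odds_ratio),
              fmt_ci(x$ci_low, x$ci_high), fmt_p(x$p_value)))
  invisible(x)
}

fmt_or <- function(or) if (is.na(or)) "N/A" else sprintf("%.3f", or)
fmt_ci <- function(lo, hi) {
  if (is.na(lo)) "N/A" else sprintf("%.2f-%.2f", lo, hi)
}
fmt_p <- function(p) {
  if (is.na(p)) "N/A"
  else if (p < 0.001) "<.001"
  else sub("^0", "", sprintf("%.3f", p))
}

#' Exhaustive enumeration of all order-m barcodes
#'
#' Scans every combination of m SNPs times every genotype assignment
#' (`choose(n_snps, m) * 3^m` candidates) and returns all fitness-maximizing
#' barcodes, the guaranteed global optimum used as the oracle for the
#' stochastic searches. Refuses (with the candidate count) when the space
#' exceeds `max_candidates`.
#'
#' @param cohort An `snp_cohort`.
#' @param order Barcode order m.
#' @param max_candidates Enumeration budget guard.
#' @return List with `best_fitness`, `barcodes` (all maximizers, in the
#'   deterministic barcode order) and `n_candidates`.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 1)
#' exhaustive_search(ch, 1)$best_fitness
exhaustive_search <- function(cohort, order, max_candidates = 1e6) {
  stopifnot(inherits(cohort, "snp_cohort"))
  n_snps <- ncol(cohort$genotypes)
  if (order < 1 || order > n_snps)
    stop("barcode order must be between 1 and the number of SNPs")
  n_cand <- choose(n_snps, order) * 3^order
  if (n_cand > max_candidates)
    stop(sprintf("exhaustive search refused: %.0f candidates exceed the budget of %.0f",
                 n_cand, max_candidates))
  cache <- build_mask_cache(cohort$genotypes, cohort$labels == "case")
  combos <- combn(n_snps, order)
  codes <- as.matrix(expand.grid(rep(list(1:3), order),
                                 KEEP.OUT.ATTRS = FALSE))
  storage.mode(codes) <- "integer"
  best_fit <- -Inf
  best <- list()
  for (i in seq_len(ncol(combos))) {
    snps <- combos[, i]
    fit <- masked_block_fitness_cpp(cache, snps, codes)
    top <- max(fit)
    if (top > best_fit) { best_fit <- top; best <- list() }
    if (top == best_fit) {
      for (r in which(fit == top))
        best <- c(best, list(barcode(snps, codes[r, ])))
    }
  }
  keys <- vapply(best, barcode_key, character(1))
  list(best_fitness = best_fit, barcodes = best[order(keys)],
       n_candidates = n_cand)
}

#' Published best-barcode table
#'
#' The best protective SNP barcodes (orders 2-7) reported for the 26-SNP
#' growth-factor cohort by each search method, with their printed control
#' and case carrier counts. These counts depend on the original authors'
#' (unrecorded) simulation draw, so they are shipped as data for recomputing
#' odds-ratio statistics, not as behavior a reimplementation reproduces.
#'
#' @return Data frame with columns `order`, `method`, `snps`, `genotypes`,
#'   `control_n`, `case_n`.
#' @export
#' @examples
#' pb <- published_barcodes()
#' subset(pb, method == "htga" & order == 2)
published_barcodes <- function() {
  read.csv(text = published_barcodes_csv, stringsAsFactors = FALSE)
}

published_barcodes_csv <- '
order,method,snps,genotypes,control_n,case_n
2,pso,"1,8",1-3,941,816
2,cpso,"1,8",1-3,941,816
2,ga,"1,10",1-2,1926,1823
2,htga,"10,17",2-1,1309,1179
3,pso,"8,9,22",3-1-2,269,225
3,cpso,"3,8,9",1-3-1,371,319
3,ga,"1,8,15",1-3-1,624,527
3,htga,"1,10,17",1-2-1,1158,1035
4,pso,"4,8,14,22",2-3-1-2,99,76
4,cpso,"10,17,21,23",2-1-1-1,268,223
4,ga,"1,10,17,21",1-2-1-1,795,692
4,htga,"1,10,17,21",1-2-1-1,795,692
5,pso,"5,6,8,9,26",1-1-3-2-1,91,75
5,cpso,"2,4,8,11,18",1-2-3-1-2,44,32
5,ga,"1,4,15,17,21",1-1-1-1-1,657,585
5,htga,"1,10,17,21,26",1-2-1-1-1,603,520
6,pso,"4,8,15,19,22,24",1-3-2-2-1-3,2,0
6,cpso,"3,4,12,16,20,24",1-1-1-2-2-3,28,21
6,ga,"1,2,4,6,15,18",1-1-1-1-1-2,276,247
6,htga,"1,10,15,17,21,26",1-2-1-1-1-1,394,327
7,pso,"5,8,11,13,14,24,25",1-1-3-1-1-2-1,6,3
7,cpso,"10,12,16,17,19,22,26",2-2-2-1-2-2-1,27,20
7,ga,"1,2,6,7,10,14,15",1-1-1-3-2-1-1,38,25
7,htga,"1,10,13,15,17,21,26",1-2-2-1-1-1-1,185,141
'

#' Association table from published carrier counts
#'
#' Rebuilds the 2x2 table for one published barcode row from its printed
#' control/case carrier counts (assuming 5000 samples per group) and
#' recomputes OR, CI and p-value.
#'
#' @param row One row of [published_barcodes()].
#' @param n_per_group Group size the counts refer to.
#' @return A `barcode_assoc`.
#' @export
published_association <- function(row, n_per_group = 5000) {
  ct <- contingency2x2(tp = row$case_n, fp = row$control_n,
                       fn = n_per_group - row$case_n,
                       tn = n_per_group - row$control_n)
  new_assoc(ct, barcode = parse_barcode(
    paste0("snps=", row$snps, " genotypes=", row$genotypes)),
    label = sprintf("%s order-%d barcode", toupper(row$method), row$order))
}

#' Write a report of barcode associations as TSV
#'
#' One row per association in the published layout (barcode, control/case
#' carrier counts, difference, OR to 3 decimals, 95% CI to 2 decimals,
#' p-value to 3 decimals with `<.001` below), each followed by its
#' complementary "Other" row (the non-carriers).
#'
#' @param results List of `barcode_assoc` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  header <- paste("barcode", "snp_genotypes", "control_number",
                  "case_number", "difference", "OR", "CI95", "p_value",
                  sep = "\t")
  lines <- character(0)
  for (a in results) {
    bc <- if (!is.null(a$barcode)) paste(a$barcode$snps, collapse = ",")
      else a$label
    gt <- if (!is.null(a$barcode)) paste(a$barcode$genotypes,
                                         collapse = "-") else ""
    lines <- c(lines,
      paste(bc, gt, a$table$fp, a$table$tp, a$difference,
            fmt_or(a$odds_ratio), fmt_ci(a$ci_low, a$ci_high),
            fmt_p(a$p_value), sep = "\t"),
      paste("Other", "", a$table$tn, a$table$fn, "", "N/A", "N/A", "N/A",
            sep = "\t"))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
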