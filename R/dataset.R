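#' Packaged 26-SNP growth-factor-gene definition table
#'
#' Per-genotype case and control counts for 26 SNPs in eight growth
#' factor-related genes (*EGF*, *IGF1*, *IGF1R*, *IGF2*, *IGFBP3*, *IL10*,
#' *TGFB1*, *VEGF*), each group already normalized to 5000 individuals.
#' These counts are the simulation marginals from which [generate_cohort()]
#' rebuilds a case-control genotype matrix with exact per-SNP counts.
#'
#' Genotype codes are 1 = homozygous major, 2 = heterozygous, 3 = homozygous
#' minor; the corresponding allele labels are in `label1`..`label3`.
#'
#' @return A data frame with one row per SNP and columns `index`, `rsid`,
#'   `gene`, `label1`..`label3`, `case1`..`case3` and `control1`..`control3`.
#' @export
#' @examples
#' tab <- snp_table()
#' rowSums(tab[, c("case1", "case2", "case3")])  # all 5000
snp_table <- function() {
  tab <- read.csv(text = snp_table_csv, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 26L)
  tab
}

# index,rsid,gene,labels,case counts,control counts ("case number/normal number")
snp_table_csv <- "
index,rsid,gene,label1,label2,label3,case1,case2,case3,control1,control2,control3
1,rs2237054,EGF,TT,TA,AA,4408,570,22,4418,569,13
2,rs5742678,IGF1,CC,CG,GG,2797,1844,359,2866,1837,297
3,rs1549593,IGF1,CC,CA,AA,2924,1753,323,2970,1771,259
4,rs6220,IGF1,AA,AG,GG,2643,1933,424,2698,1951,351
5,rs2946834,IGF1,CC,CT,TT,2295,2171,534,2336,2150,514
6,rs1568502,IGF1R,AA,AG,GG,2914,1840,246,2955,1807,238
7,IGF1R-10,IGF1R,AA,Aa,aa,3169,1545,286,3201,1582,217
8,rs2229765,IGF1R,GG,GA,AA,1523,2533,944,1429,2489,1082
9,rs8030950,IGF1R,CC,CA,AA,2737,1902,361,2745,1917,338
10,rs680,IGF2,GG,GA,AA,2538,2074,388,2451,2183,366
11,rs3741211,IGF2,TT,TC,CC,1936,2367,697,1971,2269,760
12,IGF2-05,IGF2,AA,Aa,aa,2651,1955,394,2694,1952,354
13,IGF2-06,IGF2,AA,Aa,aa,2160,2237,603,2162,2284,554
14,rs2132571,IGFBP3,GG,GA,AA,2415,2163,422,2407,2157,436
15,rs2471551,IGFBP3,GG,GC,CC,3225,1591,184,3284,1515,201
16,rs2854744,IGFBP3,AA,AC,CC,1538,2487,975,1469,2475,1056
17,rs2132572,IGFBP3,GG,GA,AA,2908,1805,287,3027,1728,245
18,rs3024496,IL10,TT,TC,CC,1218,2533,1249,1235,2549,1216
19,rs1800872,IL10,CC,CA,AA,3059,1660,281,3017,1722,261
20,rs1800890,IL10,TT,TA,AA,1703,2455,842,1701,2508,791
21,rs1554286,IL10,CC,CT,TT,3400,1431,169,3446,1410,144
22,rs1800470,TGFB1,TT,TC,CC,1850,2372,778,1914,2399,687
23,rs699947,VEGF,CC,CA,AA,1236,2511,1253,1273,2463,1264
24,rs1570360,VEGF,GG,GA,AA,2278,2214,508,2341,2132,527
25,rs2010963,VEGF,GG,GC,CC,2354,2133,513,2279,2157,564
26,rs3025039,VEGF,CC,CT,TT,3744,1160,96,3741,1174,85
"

#' Rescale genotype counts to a common group size
#'
#' Proportionally rescales the three genotype counts of one SNP so that they
#' sum exactly to `target_total`, using largest-remainder rounding: every
#' count is floored after exact rescaling, and the remaining units are given
#' to the genotypes with the largest fractional parts (ties go to the lower
#' genotype code). Each returned count is therefore within one unit of its
#' unrounded proportional value.
#'
#' @param counts Integer vector of three non-negative genotype counts.
#' @param target_total Positive integer; the group size to rescale to.
#' @return Integer vector of three counts summing to `target_total`.
#' @export
#' @examples
#' normalize_genotype_counts(c(2008, 259, 6), 5000)  # 4417 570 13
normalize_genotype_counts <- function(counts, target_total) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop("'counts' must be three non-negative genotype counts")
  if (sum(counts) == 0)
    stop("cannot rescale an all-zero genotype distribution")
  if (length(target_total) != 1L || is.na(target_total) || target_total < 1)
    stop("'target_total' must be a positive integer")
  exact <- counts / sum(counts) * target_total
  out <- floor(exact)
  short <- round(target_total - sum(out))
  if (short > 0) {
    frac <- exact - out
    # ties broken by lower genotype index: order() is stable for equal keys
    give <- order(frac, decreasing = TRUE)[seq_len(short)]
    out[give] <- out[give] + 1
  }
  as.integer(out)
}

#' Simulate a case-control genotype cohort with exact marginals
#'
#' For each group (case, control) and each SNP independently, builds the exact
#' multiset of genotype codes implied by the SNP's counts (rescaled to
#' `n_per_group` with [normalize_genotype_counts()]) and deals it to the
#' group's samples in a seeded random permutation. Per-SNP per-group genotype
#' counts in the result therefore equal the table counts exactly, so
#' single-SNP odds ratios recompute identically from the cohort; SNP columns
#' are mutually independent by construction (no linkage disequilibrium).
#'
#' Reproducibility: each (SNP, group) column uses its own child seed derived
#' deterministically from `seed`, so the same seed always yields a
#' bit-identical cohort and columns do not share a random stream. The
#' caller's RNG state is left untouched.
#'
#' @param snp_defs SNP definition table as returned by [snp_table()].
#' @param n_per_group Number of cases (= number of controls) to simulate.
#' @param seed Integer master seed.
#' @return An object of class `snp_cohort`: a list with integer matrix
#'   `genotypes` (rows = samples, columns = SNPs, codes 1/2/3), factor
#'   `labels` (`"case"`/`"control"`), character `sample_ids` and the
#'   `snp_defs` table.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 1)
#' table(ch$genotypes[ch$labels == "control", 8])
generate_cohort <- function(snp_defs = snp_table(), n_per_group = 5000,
                            seed = 1) {
  if (is.null(snp_defs) || nrow(snp_defs) == 0L)
    stop("'snp_defs' must contain at least one SNP definition")
  n_snps <- nrow(snp_defs)
  geno <- matrix(0L, nrow = 2L * n_per_group, ncol = n_snps,
                 dimnames = list(NULL, snp_defs$rsid))
  rows <- list(case = seq_len(n_per_group),
               control = n_per_group + seq_len(n_per_group))
  cols <- list(case = c("case1", "case2", "case3"),
               control = c("control1", "control2", "control3"))
  for (g in c("case", "control")) {
    gid <- if (g == "case") 1L else 2L
    for (s in seq_len(n_snps)) {
      counts <- normalize_genotype_counts(
        as.integer(snp_defs[s, cols[[g]]]), n_per_group)
      codes <- rep.int(1:3, counts)
      geno[rows[[g]], s] <- with_seed(child_seed(seed, s, gid),
                                      sample(codes, length(codes)))
    }
  }
  labels <- factor(rep(c("case", "control"), each = n_per_group),
                   levels = c("case", "control"))
  new_snp_cohort(geno, labels,
                 sample_ids = paste0(rep(c("case_", "control_"),
                                         each = n_per_group),
                                     rep(seq_len(n_per_group), 2L)),
                 snp_defs = snp_defs)
}

# deterministic child seed below 2^31, spreading (master, snp, group)
child_seed <- function(master, snp_index, group_id) {
  h <- (abs(as.numeric(master)) %% 2^31)
  h <- (h * 69069 + 1) %% 2^31
  h <- (h + snp_index * 2654435 + group_id * 999331) %% 2^31
  as.integer(h)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

new_snp_cohort <- function(genotypes, labels, sample_ids, snp_defs) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(labels),
            all(genotypes %in% 1:3))
  structure(list(genotypes = genotypes, labels = labels,
                 sample_ids = sample_ids, snp_defs = snp_defs),
            class = "snp_cohort")
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("snp_cohort: %d samples (%d cases, %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$labels == "case"),
              sum(x$labels == "control"), ncol(x$genotypes)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' Layout: header `sample_id,label,<rsid...>`, label `case` or `control`,
#' genotype codes 1/2/3. `read_cohort()` validates every cell and reports
#' the offending row and column on malformed input; if the SNP columns match
#' the packaged [snp_table()] rsids the packaged definitions are attached,
#' otherwise minimal definitions with observed counts are constructed.
#'
#' @param cohort An `snp_cohort`.
#' @param path File path.
#' @return `read_cohort()` returns an `snp_cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "snp_cohort"))
  df <- data.frame(sample_id = cohort$sample_ids,
                   label = as.character(cohort$labels),
                   cohort$genotypes, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- tryCatch(read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse cohort file '", path,
                                          "': ", conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 3L)
    stop("cohort file '", path,
         "' must have columns sample_id, label and at least one SNP")
  need <- c("sample_id", "label")
  if (!all(need %in% names(df)))
    stop("cohort file is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!df$label %in% c("case", "control"))
  if (length(bad))
    stop("invalid label '", df$label[bad[1]], "' in row ", bad[1],
         " (expected 'case' or 'control')")
  snp_cols <- setdiff(names(df), need)
  geno <- as.matrix(df[, snp_cols, drop = FALSE])
  for (j in seq_along(snp_cols)) {
    col <- suppressWarnings(as.integer(geno[, j]))
    bad <- which(is.na(col) | !col %in% 1:3)
    if (length(bad))
      stop("invalid genotype code '", geno[bad[1], j], "' in row ", bad[1],
           ", column '", snp_cols[j], "' (expected 1, 2 or 3)")
  }
  storage.mode(geno) <- "integer"
  labels <- factor(df$label, levels = c("case", "control"))
  builtin <- snp_table()
  defs <- if (identical(snp_cols, builtin$rsid)) builtin else
    observed_defs(geno, labels, snp_cols)
  new_snp_cohort(geno, labels, df$sample_id, defs)
}

# minimal SNP definitions from observed counts, for non-packaged cohorts
observed_defs <- function(geno, labels, rsids) {
  cnt <- function(rows, j) as.integer(tabulate(geno[rows, j], 3L))
  case <- t(vapply(seq_along(rsids), cnt, integer(3),
                   rows = which(labels == "case")))
  ctrl <- t(vapply(seq_along(rsids), cnt, integer(3),
                   rows = which(labels == "control")))
  data.frame(index = seq_along(rsids), rsid = rsids, gene = NA_character_,
             label1 = "1", label2 = "2", label3 = "3",
             case1 = case[, 1], case2 = case[, 2], case3 = case[, 3],
             control1 = ctrl[, 1], control2 = ctrl[, 2],
             control3 = ctrl[, 3], stringsAsFactors = FALSE)
}
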