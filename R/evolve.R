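#' Tournament selection of one chromosome
#'
#' Draws two population members uniformly at random (independently, so the
#' same member may be drawn twice) and returns the one with the higher
#' fitness; the first draw wins ties.
#'
#' @param population List of `snp_barcode`s.
#' @param fitnesses Numeric vector of their fitness values.
#' @return The winning `snp_barcode`.
#' @export
tournament_select <- function(population, fitnesses) {
  if (!length(population)) stop("cannot select from an empty population")
  i <- sample.int(length(population), 1L)
  j <- sample.int(length(population), 1L)
  if (fitnesses[i] >= fitnesses[j]) population[[i]] else population[[j]]
}

#' Uniform crossover of two barcodes
#'
#' For each slot j one bit is drawn; where the bit is 1 the slot's SNP index
#' together with its paired genotype is swapped between the two offspring.
#' Duplicate SNP indices created by the exchange are repaired as in
#' [taguchi_combine()] (left-to-right redraw from the unused SNPs).
#'
#' @param parent1,parent2 `snp_barcode`s of equal order.
#' @param n_snps Number of SNPs available.
#' @param bits Optional integer vector of 0/1 swap bits (one per slot);
#'   drawn uniformly when `NULL`.
#' @return List of two offspring `snp_barcode`s.
#' @export
uniform_crossover <- function(parent1, parent2, n_snps, bits = NULL) {
  m <- length(parent1$snps)
  if (length(parent2$snps) != m)
    stop("parents must have the same barcode order")
  if (is.null(bits)) bits <- sample(0:1, m, replace = TRUE)
  swap <- bits == 1L
  s1 <- parent1$snps; g1 <- parent1$genotypes
  s2 <- parent2$snps; g2 <- parent2$genotypes
  o1s <- ifelse(swap, s2, s1); o1g <- ifelse(swap, g2, g1)
  o2s <- ifelse(swap, s1, s2); o2g <- ifelse(swap, g1, g2)
  r1 <- repair_duplicates(o1s, o1g, n_snps)
  r2 <- repair_duplicates(o2s, o2g, n_snps)
  list(barcode(r1$snps, r1$genotypes), barcode(r2$snps, r2$genotypes))
}

#' Element-wise mutation of a barcode
#'
#' Each of the 2m chromosome elements (m SNP slots, then m genotype slots)
#' independently mutates with probability `p_m`. A mutating SNP element is
#' redrawn uniformly from the SNPs not currently in the barcode (kept
#' unchanged if none is available); a mutating genotype element is redrawn
#' uniformly from `{1, 2, 3}` (and may redraw its current value). The number
#' of triggered mutation events is attached as attribute `"n_events"`.
#'
#' @param bc An `snp_barcode`.
#' @param p_m Per-element mutation probability.
#' @param n_snps Number of SNPs available.
#' @return A valid `snp_barcode`.
#' @export
mutate_barcode <- function(bc, p_m, n_snps) {
  snps <- bc$snps; genos <- bc$genotypes
  m <- length(snps)
  hit <- runif(2L * m) < p_m
  for (j in seq_len(m)) {
    if (hit[j]) {
      free <- setdiff(seq_len(n_snps), snps)
      if (length(free)) snps[j] <- free[sample.int(length(free), 1L)]
    }
  }
  for (j in seq_len(m)) {
    if (hit[m + j]) genos[j] <- sample.int(3L, 1L)
  }
  structure(barcode(snps, genos), n_events = sum(hit))
}

#' Elitist replacement with duplicate removal
#'
#' Keeps the `m_keep` highest-fitness chromosomes from parents plus
#' offspring, preferring distinct chromosomes: duplicates of an already
#' retained barcode are only used to fill a shortfall. Equal fitness is
#' resolved by the deterministic barcode order (lexicographic on sorted SNP
#' indices, then genotype codes). The best-of-population fitness never
#' decreases; the duplicate removal keeps the elitist population from
#' collapsing onto copies of one attractor.
#'
#' @param parents,offspring Lists of `snp_barcode`s.
#' @param parent_fit,offspring_fit Their fitness values.
#' @param m_keep Population size to retain.
#' @return List with `population` and `fitnesses` of the survivors.
#' @export
replace_population <- function(parents, parent_fit, offspring,
                               offspring_fit, m_keep) {
  pool <- c(parents, offspring)
  fit <- c(parent_fit, offspring_fit)
  keys <- vapply(pool, barcode_key, character(1))
  ord <- order(-fit, keys)
  # distinct chromosomes first: elitism with duplicate removal preserves
  # population diversity; duplicates only fill an (unusual) shortfall
  first <- ord[!duplicated(keys[ord])]
  keep <- c(first, setdiff(ord, first))[seq_len(min(m_keep, length(pool)))]
  list(population = pool[keep], fitnesses = fit[keep])
}

#' Run the hybrid Taguchi-genetic algorithm or the plain genetic algorithm
#'
#' One iteration performs, in fixed RNG order: (1) M tournament selections
#' filling the mating pool; (2) uniform crossover on the M/2 sequential
#' mating-pool pairs, each pair crossing with probability `p_c` (a pair
#' that does not cross passes into the offspring pool unchanged); (3) HTGA
#' only:
#' `round(0.5 * M * p_c)` Taguchi refinements, each combining two distinct
#' chromosomes drawn from the offspring pool (from the mating pool while the
#' offspring pool has fewer than two members) and adding the refined
#' offspring to the pool; (4) element-wise mutation of every offspring-pool
#' member with rate `p_m`; (5) evaluation of the pool and elitist
#' replacement keeping the best M of parents plus offspring. Termination is
#' the fixed iteration count; the best-so-far fitness history is
#' non-decreasing by elitism.
#'
#' @param cohort An `snp_cohort`.
#' @param order Barcode order m.
#' @param pop_size Population size M.
#' @param iterations Iteration count T.
#' @param p_c Crossover probability.
#' @param p_m Per-element mutation probability.
#' @param seed Integer seed for the run's single RNG stream.
#' @param algorithm `"htga"` (with the Taguchi step) or `"ga"` (without).
#' @return An object of class `barcode_run`: list with `best_barcode`,
#'   `best_fitness`, `history` (per-iteration best), `evaluations`,
#'   `pool_sizes` (offspring evaluated per iteration), `method`, `seed` and
#'   the configuration.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 200, seed = 1)
#' run_htga(ch, order = 2, pop_size = 20, iterations = 10, seed = 1)
run_htga <- function(cohort, order, pop_size = 50, iterations = 1000,
                     p_c = 0.3, p_m = 0.05, seed = 1, algorithm = "htga") {
  stopifnot(inherits(cohort, "snp_cohort"))
  if (!algorithm %in% c("htga", "ga")) stop("unknown algorithm: ", algorithm)
  n_snps <- ncol(cohort$genotypes)
  if (pop_size < 2) stop("population size must be at least 2")
  if (iterations < 0) stop("iteration count must be non-negative")
  if (p_c < 0 || p_c > 1 || p_m < 0 || p_m > 1)
    stop("rates must be probabilities in [0, 1]")
  if (order < 1 || order > n_snps)
    stop("barcode order must be between 1 and the number of SNPs")

  ev <- make_evaluator(cohort)
  fit_bc <- function(b) ev$fitness(b$snps, b$genotypes)
  n_taguchi <- if (algorithm == "htga")
    as.integer(round(0.5 * pop_size * p_c)) else 0L

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pop <- replicate(pop_size, random_barcode(order, n_snps),
                   simplify = FALSE)
  fit <- vapply(pop, fit_bc, integer(1))
  history <- integer(iterations)
  pool_sizes <- integer(iterations)

  for (t in seq_len(iterations)) {
    mating <- replicate(pop_size, tournament_select(pop, fit),
                        simplify = FALSE)
    pool <- vector("list", 2L * (pop_size %/% 2L))
    for (i in seq_len(pop_size %/% 2L)) {
      if (runif(1) < p_c) {
        off <- uniform_crossover(mating[[2L * i - 1L]], mating[[2L * i]],
                                 n_snps)
      } else {
        off <- mating[c(2L * i - 1L, 2L * i)]  # pair passes through unchanged
      }
      pool[c(2L * i - 1L, 2L * i)] <- off
    }
    for (i in seq_len(n_taguchi)) {
      src <- if (length(pool) >= 2L) pool else mating
      pick <- sample.int(length(src), 2L)
      pool <- c(pool, list(taguchi_combine(src[[pick[1]]], src[[pick[2]]],
                                           ev$fitness, n_snps)))
    }
    pool <- lapply(pool, mutate_barcode, p_m = p_m, n_snps = n_snps)
    pool_fit <- vapply(pool, fit_bc, integer(1))
    pool_sizes[t] <- length(pool)
    nxt <- replace_population(pop, fit, pool, pool_fit, pop_size)
    pop <- nxt$population; fit <- nxt$fitnesses
    history[t] <- fit[1]  # survivors are sorted best-first
  }

  best <- which(fit == max(fit))
  best <- best[order(vapply(pop[best], barcode_key, character(1)))][1]
  structure(list(best_barcode = pop[[best]], best_fitness = fit[best],
                 history = history, evaluations = ev$count(),
                 pool_sizes = pool_sizes, n_taguchi = n_taguchi,
                 method = algorithm, order = order, pop_size = pop_size,
                 iterations = iterations, p_c = p_c, p_m = p_m,
                 seed = seed),
            class = "barcode_run")
}

#' @rdname run_htga
#' @export
run_ga <- function(cohort, order, pop_size = 50, iterations = 1000,
                   p_c = 0.3, p_m = 0.05, seed = 1) {
  run_htga(cohort, order, pop_size, iterations, p_c, p_m, seed,
           algorithm = "ga")
}

#' @export
print.barcode_run <- function(x, ...) {
  cat(sprintf("%s run (order %d, M=%d, T=%d, seed=%d)\n",
              toupper(x$method), x$order, x$pop_size, x$iterations, x$seed))
  cat("best barcode:", format(x$best_barcode), "\n")
  cat("best fitness:", x$best_fitness,
      sprintf("(%d fitness evaluations)\n", x$evaluations))
  invisible(x)
}
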