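test_that("tournament selection prefers the fitter of two uniform draws", {
  pop <- list(barcode(1, 1), barcode(2, 2))
  expect_error(tournament_select(list(), numeric(0)), "empty")
  expect_identical(tournament_select(pop[1], 5), pop[[1]])

  set.seed(51)
  wins <- replicate(2000, tournament_select(pop, c(10, 3))$snps)
  # winner has the higher fitness unless both draws hit the weaker member
  expect_equal(mean(wins == 1), 0.75, tolerance = 0.05)

  ties <- replicate(200, tournament_select(pop, c(7, 7))$snps)
  expect_true(all(ties %in% 1:2))  # tie rule: first-drawn chromosome
})

test_that("uniform crossover swaps SNP and genotype slots as a unit", {
  a <- barcode(c(1, 8), c(1, 3))
  b <- barcode(c(10, 17), c(2, 1))
  off <- uniform_crossover(a, b, n_snps = 26, bits = c(1, 0))
  expect_identical(off[[1]], barcode(c(10, 8), c(2, 3)))
  expect_identical(off[[2]], barcode(c(1, 17), c(1, 1)))

  same <- uniform_crossover(a, a, n_snps = 26)
  expect_identical(same[[1]], a)
  expect_identical(same[[2]], a)

  none <- uniform_crossover(a, b, n_snps = 26, bits = c(0, 0))
  expect_identical(none, list(a, b))

  expect_error(uniform_crossover(a, barcode(1, 1), 26), "same barcode")
})

test_that("crossover repairs duplicate SNPs into valid offspring", {
  set.seed(52)
  for (i in 1:30) {
    p1 <- random_barcode(3, 6)
    p2 <- random_barcode(3, 6)
    off <- uniform_crossover(p1, p2, n_snps = 6)
    for (o in off) {
      expect_identical(anyDuplicated(o$snps), 0L)
      expect_true(all(o$snps %in% 1:6) && all(o$genotypes %in% 1:3))
    }
  }
})

test_that("mutation respects the per-element rate and keeps validity", {
  b <- barcode(c(2, 9), c(1, 3))
  expect_identical(strip_events(mutate_barcode(b, 0, 26)), b)

  full <- barcode(1:5, rep(1, 5))
  mut <- mutate_barcode(full, 1, 5)  # no unused SNPs: slots keep their SNP
  expect_identical(sort(mut$snps), 1:5)
  expect_identical(attr(mut, "n_events"), 10L)

  set.seed(53)
  events <- replicate(10000, attr(mutate_barcode(b, 0.05, 26), "n_events"))
  expect_lt(abs(mean(events) / 4 - 0.05), 0.005)  # ~4.5 sd of the mean
})

test_that("replacement is elitist and prefers distinct chromosomes", {
  parents <- list(barcode(1, 1), barcode(2, 2), barcode(3, 3))
  pf <- c(9, 5, 3)
  worse <- list(barcode(4, 1), barcode(5, 1))
  r <- replace_population(parents, pf, worse, c(1, 0), 3)
  expect_identical(r$population, parents)
  expect_identical(r$fitnesses, pf)

  better <- list(barcode(6, 2))
  r2 <- replace_population(parents, pf, better, 7, 3)
  expect_identical(r2$fitnesses, c(9, 7, 5))  # worst parent evicted

  # duplicates of a retained barcode rank behind distinct chromosomes
  dup <- list(barcode(1, 1))
  r3 <- replace_population(parents, pf, dup, 9, 3)
  expect_identical(r3$fitnesses, c(9, 5, 3))
  expect_identical(r3$population, parents)

  set.seed(54)
  best <- -Inf
  pop <- lapply(1:6, function(i) random_barcode(2, 8))
  fit <- runif(6)
  for (i in 1:20) {
    off <- lapply(1:4, function(i) random_barcode(2, 8))
    of <- runif(4)
    r <- replace_population(pop, fit, off, of, 6)
    pop <- r$population
    fit <- r$fitnesses
    expect_gte(max(fit), best)
    best <- max(fit)
  }
})

test_that("search runs are deterministic and elitist", {
  ch <- generate_cohort(snp_table(), n_per_group = 150, seed = 2)
  a <- run_htga(ch, order = 2, pop_size = 20, iterations = 25, seed = 9)
  b <- run_htga(ch, order = 2, pop_size = 20, iterations = 25, seed = 9)
  expect_identical(a$best_barcode, b$best_barcode)
  expect_identical(a$history, b$history)
  expect_true(all(diff(a$history) >= 0))
  expect_identical(a$best_fitness, barcode_fitness(ch, a$best_barcode))
  expect_identical(a$best_fitness, a$history[length(a$history)])
})

test_that("zero iterations return the best of the initial population", {
  ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 2)
  h <- run_htga(ch, order = 3, pop_size = 15, iterations = 0, seed = 4)
  g <- run_ga(ch, order = 3, pop_size = 15, iterations = 0, seed = 4)
  expect_identical(h$evaluations, 15L)
  expect_length(h$history, 0)
  expect_identical(h$best_barcode, g$best_barcode)  # same init stream
  expect_identical(h$best_fitness, g$best_fitness)
})

test_that("with zero crossover and mutation the population is static", {
  ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 2)
  r <- run_ga(ch, order = 2, pop_size = 10, iterations = 15, p_c = 0,
              p_m = 0, seed = 3)
  r0 <- run_ga(ch, order = 2, pop_size = 10, iterations = 0, p_c = 0,
               p_m = 0, seed = 3)
  expect_true(all(r$history == r0$best_fitness))
})

test_that("fitness evaluation counts match the predicted budget", {
  ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 2)
  r <- run_htga(ch, order = 4, pop_size = 12, iterations = 10, seed = 8)
  n_runs <- nrow(orthogonal_array(ceiling(log2(4 + 1))))  # L8 for order 4
  expect_identical(
    r$evaluations,
    12L + sum(r$pool_sizes) + r$n_taguchi * 10L * (n_runs + 1L))
  # pool = M/2 pairs' offspring plus one child per Taguchi refinement
  expect_true(all(r$pool_sizes == 12L + r$n_taguchi))

  g <- run_ga(ch, order = 4, pop_size = 12, iterations = 10, seed = 8)
  expect_identical(g$n_taguchi, 0L)
  expect_identical(g$evaluations, 12L + sum(g$pool_sizes))
})

test_that("invalid configurations are rejected before any evaluation", {
  ch <- generate_cohort(snp_table(), n_per_group = 50, seed = 2)
  expect_error(run_htga(ch, order = 2, pop_size = 1), "at least 2")
  expect_error(run_htga(ch, order = 0), "between 1 and")
  expect_error(run_htga(ch, order = 2, p_c = 1.5), "probabilities")
  expect_error(run_htga(ch, order = 2, iterations = -1), "non-negative")
  expect_error(run_htga(ch, order = 2, algorithm = "annealing"),
               "unknown algorithm")
})

test_that("a short HTGA run finds the exhaustive 1-SNP optimum", {
  ch <- generate_cohort(snp_table(), n_per_group = 500, seed = 42)
  opt <- exhaustive_search(ch, 1)
  r <- run_htga(ch, order = 1, pop_size = 50, iterations = 50, seed = 1)
  expect_identical(r$best_fitness, opt$best_fitness)
})
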