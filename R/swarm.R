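#' Particle-swarm and chaotic particle-swarm barcode search
#'
#' Continuous relaxation of the discrete barcode space: each particle holds a
#' position of length 2m (m SNP coordinates in `[1, n_snps]`, then m genotype
#' coordinates in `[1, 3]`). Before every fitness evaluation the position is
#' decoded by rounding, clamping to the bounds and repairing duplicate SNP
#' indices (left-to-right redraw from the unused SNPs). Velocities follow
#' the standard global-best update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with per-coordinate
#' uniform `r1, r2`, clamped to half the coordinate range. In `run_pso()`
#' the inertia weight decreases linearly from `w_max` to `w_min` over the
#' iterations; in `run_cpso()` it is modulated by a logistic-map chaotic
#' sequence `z <- 4 z (1 - z)` via `w = w_min + (w_max - w_min) z`, with
#' `z0` drawn uniformly in (0, 1) avoiding the map's fixed and eventually
#' fixed points `{0, 0.25, 0.5, 0.75, 1}`.
#'
#' The published method this reimplements does not describe its PSO/CPSO
#' discrete encoding; this rounding/clamping/repair decoding is this
#' package's own choice, so published PSO/CPSO barcode tables are treated as
#' data, not as behavior these runs must match.
#'
#' @inheritParams run_htga
#' @param w_min,w_max Minimum and maximum inertia weights.
#' @param c1,c2 Cognitive and social learning factors.
#' @return A `barcode_run` (see [run_htga()]); `pool_sizes` is the swarm
#'   size evaluated per iteration.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 200, seed = 1)
#' run_pso(ch, order = 2, pop_size = 20, iterations = 10, seed = 1)
run_pso <- function(cohort, order, pop_size = 50, iterations = 1000,
                    w_min = 0.4, w_max = 0.9, c1 = 2, c2 = 2, seed = 1,
                    variant = "pso") {
  stopifnot(inherits(cohort, "snp_cohort"))
  if (!variant %in% c("pso", "cpso")) stop("unknown variant: ", variant)
  if (pop_size < 2) stop("population size must be at least 2")
  if (iterations < 0) stop("iteration count must be non-negative")
  if (w_min <= 0 || w_min > w_max) stop("need 0 < w_min <= w_max")
  if (c1 < 0 || c2 < 0) stop("learning factors must be non-negative")
  n_snps <- ncol(cohort$genotypes)
  if (order < 1 || order > n_snps)
    stop("barcode order must be between 1 and the number of SNPs")

  ev <- make_evaluator(cohort)
  m <- order
  lo <- c(rep(1, m), rep(1, m))
  hi <- c(rep(n_snps, m), rep(3, m))
  vmax <- (hi - lo) / 2

  decode <- function(x) {
    r <- pmin(pmax(round(x), lo), hi)
    rep <- repair_duplicates(as.integer(r[seq_len(m)]),
                             as.integer(r[m + seq_len(m)]), n_snps)
    barcode(rep$snps, rep$genotypes)
  }

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  pos <- lapply(seq_len(pop_size),
                function(i) lo + runif(2L * m) * (hi - lo))
  vel <- lapply(seq_len(pop_size),
                function(i) runif(2L * m, -vmax, vmax))
  pbest_pos <- pos
  decoded <- lapply(pos, decode)
  pbest_fit <- vapply(decoded, function(b) ev$fitness(b$snps, b$genotypes),
                      integer(1))
  g <- which.max(pbest_fit)
  gbest_pos <- pbest_pos[[g]]
  gbest_bc <- decoded[[g]]
  gbest_fit <- pbest_fit[g]

  if (variant == "cpso") {
    z <- runif(1)
    while (z %in% c(0, 0.25, 0.5, 0.75, 1)) z <- runif(1)
  }

  history <- integer(iterations)
  for (t in seq_len(iterations)) {
    w <- if (variant == "pso") {
      if (iterations > 1L)
        w_max - (w_max - w_min) * (t - 1) / (iterations - 1)
      else w_max
    } else {
      z <- 4 * z * (1 - z)
      w_min + (w_max - w_min) * z
    }
    for (i in seq_len(pop_size)) {
      r1 <- runif(2L * m); r2 <- runif(2L * m)
      v <- w * vel[[i]] + c1 * r1 * (pbest_pos[[i]] - pos[[i]]) +
        c2 * r2 * (gbest_pos - pos[[i]])
      v <- pmin(pmax(v, -vmax), vmax)
      x <- pmin(pmax(pos[[i]] + v, lo), hi)
      vel[[i]] <- v; pos[[i]] <- x
      bc <- decode(x)
      f <- ev$fitness(bc$snps, bc$genotypes)
      if (f > pbest_fit[i]) {
        pbest_fit[i] <- f; pbest_pos[[i]] <- x
      }
      if (f > gbest_fit) {
        gbest_fit <- f; gbest_pos <- x; gbest_bc <- bc
      }
    }
    history[t] <- gbest_fit
  }

  structure(list(best_barcode = gbest_bc, best_fitness = gbest_fit,
                 history = history, evaluations = ev$count(),
                 pool_sizes = rep(pop_size, iterations),
                 method = variant, order = order, pop_size = pop_size,
                 iterations = iterations, w_min = w_min, w_max = w_max,
                 c1 = c1, c2 = c2, seed = seed),
            class = "barcode_run")
}

#' @rdname run_pso
#' @export
run_cpso <- function(cohort, order, pop_size = 50, iterations = 1000,
                     w_min = 0.4, w_max = 0.9, c1 = 2, c2 = 2, seed = 1) {
  run_pso(cohort, order, pop_size, iterations, w_min, w_max, c1, c2, seed,
          variant = "cpso")
}

#' Logistic-map chaotic sequence
#'
#' Iterates `z <- 4 z (1 - z)`, the sequence modulating the CPSO inertia
#' weight. Stays in (0, 1) for any start in (0, 1) off the fixed points.
#'
#' @param z0 Start value in (0, 1).
#' @param n Number of iterates to return.
#' @return Numeric vector of length `n`.
#' @export
logistic_map <- function(z0, n) {
  if (z0 <= 0 || z0 >= 1) stop("'z0' must lie strictly in (0, 1)")
  z <- numeric(n)
  cur <- z0
  for (i in seq_len(n)) {
    cur <- 4 * cur * (1 - cur)
    z[i] <- cur
  }
  z
}
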