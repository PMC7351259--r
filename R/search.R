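#' Search a cohort for the best order-m SNP barcode
#'
#' Single front end over the search methods: the hybrid Taguchi-genetic
#' algorithm (`"htga"`), the plain genetic algorithm (`"ga"`), particle
#' swarm (`"pso"`), chaotic particle swarm (`"cpso"`) or exhaustive
#' enumeration (`"exhaustive"`). Defaults are the study conditions of the
#' method being reimplemented: population 50, 1000 iterations, crossover
#' rate 0.3, mutation rate 0.05, inertia weights in \[0.4, 0.9\], learning
#' factors 2. The returned object carries the best barcode found, its
#' fitness (controls carrying it minus cases carrying it), the convergence
#' history and the association statistics of the best barcode.
#'
#' @param cohort An `snp_cohort` from [generate_cohort()] or
#'   [read_cohort()].
#' @param order Barcode order m (number of SNPs combined).
#' @param method One of `"htga"`, `"ga"`, `"pso"`, `"cpso"`,
#'   `"exhaustive"`.
#' @param pop_size Population / swarm size.
#' @param iterations Iteration count.
#' @param p_c,p_m GA/HTGA crossover and mutation rates.
#' @param w_min,w_max,c1,c2 PSO/CPSO inertia weights and learning factors.
#' @param seed Integer seed (ignored by `"exhaustive"`).
#' @return An object of class `barcode_search`: list with `best_barcode`,
#'   `best_fitness`, `association` (a `barcode_assoc`), `run` (the
#'   underlying `barcode_run`, or the exhaustive result), `method`, `order`
#'   and `seed`.
#' @export
#' @examples
#' ch <- generate_cohort(snp_table(), n_per_group = 200, seed = 1)
#' fit <- barcode_search(ch, order = 2, method = "htga",
#'                       pop_size = 20, iterations = 25, seed = 7)
#' print(fit)
#' summary(fit)
barcode_search <- function(cohort, order,
                           method = c("htga", "ga", "pso", "cpso",
                                      "exhaustive"),
                           pop_size = 50, iterations = 1000, p_c = 0.3,
                           p_m = 0.05, w_min = 0.4, w_max = 0.9, c1 = 2,
                           c2 = 2, seed = 1) {
  method <- match.arg(method)
  run <- switch(method,
    htga = run_htga(cohort, order, pop_size, iterations, p_c, p_m, seed),
    ga = run_ga(cohort, order, pop_size, iterations, p_c, p_m, seed),
    pso = run_pso(cohort, order, pop_size, iterations, w_min, w_max, c1,
                  c2, seed),
    cpso = run_cpso(cohort, order, pop_size, iterations, w_min, w_max, c1,
                    c2, seed),
    exhaustive = exhaustive_search(cohort, order))
  if (method == "exhaustive") {
    best <- run$barcodes[[1]]
    best_fit <- run$best_fitness
    history <- NULL
  } else {
    best <- run$best_barcode
    best_fit <- run$best_fitness
    history <- run$history
  }
  structure(list(best_barcode = best, best_fitness = best_fit,
                 association = barcode_association(cohort, best),
                 run = run, history = history, method = method,
                 order = order, seed = seed),
            class = "barcode_search")
}

#' @export
print.barcode_search <- function(x, ...) {
  cat(sprintf("barcode_search: %s, order %d\n", toupper(x$method), x$order))
  cat("best barcode:", format(x$best_barcode), "\n")
  cat("fitness (controls - cases carrying):", x$best_fitness, "\n")
  invisible(x)
}

#' @export
summary.barcode_search <- function(object, ...) {
  print(object)
  print(object$association)
  if (!is.null(object$history))
    cat(sprintf("converged from %d to %d over %d iterations\n",
                as.integer(object$history[1]), as.integer(object$best_fitness),
                length(object$history)))
  invisible(object)
}

#' Plot the convergence history of a search
#'
#' Best-so-far fitness per iteration; flat lines mean an elitist plateau.
#'
#' @param x A `barcode_search` with a stochastic method.
#' @param ... Passed to [plot()].
#' @export
plot.barcode_search <- function(x, ...) {
  if (is.null(x$history))
    stop("exhaustive searches have no convergence history")
  plot(seq_along(x$history), x$history, type = "s",
       xlab = "iteration", ylab = "best fitness",
       main = sprintf("%s convergence (order %d)", toupper(x$method),
                      x$order), ...)
  invisible(x)
}

#' Write the per-iteration convergence history as TSV
#'
#' @param x A `barcode_search` or `barcode_run`.
#' @param path Output path; columns `iteration`, `best_fitness`.
#' @return `path`, invisibly.
#' @export
write_history <- function(x, path) {
  h <- x$history
  if (is.null(h)) stop("object has no convergence history")
  writeLines(c("iteration\tbest_fitness",
               paste(seq_along(h), h, sep = "\t")), path)
  invisible(path)
}
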