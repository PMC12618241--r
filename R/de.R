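#' Bounded differential-evolution minimiser
#'
#' Classic rand/1/bin differential evolution over a box-constrained
#' parameter space: each generation mutates a random base member with a
#' scaled difference of two others, applies binomial crossover, reflects
#' escapees back inside the bounds, and keeps the better of parent and
#' trial point.  Converges when the spread of population costs falls below
#' `tol` relative to their mean, or at `maxiter` generations.  Fully
#' reproducible from `seed`.
#'
#' @param fn objective returning a finite scalar.
#' @param lower,upper numeric bounds of equal length.
#' @param maxiter maximum generations (default 500).
#' @param popsize population size (default `15 * length(lower)`).
#' @param F mutation weight.
#' @param CR crossover probability.
#' @param tol relative convergence tolerance on population costs.
#' @param seed integer seed.
#' @param init optional matrix of candidate points (one per row) injected
#'   into the initial population, e.g. warm starts from a nested model.
#' @return list with `par`, `value`, `iterations`, `converged`,
#'   `n_evaluations`.
#' @export
de_optim <- function(fn, lower, upper, maxiter = 500, popsize = NULL,
                     F = 0.8, CR = 0.9, tol = 1e-7, seed = 1L, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  np <- popsize %||% (15L * d)
  np <- max(np, 5L)
  withr::with_seed(seed, {
    pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                  np, d)
    if (!is.null(init)) {
      init <- matrix(as.numeric(as.matrix(init)), ncol = d)
      lo <- matrix(lower, nrow(init), d, byrow = TRUE)
      hi <- matrix(upper, nrow(init), d, byrow = TRUE)
      init <- pmin(pmax(init, lo), hi)
      k <- min(nrow(init), np)
      pop[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
    }
    cost <- apply(pop, 1L, fn)
    nev <- np
    converged <- FALSE
    iter <- 0L
    while (iter < maxiter) {
      iter <- iter + 1L
      for (i in seq_len(np)) {
        idx <- sample.int(np, 3L)
        while (any(idx == i)) idx <- sample.int(np, 3L)
        mutant <- pop[idx[1L], ] + F * (pop[idx[2L], ] - pop[idx[3L], ])
        cross <- runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        trial <- ifelse(cross, mutant, pop[i, ])
        # reflect out-of-bounds components back into the box
        below <- trial < lower
        trial[below] <- pmin(upper[below],
                             2 * lower[below] - trial[below])
        above <- trial > upper
        trial[above] <- pmax(lower[above],
                             2 * upper[above] - trial[above])
        trial <- pmin(pmax(trial, lower), upper)
        tc <- fn(trial)
        nev <- nev + 1L
        if (tc <= cost[i]) {
          pop[i, ] <- trial
          cost[i] <- tc
        }
      }
      if (sd(cost) <= tol * (abs(mean(cost)) + tol)) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(cost)
    list(par = pop[best, ], value = cost[best], iterations = iter,
         converged = converged, n_evaluations = nev)
  })
}
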