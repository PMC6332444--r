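# Multi-population real-coded genetic algorithm with information-entropy
# aggregation and search-space narrowing, usable standalone on any bounded
# objective (minimization).
#
# m populations share the initial design space. Each generation the best
# fitness F_j of every population is mapped to an occurrence probability p_j
# (better population, higher probability), the information entropy
# H = -sum p_j ln p_j is recorded, and every population's search box is
# narrowed around its own best member by the factor (1 - p_j), clamped to
# the initial design space. The bi-objective (min sum p_j F_j, min H) is
# scalarized with weighted coefficients; over the probability simplex its
# minimizer sits on the vertex of the best population, so the scalarized
# problem and min_j F_j share their optimal solution.

#' GA configuration
#'
#' @param m number of populations (default 16).
#' @param pop_size individuals per population.
#' @param n_generations maximum generations.
#' @param crossover_rate,mutation_rate probabilities in `[0, 1]`.
#' @param entropy_weights `c(w1, w2)` weights of the mean-fitness and entropy
#'   terms in the scalarized objective (both >= 0, not both 0).
#' @param narrowing enable per-population search-space narrowing.
#' @param prob_method `"softmax"` (softmax of per-generation standardized,
#'   negated best fitnesses; shift- and scale-invariant) or `"rank"`
#'   (`p_j = 2 (m - rank_j + 1) / (m (m + 1))`).
#' @param softmax_temperature temperature of the softmax method (smaller =
#'   greedier).
#' @param elitism keep each population's best member unchanged.
#' @param mutation_sigma mutation standard deviation as a fraction of the
#'   current per-variable extent.
#' @param early_stop_tol,early_stop_window stop early when the relative
#'   improvement of the global best over `early_stop_window` generations
#'   falls below `early_stop_tol`.
#' @param seed optional integer; if given, [evolve()] seeds its own stream
#'   (and restores the caller's), otherwise it continues the ambient stream.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(m = 16L, pop_size = 20L, n_generations = 25L,
                      crossover_rate = 0.9, mutation_rate = 0.15,
                      entropy_weights = c(1, 0.1), narrowing = TRUE,
                      prob_method = c("softmax", "rank"),
                      softmax_temperature = 0.5, elitism = TRUE,
                      mutation_sigma = 0.1,
                      early_stop_tol = 1e-4, early_stop_window = 5L,
                      seed = NULL) {
  if (m < 2L) stop("m must be >= 2", call. = FALSE)
  stopifnot(pop_size >= 2L, n_generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (length(entropy_weights) != 2L || any(entropy_weights < 0) ||
      sum(entropy_weights) == 0)
    stop("entropy_weights must be two non-negative values, not both 0",
         call. = FALSE)
  structure(list(m = as.integer(m), pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 entropy_weights = entropy_weights,
                 narrowing = isTRUE(narrowing),
                 prob_method = match.arg(prob_method),
                 softmax_temperature = softmax_temperature,
                 elitism = isTRUE(elitism),
                 mutation_sigma = mutation_sigma,
                 early_stop_tol = early_stop_tol,
                 early_stop_window = as.integer(early_stop_window),
                 seed = seed),
            class = "ga_config")
}

.check_bounds <- function(bounds) {
  if (!is.matrix(bounds) || nrow(bounds) != 2L)
    stop("bounds must be a 2 x d matrix (rows: lower, upper)", call. = FALSE)
  if (any(!is.finite(bounds)) || any(bounds[1, ] >= bounds[2, ]))
    stop("degenerate bounds: need lower < upper per variable", call. = FALSE)
  bounds
}

#' Initialize the populations
#'
#' All `m` populations share the same initial design space and are filled
#' with uniform-random individuals.
#'
#' @param bounds 2 x d matrix, rows = (lower, upper).
#' @param cfg a [ga_config()].
#' @return list of `m` population states, each with fields `lower`, `upper`,
#'   `init_lower`, `init_upper`, `E` (current per-variable extent),
#'   `individuals` (pop_size x d), `best_x`, `best_f`.
#' @export
init_populations <- function(bounds, cfg) {
  .check_bounds(bounds)
  d <- ncol(bounds)
  lapply(seq_len(cfg$m), function(j) {
    ind <- matrix(runif(cfg$pop_size * d, rep(bounds[1, ], each = cfg$pop_size),
                        rep(bounds[2, ], each = cfg$pop_size)),
                  nrow = cfg$pop_size)
    list(lower = bounds[1, ], upper = bounds[2, ],
         init_lower = bounds[1, ], init_upper = bounds[2, ],
         E = bounds[2, ] - bounds[1, ],
         individuals = ind, best_x = NULL, best_f = Inf)
  })
}

#' Occurrence probabilities of the populations
#'
#' Maps per-population best fitnesses to probabilities on the simplex,
#' strictly decreasing in fitness (lower/better fitness receives higher
#' probability) and invariant to adding a constant to all fitnesses.
#'
#' @param best_fitnesses numeric vector of per-population best (minimal)
#'   fitness values.
#' @param method,temperature see [ga_config()].
#' @return probability vector summing to 1.
#' @export
update_probabilities <- function(best_fitnesses,
                                 method = c("softmax", "rank"),
                                 temperature = 0.5) {
  if (any(!is.finite(best_fitnesses)))
    stop("non-finite fitness", call. = FALSE)
  m <- length(best_fitnesses)
  method <- match.arg(method)
  if (method == "rank") {
    r <- rank(best_fitnesses, ties.method = "average")
    p <- 2 * (m - r + 1) / (m * (m + 1))
    return(p / sum(p))
  }
  s <- sd(best_fitnesses)
  if (!is.finite(s) || s == 0) return(rep(1 / m, m))
  z <- (best_fitnesses - mean(best_fitnesses)) / s
  w <- exp(-z / temperature)
  w / sum(w)
}

#' Information entropy of the population probabilities
#'
#' `H = -sum p_j ln p_j` with the convention `0 ln 0 = 0`; bounded by
#' `0 <= H <= ln(m)`.
#'
#' @param p probability vector (must sum to 1).
#' @return the entropy H.
#' @export
entropy <- function(p) {
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("p is not a probability vector", call. = FALSE)
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Narrow a population's search space
#'
#' Applies the narrowing recursion: the per-variable extent shrinks as
#' `E(K) = (1 - p_j) E(K-1)` and the bounds are re-centered on the
#' population's best member, clamped so they never exceed the initial design
#' space. Individuals falling outside the new bounds are re-drawn uniformly
#' inside them.
#'
#' @param pop a population state (see [init_populations()]).
#' @param p_j the population's occurrence probability in `[0, 1]`.
#' @param K iteration index (informational; the extent recursion state lives
#'   in `pop$E`).
#' @return the narrowed population state.
#' @export
narrow_space <- function(pop, p_j, K = NA_integer_) {
  stopifnot(p_j >= 0, p_j <= 1)
  if (is.null(pop$best_x)) return(pop)
  E_new <- (1 - p_j) * pop$E
  lower <- pmax(pop$best_x - 0.5 * E_new, pop$init_lower)
  upper <- pmin(pop$best_x + 0.5 * E_new, pop$init_upper)
  pop$E <- E_new
  pop$lower <- lower
  pop$upper <- upper
  ind <- pop$individuals
  for (i in seq_len(nrow(ind))) {
    out <- ind[i, ] < lower | ind[i, ] > upper
    if (any(out))
      ind[i, out] <- runif(sum(out), lower[out], upper[out])
  }
  pop$individuals <- ind
  pop
}

#' Weighted-coefficient scalarization of the entropy bi-objective
#'
#' `w1 * sum(p_j F_j) + w2 * H(p)`. Over the probability simplex the
#' minimizer of this scalar is the degenerate distribution on the best
#' population (H = 0 there), so its argmin coincides with `min_j F_j`; see
#' [optimal_probabilities()].
#'
#' @param best_fitnesses per-population best fitness values.
#' @param p probability vector.
#' @param cfg a [ga_config()] (supplies `entropy_weights`).
#' @return scalar objective value.
#' @export
aggregate_objective <- function(best_fitnesses, p, cfg = ga_config()) {
  w <- cfg$entropy_weights
  w[1] * sum(p * best_fitnesses) + w[2] * entropy(p)
}

#' Simplex minimizer of the scalarized objective
#'
#' Returns the probability vector minimizing [aggregate_objective()] over
#' the simplex: all mass on the population with minimal best fitness (first
#' such population on ties).
#'
#' @inheritParams aggregate_objective
#' @return probability vector.
#' @export
optimal_probabilities <- function(best_fitnesses, cfg = ga_config()) {
  p <- numeric(length(best_fitnesses))
  p[which.min(best_fitnesses)] <- 1
  p
}

# tournament selection (size 2) of nrow(ind) parents, by fitness (minimize)
.select_parents <- function(ind, fit) {
  n <- nrow(ind)
  a <- sample.int(n, n, replace = TRUE)
  b <- sample.int(n, n, replace = TRUE)
  win <- ifelse(fit[a] <= fit[b], a, b)
  ind[win, , drop = FALSE]
}

# blend crossover of consecutive parent pairs (BLX-alpha, alpha = 0.5)
.crossover <- function(parents, rate) {
  n <- nrow(parents); d <- ncol(parents)
  out <- parents
  for (i in seq(1L, n - 1L, by = 2L)) {
    if (runif(1) < rate) {
      u <- runif(d, -0.5, 1.5)
      x1 <- parents[i, ]; x2 <- parents[i + 1L, ]
      out[i, ] <- x1 + u * (x2 - x1)
      out[i + 1L, ] <- x2 + u * (x1 - x2)
    }
  }
  out
}

.mutate <- function(ind, rate, sigma_frac, lower, upper) {
  n <- nrow(ind); d <- ncol(ind)
  hit <- matrix(runif(n * d) < rate, n, d)
  if (any(hit)) {
    sig <- rep(sigma_frac * (upper - lower), each = n)
    ind[hit] <- ind[hit] + rnorm(sum(hit)) * matrix(sig, n, d)[hit]
  }
  ind
}

.clip <- function(ind, lower, upper) {
  d <- ncol(ind)
  for (k in seq_len(d)) ind[, k] <- pmin(pmax(ind[, k], lower[k]), upper[k])
  ind
}

#' Run the multi-population entropy GA
#'
#' Minimizes `fitness` over the box `bounds`. Per generation: evaluate all
#' individuals, update each population's historical best, compute the
#' occurrence probabilities and entropy, narrow each population's space
#' around its best member, then apply tournament selection, blend crossover
#' and Gaussian mutation within each population (with elitism). Individuals
#' are never evaluated outside the initial design space, and the recorded
#' global best is non-increasing.
#'
#' @param fitness function taking a length-d numeric vector, returning a
#'   scalar; non-finite values are replaced by the worst finite fitness of
#'   the generation (and counted in the result).
#' @param bounds 2 x d matrix, rows = (lower, upper).
#' @param cfg a [ga_config()].
#' @return list with `best_x`, `best_f`, `history` (data frame: generation,
#'   best_f, H, aggregate, mean_E), `E_history` (generations x m matrix of
#'   mean per-population extents), `n_evaluations`, `n_nonfinite`,
#'   `converged`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- evolve(sphere, rbind(c(-pi, 0), c(pi, pi / 2)),
#'               ga_config(pop_size = 10, n_generations = 10, seed = 1))
#' res$best_f
#' @export
evolve <- function(fitness, bounds, cfg = ga_config()) {
  .check_bounds(bounds)
  runner <- function() {
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    pops <- init_populations(bounds, cfg)
    d <- ncol(bounds)
    best_x <- NULL; best_f <- Inf
    hist_rows <- vector("list", cfg$n_generations)
    E_hist <- matrix(NA_real_, cfg$n_generations, cfg$m)
    n_eval <- 0L; n_nonfinite <- 0L
    best_trace <- numeric(0)
    converged <- FALSE

    for (K in seq_len(cfg$n_generations)) {
      for (j in seq_len(cfg$m)) {
        fit <- apply(pops[[j]]$individuals, 1L, fitness)
        n_eval <- n_eval + length(fit)
        bad <- !is.finite(fit)
        if (any(bad)) {
          n_nonfinite <- n_nonfinite + sum(bad)
          worst <- if (all(bad)) Inf else max(fit[!bad])
          fit[bad] <- worst
        }
        pops[[j]]$fitness <- fit
        i_best <- which.min(fit)
        if (fit[i_best] < pops[[j]]$best_f) {
          pops[[j]]$best_f <- fit[i_best]
          pops[[j]]$best_x <- pops[[j]]$individuals[i_best, ]
        }
      }
      Fj <- vapply(pops, `[[`, 0, "best_f")
      gen_best <- which.min(Fj)
      if (Fj[gen_best] < best_f) {
        best_f <- Fj[gen_best]
        best_x <- pops[[gen_best]]$best_x
      }
      p <- update_probabilities(Fj, cfg$prob_method, cfg$softmax_temperature)
      H <- entropy(p)
      agg <- aggregate_objective(Fj, p, cfg)
      E_hist[K, ] <- vapply(pops, function(q) mean(q$E), 0)
      hist_rows[[K]] <- data.frame(generation = K, best_f = best_f, H = H,
                                   aggregate = agg,
                                   mean_E = mean(E_hist[K, ]))
      best_trace <- c(best_trace, best_f)

      # early stopping on stagnation of the global best; a run that exhausts
      # its generations while still improving is flagged unconverged
      wnd <- cfg$early_stop_window
      if (K > wnd) {
        prev <- best_trace[K - wnd]
        rel <- (prev - best_f) / max(abs(prev), 1e-12)
        if (rel < cfg$early_stop_tol) { converged <- TRUE; break }
      }
      if (K == cfg$n_generations) break

      for (j in seq_len(cfg$m)) {
        if (cfg$narrowing) pops[[j]] <- narrow_space(pops[[j]], p[j], K)
        pop <- pops[[j]]
        parents <- .select_parents(pop$individuals, pop$fitness)
        kids <- .crossover(parents, cfg$crossover_rate)
        kids <- .mutate(kids, cfg$mutation_rate, cfg$mutation_sigma,
                        pop$lower, pop$upper)
        kids <- .clip(kids, pop$lower, pop$upper)
        if (cfg$elitism && !is.null(pop$best_x)) {
          elite <- pmin(pmax(pop$best_x, pop$lower), pop$upper)
          kids[1L, ] <- elite
        }
        pops[[j]]$individuals <- kids
      }
    }
    list(best_x = best_x, best_f = best_f,
         history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)]),
         E_history = E_hist[seq_along(best_trace), , drop = FALSE],
         n_evaluations = n_eval, n_nonfinite = n_nonfinite,
         converged = converged)
  }
  if (!is.null(cfg$seed)) .with_preserved_rng(runner()) else runner()
}

#' Built-in demo objectives
#'
#' `"sphere"`: convex quadratic bowl centered at (0.5, 0.7). `"bimodal"`:
#' two Gaussian wells of depth 2 (global, at (-2, 0.5)) and 1 (local, at
#' (2, 1)) separated by a barrier.
#'
#' @param name objective name.
#' @return a function of a length-2 numeric vector.
#' @export
demo_objective <- function(name = c("sphere", "bimodal")) {
  name <- match.arg(name)
  switch(name,
    sphere = function(x) (x[1] - 0.5)^2 + 2 * (x[2] - 0.7)^2,
    bimodal = function(x) {
      -2 * exp(-((x[1] + 2)^2 + (x[2] - 0.5)^2) / 0.3) -
        1 * exp(-((x[1] - 2)^2 + (x[2] - 1)^2) / 0.3)
    })
}
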