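# Multi-population entropy GA: probability/entropy/narrowing algebra and
# optimization quality against brute-force oracles.

test_that("initial populations are uniform in the shared design space", {
  bounds <- rbind(c(-pi, 0), c(pi, pi / 2))
  cfg <- ga_config(m = 16, pop_size = 20)
  set.seed(1)
  pops <- init_populations(bounds, cfg)
  expect_length(pops, 16L)
  all_ind <- do.call(rbind, lapply(pops, `[[`, "individuals"))
  expect_equal(nrow(all_ind), 320L)
  expect_true(all(all_ind[, 1] >= -pi & all_ind[, 1] <= pi))
  expect_true(all(all_ind[, 2] >= 0 & all_ind[, 2] <= pi / 2))
  # empirical means within 3 standard errors of the box midpoints
  for (k in 1:2) {
    mid <- mean(bounds[, k])
    se <- diff(bounds[, k]) / sqrt(12) / sqrt(nrow(all_ind))
    expect_lt(abs(mean(all_ind[, k]) - mid), 3 * se)
  }
  # seed determinism
  set.seed(7); a <- init_populations(bounds, cfg)
  set.seed(7); b <- init_populations(bounds, cfg)
  expect_identical(a, b)
  expect_error(init_populations(rbind(c(0, 0), c(0, 1)), cfg), "degenerate")
})

test_that("occurrence probabilities favour better populations", {
  # equal fitnesses: exactly uniform
  expect_equal(update_probabilities(rep(2.5, 16)), rep(1 / 16, 16))
  # near-degenerate gap: almost all mass on the better population
  p <- update_probabilities(c(0, 1e6))
  expect_gt(p[1], 0.9)
  expect_lt(p[2], 0.1)
  # strictly decreasing in fitness
  p2 <- update_probabilities(c(3, 1, 2, 5))
  expect_equal(order(p2, decreasing = TRUE), c(2, 3, 1, 4))
  # shift invariance (property over random draws)
  set.seed(2)
  for (i in 1:20) {
    F <- rnorm(8); c0 <- rnorm(1, sd = 100)
    expect_equal(update_probabilities(F), update_probabilities(F + c0),
                 tolerance = 1e-12)
  }
  # rank method matches its closed form
  pr <- update_probabilities(c(10, 20, 30), method = "rank")
  expect_equal(pr, 2 * (3 - (1:3) + 1) / (3 * 4))
  expect_error(update_probabilities(c(1, NaN)), "finite")
})

test_that("entropy follows the Shannon form with its bounds", {
  expect_equal(entropy(rep(1 / 16, 16)), log(16))
  expect_equal(entropy(c(1, rep(0, 7))), 0)
  set.seed(3)
  for (i in 1:50) {
    m <- sample(2:20, 1)
    w <- rexp(m); p <- w / sum(w)
    H <- entropy(p)
    expect_gte(H, 0)
    expect_lte(H, log(m) + 1e-12)
  }
  expect_error(entropy(c(0.5, 0.4)), "probability")
})

test_that("search-space narrowing follows the extent recursion exactly", {
  bounds <- rbind(c(0, -1), c(10, 1))
  cfg <- ga_config(m = 2, pop_size = 8)
  set.seed(4)
  pop <- init_populations(bounds, cfg)[[1]]
  pop$best_x <- c(7, 0.5)
  pop$best_f <- 0

  # p_j = 0: extent unchanged, bounds recentred on the best member but
  # clamped to the initial space
  n0 <- narrow_space(pop, 0)
  expect_equal(n0$E, pop$E)
  expect_equal(n0$lower, pmax(c(7, 0.5) - 0.5 * pop$E, bounds[1, ]))
  expect_equal(n0$upper, pmin(c(7, 0.5) + 0.5 * pop$E, bounds[2, ]))

  # p_j = 1: the space collapses onto the best member
  n1 <- narrow_space(pop, 1)
  expect_equal(n1$E, c(0, 0))
  expect_equal(n1$lower, c(7, 0.5))
  expect_equal(n1$upper, c(7, 0.5))

  # constant p: E(K) = (1 - p)^K E(0) to 1e-12
  q <- pop
  for (K in 1:6) q <- narrow_space(q, 0.3, K)
  expect_equal(q$E, 0.7^6 * pop$E, tolerance = 1e-12)
  # individuals always inside the narrowed bounds
  expect_true(all(sweep(q$individuals, 2, q$lower, `>=`)))
  expect_true(all(sweep(q$individuals, 2, q$upper, `<=`)))
})

test_that("the scalarized bi-objective reduces correctly and is minimized on a vertex", {
  F <- c(4, 1, 3)
  cfg0 <- ga_config(m = 3, entropy_weights = c(1, 0))
  p <- c(0.2, 0.5, 0.3)
  expect_equal(aggregate_objective(F, p, cfg0), sum(p * F))
  expect_equal(aggregate_objective(F, rep(1 / 3, 3), cfg0), mean(F))

  # grid search over the m = 2 simplex agrees with the analytic vertex optimum
  cfg <- ga_config(m = 2, entropy_weights = c(1, 0.1))
  F2 <- c(2, 5)
  grid <- seq(0, 1, by = 1e-4)
  vals <- vapply(grid, function(a) aggregate_objective(F2, c(a, 1 - a), cfg), 0)
  p_star <- optimal_probabilities(F2, cfg)
  expect_equal(c(grid[which.min(vals)], 1 - grid[which.min(vals)]), p_star)
  expect_equal(min(vals), aggregate_objective(F2, p_star, cfg))
})

test_that("the population with minimal best fitness gets maximal probability and the aggregate argmin matches", {
  # enumerable toy: each population's fitness is constant
  F <- c(7, 3, 9, 5)
  p <- update_probabilities(F)
  expect_equal(which.max(p), which.min(F))
  # the aggregate over all vertex distributions is minimized at argmin_j F_j
  cfg <- ga_config(m = 4)
  vertex_vals <- vapply(1:4, function(j) {
    pv <- numeric(4); pv[j] <- 1
    aggregate_objective(F, pv, cfg)
  }, 0)
  expect_equal(which.min(vertex_vals), which.min(F))
})

test_that("evolve matches a dense grid oracle on a convex bowl", {
  bounds <- rbind(c(-pi, 0), c(pi, pi / 2))
  bowl <- demo_objective("sphere")
  # oracle: dense grid minimum
  gx <- seq(-pi, pi, length.out = 500)
  gy <- seq(0, pi / 2, length.out = 200)
  grid_min <- min(outer(gx, gy, function(a, b) (a - 0.5)^2 + 2 * (b - 0.7)^2))
  for (seed in 1:5) {
    res <- evolve(bowl, bounds, ga_config(seed = seed))
    expect_lt(res$best_f, grid_min + 1e-3)
    expect_equal(res$best_x, c(0.5, 0.7), tolerance = 0.05)
  }
})

test_that("evolve finds the global basin of a bimodal objective", {
  bounds <- rbind(c(-4, -1), c(4, 3))
  f <- demo_objective("bimodal")
  hits <- 0L
  for (seed in 1:10) {
    res <- evolve(f, bounds, ga_config(seed = seed))
    if (sqrt(sum((res$best_x - c(-2, 0.5))^2)) < 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("evolve is elitist, bounded, deterministic, and robust to bad fitness", {
  bounds <- rbind(c(-2, -2), c(2, 2))
  bad_count <- 0L
  f <- function(x) {
    if (abs(x[1] - 1) < 0.05) return(NaN)  # a crack of invalid fitness
    sum(x^2)
  }
  res <- evolve(f, bounds, ga_config(m = 4, pop_size = 10, n_generations = 12,
                                     seed = 5))
  # recorded global best is non-increasing
  expect_true(all(diff(res$history$best_f) <= 0))
  # entropy bounded by ln m each generation
  expect_true(all(res$history$H >= 0 & res$history$H <= log(4) + 1e-12))
  expect_gt(res$n_nonfinite, 0L)
  expect_true(is.finite(res$best_f))

  res2 <- evolve(f, bounds, ga_config(m = 4, pop_size = 10, n_generations = 12,
                                      seed = 5))
  expect_identical(res$best_x, res2$best_x)
  expect_identical(res$history, res2$history)
})

test_that("no individual is ever evaluated outside the initial design space", {
  bounds <- rbind(c(-1, 0), c(1, 2))
  seen <- new.env(); seen$bad <- 0L
  f <- function(x) {
    if (x[1] < -1 - 1e-12 || x[1] > 1 + 1e-12 ||
        x[2] < -1e-12 || x[2] > 2 + 1e-12) seen$bad <- seen$bad + 1L
    (x[1] + 0.3)^2 + (x[2] - 1.2)^2
  }
  invisible(evolve(f, bounds, ga_config(m = 6, pop_size = 8,
                                        n_generations = 15, seed = 2)))
  expect_identical(seen$bad, 0L)
})
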