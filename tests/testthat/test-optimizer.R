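# Direction parameterization, trigger logic, trial-segment evaluation and
# the full self-adaptive driver.

test_that("directions from angles satisfy the closed-form geometry", {
  n0 <- c(0, 0, 1)
  expect_equal(direction_from_angles(0, 1.2, n0), n0)
  d90 <- direction_from_angles(pi / 2, 0.4, n0)
  expect_equal(sum(d90 * n0), 0, tolerance = 1e-12)

  set.seed(10)
  for (i in 1:1000) {
    th <- runif(1, 0, pi / 2); ph <- runif(1, -pi, pi)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    d <- direction_from_angles(th, ph, axis)
    expect_equal(sum(d^2), 1, tolerance = 1e-12)
    expect_equal(sum(d * axis), cos(th), tolerance = 1e-12)
  }
  expect_error(direction_from_angles(2, 0, n0), "theta")
  expect_error(direction_from_angles(0.3, 4, n0), "phi")
})

test_that("the optimization trigger requires both elapsed time and force", {
  cfg <- controller_config(t0 = 5, f0_pN = 250)
  f_lo <- force_from_pn(200)
  f_hi <- force_from_pn(260)
  # only 4 ps elapsed: never, regardless of force
  expect_false(should_optimize(104, 100, f_hi, cfg))
  expect_false(should_optimize(104, 100, 1e6, cfg))
  # 6 ps elapsed, force above the cut-off: fire
  expect_true(should_optimize(106, 100, f_hi, cfg))
  # 6 ps elapsed, force below: hold
  expect_false(should_optimize(106, 100, f_lo, cfg))
  # the elapsed-time comparison is strict
  expect_false(should_optimize(105, 100, f_hi, cfg))
})

test_that("trial evaluations use common random numbers and leave state untouched", {
  l <- std_landscape()
  cfg <- fast_config()
  s <- sim_state(l$center, seed = 21)
  s <- equilibrate(s, l, 5, cfg$engine)
  pull <- pull_spec(k = cfg$k, v = cfg$v, n = cfg$n0, r_ref = s$r,
                    t_start = s$t, x_offset = 0.5)
  snap <- checkpoint(s)

  f1 <- trial_average_force(snap, 0.3, 1.0, pull, cfg, l)
  f2 <- trial_average_force(snap, 0.3, 1.0, pull, cfg, l)
  expect_identical(f1, f2)

  # the caller's stream and the snapshot are unaffected by trials
  before <- .Random.seed
  invisible(trial_average_force(snap, 0.7, -2, pull, cfg, l))
  expect_identical(.Random.seed, before)
  expect_identical(restore(snap)$r, s$r)
})

test_that("trial force is phi-invariant on an isotropic landscape at T = 0", {
  l <- make_harmonic_landscape(stiffness = 800)
  cfg <- controller_config(engine = engine_params(temperature = 0))
  s <- sim_state(c(0, 0, 0), t = 0, seed = 1)
  pull <- pull_spec(k = 200, v = 0.002, n = c(0, 0, 1), r_ref = c(0, 0, 0),
                    t_start = 0, x_offset = 0.4)
  snap <- checkpoint(s)
  vals <- vapply(seq(-pi, pi, length.out = 9), function(ph)
    trial_average_force(snap, 0.6, ph, pull, cfg, l), 0)
  expect_lt(max(vals) - min(vals), 1e-9)
})

test_that("a trial grid locates the soft channel at T = 0", {
  l <- std_landscape()
  cfg <- controller_config(engine = engine_params(temperature = 0))
  # tensioned state at the pocket bottom
  s <- sim_state(l$center, t = 0, seed = 1)
  pull <- pull_spec(k = cfg$k, v = cfg$v, n = cfg$n0, r_ref = s$r,
                    t_start = 0, x_offset = 0.55)
  snap <- checkpoint(s)
  phis <- seq(-pi, pi, length.out = 37)[-37]
  thetas <- seq(0, pi / 2, length.out = 9)
  gr <- expand.grid(phi = phis, theta = thetas)
  vals <- mapply(function(ph, th)
    trial_average_force(snap, th, ph, pull, cfg, l), gr$phi, gr$theta)
  best <- gr[which.min(vals), ]
  d <- direction_from_angles(best$theta, best$phi, cfg$n0)
  soft <- l$channels[[1]]$direction
  angle <- acos(pmin(1, sum(d * soft))) * 180 / pi
  expect_lt(angle, 15)

  # the GA finds a direction at least as good as pulling along n0, close to
  # the grid optimum and the soft channel
  opt <- optimize_direction(snap, pull, cfg,
                            ga_config(m = 8, pop_size = 8, n_generations = 8,
                                      seed = 2), l)
  f_n0 <- trial_average_force(snap, 0, 0, pull, cfg, l)
  expect_lte(opt$record$objective_value, f_n0)
  expect_lte(opt$record$objective_value, min(vals) + 1.0)
  d_ga <- opt$direction
  expect_lt(acos(pmin(1, sum(d_ga * soft))) * 180 / pi, 15)
  # the record's objective is exactly the trial force of the chosen angles
  expect_equal(opt$record$objective_value,
               trial_average_force(snap, opt$record$theta, opt$record$phi,
                                   pull, cfg, l))
})

test_that("SA-SMD with an infinite trigger is bit-identical to C-SMD", {
  l <- std_landscape()
  cfg <- fast_config(f0_pN = Inf)
  a <- run_csmd(l, cfg, seed = 9)
  b <- run_sasmd(l, cfg, seed = 9)
  expect_identical(a$rupture_force, b$rupture_force)
  expect_identical(a$end_time, b$end_time)
  expect_identical(a$profile$f_avg, b$profile$f_avg)
  expect_identical(a$final_state$r, b$final_state$r)
  expect_equal(b$n_direction_switches, 0L)
})

test_that("SA-SMD runs are reproducible and respect the hemisphere and trigger contracts", {
  l <- std_landscape()
  cfg <- fast_config()
  res <- run_sasmd(l, cfg, seed = 2)
  res2 <- run_sasmd(l, cfg, seed = 2)
  expect_identical(res$rupture_force, res2$rupture_force)
  expect_identical(res$n_direction_switches, res2$n_direction_switches)

  expect_gte(res$n_direction_switches, 1L)
  # every adopted direction lies in the hemisphere of n0
  dirs <- t(vapply(res$records, function(rec)
    direction_from_angles(rec$theta, rec$phi, cfg$n0), numeric(3)))
  expect_true(all(dirs %*% cfg$n0 >= -1e-12))
  # consecutive optimizations are separated by more than t0
  t_opt <- vapply(res$records, `[[`, 0, "t_opt")
  expect_true(all(diff(t_opt) > cfg$t0))
  # and each fired above the trigger force
  expect_gt(min(vapply(res$records, `[[`, 0, "f_recent")), cfg$f0)
})

test_that("SA-SMD lowers the rupture force on the anisotropic landscape", {
  l <- std_landscape()
  cfg <- fast_config()
  cs <- vapply(1:5, function(s) run_csmd(l, cfg, seed = s)$rupture_force_pN, 0)
  sa <- vapply(1:5, function(s) run_sasmd(l, cfg, seed = s)$rupture_force_pN, 0)
  expect_lt(mean(sa), mean(cs))
  # re-optimization cycles make dissociation slower, not faster: the
  # self-adaptive pathway is the more tortuous one in most paired runs
  cs_end <- vapply(1:5, function(s) run_csmd(l, cfg, seed = s)$end_time, 0)
  sa_end <- vapply(1:5, function(s) run_sasmd(l, cfg, seed = s)$end_time, 0)
  expect_gte(sum(sa_end >= cs_end), 3L)
})

test_that("optimization logs export the per-switch record", {
  l <- std_landscape()
  res <- run_sasmd(l, fast_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_optimization_log(res, path)
  df <- read.csv(path)
  expect_equal(nrow(df), res$n_direction_switches)
  expect_true(all(c("t_opt_ps", "theta_rad", "phi_rad", "objective_pN",
                    "n_evals") %in% names(df)))
})
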