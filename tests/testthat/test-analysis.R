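# Experiment orchestration: sweeps, family runs, correlation analysis, I/O.

test_that("pearson matches the long-form covariance computation", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  long_form <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), long_form, tolerance = 1e-12)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, rep(3, 4)), "constant")
  expect_error(pearson(x, y[1:3]), "equal-length")
  expect_error(pearson(c(1, 2), c(3, 4)), "3 observations")
})

test_that("sweep tables carry the C-SMD reference row labelled Inf", {
  l <- std_landscape()
  cfg <- fast_config()
  sp <- sweep_spec("cutoff_force", c(300, 250), n_seeds = 2,
                   base_config = cfg)
  tab <- run_sweep(sp, l)
  expect_equal(nrow(tab), 6L)  # 2 values x 2 seeds + 2 C-SMD reference rows
  expect_true(any(is.infinite(tab$value)))
  ref <- tab[is.infinite(tab$value), ]
  expect_true(all(ref$n_switches == 0))
  expect_false(any(tab$failed))
  # lower trigger force, more optimizations (aggregated over this table)
  m <- aggregate(n_switches ~ value, tab[is.finite(tab$value), ], mean)
  expect_gte(m$n_switches[m$value == 250], m$n_switches[m$value == 300])
  expect_error(sweep_spec("cutoff_force", 400), "2 sweep values")
})

test_that("family runs summarize repeats with standard errors", {
  fam <- make_family(family_spec(3, c(35, 60)))
  cfg <- fast_config()
  fr <- run_family(fam, cfg, n_repeats = 2, seeds = c(1, 2),
                   f0_fraction = 0.75)
  expect_s3_class(fr, "family_run_result")
  expect_equal(nrow(fr), 3L)
  expect_true(all(fr$n_runs == 2L))
  expect_true(all(is.finite(fr$std_error_pN)))
  expect_true(all(fr$f0_pN < fr$csmd_rupture_force_pN))
  # determinism of the whole experiment
  fr2 <- run_family(fam, cfg, n_repeats = 2, seeds = c(1, 2),
                    f0_fraction = 0.75)
  expect_identical(fr$mean_rupture_force_pN, fr2$mean_rupture_force_pN)
  # a single repeat reports no standard error
  fr1 <- run_family(fam[1:2], cfg, n_repeats = 1, f0_fraction = 0.75)
  expect_true(all(is.na(fr1$std_error_pN)))
  # deeper wells resist unbinding more strongly
  expect_gt(cor(fr$well_depth, fr$mean_rupture_force_pN, method = "spearman"), 0)
})

test_that("correlation reports are self-consistent with their own table", {
  fr <- structure(
    data.frame(member_id = sprintf("m%02d", 1:5),
               well_depth = c(20, 30, 40, 50, 60),
               reference_energy = -c(20, 30, 40, 50, 60),
               mean_rupture_force_pN = c(150, 180, 230, 255, 300),
               std_error_pN = rep(5, 5), n_runs = 4L, failed = FALSE),
    class = c("family_run_result", "data.frame"))
  rep_ <- correlation_report(fr)
  expect_equal(rep_$r,
               pearson(rep_$table$reference_energy,
                       rep_$table$mean_rupture_force_pN))
  # deeper well (more negative reference energy) => larger rupture force
  expect_lt(rep_$r, 0)
  expect_lt(rep_$slope, 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_correlation_report(rep_, path)
  df <- read.csv(path)
  expect_equal(pearson(df$reference_energy, df$mean_rupture_force_pN), rep_$r)

  # a family with no depth spread has an undefined correlation
  fr$reference_energy <- rep(-40, 5)
  expect_error(correlation_report(fr), "constant")
})

test_that("mode comparisons pair C-SMD and SA-SMD on identical seeds", {
  l <- std_landscape()
  cfg <- fast_config()
  cmp <- compare_modes(l, cfg, seeds = 1:2)
  expect_equal(nrow(cmp$pairs), 2L)
  expect_true(all(cmp$pairs$sasmd_switches >= 1))
  # degenerate trigger: per-seed results identical to C-SMD, bit-exact
  cfg_inf <- fast_config(f0_pN = Inf)
  cmp_inf <- compare_modes(l, cfg_inf, seeds = 3L)
  expect_identical(cmp_inf$pairs$csmd_rupture_pN,
                   cmp_inf$pairs$sasmd_rupture_pN)
  expect_identical(cmp_inf$pairs$csmd_end_ps, cmp_inf$pairs$sasmd_end_ps)
})

test_that("a control pocket with its channel along n0 offers no adaptive advantage", {
  # single exit channel aligned with the pulling axis; the trigger is set
  # near the conventional rupture force so re-optimization cannot relieve
  # tension before rupture: both modes should agree within noise
  l <- axial_landscape()
  cfg0 <- fast_config()
  c_ref <- mean(vapply(1:3, function(s)
    run_csmd(l, cfg0, seed = s)$rupture_force_pN, 0))
  cfg <- fast_config(f0_pN = 0.95 * c_ref)
  cmp <- compare_modes(l, cfg, seeds = 1:3)
  rel <- abs(cmp$means["sasmd_rupture_pN"] - cmp$means["csmd_rupture_pN"]) /
    cmp$means["csmd_rupture_pN"]
  expect_lt(rel, 0.1)
})

test_that("runs ledger and trajectory writers produce well-formed files", {
  l <- std_landscape()
  cfg <- fast_config()
  res <- run_csmd(l, cfg, seed = 1)
  ledger <- withr::local_tempfile(fileext = ".csv")
  append_runs_ledger(res, cfg, ledger, run_id = "a")
  append_runs_ledger(res, cfg, ledger, run_id = "b")
  df <- read.csv(ledger)
  expect_equal(nrow(df), 2L)
  expect_equal(df$mode, c("csmd", "csmd"))
  expect_equal(df$rupture_force_pN, rep(res$rupture_force_pN, 2))

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(res$trajectory, res$trajectory_t, xyz)
  lines <- readLines(xyz)
  expect_equal(length(lines), 3L * nrow(res$trajectory))
  expect_equal(lines[1], "1")
  # coordinates on the atom lines match the trajectory
  coords <- as.numeric(strsplit(trimws(lines[3]), "\\s+")[[1]][2:4])
  expect_equal(coords, unname(res$trajectory[1, ]), tolerance = 1e-3)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(res$trajectory, res$trajectory_t, csv)
  df2 <- read.csv(csv)
  expect_equal(df2$t, res$trajectory_t)
  expect_equal(df2$z, res$trajectory[, 3])
})

test_that("configuration files round-trip into the package objects", {
  path <- system.file("extdata", "example_config.yaml", package = "sasmd")
  cfgs <- read_config(path)
  expect_equal(cfgs$controller$k, 200)
  expect_equal(cfgs$controller$v, 0.002)
  expect_equal(cfgs$controller$t0, 5)
  expect_equal(cfgs$controller$f0_pN, 250)
  expect_equal(cfgs$controller$cutoff_separation, 0.6)
  expect_equal(cfgs$ga$m, 16L)
  l <- make_funnel_landscape(cfgs$landscape_params)
  expect_equal(l$well_depth, 50)
  expect_length(l$channels, 2L)
  # a config file with overrides
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("controller:", "  v: 0.005", "  f0_pN: 300"), tmp)
  over <- read_config(tmp)
  expect_equal(over$controller$v, 0.005)
  expect_equal(over$controller$f0, 300 / 1.66054, tolerance = 1e-6)
})
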